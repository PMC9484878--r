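#' mRMR feature ranking (MID criterion)
#'
#' Greedy minimum-redundancy maximum-relevance ordering.  Continuous
#' features are discretized into three bins at mean +/- one standard
#' deviation (the classical mRMR convention); relevance and redundancy
#' are mutual information computed from the discretized contingency
#' tables.  The first feature maximizes MI with the labels; each later
#' pick maximizes the MID (difference) criterion
#' `MI(f; labels) - mean over selected s of MI(f; s)`.  Ties are broken
#' by original column order, so the ranking is fully deterministic.
#'
#' @param fm A `feature_matrix`.
#' @param labels Labels tibble (`protein`, `class_index`) or vector.
#' @param k Number of features to rank (default: all).
#' @return A `ranked_features` tibble (rank, feature, group, source,
#'   score), where `score` is the criterion value at selection time
#'   (plain relevance for rank 1).
#' @export
mrmr_rank <- function(fm, labels, k = NULL) {
  al <- align_labels(fm, labels)
  x <- al$x; lab <- al$labels
  d <- ncol(x)
  if (is.null(k)) k <- d
  check_count(k, "k")
  if (k > d) abort("`k` exceeds the number of features",
                   class = "sublocfs_config_error")
  xd <- apply(x, 2, discretize_3bin)
  y <- match(lab, sort(unique(lab)))
  n_y <- length(unique(y))

  rel <- vapply(seq_len(d), function(j) mi_disc(xd[, j], 3L, y, n_y),
                numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(d)
  candidate <- rep(TRUE, d)
  for (step in seq_len(k)) {
    crit <- if (step == 1) rel else rel - red_sum / length(selected)
    crit[!candidate] <- -Inf
    pick <- which.max(crit)               # first maximum = column-order tie-break
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    candidate[pick] <- FALSE
    if (step < k) {
      idx <- which(candidate)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
        mi_disc(xd[, j], 3L, xd[, pick], 3L)
      }, numeric(1))
    }
  }
  scores_full <- numeric(d)
  scores_full[selected] <- scores
  rank_result(colnames(x), scores_full, selected, "mrmr")
}

# 3-bin discretization at mean +/- sd; constant columns collapse to bin 2
discretize_3bin <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) return(rep(2L, length(v)))
  m <- mean(v)
  ifelse(v < m - s, 1L, ifelse(v > m + s, 3L, 2L))
}

# mutual information (nats) of two discrete vectors from joint counts
mi_disc <- function(a, n_a, b, n_b) {
  n <- length(a)
  joint <- tabulate((a - 1L) * n_b + b, nbins = n_a * n_b) / n
  pa <- tabulate(a, nbins = n_a) / n
  pb <- tabulate(b, nbins = n_b) / n
  pab <- outer(pb, pa)                  # column-major layout matches joint
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pab[nz]))
}
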