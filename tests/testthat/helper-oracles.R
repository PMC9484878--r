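# independent oracles and small fixture builders used across the suite

# hypergeometric upper tail by direct pmf enumeration
hyper_tail_oracle <- function(q, m, N, k) {
  lo <- max(q, 0, k - (N - m))
  hi <- min(k, m)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(i) {
    choose(m, i) * choose(N - m, k - i) / choose(N, k)
  }, numeric(1)))
}

# Rk multiclass MCC from a confusion matrix (closed form)
rk_confusion_oracle <- function(cm) {
  s <- sum(cm)
  c_trace <- sum(diag(cm))
  t_k <- rowSums(cm)   # actual counts
  p_k <- colSums(cm)   # predicted counts
  num <- c_trace * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

# textbook binary MCC from prediction vectors (positive class = 2)
binary_mcc_oracle <- function(pred, act) {
  tp <- sum(pred == 2 & act == 2); tn <- sum(pred == 1 & act == 1)
  fp <- sum(pred == 2 & act == 1); fn <- sum(pred == 1 & act == 2)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# entropy-based MI (different route than the implementation's plogp sum)
mi_entropy_oracle <- function(a, b) {
  h <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  h(a) + h(b) - h(paste(a, b))
}

disc3_oracle <- function(v) {
  s <- sd(v)
  if (is.na(s) || s == 0) return(rep(2L, length(v)))
  m <- mean(v)
  ifelse(v < m - s, 1L, ifelse(v > m + s, 3L, 2L))
}

# exhaustive greedy re-evaluation of the mRMR MID criterion
mrmr_oracle <- function(x, y, k = ncol(x)) {
  xd <- apply(x, 2, disc3_oracle)
  d <- ncol(x)
  rel <- vapply(seq_len(d), function(j) mi_entropy_oracle(xd[, j], y),
                numeric(1))
  sel <- integer(0)
  for (step in seq_len(k)) {
    crit <- vapply(seq_len(d), function(j) {
      if (j %in% sel) return(-Inf)
      if (step == 1) return(rel[j])
      rel[j] - mean(vapply(sel, function(s2) {
        mi_entropy_oracle(xd[, j], xd[, s2])
      }, numeric(1)))
    }, numeric(1))
    sel <- c(sel, which.max(crit))
  }
  sel
}

# pairwise lexicographic comparator for integrated features
integration_compare_oracle <- function(a, b) {
  # a, b: lists with selection_count, best_rank, mean_rank, feature
  if (a$selection_count != b$selection_count) {
    return(a$selection_count > b$selection_count)
  }
  if (a$best_rank != b$best_rank) return(a$best_rank < b$best_rank)
  if (a$mean_rank != b$mean_rank) return(a$mean_rank < b$mean_rank)
  a$feature < b$feature
}

# wrap a plain matrix as a feature_matrix tibble
make_fm <- function(x, prefix = "GO:f") {
  colnames(x) <- paste0(prefix, sprintf("%03d", seq_len(ncol(x))))
  out <- tibble::tibble(protein = sprintf("P%04d", seq_len(nrow(x))))
  out <- dplyr::bind_cols(out, tibble::as_tibble(x, .name_repair = "minimal"))
  class(out) <- c("feature_matrix", class(out))
  out
}

labels_for <- function(fm, y) {
  tibble::tibble(protein = fm$protein, class_index = as.integer(y))
}

small_dataset <- function(seed = 1, class_sizes = c(60L, 40L, 20L),
                          n_go = 25L, n_pw = 6L, density = 0.06, ipc = 2L) {
  simulate_dataset(simulation_config(
    class_sizes = class_sizes, n_go_terms = n_go, n_pathways = n_pw,
    edge_density = density, informative_terms_per_class = ipc,
    signal_strength = 0.9, background_rate = 0.05, seed = seed))
}

# a manually constructed IFS curve for the selection-rule tests
fake_curve <- function(sizes, mccs, method = "gbdt", algorithm = "rf") {
  per_class <- lapply(sizes, function(.) {
    tibble::tibble(class_index = 1:2, class_accuracy = c(1, 1),
                   class_n = c(5L, 5L))
  })
  sublocfs:::new_ifs_curve(
    tibble::tibble(size = as.integer(sizes), mcc = mccs, acc = mccs,
                   per_class = per_class),
    method = method, algorithm = algorithm, step = 1L, seed = 1L)
}
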