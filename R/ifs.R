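#' Incremental feature selection over a ranked list
#'
#' Evaluates nested prefixes of a ranked feature list: with step size s,
#' the prefixes of size s, 2s, ... (up to `max_size`) are each scored by
#' [evaluate_classifier()] under SMOTE-balanced stratified
#' cross-validation, producing the curve from which the optimal and a
#' compact near-optimal subset are read off.
#'
#' @param ranked A `ranked_features` list from one of the rankers.
#' @param fm The `feature_matrix` the list was computed on.
#' @param labels Labels tibble (`protein`, `class_index`) or vector.
#' @param algorithm `"rf"` or `"svm"` (see [evaluate_classifier()]).
#' @param step Prefix-size increment (default 1).
#' @param max_size Largest prefix to evaluate; clipped to the list length
#'   with a warning.  Default: the full list.
#' @param n_folds,balance,seed Passed to [evaluate_classifier()]; the
#'   per-prefix seed is derived from `seed` and the prefix size, so any
#'   single record can be reproduced in isolation.
#' @return An `ifs_curve`: a tibble with columns `size`, `mcc`, `acc` and
#'   a `per_class` list-column of per-class accuracy tibbles, carrying
#'   the ranking method, algorithm, step and seed as attributes.
#' @export
run_ifs <- function(ranked, fm, labels, algorithm = c("rf", "svm"),
                    step = 1L, max_size = NULL, n_folds = 10L,
                    balance = TRUE, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_features"), nrow(ranked) > 0)
  algorithm <- match.arg(algorithm)
  check_count(step, "step")
  if (is.null(max_size)) max_size <- nrow(ranked)
  if (max_size > nrow(ranked)) {
    warn("`max_size` exceeds the list length; clipping")
    max_size <- nrow(ranked)
  }
  sizes <- seq(step, max_size, by = step)
  # one derived seed for every prefix: all subset sizes are scored on the
  # same folds, so comparisons along the curve are paired
  eval_seed <- derive_seed(seed, "ifs-eval")
  records <- purrr::map(sizes, function(k) {
    rep <- evaluate_classifier(
      fm, labels, features = ranked$feature[seq_len(k)],
      algorithm = algorithm, n_folds = n_folds, balance = balance,
      seed = eval_seed)
    tibble(size = as.integer(k), mcc = rep$mcc, acc = rep$acc,
           per_class = list(rep$per_class))
  })
  new_ifs_curve(dplyr::bind_rows(records), method = attr(ranked, "method"),
                algorithm = algorithm, step = step, seed = seed)
}

new_ifs_curve <- function(tbl, method, algorithm, step, seed) {
  out <- as_tibble(tbl)
  attr(out, "method") <- method
  attr(out, "algorithm") <- algorithm
  attr(out, "step") <- step
  attr(out, "seed") <- seed
  class(out) <- c("ifs_curve", class(out))
  out
}

#' Read the optimal subset off an IFS curve
#'
#' The optimal subset is the smallest evaluated prefix achieving the
#' maximum MCC on the curve (parsimony breaks argmax ties).
#'
#' @param curve An `ifs_curve`.
#' @return One-row tibble with `optimal_size`, `optimal_mcc`.
#' @export
select_optimal <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve) > 0)
  best <- max(curve$mcc)
  i <- which(curve$mcc == best)[1]
  tibble(optimal_size = curve$size[i], optimal_mcc = curve$mcc[i])
}

#' Read a compact near-optimal subset off an IFS curve
#'
#' Published compact subsets on curves of this kind are typically chosen
#' by eye where the curve flattens; this formalizes the choice as the
#' smallest evaluated prefix whose MCC is within `tolerance` of the
#' optimum.  `tolerance = 0` returns the optimal size itself.
#'
#' @param curve An `ifs_curve`.
#' @param tolerance Allowed MCC shortfall relative to the optimum.
#' @return One-row tibble with `optimal_size`, `optimal_mcc`,
#'   `compact_size`, `compact_mcc`, `tolerance`.
#' @export
select_compact <- function(curve, tolerance = 0.05) {
  stopifnot(inherits(curve, "ifs_curve"), tolerance >= 0)
  opt <- select_optimal(curve)
  i <- which(curve$mcc >= opt$optimal_mcc - tolerance)[1]
  tibble(optimal_size = opt$optimal_size, optimal_mcc = opt$optimal_mcc,
         compact_size = curve$size[i], compact_mcc = curve$mcc[i],
         tolerance = tolerance)
}
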