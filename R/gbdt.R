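#' Gradient-boosted-tree split-count feature ranking
#'
#' Trains a multiclass gradient-boosted decision-tree ensemble (xgboost,
#' softprob objective, default tree hyperparameters, single-threaded so
#' the fit is deterministic given the seed) and ranks features by the
#' total number of tree split nodes that use them, in decreasing order.
#' The split counts are aggregated from the fitted ensemble's tree dump
#' by this package; ties are broken by original column order, and unused
#' features (including constant columns, which no split can use) rank
#' last with count 0.
#'
#' @param fm A `feature_matrix`.
#' @param labels Labels tibble (`protein`, `class_index`) or vector.
#' @param n_rounds Boosting rounds (default 100).
#' @param seed Integer seed.
#' @return A `ranked_features` tibble with `score` = split count
#'   (a nonnegative integer).
#' @export
gbdt_rank <- function(fm, labels, n_rounds = 100L, seed = 1L) {
  check_count(n_rounds, "n_rounds")
  al <- align_labels(fm, labels)
  x <- al$x; lab <- al$labels
  if (length(unique(lab)) < 2) abort("labels must contain at least two classes")
  col_var <- apply(x, 2, stats::var)
  if (all(col_var == 0)) abort("all features are constant; nothing to rank")
  d <- ncol(x)
  feats <- colnames(x)
  # internal names avoid any tree-dump escaping of ':' in feature ids
  xi <- x
  colnames(xi) <- paste0("f", seq_len(d))
  classes <- sort(unique(lab))
  dtrain <- xgboost::xgb.DMatrix(xi, label = match(lab, classes) - 1L)
  fit <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes),
                  nthread = 1, seed = seed, verbosity = 0),
    data = dtrain, nrounds = n_rounds, verbose = 0)
  dump <- xgboost::xgb.model.dt.tree(model = fit)
  used <- dump$Feature[dump$Feature != "Leaf"]
  counts <- table(factor(used, levels = colnames(xi)))
  score <- as.integer(counts)
  ord <- order(-score, seq_len(d))
  rank_result(feats, as.numeric(score), ord, "gbdt")
}
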