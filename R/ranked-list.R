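# shared constructor and label alignment for the ranking modules

new_ranked_features <- function(tbl, method) {
  stopifnot(all(c("rank", "feature", "group", "source", "score") %in%
                  names(tbl)))
  if (anyDuplicated(tbl$feature)) abort("ranked features must be unique")
  out <- as_tibble(tbl[, c("rank", "feature", "group", "source", "score")])
  attr(out, "method") <- method
  class(out) <- c("ranked_features", class(out))
  out
}

rank_result <- function(features, scores, order_idx, method) {
  info <- feature_info(features)
  new_ranked_features(
    tibble(rank = seq_along(order_idx),
           feature = features[order_idx],
           group = info$group[order_idx],
           source = info$source[order_idx],
           score = scores[order_idx]),
    method)
}

# labels may be a (protein, class_index) tibble or a vector aligned to rows
align_labels <- function(fm, labels) {
  x <- fm_matrix(fm)
  if (is.data.frame(labels)) {
    lab <- labels$class_index[match(rownames(x), labels$protein)]
    if (anyNA(lab)) abort("every protein in the feature matrix needs a label")
  } else {
    if (length(labels) != nrow(x)) abort("`labels` length must match rows")
    lab <- as.integer(labels)
  }
  list(x = x, labels = as.integer(lab))
}
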