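#' Integrate compact selected feature sets across ranking methods
#'
#' Merges the compact selected lists of several ranking methods into one
#' key-feature table.  Candidates are the union of all lists; they are
#' ordered lexicographically by (1) the number of methods that selected
#' the feature, descending, (2) the best (minimum) rank across selecting
#' methods, ascending, (3) the mean rank across selecting methods,
#' ascending, and finally by feature id, which makes the order total.
#' The mean rank averages only over methods that selected the feature;
#' non-selecting methods contribute nothing rather than a penalty rank.
#'
#' @param selected Named list of character vectors, each an *ordered*
#'   selected feature list (position = rank 1, 2, ...); duplicate
#'   features within a list are invalid.
#' @param top_k Number of integrated features to return (default 38,
#'   the size of the reference key-feature table).  If it exceeds the
#'   candidate union, the full union is returned with a warning.
#' @return Tibble with columns `final_rank`, `feature`, `group`,
#'   `source`, `selection_count`, `best_rank`, `mean_rank`, `methods`.
#' @examples
#' integrate_ranks(list(a = c("f1", "f2"), b = c("f2", "f3")), top_k = 3)
#' @export
integrate_ranks <- function(selected, top_k = 38L) {
  stopifnot(is.list(selected), length(selected) >= 1)
  check_count(top_k, "top_k")
  for (nm in names(selected)) {
    if (anyDuplicated(selected[[nm]])) {
      abort(sprintf("list '%s' contains duplicate features", nm))
    }
  }
  long <- dplyr::bind_rows(lapply(names(selected), function(nm) {
    v <- selected[[nm]]
    if (length(v) == 0) return(NULL)
    tibble(method = nm, feature = v, rank = seq_along(v))
  }))
  if (is.null(long) || nrow(long) == 0) abort("no features in any list")
  agg <- long |>
    group_by(.data$feature) |>
    summarise(selection_count = dplyr::n(),
              best_rank = min(.data$rank),
              mean_rank = mean(.data$rank),
              methods = paste(sort(unique(.data$method)), collapse = ","),
              .groups = "drop") |>
    arrange(desc(.data$selection_count), .data$best_rank, .data$mean_rank,
            .data$feature)
  if (top_k > nrow(agg)) {
    warn("`top_k` exceeds the candidate union; returning all candidates")
    top_k <- nrow(agg)
  }
  out <- agg[seq_len(top_k), ]
  info <- feature_info(out$feature)
  tibble(final_rank = seq_len(top_k), feature = out$feature,
         group = info$group, source = info$source,
         selection_count = out$selection_count,
         best_rank = out$best_rank, mean_rank = out$mean_rank,
         methods = out$methods)
}
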