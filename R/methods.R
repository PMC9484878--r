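# print, tidy/glance and autoplot methods for the result classes

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d proteins in %d classes (sizes %s)\n", x$n_proteins,
              x$n_classes, paste(x$class_sizes, collapse = "/")))
  cat(sprintf("  %d GO terms (%d planted per class), %d pathways\n",
              x$n_go_terms, x$informative_terms_per_class, x$n_pathways))
  cat(sprintf("  edge density %.3g, signal %.2f vs background %.2f, seed %d\n",
              x$edge_density, x$signal_strength, x$background_rate, x$seed))
  invisible(x)
}

#' @export
print.subloc_dataset <- function(x, ...) {
  cat("<subloc_dataset>\n")
  cat(sprintf("  network: %d nodes, %d edges\n",
              length(network_nodes(x$network)), nrow(x$network)))
  cat(sprintf("  catalogs: %d GO terms, %d pathways; %d planted terms\n",
              length(unique(x$go$term)), length(unique(x$pathway$term)),
              nrow(x$ground_truth)))
  cat(sprintf("  labels: %d proteins in %d classes\n", nrow(x$labels),
              length(unique(x$labels$class_index))))
  invisible(x)
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d confirmed, %d rejected, %d tentative (%d iterations)\n",
              length(x$confirmed), length(x$rejected), length(x$tentative),
              x$n_iterations))
  invisible(x)
}

#' Tidy a Boruta result into one row per feature
#' @param x A `boruta_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.boruta_result <- function(x, ...) x$decision

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold CV%s: MCC %.3f, ACC %.3f\n",
              x$config$algorithm, x$config$n_folds,
              if (x$config$balance) " (SMOTE-balanced folds)" else "",
              x$mcc, x$acc))
  invisible(x)
}

#' Per-class accuracies of a cross-validated evaluation
#' @param x An `eval_report` from [evaluate_classifier()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) x$per_class

#' One-row summary (MCC, ACC) of an evaluation
#' @param x An `eval_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble(mcc = x$mcc, acc = x$acc,
         algorithm = x$config$algorithm, n_folds = x$config$n_folds,
         n_features = x$config$n_features)
}

#' Records of an IFS curve without the per-class list column
#' @param x An `ifs_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ifs_curve <- function(x, ...) {
  tibble(size = x$size, mcc = x$mcc, acc = x$acc,
         method = attr(x, "method"), algorithm = attr(x, "algorithm"))
}

#' Optimal and compact selection summary of an IFS curve
#' @param x An `ifs_curve`.
#' @param tolerance Passed to [select_compact()].
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ifs_curve <- function(x, tolerance = 0.05, ...) {
  sel <- select_compact(x, tolerance)
  sel$method <- attr(x, "method")
  sel$algorithm <- attr(x, "algorithm")
  sel
}

#' Plot an IFS curve
#'
#' MCC against prefix size, with the optimal prefix (dashed) and the
#' compact near-optimal prefix (dotted) marked.
#'
#' @param object An `ifs_curve`.
#' @param tolerance Compact-selection tolerance (see [select_compact()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ifs_curve <- function(object, tolerance = 0.05, ...) {
  sel <- select_compact(object, tolerance)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$mcc)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = sel$optimal_size, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = sel$compact_size, linetype = "dotted") +
    ggplot2::labs(
      x = "number of top-ranked features",
      y = "multiclass MCC (10-fold CV)",
      title = sprintf("IFS curve: %s list, %s classifier",
                      attr(object, "method"), attr(object, "algorithm")),
      subtitle = sprintf("optimal %d (MCC %.3f), compact %d (MCC %.3f)",
                         sel$optimal_size, sel$optimal_mcc,
                         sel$compact_size, sel$compact_mcc)) +
    ggplot2::theme_minimal()
}

#' Plot the score profile of a ranked feature list
#'
#' @param object A `ranked_features` list.
#' @param top_n How many top features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ranked_features <- function(object, top_n = 30L, ...) {
  df <- head(as_tibble(object), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("%s score", attr(object, "method")),
                  y = NULL, fill = "feature group") +
    ggplot2::theme_minimal()
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> %d artifacts, %d features -> %d confirmed -> %d integrated\n",
              nrow(x$files), x$counts$n_features, x$counts$n_confirmed,
              nrow(x$integrated)))
  invisible(x)
}
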