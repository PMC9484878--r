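#' Read and write the study's plain-text formats
#'
#' Edge lists are 3-column TSVs (`protein_a`, `protein_b`, `weight` in
#' (0,1]); labels are 2-column TSVs (`protein`, `class_index`); annotation
#' catalogs use the GMT convention (one term per line: id, description,
#' then tab-separated member proteins).  Ranked feature lists and IFS
#' curves round-trip through TSV so every pipeline stage can be inspected
#' or re-entered from disk.
#'
#' @param path File path.
#' @param edges,labels,catalog,ranked,curve Objects to serialize, as
#'   produced by the corresponding pipeline stages.
#' @param namespace Namespace tag (`"GO"` or `"pathway"`) attached to a
#'   catalog on read.
#' @return Readers return tibbles (`read_gmt` with a `namespace`
#'   attribute, `read_ifs_curve` an `ifs_curve`); writers return the path
#'   invisibly.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_edges <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(out) <- c("protein_a", "protein_b", "weight")
  validate_edges(out)
  out
}

#' @rdname study_io
#' @export
write_edges <- function(edges, path) {
  validate_edges(edges)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_labels <- function(path) {
  out <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  names(out) <- c("protein", "class_index")
  out
}

#' @rdname study_io
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("protein", "class_index") %in% names(labels)))
  readr::write_tsv(labels[, c("protein", "class_index")], path,
                   progress = FALSE)
  invisible(path)
}

# GMT is a trivial line format (term \t description \t members...); read
# and written directly so the description column survives the round trip.
#' @rdname study_io
#' @export
read_gmt <- function(path, namespace = "GO") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("malformed GMT line(s) %s in %s: need term, description, >=1 member",
                  paste(which(bad), collapse = ", "), path))
  }
  out <- tibble(
    term = rep(vapply(parts, `[`, "", 1), lengths(parts) - 2L),
    description = rep(vapply(parts, `[`, "", 2), lengths(parts) - 2L),
    protein = unlist(lapply(parts, function(x) x[-(1:2)]), use.names = FALSE))
  attr(out, "namespace") <- namespace
  out
}

#' @rdname study_io
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(all(c("term", "description", "protein") %in% names(catalog)))
  rows <- split(catalog, factor(catalog$term, levels = unique(catalog$term)))
  lines <- vapply(rows, function(d) {
    paste(c(d$term[1], d$description[1], d$protein), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname study_io
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_features"))
  out <- as_tibble(ranked)
  out$method <- attr(ranked, "method")
  readr::write_tsv(out[, c("rank", "method", "group", "source", "feature",
                           "score")], path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_ranked_list <- function(path) {
  out <- readr::read_tsv(path, col_types = "iccccd", progress = FALSE)
  method <- unique(out$method)
  res <- out[, c("rank", "feature", "group", "source", "score")]
  new_ranked_features(res, method)
}

#' @rdname study_io
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  flat <- tidyr::unnest(as_tibble(curve), "per_class")
  flat <- tidyr::pivot_wider(flat, names_from = "class_index",
                             values_from = c("class_accuracy", "class_n"),
                             names_sep = "_")
  flat$method <- attr(curve, "method")
  flat$algorithm <- attr(curve, "algorithm")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_ifs_curve <- function(path) {
  flat <- readr::read_tsv(path, progress = FALSE,
                          col_types = readr::cols())
  acc_cols <- grep("^class_accuracy_", names(flat), value = TRUE)
  n_cols <- grep("^class_n_", names(flat), value = TRUE)
  per_class <- lapply(seq_len(nrow(flat)), function(i) {
    tibble(class_index = as.integer(sub("^class_accuracy_", "", acc_cols)),
           class_accuracy = as.numeric(flat[i, acc_cols]),
           class_n = as.integer(flat[i, n_cols]))
  })
  out <- tibble(size = as.integer(flat$size), mcc = flat$mcc, acc = flat$acc,
                per_class = per_class)
  new_ifs_curve(out, method = flat$method[1], algorithm = flat$algorithm[1],
                step = diff(c(0, flat$size))[1], seed = NA_integer_)
}
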