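#' Neighborhood enrichment score against one annotation term
#'
#' Scores how surprisingly a protein's closed network neighborhood
#' overlaps a term's member set: the -log10 of the one-sided upper-tail
#' hypergeometric p-value of observing at least `|neigh intersect term|`
#' annotated proteins when drawing `|neigh|` proteins from the population.
#' A zero overlap gives p = 1, hence score 0.  Underflowing p-values are
#' floored at `p_floor` (default 1e-300), capping the score at 300 while
#' preserving order.
#'
#' @param neigh Character vector: the neighborhood protein set (nonempty,
#'   subset of `population`).
#' @param term_members Character vector: proteins annotated by the term
#'   (subset of `population`).
#' @param population Character vector: the full population (all network
#'   nodes).
#' @param p_floor Lower bound applied to the p-value before the log.
#' @return A nonnegative number.
#' @examples
#' pop <- letters[1:10]
#' enrichment_score(letters[1:4], letters[1:5], pop)
#' @export
enrichment_score <- function(neigh, term_members, population,
                             p_floor = 1e-300) {
  if (length(neigh) == 0) abort("`neigh` must be nonempty")
  if (length(population) == 0) abort("`population` must be nonempty")
  neigh <- unique(neigh); term_members <- unique(term_members)
  population <- unique(population)
  if (!all(neigh %in% population)) abort("`neigh` must be a subset of `population`")
  if (!all(term_members %in% population)) {
    abort("`term_members` must be a subset of `population`")
  }
  q <- length(intersect(neigh, term_members))
  m <- length(term_members)
  N <- length(population)
  k <- length(neigh)
  p <- phyper(q - 1, m, N - m, k, lower.tail = FALSE)
  -log10(max(p, p_floor))
}

#' Encode proteins as network + GO + pathway feature rows
#'
#' Builds the full feature matrix: one block of adjacency-row network
#' features (one column per network node, value = edge weight or 0), one
#' block of GO enrichment scores and one block of pathway enrichment
#' scores (one column per catalog term, value = [enrichment_score()] of
#' the protein's closed neighborhood against the term over the population
#' of all network nodes).  Column blocks are ordered network, GO, pathway;
#' nodes and terms are in sorted-id order, so the encoding is a
#' deterministic function of its inputs.  Column names carry the feature
#' group and source id as `group:source_id`.
#'
#' Catalog members absent from the network are ignored: the population of
#' the enrichment test is the node set.
#'
#' @param edges Edge-list tibble (see [validate_edges()]).
#' @param go,kegg Annotation catalogs (tibbles `term`, `description`,
#'   `protein`), or `NULL` for an empty block.
#' @param proteins Character vector of proteins to encode (rows); defaults
#'   to all network nodes.  Every protein must be a network node.
#' @param nodes Optional explicit node set (to include isolated nodes).
#' @param p_floor Passed to the enrichment computation.
#' @return A `feature_matrix`: a tibble whose first column is `protein`
#'   followed by one numeric column per feature.
#' @seealso [feature_info()]
#' @export
encode_features <- function(edges, go = NULL, kegg = NULL, proteins = NULL,
                            nodes = NULL, p_floor = 1e-300) {
  validate_edges(edges)
  node_order <- network_nodes(edges, nodes)
  if (is.null(proteins)) proteins <- node_order
  missing <- setdiff(proteins, node_order)
  if (length(missing) > 0) {
    abort(sprintf("proteins absent from the network: %s",
                  paste(missing, collapse = ", ")),
          class = "sublocfs_lookup_error")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b", "weight")], directed = FALSE,
    vertices = data.frame(name = node_order))
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  net_block <- as.matrix(A[proteins, node_order, drop = FALSE])
  colnames(net_block) <- paste0("network:", node_order)

  nb <- igraph::ego(g, order = 1, nodes = proteins)  # includes the vertex itself
  nb_idx <- lapply(nb, as.integer)

  blocks <- list(net_block)
  for (spec in list(list(cat = go, tag = "GO"),
                    list(cat = kegg, tag = "pathway"))) {
    if (!is.null(spec$cat) && nrow(spec$cat) > 0) {
      blocks <- c(blocks, list(
        enrichment_block(spec$cat, nb_idx, node_order, spec$tag, p_floor)))
    }
  }
  fm <- do.call(cbind, blocks)
  out <- tibble(protein = proteins)
  out <- dplyr::bind_cols(out, as_tibble(fm, .name_repair = "minimal"))
  class(out) <- c("feature_matrix", class(out))
  out
}

# vectorized hypergeometric upper tails for all (term, protein) pairs
enrichment_block <- function(catalog, nb_idx, node_order, tag, p_floor) {
  terms <- sort(unique(catalog$term))
  keep <- catalog$protein %in% node_order
  ti <- match(catalog$term[keep], terms)
  pi <- match(catalog$protein[keep], node_order)
  dup <- duplicated(cbind(ti, pi))
  ti <- ti[!dup]; pi <- pi[!dup]
  n_nodes <- length(node_order)
  member <- matrix(FALSE, length(terms), n_nodes)
  member[cbind(ti, pi)] <- TRUE
  m_t <- rowSums(member)                      # term sizes within the population
  k_p <- lengths(nb_idx)
  overlap <- vapply(nb_idx, function(ix) rowSums(member[, ix, drop = FALSE]),
                    numeric(length(terms)))
  overlap <- matrix(overlap, nrow = length(terms))
  p <- phyper(overlap - 1, m_t, n_nodes - m_t,
              rep(k_p, each = length(terms)), lower.tail = FALSE)
  scores <- -log10(pmax(p, p_floor))
  block <- t(scores)
  colnames(block) <- paste0(tag, ":", terms)
  block
}

#' Describe the columns of a feature matrix
#'
#' @param fm A `feature_matrix` from [encode_features()], or a character
#'   vector of `group:source_id` feature names.
#' @return Tibble with columns `feature`, `group`, `source`.
#' @export
feature_info <- function(fm) {
  feats <- if (is.character(fm)) fm else setdiff(names(fm), "protein")
  parts <- split_feature_id(feats)
  tibble(feature = feats, group = parts$group, source = parts$source)
}

# numeric matrix view of a feature matrix, rownames = protein ids
fm_matrix <- function(fm, features = NULL) {
  stopifnot(is.data.frame(fm), "protein" %in% names(fm))
  cols <- setdiff(names(fm), "protein")
  if (!is.null(features)) {
    missing <- setdiff(features, cols)
    if (length(missing) > 0) {
      abort(sprintf("features not in matrix: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    cols <- features
  }
  x <- as.matrix(fm[, cols, drop = FALSE])
  rownames(x) <- fm$protein
  storage.mode(x) <- "double"
  x
}

#' Write / read a feature matrix TSV
#'
#' The header row carries the typed `group:source_id` feature names, so
#' column identity survives the round trip.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @rdname feature_matrix_io
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_tsv(as_tibble(fm), path, progress = FALSE)
  invisible(path)
}

#' @rdname feature_matrix_io
#' @export
read_feature_matrix <- function(path) {
  out <- readr::read_tsv(path, progress = FALSE, col_types = readr::cols())
  class(out) <- c("feature_matrix", class(out))
  out
}
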