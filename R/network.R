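#' Interaction-network primitives
#'
#' The interaction network is an undirected weighted graph kept as a tidy
#' edge list: a tibble with columns `protein_a`, `protein_b` and `weight`
#' in (0, 1] (STRING-style confidence).  Self-loops and duplicate
#' unordered pairs are invalid.
#'
#' @param edges Edge-list tibble.
#' @param protein A protein id.
#' @param nodes Optional full node set (character).  Defaults to the
#'   proteins appearing in `edges`; pass explicitly to represent isolated
#'   nodes.
#' @name network
NULL

#' @rdname network
#' @export
validate_edges <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b", "weight") %in% names(edges)))
  if (any(edges$protein_a == edges$protein_b)) {
    abort("network contains self-loops")
  }
  if (any(edges$weight <= 0 | edges$weight > 1)) {
    abort("edge weights must lie in (0, 1]")
  }
  key <- paste(pmin(edges$protein_a, edges$protein_b),
               pmax(edges$protein_a, edges$protein_b))
  if (anyDuplicated(key)) abort("network contains duplicate edges")
  invisible(edges)
}

#' @rdname network
#' @export
network_nodes <- function(edges, nodes = NULL) {
  if (!is.null(nodes)) return(sort(unique(as.character(nodes))))
  sort(unique(c(edges$protein_a, edges$protein_b)))
}

#' @rdname network
#' @return `neighborhood()`: the closed neighborhood \{p\} plus all direct
#'   interaction partners of `protein`, regardless of edge weight.
#' @examples
#' edges <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "c"),
#'                         weight = c(0.5, 0.9))
#' neighborhood(edges, "b")
#' @export
neighborhood <- function(edges, protein, nodes = NULL) {
  all_nodes <- network_nodes(edges, nodes)
  if (!protein %in% all_nodes) {
    abort(sprintf("protein '%s' is not a network node", protein),
          class = "sublocfs_lookup_error")
  }
  partners <- c(edges$protein_b[edges$protein_a == protein],
                edges$protein_a[edges$protein_b == protein])
  sort(unique(c(protein, partners)))
}

#' @rdname network
#' @param node_order Character vector fixing the feature-column order; must
#'   be a permutation of the node set.
#' @return `network_feature_vector()`: the adjacency-matrix row of
#'   `protein` in `node_order` (edge weight, or 0 where no edge; 0 at the
#'   protein's own position), named by node id.
#' @export
network_feature_vector <- function(edges, protein, node_order = NULL) {
  all_nodes <- network_nodes(edges, node_order)
  if (is.null(node_order)) node_order <- all_nodes
  if (!setequal(node_order, all_nodes) ||
      length(node_order) != length(all_nodes)) {
    abort("`node_order` must be a permutation of the network's node set")
  }
  if (!protein %in% node_order) {
    abort(sprintf("protein '%s' is not a network node", protein),
          class = "sublocfs_lookup_error")
  }
  v <- setNames(numeric(length(node_order)), node_order)
  ia <- edges$protein_a == protein
  ib <- edges$protein_b == protein
  v[edges$protein_b[ia]] <- edges$weight[ia]
  v[edges$protein_a[ib]] <- edges$weight[ib]
  v[protein] <- 0
  v
}
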