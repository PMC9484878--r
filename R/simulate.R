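#' Configuration for the synthetic localization dataset generator
#'
#' Describes a synthetic study: a sparse weighted interaction network over
#' `n_proteins` proteins, an imbalanced multi-class label profile, and GO /
#' pathway annotation catalogs in which each class owns a set of planted
#' informative terms.  Members of a class are annotated by their class's
#' planted terms with probability `signal_strength`; every other
#' protein-term annotation happens at `background_rate`.  Defaults mirror
#' the curated reference study: 16 classes with the
#' [reference_class_profile()] sizes (3 up to 1487 proteins per class).
#'
#' When `class_sizes` is omitted but `n_proteins`/`n_classes` are given,
#' an imbalanced profile with the reference shape is allocated by largest
#' remainder so that small synthetic studies keep a realistic skew.
#'
#' @param n_proteins Total number of proteins (nodes).
#' @param n_classes Number of localization classes.
#' @param class_sizes Integer vector of per-class protein counts; must sum
#'   to `n_proteins`.
#' @param n_go_terms,n_pathways Catalog sizes.  Planted informative terms
#'   live in the GO catalog; the pathway catalog is pure background.
#' @param edge_density Baseline probability of an edge between any two
#'   proteins.  Within-class pairs receive an independent second draw at
#'   the same rate, roughly doubling within-class density so that network
#'   neighborhoods carry class signal.
#' @param informative_terms_per_class Planted GO terms per class.
#' @param signal_strength Probability that a class member is annotated by
#'   each of its class's planted terms.  Must exceed `background_rate`.
#' @param background_rate Annotation probability for every other
#'   protein-term pair.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_dataset()]
#' @examples
#' simulation_config(n_proteins = 100, n_classes = 3, seed = 1)
#' @export
simulation_config <- function(n_proteins = NULL,
                              n_classes = 16L,
                              class_sizes = NULL,
                              n_go_terms = 200L,
                              n_pathways = 30L,
                              edge_density = 0.01,
                              informative_terms_per_class = 3L,
                              signal_strength = 0.9,
                              background_rate = 0.05,
                              seed = 1L) {
  if (is.null(class_sizes)) {
    if (is.null(n_proteins)) {
      class_sizes <- reference_class_profile()$n_proteins
    } else {
      check_count(n_proteins, "n_proteins")
      check_count(n_classes, "n_classes")
      class_sizes <- allocate_profile(n_proteins, n_classes)
    }
  }
  class_sizes <- vapply(class_sizes, check_count, integer(1),
                        name = "class_sizes", min = 1)
  n_classes <- length(class_sizes)
  if (!is.null(n_proteins) && sum(class_sizes) != n_proteins) {
    abort("`class_sizes` must sum to `n_proteins`",
          class = "sublocfs_config_error")
  }
  n_proteins <- sum(class_sizes)
  check_count(n_go_terms, "n_go_terms")
  check_count(n_pathways, "n_pathways")
  check_prob(edge_density, "edge_density")
  if (edge_density <= 0 || edge_density >= 1) {
    abort("`edge_density` must lie strictly between 0 and 1",
          class = "sublocfs_config_error")
  }
  check_count(informative_terms_per_class, "informative_terms_per_class")
  check_prob(signal_strength, "signal_strength")
  check_prob(background_rate, "background_rate")
  if (signal_strength <= background_rate) {
    abort("`signal_strength` must exceed `background_rate`",
          class = "sublocfs_config_error")
  }
  if (n_classes * informative_terms_per_class > n_go_terms) {
    abort("`n_go_terms` too small for `informative_terms_per_class` planted terms per class",
          class = "sublocfs_config_error")
  }
  check_count(seed, "seed", min = 0)
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_classes = as.integer(n_classes),
         class_sizes = as.integer(class_sizes),
         n_go_terms = as.integer(n_go_terms),
         n_pathways = as.integer(n_pathways),
         edge_density = edge_density,
         informative_terms_per_class = as.integer(informative_terms_per_class),
         signal_strength = signal_strength,
         background_rate = background_rate,
         seed = as.integer(seed)),
    class = "simulation_config")
}

# largest-remainder allocation of n proteins over k classes with the
# reference imbalance shape (evenly-spaced quantiles of the sorted profile)
allocate_profile <- function(n_proteins, n_classes) {
  ref <- sort(reference_class_profile()$n_proteins, decreasing = TRUE)
  idx <- round(seq(1, length(ref), length.out = n_classes))
  props <- ref[idx] / sum(ref[idx])
  raw <- props * (n_proteins - 2 * n_classes)  # reserve a floor of 2 each
  sizes <- floor(raw)
  rem <- n_proteins - 2 * n_classes - sum(sizes)
  if (rem > 0) {
    bump <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1
  }
  as.integer(sizes + 2)
}

#' Generate a synthetic localization study
#'
#' Draws a weighted undirected interaction network, GO and pathway
#' annotation catalogs with planted class-informative GO terms, and the
#' class labels described by a [simulation_config()].  The whole dataset is
#' a deterministic function of the configuration (identical configs give
#' byte-identical datasets); the generator never touches the global RNG
#' stream.
#'
#' Edges are sampled Erdos-Renyi style at `edge_density` over all pairs
#' plus an independent second draw over within-class pairs, so class
#' neighborhoods are denser than the background.  Edge weights are
#' uniform(0.15, 1), emulating STRING-like positive confidence scores.
#' Any node left isolated is connected to one uniformly chosen partner so
#' that the edge list carries every protein.
#'
#' @param config A [simulation_config()].
#' @return An object of class `subloc_dataset`: a list with elements
#'   `network` (tibble `protein_a`, `protein_b`, `weight`), `go` and
#'   `pathway` (annotation catalogs: tibbles `term`, `description`,
#'   `protein` with a `namespace` attribute), `labels` (tibble `protein`,
#'   `class_index`), `ground_truth` (tibble `class_index`, `term`) and
#'   `config`.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_proteins = 60, n_classes = 3,
#'                                          n_go_terms = 20, n_pathways = 5,
#'                                          edge_density = 0.1, seed = 7))
#' nrow(ds$network)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must be created by simulation_config()",
          class = "sublocfs_config_error")
  }
  local_seed(config$seed)

  n <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))
  class_of <- rep(seq_len(config$n_classes), config$class_sizes)
  labels <- tibble(protein = proteins, class_index = as.integer(class_of))

  # --- network -------------------------------------------------------------
  base <- sample_upper_tri(n, config$edge_density)
  within <- lapply(which(config$class_sizes >= 2), function(k) {
    members <- which(class_of == k)
    pr <- sample_upper_tri(length(members), config$edge_density)
    cbind(members[pr[, 1]], members[pr[, 2]])
  })
  pairs <- rbind(base, do.call(rbind, within))
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  # canonical orientation + dedupe
  a <- pmin(pairs[, 1], pairs[, 2]); b <- pmax(pairs[, 1], pairs[, 2])
  keep <- !duplicated(a * (n + 1) + b)
  a <- a[keep]; b <- b[keep]
  isolated <- setdiff(seq_len(n), unique(c(a, b)))
  if (length(isolated) > 0 && n >= 2) {
    partner <- vapply(isolated, function(i) {
      sample(setdiff(seq_len(n), i), 1L)
    }, integer(1))
    a <- c(a, pmin(isolated, partner)); b <- c(b, pmax(isolated, partner))
    keep <- !duplicated(a * (n + 1) + b)
    a <- a[keep]; b <- b[keep]
  }
  w <- runif(length(a), 0.15, 1.0)
  o <- order(a, b)
  network <- tibble(protein_a = proteins[a[o]], protein_b = proteins[b[o]],
                    weight = w[o])

  # --- catalogs ------------------------------------------------------------
  ipc <- config$informative_terms_per_class
  go_ids <- sprintf("GOS%05d", seq_len(config$n_go_terms))
  planted_class <- rep(seq_len(config$n_classes), each = ipc)
  go_members <- vector("list", config$n_go_terms)
  go_desc <- character(config$n_go_terms)
  for (t in seq_len(config$n_go_terms)) {
    if (t <= length(planted_class)) {
      k <- planted_class[t]
      in_class <- class_of == k
      hit <- runif(n) < ifelse(in_class, config$signal_strength,
                               config$background_rate)
      go_desc[t] <- sprintf("planted informative term for class %d", k)
    } else {
      hit <- runif(n) < config$background_rate
      go_desc[t] <- "background term"
    }
    mem <- which(hit)
    if (length(mem) == 0) mem <- sample.int(n, 1L)  # catalogs keep terms nonempty
    go_members[[t]] <- proteins[mem]
  }
  go <- catalog_tibble(go_ids, go_desc, go_members, "GO")

  pw_ids <- sprintf("PWY%04d", seq_len(config$n_pathways))
  pw_members <- lapply(seq_len(config$n_pathways), function(t) {
    mem <- which(runif(n) < config$background_rate)
    if (length(mem) == 0) mem <- sample.int(n, 1L)
    proteins[mem]
  })
  pathway <- catalog_tibble(pw_ids, rep("background pathway", config$n_pathways),
                            pw_members, "pathway")

  ground_truth <- tibble(class_index = as.integer(planted_class),
                         term = go_ids[seq_along(planted_class)])

  structure(list(network = network, go = go, pathway = pathway,
                 labels = labels, ground_truth = ground_truth,
                 config = config),
            class = "subloc_dataset")
}

# Bernoulli(p) sample of unordered pairs over 1..n_items, returned as a
# 2-column matrix; draws the pair count binomially then samples linear
# upper-triangle indices, so cost scales with the expected edge count.
sample_upper_tri <- function(n_items, p) {
  n_pairs <- n_items * (n_items - 1) / 2
  if (n_pairs < 1) return(matrix(integer(0), ncol = 2))
  m <- stats::rbinom(1, n_pairs, p)
  if (m == 0) return(matrix(integer(0), ncol = 2))
  t <- sort(sample(n_pairs, m))
  j <- ceiling((1 + sqrt(1 + 8 * t)) / 2)
  i <- t - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

catalog_tibble <- function(ids, descriptions, members, namespace) {
  out <- tibble(
    term = rep(ids, lengths(members)),
    description = rep(descriptions, lengths(members)),
    protein = unlist(lapply(members, sort), use.names = FALSE))
  attr(out, "namespace") <- namespace
  out
}

#' Write a synthetic dataset to plain-text study files
#'
#' Persists the network as an edge-list TSV, the catalogs as GMT files,
#' the labels as a TSV and the planted ground truth as JSON, in the
#' formats consumed by [run_pipeline()] and the `read_*` helpers.
#'
#' @param dataset A `subloc_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "subloc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    go = file.path(dir, "go.gmt"),
    pathways = file.path(dir, "pathways.gmt"),
    labels = file.path(dir, "labels.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_edges(dataset$network, paths[["edges"]])
  write_gmt(dataset$go, paths[["go"]])
  write_gmt(dataset$pathway, paths[["pathways"]])
  write_labels(dataset$labels, paths[["labels"]])
  gt <- split(dataset$ground_truth$term, dataset$ground_truth$class_index)
  jsonlite::write_json(gt, paths[["ground_truth"]], pretty = TRUE)
  invisible(paths)
}
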