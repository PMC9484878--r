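#' End-to-end pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a
#' [simulation_config()] or paths to real study inputs (edge-list TSV,
#' GO and pathway GMT files, label TSV) — exactly one of the two — plus
#' the stage parameters and one global seed from which every stage's
#' seed is derived via [derive_seed()].
#'
#' The defaults describe a desk-scale synthetic study (200 proteins,
#' 3 classes, 40 GO terms, 10 pathways, strong planted signal) on which
#' the whole cascade runs in minutes on one CPU.
#'
#' @param simulation A [simulation_config()], or `NULL` when real input
#'   paths are given.
#' @param inputs Named list with paths `edges`, `go`, `pathways`,
#'   `labels`, or `NULL` when simulating.
#' @param out_dir Output directory for all artifacts.
#' @param seed Global integer seed.
#' @param boruta_max_iter,boruta_alpha,boruta_trees Boruta stage
#'   parameters.
#' @param mcfs_projections,mcfs_trees Optional MCFS overrides (`NULL`
#'   uses [mcfs_rank()] defaults).
#' @param gbdt_rounds Boosting rounds for the GBDT ranker.
#' @param ifs_step,ifs_max_size,ifs_folds,ifs_tolerance IFS stage
#'   parameters; `ifs_max_size = NULL` evaluates the full list.
#' @param algorithms Classifiers to run IFS with.
#' @param integration_algorithm The classifier whose compact subsets are
#'   integrated (default `"rf"`).
#' @param top_k Integrated key-feature table size.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            out_dir = tempfile("sublocfs-run-"),
                            seed = 1L,
                            boruta_max_iter = 30L, boruta_alpha = 0.05,
                            boruta_trees = 100L,
                            mcfs_projections = NULL, mcfs_trees = 5L,
                            gbdt_rounds = 50L,
                            ifs_step = 1L, ifs_max_size = 20L,
                            ifs_folds = 10L, ifs_tolerance = 0.05,
                            algorithms = c("rf", "svm"),
                            integration_algorithm = "rf",
                            top_k = 6L) {
  if (is.null(simulation) && is.null(inputs)) {
    simulation <- simulation_config(
      n_proteins = 200L, class_sizes = c(100L, 60L, 40L),
      n_go_terms = 40L, n_pathways = 10L, edge_density = 0.05,
      informative_terms_per_class = 3L, signal_strength = 0.9,
      background_rate = 0.05, seed = seed)
  }
  if (!is.null(simulation) && !is.null(inputs)) {
    abort("supply either `simulation` or `inputs`, not both",
          class = "sublocfs_config_error")
  }
  if (!is.null(inputs)) {
    stopifnot(all(c("edges", "go", "pathways", "labels") %in% names(inputs)))
  }
  stopifnot(all(algorithms %in% c("rf", "svm")),
            integration_algorithm %in% algorithms)
  structure(
    list(simulation = simulation, inputs = inputs, out_dir = out_dir,
         seed = as.integer(seed),
         boruta_max_iter = boruta_max_iter, boruta_alpha = boruta_alpha,
         boruta_trees = boruta_trees,
         mcfs_projections = mcfs_projections, mcfs_trees = mcfs_trees,
         gbdt_rounds = gbdt_rounds,
         ifs_step = ifs_step, ifs_max_size = ifs_max_size,
         ifs_folds = ifs_folds, ifs_tolerance = ifs_tolerance,
         algorithms = algorithms,
         integration_algorithm = integration_algorithm,
         top_k = as.integer(top_k)),
    class = "pipeline_config")
}

#' Run the full localization feature-selection pipeline
#'
#' Executes encode -> Boruta -> \{mRMR, MCFS, GBDT\} ranking of the
#' confirmed features -> incremental feature selection for every
#' (list, classifier) pair -> compact-subset selection -> rank
#' integration, writing every intermediate artifact (TSV/GMT/JSON) under
#' `config$out_dir` together with a manifest of file MD5 hashes and the
#' full configuration echo.  Re-running with an identical configuration
#' reproduces identical artifacts and manifest hashes.  A failing stage
#' aborts with the stage name and leaves a `FAILED` marker next to the
#' partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_manifest`: list with `files` (tibble
#'   `file`, `md5`), `counts` (per-stage feature counts), `selections`,
#'   `integrated` and the config echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage_log <- function(stage, ...) {
    inform(sprintf("[%s] %5.1fs %s", stage,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   sprintf(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            class = "sublocfs_stage_error")
    })
  }
  files <- character(0)
  add_file <- function(path) files <<- c(files, path)

  # --- inputs --------------------------------------------------------------
  ds <- run_stage("input", {
    if (!is.null(config$simulation)) {
      ds <- simulate_dataset(config$simulation)
      for (p in write_dataset(ds, file.path(config$out_dir, "dataset"))) {
        add_file(p)
      }
      ds
    } else {
      list(network = read_edges(config$inputs$edges),
           go = read_gmt(config$inputs$go, "GO"),
           pathway = read_gmt(config$inputs$pathways, "pathway"),
           labels = read_labels(config$inputs$labels),
           ground_truth = NULL)
    }
  })
  stage_log("input", "%d proteins, %d edges, %d GO terms, %d pathways",
            nrow(ds$labels), nrow(ds$network),
            length(unique(ds$go$term)), length(unique(ds$pathway$term)))

  # --- encode --------------------------------------------------------------
  fm <- run_stage("encode", {
    fm <- encode_features(ds$network, ds$go, ds$pathway,
                          proteins = ds$labels$protein)
    add_file(write_feature_matrix(fm, file.path(config$out_dir,
                                                "feature_matrix.tsv")))
    fm
  })
  stage_log("encode", "%d features", ncol(fm) - 1L)

  # --- boruta --------------------------------------------------------------
  bor <- run_stage("boruta", {
    bor <- boruta_filter(fm, ds$labels, max_iter = config$boruta_max_iter,
                         alpha = config$boruta_alpha,
                         num_trees = config$boruta_trees,
                         seed = derive_seed(config$seed, "boruta"))
    readr::write_tsv(bor$decision,
                     file.path(config$out_dir, "boruta_decisions.tsv"),
                     progress = FALSE)
    add_file(file.path(config$out_dir, "boruta_decisions.tsv"))
    bor
  })
  if (length(bor$confirmed) == 0) {
    run_stage("boruta", abort("no features confirmed"))
  }
  stage_log("boruta", "confirmed %d / rejected %d / tentative %d",
            length(bor$confirmed), length(bor$rejected),
            length(bor$tentative))
  fm_conf <- fm[, c("protein", bor$confirmed)]
  class(fm_conf) <- class(fm)

  # --- ranking -------------------------------------------------------------
  lists <- run_stage("ranking", {
    lists <- list(
      mrmr = mrmr_rank(fm_conf, ds$labels),
      mcfs = mcfs_rank(fm_conf, ds$labels,
                       projections = config$mcfs_projections,
                       trees_per_projection = config$mcfs_trees,
                       seed = derive_seed(config$seed, "mcfs")),
      gbdt = gbdt_rank(fm_conf, ds$labels, n_rounds = config$gbdt_rounds,
                       seed = derive_seed(config$seed, "gbdt")))
    for (nm in names(lists)) {
      add_file(write_ranked_list(
        lists[[nm]], file.path(config$out_dir,
                               sprintf("ranked_%s.tsv", nm))))
    }
    lists
  })
  stage_log("ranking", "3 lists over %d confirmed features",
            length(bor$confirmed))

  # --- IFS -----------------------------------------------------------------
  selections <- list()
  compact_sets <- list()
  for (nm in names(lists)) {
    for (alg in config$algorithms) {
      key <- paste(nm, alg, sep = "_")
      curve <- run_stage(paste0("ifs-", key), {
        curve <- run_ifs(lists[[nm]], fm_conf, ds$labels, algorithm = alg,
                         step = config$ifs_step,
                         max_size = min(config$ifs_max_size %||%
                                          nrow(lists[[nm]]),
                                        nrow(lists[[nm]])),
                         n_folds = config$ifs_folds,
                         seed = derive_seed(config$seed,
                                            paste0("ifs-", key)))
        add_file(write_ifs_curve(
          curve, file.path(config$out_dir,
                           sprintf("ifs_curve_%s.tsv", key))))
        curve
      })
      sel <- select_compact(curve, config$ifs_tolerance)
      selections[[key]] <- sel
      stage_log(paste0("ifs-", key),
                "optimal %d (MCC %.3f), compact %d (MCC %.3f)",
                sel$optimal_size, sel$optimal_mcc, sel$compact_size,
                sel$compact_mcc)
      if (alg == config$integration_algorithm) {
        compact_sets[[nm]] <- lists[[nm]]$feature[seq_len(sel$compact_size)]
      }
    }
  }
  sel_tbl <- dplyr::bind_rows(selections, .id = "list_algorithm")
  jsonlite::write_json(sel_tbl, file.path(config$out_dir, "selections.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  add_file(file.path(config$out_dir, "selections.json"))

  # --- integration ---------------------------------------------------------
  integrated <- run_stage("integration", {
    integrated <- integrate_ranks(compact_sets, top_k = config$top_k)
    readr::write_tsv(integrated,
                     file.path(config$out_dir, "integrated_features.tsv"),
                     progress = FALSE)
    add_file(file.path(config$out_dir, "integrated_features.tsv"))
    integrated
  })
  stage_log("integration", "%d key features", nrow(integrated))

  # --- manifest ------------------------------------------------------------
  files <- unique(files)
  manifest <- list(
    files = tibble(file = sub(paste0("^", config$out_dir, "/?"), "", files),
                   md5 = unname(tools::md5sum(files))),
    counts = list(n_proteins = nrow(ds$labels),
                  n_features = ncol(fm) - 1L,
                  n_confirmed = length(bor$confirmed),
                  n_curves = length(lists) * length(config$algorithms),
                  n_compact_union = length(unique(unlist(compact_sets)))),
    selections = sel_tbl,
    integrated = integrated,
    config = config_echo(config))
  json <- manifest
  json$integrated <- NULL
  jsonlite::write_json(json, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA,
                       auto_unbox = TRUE, null = "null")
  class(manifest) <- "pipeline_manifest"
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$simulation)) out$simulation <- unclass(out$simulation)
  out
}
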