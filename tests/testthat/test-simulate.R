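test_that("identical configurations reproduce identical datasets, different seeds differ", {
  cfg <- simulation_config(class_sizes = c(30L, 20L, 10L), n_go_terms = 15L,
                           n_pathways = 4L, edge_density = 0.08, seed = 11)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$network, ds2$network)
  expect_identical(ds1$go, ds2$go)
  expect_identical(ds1$pathway, ds2$pathway)
  expect_identical(ds1$labels, ds2$labels)
  ds3 <- simulate_dataset(simulation_config(
    class_sizes = c(30L, 20L, 10L), n_go_terms = 15L, n_pathways = 4L,
    edge_density = 0.08, seed = 12))
  expect_false(identical(ds1$network, ds3$network))
})

test_that("class sizes are honored exactly, including the reference 16-class profile", {
  profile <- reference_class_profile()$n_proteins
  ds <- simulate_dataset(simulation_config(
    class_sizes = profile, n_go_terms = 48L, n_pathways = 5L,
    edge_density = 0.001, seed = 2))
  counts <- table(ds$labels$class_index)
  expect_equal(as.integer(counts), profile)
  expect_equal(min(profile), 3L)
  expect_equal(max(profile), 1487L)
  # every labeled protein appears in the network edge list
  expect_true(all(ds$labels$protein %in% network_nodes(ds$network)))
})

test_that("generated networks are simple weighted graphs", {
  ds <- small_dataset(seed = 5)
  expect_silent(validate_edges(ds$network))   # no loops, dups, bad weights
  expect_true(all(ds$network$weight > 0 & ds$network$weight <= 1))
})

test_that("planted terms annotate their class above background", {
  ds <- small_dataset(seed = 7, class_sizes = c(100L, 70L, 50L), ipc = 3L)
  anno <- split(ds$go$protein, ds$go$term)
  lab <- setNames(ds$labels$class_index, ds$labels$protein)
  for (i in seq_len(nrow(ds$ground_truth))) {
    cls <- ds$ground_truth$class_index[i]
    members <- anno[[ds$ground_truth$term[i]]]
    in_rate <- mean(names(lab)[lab == cls] %in% members)
    out_rate <- mean(names(lab)[lab != cls] %in% members)
    expect_gt(in_rate, out_rate)
  }
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(simulation_config(n_proteins = 10, class_sizes = c(5L, 4L)),
               "class_sizes")
  expect_error(simulation_config(class_sizes = c(10L, 10L),
                                 signal_strength = 0.1,
                                 background_rate = 0.2),
               "signal_strength")
  expect_error(simulation_config(class_sizes = c(10L, 10L), edge_density = 0),
               "edge_density")
  expect_error(simulation_config(class_sizes = c(10L, 10L), n_go_terms = 2L,
                                 informative_terms_per_class = 3L),
               "n_go_terms")
})

test_that("datasets round-trip through the study file formats", {
  ds <- small_dataset(seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  edges <- read_edges(paths[["edges"]])
  expect_equal(edges, ds$network, ignore_attr = TRUE)
  go <- read_gmt(paths[["go"]], "GO")
  expect_equal(go$term, ds$go$term)
  expect_equal(go$protein, ds$go$protein)
  labels <- read_labels(paths[["labels"]])
  expect_equal(labels, ds$labels, ignore_attr = TRUE)
})
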