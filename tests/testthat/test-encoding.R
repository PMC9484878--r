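triangle <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "c"),
                           weight = c(0.5, 0.9))

test_that("neighborhoods are closed and weight-blind", {
  expect_setequal(neighborhood(triangle, "b"), c("a", "b", "c"))
  expect_setequal(neighborhood(triangle, "a"), c("a", "b"))
  # isolated node: present via explicit node set, neighborhood is itself
  expect_equal(neighborhood(triangle, "z", nodes = c("a", "b", "c", "z")), "z")
  # tiny weights still count as edges
  tiny <- tibble::tibble(protein_a = "p", protein_b = "q", weight = 0.01)
  expect_true("q" %in% neighborhood(tiny, "p"))
  expect_error(neighborhood(triangle, "nope"), "not a network node")
})

test_that("network feature vectors read the adjacency row", {
  v <- network_feature_vector(triangle, "b", node_order = c("a", "b", "c"))
  expect_equal(unname(v), c(0.5, 0, 0.9))
  vz <- network_feature_vector(triangle, "z",
                               node_order = c("a", "b", "c", "z"))
  expect_equal(unname(vz), c(0, 0, 0, 0))
  expect_error(network_feature_vector(triangle, "q"), "not a network node")
})

test_that("enrichment score matches the exact hypergeometric tail", {
  pop <- letters[1:10]
  expect_equal(enrichment_score(letters[6:9], letters[1:5], pop), 0)  # no overlap
  # overlap 4 of neigh 4 against term of 5 in population 10
  expected <- -log10(choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(enrichment_score(letters[1:4], letters[1:5], pop), expected,
               tolerance = 1e-12)
  expect_error(enrichment_score(character(), letters[1:2], pop), "nonempty")
})

test_that("enrichment equals brute-force tail enumeration for all small configurations", {
  for (N in c(3L, 7L, 12L, 20L)) {
    pop <- sprintf("p%02d", seq_len(N))
    for (m in 1:N) {
      for (k in 1:N) {
        q_lo <- max(0, k - (N - m))
        for (q in q_lo:min(k, m)) {
          # construct sets realizing exactly this overlap
          neigh <- c(pop[seq_len(q)],
                     if (k > q) pop[(m + 1):(m + k - q)])
          score <- enrichment_score(neigh, pop[seq_len(m)], pop)
          expect_equal(score, -log10(max(hyper_tail_oracle(q, m, N, k),
                                         1e-300)),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("enrichment is nondecreasing in overlap", {
  pop <- sprintf("p%02d", 1:20)
  for (k in c(3, 6, 9)) {
    scores <- vapply(0:k, function(q) {
      neigh <- c(pop[seq_len(q)], if (k > q) pop[(8 + 1):(8 + k - q)])
      enrichment_score(neigh, pop[1:8], pop)
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-12))
  }
})

test_that("encode_features builds ordered blocks of the right width", {
  ds <- small_dataset(seed = 4)
  fm <- encode_features(ds$network, ds$go, ds$pathway,
                        proteins = ds$labels$protein)
  info <- feature_info(fm)
  n_nodes <- length(network_nodes(ds$network))
  expect_equal(nrow(info),
               n_nodes + length(unique(ds$go$term)) +
                 length(unique(ds$pathway$term)))
  expect_equal(unique(info$group), c("network", "GO", "pathway"))  # block order
  expect_true(all(fm_net <- as.matrix(fm[, info$feature[info$group == "network"]]) <= 1))
  expect_true(all(as.matrix(fm[, info$feature[info$group != "network"]]) >= 0))
  expect_false(anyNA(fm))
})

test_that("empty catalogs leave only the network block", {
  fm <- encode_features(triangle)
  expect_equal(setdiff(names(fm), "protein"),
               paste0("network:", c("a", "b", "c")))
})

test_that("encoding is row-permutation-equivariant", {
  ds <- small_dataset(seed = 9, class_sizes = c(20L, 15L))
  prots <- ds$labels$protein
  fm1 <- encode_features(ds$network, ds$go, ds$pathway, proteins = prots)
  perm <- rev(prots)
  fm2 <- encode_features(ds$network, ds$go, ds$pathway, proteins = perm)
  expect_equal(fm2, fm1[match(perm, fm1$protein), ], ignore_attr = TRUE)
})

test_that("proteins outside the network are rejected by name", {
  expect_error(encode_features(triangle, proteins = c("a", "ghost")), "ghost")
})

test_that("planted terms score higher inside their class than outside", {
  ds <- small_dataset(seed = 21, class_sizes = c(80L, 60L, 40L), ipc = 2L)
  fm <- encode_features(ds$network, ds$go, ds$pathway,
                        proteins = ds$labels$protein)
  for (i in seq_len(nrow(ds$ground_truth))) {
    col <- paste0("GO:", ds$ground_truth$term[i])
    cls <- ds$ground_truth$class_index[i]
    in_cls <- ds$labels$class_index == cls
    expect_gt(mean(fm[[col]][in_cls]), mean(fm[[col]][!in_cls]))
  }
})
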