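# --- Boruta ---------------------------------------------------------------

test_that("boruta matches every active feature with one shadow per iteration", {
  set.seed(1)
  x <- matrix(rnorm(80 * 12), 80)
  y <- rep(1:2, each = 40)
  res <- boruta_filter(make_fm(x), y, max_iter = 10, num_trees = 50, seed = 2)
  expect_true(all(res$log$n_shadow == res$log$n_active))
  expect_equal(sort(c(res$confirmed, res$rejected, res$tentative)),
               sort(paste0("GO:f", sprintf("%03d", 1:12))))
})

test_that("boruta confirms a label-identical feature and rejects pure noise", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    y <- rep(1:2, each = 150)
    x <- cbind(y + 0, matrix(rnorm(300 * 50), 300))
    fm <- make_fm(x)
    res <- boruta_filter(fm, y, max_iter = 30, num_trees = 100, seed = seed)
    expect_true("GO:f001" %in% res$confirmed)

    # large enough that chance feature-label correlations stay below the
    # shadow bar; at small n Boruta legitimately flags them as relevant
    noise <- matrix(rnorm(400 * 20), 400)
    resn <- boruta_filter(make_fm(noise), rep(1:2, each = 200), max_iter = 25,
                          num_trees = 100, seed = seed)
    expect_length(resn$confirmed, 0)
  }
})

test_that("boruta rejects degenerate inputs", {
  x <- matrix(rnorm(40), 20)
  expect_error(boruta_filter(make_fm(x), rep(1, 20)), "two classes")
  expect_error(boruta_filter(make_fm(x), rep(1:2, 10), max_iter = 0),
               "max_iter")
})

# --- mRMR -----------------------------------------------------------------

test_that("a single feature is trivially rank 1", {
  x <- matrix(rnorm(30), 30, 1)
  r <- mrmr_rank(make_fm(x), rep(1:2, 15), k = 1)
  expect_equal(r$rank, 1L)
  expect_equal(r$feature, "GO:f001")
})

test_that("greedy mRMR order equals exhaustive MID recomputation on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 12
    x <- matrix(rbinom(n * 4, 1, 0.5) * 2 - 1 + rnorm(n * 4, 0, 0.01), n, 4)
    y <- rbinom(n, 1, 0.5) + 1
    fm <- make_fm(x)
    got <- mrmr_rank(fm, y)
    expect_equal(match(got$feature, names(fm)[-1]), mrmr_oracle(x, y))
  }
  # larger instances, still within the exhaustive oracle's reach
  for (seed in 7:9) {
    set.seed(seed)
    x <- matrix(rnorm(20 * 6), 20, 6)
    y <- rep(1:2, 10)
    fm <- make_fm(x)
    got <- mrmr_rank(fm, y)
    expect_equal(match(got$feature, names(fm)[-1]), mrmr_oracle(x, y))
  }
})

test_that("an exact copy is penalized below an independent informative feature", {
  set.seed(42)
  n <- 60
  y <- rep(1:2, each = 30)
  f1 <- y + rnorm(n, 0, 0.2)
  f3 <- y + rnorm(n, 0, 0.3)        # independent, informative
  x <- cbind(f1, f1, f3)            # column 2 duplicates column 1
  r <- mrmr_rank(make_fm(x), y)
  expect_equal(r$feature[1], "GO:f001")
  expect_equal(r$feature[2], "GO:f003")   # copy does not follow its original
  expect_equal(match(r$feature, paste0("GO:f", sprintf("%03d", 1:3))),
               mrmr_oracle(x, y))
})

test_that("mRMR is invariant under sample order", {
  set.seed(5)
  x <- matrix(rnorm(40 * 8), 40)
  y <- rep(1:2, 20)
  fm <- make_fm(x)
  r1 <- mrmr_rank(fm, y)
  perm <- sample(40)
  fmp <- fm[perm, ]
  class(fmp) <- class(fm)
  r2 <- mrmr_rank(fmp, y[perm])
  expect_equal(r1$feature, r2$feature)
  expect_equal(r1$score, r2$score)
})

# --- MCFS -----------------------------------------------------------------

test_that("MCFS scores are nonincreasing and unsampled features stay at zero", {
  set.seed(3)
  x <- matrix(rnorm(50 * 10), 50)
  y <- rep(1:2, 25)
  r <- mcfs_rank(make_fm(x), y, projections = 1, proj_features = 3,
                 trees_per_projection = 2, seed = 4)
  expect_true(all(diff(r$score) <= 1e-12))
  expect_lte(sum(r$score > 0), 3)        # only one 3-feature projection ran
  r2 <- mcfs_rank(make_fm(x), y, projections = 1, proj_features = 3,
                  trees_per_projection = 2, seed = 4)
  expect_identical(r, r2)                # seeded determinism
})

test_that("a perfectly separating feature tops the MCFS list across seeds", {
  for (seed in 1:5) {
    set.seed(seed + 300)
    n <- 90
    y <- rep(1:3, each = 30)
    x <- cbind(y + 0, matrix(rnorm(n * 30), n))
    r <- mcfs_rank(make_fm(x), y, projections = 50, proj_features = 6,
                   trees_per_projection = 5, seed = seed)
    expect_equal(r$feature[1], "GO:f001")
  }
})

# --- GBDT -----------------------------------------------------------------

test_that("GBDT split counts are integer, constants rank last, planted wins", {
  for (seed in 1:5) {
    set.seed(seed + 500)
    n <- 80
    y <- rep(1:2, each = 40)
    x <- cbind(y + rnorm(n, 0, 0.1), matrix(rnorm(n * 10), n),
               rep(1, n))                 # last column constant
    fm <- make_fm(x)
    r <- gbdt_rank(fm, y, n_rounds = 30, seed = seed)
    expect_true(all(r$score >= 0 & r$score == floor(r$score)))
    expect_equal(r$feature[1], "GO:f001")
    const_pos <- which(r$feature == "GO:f012")
    expect_equal(r$score[const_pos], 0)
    expect_true(all(r$score[seq_len(const_pos - 1)] >= 0))
  }
  expect_error(gbdt_rank(make_fm(matrix(1, 30, 3)), rep(1:2, 15)), "constant")
})
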