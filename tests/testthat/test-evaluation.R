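# --- SMOTE ----------------------------------------------------------------

test_that("SMOTE equalizes classes to the majority and preserves observed rows", {
  set.seed(8)
  x <- matrix(rnorm(60 * 3), 60)
  y <- rep(1:3, c(30, 20, 10))
  bal <- smote_balance(x, y, seed = 2)
  expect_equal(unname(table(bal$labels)), rep(30L, 3), ignore_attr = TRUE)
  expect_equal(as.matrix(bal$data[seq_len(60), ]), x, ignore_attr = TRUE)
  expect_equal(bal$origin[seq_len(60)], rep("observed", 60))
  expect_true(all(bal$labels[bal$origin == "synthetic"] != 1))  # majority untouched
})

test_that("already balanced input returns unchanged", {
  x <- matrix(rnorm(40), 20)
  y <- rep(1:2, each = 10)
  bal <- smote_balance(x, y, seed = 1)
  expect_equal(nrow(bal$data), 20)
  expect_true(all(bal$origin == "observed"))
})

test_that("the reference 16-class profile balances to the dominant class", {
  profile <- reference_class_profile()$n_proteins
  set.seed(4)
  y <- rep(seq_along(profile), profile)
  x <- matrix(rnorm(length(y) * 2), length(y))
  bal <- smote_balance(x, y, seed = 9)
  expect_equal(unname(table(bal$labels)), rep(1487L, 16), ignore_attr = TRUE)
})

test_that("synthetic points lie on segments between same-class observed points", {
  set.seed(10)
  x <- matrix(rnorm(24), 12, 2)
  y <- rep(1:2, c(8, 4))
  bal <- smote_balance(x, y, k_neighbors = 3, seed = 5)
  syn <- as.matrix(bal$data[bal$origin == "synthetic", ])
  minority <- x[y == 2, ]
  on_segment <- function(p) {
    for (i in seq_len(nrow(minority))) {
      for (j in seq_len(nrow(minority))) {
        if (i == j) next
        a <- minority[i, ]; b <- minority[j, ]
        d <- b - a
        if (all(abs(d) < 1e-12)) next
        u <- (p - a)[which.max(abs(d))] / d[which.max(abs(d))]
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(a + u * d - p)) < 1e-9) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))
})

test_that("singleton classes fall back to duplication with a warning", {
  x <- matrix(rnorm(12), 6, 2)
  y <- c(1, 1, 1, 1, 1, 2)
  expect_warning(bal <- smote_balance(x, y, seed = 3), "single sample")
  expect_equal(sum(bal$labels == 2), 5)
})

# --- stratified folds -----------------------------------------------------

test_that("test folds partition samples with balanced class coverage", {
  y <- rep(1:3, each = 10)
  folds <- stratified_folds(y, n_folds = 10, seed = 6)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_along(y))     # partition
  for (f in folds) {
    expect_length(f$test, 3)
    expect_equal(sort(y[f$test]), 1:3)                # one per class
    expect_equal(sort(c(f$train, f$test)), seq_along(y))
  }
  # per-class counts across folds differ by at most one for ragged sizes
  y2 <- rep(1:3, c(23, 11, 7))
  folds2 <- stratified_folds(y2, n_folds = 5, seed = 6)
  for (cls in 1:3) {
    per_fold <- vapply(folds2, function(f) sum(y2[f$test] == cls), integer(1))
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_identical(folds, stratified_folds(y, n_folds = 10, seed = 6))
  expect_error(stratified_folds(1:5, n_folds = 6), "exceeds")
})

# --- multiclass MCC -------------------------------------------------------

test_that("MCC is 1 for perfect, -1 for flipped binary predictions", {
  act <- rep(1:3, each = 5)
  expect_equal(gorodkin_mcc(act, act, 3), 1)
  b <- rep(1:2, each = 10)
  expect_equal(gorodkin_mcc(3 - b, b, 2), -1)
})

test_that("one-hot covariance MCC equals the confusion-matrix Rk closed form", {
  cm <- matrix(c(2, 1, 0, 0, 3, 1, 1, 0, 2), 3, byrow = TRUE)
  act <- rep(1:3, rowSums(cm))
  pred <- unlist(lapply(1:3, function(i) rep(1:3, cm[i, ])))
  expect_equal(gorodkin_mcc(pred, act, 3), rk_confusion_oracle(cm),
               tolerance = 1e-12)
  # random multiclass instances
  set.seed(77)
  for (i in 1:50) {
    K <- sample(2:5, 1)
    n <- sample(10:40, 1)
    act <- sample(K, n, replace = TRUE)
    pred <- sample(K, n, replace = TRUE)
    cm <- as.matrix(table(factor(act, 1:K), factor(pred, 1:K)))
    expect_equal(gorodkin_mcc(pred, act, K), rk_confusion_oracle(cm),
                 tolerance = 1e-12)
  }
})

test_that("the K=2 case reduces to the textbook binary MCC", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    act <- sample(1:2, n, replace = TRUE)
    pred <- sample(1:2, n, replace = TRUE)
    expect_equal(gorodkin_mcc(pred, act, 2), binary_mcc_oracle(pred, act),
                 tolerance = 1e-12)
  }
})

test_that("MCC is invariant under consistent class relabeling", {
  set.seed(9)
  act <- sample(1:4, 40, replace = TRUE)
  pred <- sample(1:4, 40, replace = TRUE)
  perm <- sample(4)
  expect_equal(gorodkin_mcc(perm[pred], perm[act], 4),
               gorodkin_mcc(pred, act, 4), tolerance = 1e-12)
})

test_that("degenerate single-class cases return 0 with a warning", {
  expect_warning(v <- gorodkin_mcc(rep(1, 5), rep(1, 5), 2), "degenerate")
  expect_equal(v, 0)
  expect_error(gorodkin_mcc(1:3, 1:2, 3), "equal length")
})

# --- evaluate_classifier --------------------------------------------------

test_that("separable data is classified perfectly and ACC matches pooled predictions", {
  set.seed(15)
  n <- 60
  y <- rep(1:3, each = 20)
  x <- cbind(y * 10 + rnorm(n, 0, 0.1), rnorm(n))
  fm <- make_fm(x)
  for (alg in c("rf", "svm")) {
    rep <- evaluate_classifier(fm, labels_for(fm, y), algorithm = alg,
                               n_folds = 5, seed = 3)
    expect_equal(rep$acc, 1)
    expect_equal(rep$mcc, 1)
    expect_true(all(rep$per_class$class_accuracy == 1))
  }
})

test_that("report arithmetic is internally consistent and leakage-free", {
  ds <- small_dataset(seed = 31, class_sizes = c(30L, 20L, 10L))
  fm <- encode_features(ds$network, ds$go, ds$pathway,
                        proteins = ds$labels$protein)
  rep <- evaluate_classifier(fm, ds$labels, algorithm = "rf", n_folds = 5,
                             seed = 4)
  p <- rep$predictions
  expect_equal(nrow(p), nrow(fm))                 # only observed rows scored
  expect_equal(sort(p$row), seq_len(nrow(fm)))    # each exactly once
  expect_equal(rep$acc, mean(p$predicted == p$actual))
  for (i in seq_len(nrow(rep$per_class))) {
    cls <- rep$per_class$class_index[i]
    expect_equal(rep$per_class$class_accuracy[i],
                 mean(p$predicted[p$actual == cls] == cls))
  }
  rep2 <- evaluate_classifier(fm, ds$labels, algorithm = "rf", n_folds = 5,
                              seed = 4)
  expect_equal(rep$predictions, rep2$predictions)  # seeded determinism
  expect_error(evaluate_classifier(fm, ds$labels, algorithm = "nn"))
})
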