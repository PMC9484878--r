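#' SMOTE class balancing
#'
#' Oversamples every minority class up to the majority-class count by
#' synthesizing points on segments between a minority sample and one of
#' its `k_neighbors` nearest same-class neighbors (Euclidean): each new
#' row is `x + u * (x' - x)` with `u ~ uniform(0, 1)`.  Observed rows are
#' returned unchanged (bit-for-bit) ahead of the synthetic rows; a class
#' with a single sample falls back to duplication with a warning.
#'
#' @param data Data frame or matrix of numeric features (rows = samples).
#' @param labels Vector of class labels aligned with `data` rows.
#' @param k_neighbors Neighborhood size for interpolation partners
#'   (reduced for classes smaller than `k_neighbors + 1`).
#' @param seed Integer seed; the result is deterministic given it.
#' @return A list with `data` (tibble), `labels`, and `origin`
#'   (`"observed"` / `"synthetic"` per row).
#' @examples
#' x <- data.frame(a = c(0, 1, 0, 4, 5, 6, 7), b = c(0, 1, 2, 0, 1, 2, 3))
#' y <- c(1, 1, 1, 2, 2, 2, 2)
#' smote_balance(x, y, seed = 1)$labels
#' @export
smote_balance <- function(data, labels, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  if (any(counts == 0)) abort("empty class in `labels`")
  n_max <- max(counts)
  local_seed(seed)
  syn_x <- list(); syn_y <- list()
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0) next
    rows <- which(labels == cl)
    xc <- x[rows, , drop = FALSE]
    nc <- nrow(xc)
    if (nc == 1) {
      warn(sprintf("class '%s' has a single sample; duplicating instead of interpolating", cl))
      syn_x[[cl]] <- xc[rep(1, need), , drop = FALSE]
      syn_y[[cl]] <- rep(labels[rows[1]], need)
      next
    }
    k <- min(k_neighbors, nc - 1)
    d <- as.matrix(dist(xc))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
    nn <- matrix(nn, nrow = k)                  # k x nc, ties broken stably
    parent <- ((seq_len(need) - 1) %% nc) + 1   # cycle through minority rows
    pick <- sample.int(k, need, replace = TRUE)
    u <- runif(need)
    mate <- nn[cbind(pick, parent)]
    syn_x[[cl]] <- xc[parent, , drop = FALSE] +
      u * (xc[mate, , drop = FALSE] - xc[parent, , drop = FALSE])
    syn_y[[cl]] <- rep(labels[rows[1]], need)
  }
  new_x <- do.call(rbind, syn_x)
  out_x <- rbind(x, new_x)
  out <- as_tibble(as.data.frame(out_x), .name_repair = "minimal")
  list(data = out,
       labels = c(labels, unlist(syn_y, use.names = FALSE)),
       origin = c(rep("observed", nrow(x)),
                  rep("synthetic", if (is.null(new_x)) 0 else nrow(new_x))))
}

#' Seeded stratified cross-validation folds
#'
#' Assigns samples of each class round-robin to folds after a seeded
#' within-class shuffle, so test folds partition the data and per-class
#' test counts differ by at most one across folds.
#'
#' @param labels Class label per sample.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of `n_folds` elements, each `list(train =, test =)`
#'   integer index vectors.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  check_count(n_folds, "n_folds", min = 2)
  n <- length(labels)
  if (n_folds > n) {
    abort("`n_folds` exceeds the number of samples",
          class = "sublocfs_config_error")
  }
  local_seed(seed)
  fold_of <- integer(n)
  offset <- 0L
  for (cl in sort(unique(as.character(labels)))) {
    rows <- which(labels == cl)
    rows <- rows[sample.int(length(rows))]
    fold_of[rows] <- ((offset + seq_along(rows) - 1L) %% n_folds) + 1L
    offset <- offset + length(rows)   # stagger classes across folds
  }
  lapply(seq_len(n_folds), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Multiclass Matthews correlation coefficient (Rk)
#'
#' Computes the Gorodkin multiclass MCC from one-hot indicator matrices:
#' with X the N x K 0-1 matrix of predicted classes and Y the matrix of
#' actual classes, returns cov(X, Y) / sqrt(cov(X, X) cov(Y, Y)), where
#' cov(A, B) is the sum over classes of the column-centered cross
#' products.  Ranges over \[-1, 1\]; 1 for perfect prediction.  When a
#' variance term vanishes (all predictions or all truths in one class)
#' the coefficient is undefined and 0 is returned with a warning.
#'
#' @param predicted,actual Integer class indices in `1..n_classes`, equal
#'   length.
#' @param n_classes Number of classes K.
#' @return A number in \[-1, 1\].
#' @examples
#' gorodkin_mcc(c(1, 2, 3, 1), c(1, 2, 3, 2), 3)
#' @export
gorodkin_mcc <- function(predicted, actual, n_classes) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length")
  }
  stopifnot(all(predicted %in% seq_len(n_classes)),
            all(actual %in% seq_len(n_classes)))
  n <- length(predicted)
  X <- matrix(0, n, n_classes); X[cbind(seq_len(n), predicted)] <- 1
  Y <- matrix(0, n, n_classes); Y[cbind(seq_len(n), actual)] <- 1
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  num <- sum(Xc * Yc)
  den <- sqrt(sum(Xc * Xc)) * sqrt(sum(Yc * Yc))
  if (den == 0) {
    warn("degenerate single-class predictions or truths; MCC set to 0")
    return(0)
  }
  num / den
}

#' Cross-validated classifier evaluation
#'
#' Evaluates a feature subset with a named classifier under seeded
#' stratified `n_folds` cross-validation.  With `balance = TRUE` (the
#' default) SMOTE is applied to the *training* portion of each fold only,
#' so no synthetic sample can leak into a test fold; `balance_global`
#' reproduces the historically common—but leaky—variant that balances
#' the whole dataset before splitting, for comparison.
#'
#' Classifier contracts: `"rf"` is a 100-tree random forest (randomForest,
#' impurity splits, seeded); `"svm"` is a support vector
#' machine with polynomial kernel of degree 1 and cost C = 1
#' (one-vs-one multiclass).
#'
#' @param fm A `feature_matrix` (tibble with `protein` column).
#' @param labels Tibble with `protein`, `class_index`.
#' @param features Character vector of feature columns to use (default:
#'   all).
#' @param algorithm `"rf"` or `"svm"`.
#' @param n_folds Cross-validation folds (default 10).
#' @param balance Apply SMOTE inside each training fold.
#' @param balance_global Balance the full dataset before splitting
#'   (leaky; off by default).
#' @param k_neighbors SMOTE neighborhood size.
#' @param num_trees Trees for the random forest contract.
#' @param seed Integer seed controlling folds, balancing and the forest.
#' @return An `eval_report`: list with `mcc`, `acc`, `per_class` (tibble
#'   `class_index`, `class_accuracy`, `class_n`), `predictions` (tibble
#'   `row`, `fold`, `actual`, `predicted`) and `config`.
#' @export
evaluate_classifier <- function(fm, labels, features = NULL,
                                algorithm = c("rf", "svm"),
                                n_folds = 10L, balance = TRUE,
                                balance_global = FALSE,
                                k_neighbors = 5L, num_trees = 100L,
                                seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- fm_matrix(fm, features)
  lab <- labels$class_index[match(rownames(x), labels$protein)]
  if (anyNA(lab)) abort("every encoded protein needs a label")
  n_classes <- max(lab)
  if (length(unique(lab)) < 2) abort("need at least two classes")
  if (nrow(x) < n_folds) abort("fewer samples than folds",
                               class = "sublocfs_config_error")

  if (balance_global) {
    bal <- smote_balance(x, lab, k_neighbors, derive_seed(seed, "global-balance"))
    x <- as.matrix(bal$data); lab <- bal$labels
    balance <- FALSE
  }
  folds <- stratified_folds(lab, n_folds, derive_seed(seed, "folds"))
  preds <- integer(nrow(x)); fold_id <- integer(nrow(x))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    x_tr <- x[tr, , drop = FALSE]; y_tr <- lab[tr]
    if (balance) {
      bal <- smote_balance(x_tr, y_tr, k_neighbors,
                           derive_seed(seed, paste0("smote-fold-", f)))
      x_tr <- as.matrix(bal$data); y_tr <- bal$labels
    }
    preds[te] <- fit_predict(x_tr, y_tr, x[te, , drop = FALSE], algorithm,
                             num_trees, derive_seed(seed, paste0("fit-", f)),
                             n_classes)
    fold_id[te] <- f
  }
  acc <- mean(preds == lab)
  per_class <- tibble(class_index = sort(unique(lab))) |>
    mutate(class_accuracy = vapply(.data$class_index, function(k) {
             mean(preds[lab == k] == k)
           }, numeric(1)),
           class_n = vapply(.data$class_index, function(k) sum(lab == k),
                            integer(1)))
  structure(
    list(mcc = gorodkin_mcc(preds, lab, n_classes),
         acc = acc,
         per_class = per_class,
         predictions = tibble(row = seq_len(nrow(x)), fold = fold_id,
                              actual = lab, predicted = preds),
         config = list(algorithm = algorithm, n_folds = n_folds,
                       balance = balance, balance_global = balance_global,
                       n_features = ncol(x), seed = seed)),
    class = "eval_report")
}

fit_predict <- function(x_tr, y_tr, x_te, algorithm, num_trees, seed,
                        n_classes) {
  yf <- factor(y_tr, levels = seq_len(n_classes))
  colnames(x_tr) <- colnames(x_te) <- paste0("f", seq_len(ncol(x_tr)))
  if (algorithm == "rf") {
    # randomForest draws from the R RNG, so seeding here makes the fit
    # bit-reproducible even on tie-heavy SMOTE-augmented training sets
    local_seed(seed)
    fit <- randomForest::randomForest(x = x_tr, y = droplevels(yf),
                                      ntree = num_trees)
    as.integer(as.character(predict(fit, newdata = x_te)))
  } else {
    fit <- e1071::svm(x = x_tr, y = droplevels(yf), kernel = "polynomial",
                      degree = 1, cost = 1, scale = FALSE)
    as.integer(as.character(predict(fit, newdata = x_te)))
  }
}
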