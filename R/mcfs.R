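#' Monte Carlo feature selection (relative importance ranking)
#'
#' Ranks features by aggregating their contribution to many small
#' decision trees trained on random feature subsets ("projections").
#' For each of `projections` subsets of `proj_features` features,
#' `trees_per_projection` entropy CART trees are grown on a stratified
#' random `train_fraction` of the samples (per-class sampling, so rare
#' classes reach every tree) and scored on the held-out remainder.
#' The relative importance of feature g is
#'
#'   RI(g) = sum over trees wAcc(tree) * sum over nodes splitting on g of
#'           IG(node) * n(node) / n(root)
#'
#' where wAcc is the tree's balanced accuracy (mean per-class recall) on
#' its held-out samples and IG the information gain of the split.
#' Features are returned in decreasing RI order, ties broken by original
#' column order; a feature appearing in no projection has RI 0.  The run
#' is deterministic given `seed`.
#'
#' The projection trees are grown by a small dedicated entropy CART
#' implementation because the RI score needs each split's information
#' gain and node sample fraction, which off-the-shelf tree fitters do not
#' expose.
#'
#' @param fm A `feature_matrix`.
#' @param labels Labels tibble (`protein`, `class_index`) or vector.
#' @param projections Number s of random feature subsets; default gives
#'   each feature about `coverage` appearances in expectation.
#' @param proj_features Features m per projection; default `ceiling(sqrt(d))`.
#' @param trees_per_projection Trees t per projection (default 5).
#' @param coverage Expected appearances per feature used to derive the
#'   default `projections`.
#' @param max_depth,min_node Tree growth limits.
#' @param train_fraction Fraction of samples used to grow each tree.
#' @param seed Integer seed.
#' @return A `ranked_features` tibble with `score` = RI.
#' @export
mcfs_rank <- function(fm, labels, projections = NULL, proj_features = NULL,
                      trees_per_projection = 5L, coverage = 20,
                      max_depth = 6L, min_node = 5L, train_fraction = 0.66,
                      seed = 1L) {
  al <- align_labels(fm, labels)
  x <- al$x; lab <- al$labels
  d <- ncol(x); n <- nrow(x)
  if (is.null(proj_features)) proj_features <- ceiling(sqrt(d))
  check_count(proj_features, "proj_features")
  if (proj_features > d) {
    abort("`proj_features` exceeds the number of features",
          class = "sublocfs_config_error")
  }
  if (is.null(projections)) {
    projections <- ceiling(coverage * d / proj_features)
  }
  check_count(projections, "projections")
  check_count(trees_per_projection, "trees_per_projection")
  y <- match(lab, sort(unique(lab)))
  n_y <- max(y)

  local_seed(derive_seed(seed, "mcfs"))
  ri <- numeric(d)
  cls_rows <- split(seq_len(n), y)   # stratified splits keep rare classes in every tree
  for (p in seq_len(projections)) {
    feats <- sample.int(d, proj_features)
    xp <- x[, feats, drop = FALSE]
    for (t in seq_len(trees_per_projection)) {
      tr <- sort(unlist(lapply(cls_rows, function(r) {
        r[sample.int(length(r), max(1L, round(train_fraction * length(r))))]
      }), use.names = FALSE))
      if (length(tr) >= n) tr <- tr[-length(tr)]
      tree <- grow_entropy_tree(xp[tr, , drop = FALSE], y[tr], n_y,
                                max_depth, min_node)
      if (is.null(tree$feature)) next          # root is a leaf
      oob <- setdiff(seq_len(n), tr)
      pred <- predict_entropy_tree(tree, xp[oob, , drop = FALSE])
      wacc <- balanced_accuracy(pred, y[oob])
      if (is.na(wacc) || wacc <= 0) next
      contrib <- tree_contributions(tree, n_root = length(tr))
      ri[feats[contrib$feature]] <- ri[feats[contrib$feature]] +
        wacc * contrib$weight
    }
  }
  ord <- order(-ri, seq_len(d))
  rank_result(colnames(x), ri, ord, "mcfs")
}

balanced_accuracy <- function(pred, truth) {
  classes <- unique(truth)
  mean(vapply(classes, function(k) mean(pred[truth == k] == k), numeric(1)))
}

# --- minimal entropy CART used only for the RI computation ----------------

grow_entropy_tree <- function(x, y, n_y, max_depth, min_node, depth = 0L) {
  n <- length(y)
  maj <- which.max(tabulate(y, nbins = n_y))
  if (depth >= max_depth || n < min_node || length(unique(y)) == 1) {
    return(list(leaf = TRUE, class = maj))
  }
  best <- list(gain = 0)
  for (j in seq_len(ncol(x))) {
    sp <- best_entropy_split(x[, j], y, n_y)
    if (!is.null(sp) && sp$gain > best$gain + 1e-12) {
      best <- c(sp, feature = j)
    }
  }
  if (is.null(best$threshold)) return(list(leaf = TRUE, class = maj))
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       gain = best$gain, n = n, class = maj,
       left = grow_entropy_tree(x[left, , drop = FALSE], y[left], n_y,
                                max_depth, min_node, depth + 1L),
       right = grow_entropy_tree(x[!left, , drop = FALSE], y[!left], n_y,
                                 max_depth, min_node, depth + 1L))
}

best_entropy_split <- function(v, y, n_y) {
  n <- length(y)
  o <- order(v)
  vs <- v[o]; ys <- y[o]
  cuts <- which(vs[-n] < vs[-1])
  if (length(cuts) == 0) return(NULL)
  onehot <- matrix(0, n, n_y)
  onehot[cbind(seq_len(n), ys)] <- 1
  cum <- apply(onehot, 2, cumsum)
  tot <- cum[n, ]
  left <- cum[cuts, , drop = FALSE]
  right <- rep(tot, each = length(cuts)) - left
  nl <- cuts; nr <- n - cuts
  h <- function(cnt, size) {
    p <- cnt / size
    -rowSums(ifelse(p > 0, p * log(p), 0))
  }
  h_parent <- {
    p <- tot / n
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  gain <- h_parent - (nl * h(left, nl) + nr * h(right, nr)) / n
  b <- which.max(gain)
  list(gain = gain[b], threshold = (vs[cuts[b]] + vs[cuts[b] + 1]) / 2)
}

predict_entropy_tree <- function(tree, x) {
  pred <- integer(nrow(x))
  walk <- function(node, rows) {
    if (length(rows) == 0) return()
    if (isTRUE(node$leaf)) {
      pred[rows] <<- node$class
      return()
    }
    left <- x[rows, node$feature] <= node$threshold
    walk(node$left, rows[left])
    walk(node$right, rows[!left])
  }
  walk(tree, seq_len(nrow(x)))
  pred
}

# per-split RI contributions: feature index + IG * node fraction
tree_contributions <- function(tree, n_root) {
  feats <- integer(0); w <- numeric(0)
  walk <- function(node) {
    if (isTRUE(node$leaf)) return()
    feats <<- c(feats, node$feature)
    w <<- c(w, node$gain * node$n / n_root)
    walk(node$left); walk(node$right)
  }
  walk(tree)
  list(feature = feats, weight = w)
}
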