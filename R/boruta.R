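#' Boruta all-relevant feature filtering
#'
#' Separates features that carry any information about the class labels
#' from irrelevant ones by competing them against "shadow" copies of
#' themselves.  Each iteration appends one independently permuted shadow
#' column per active original column, trains a random forest on the
#' combined matrix, and records for every undecided feature whether its
#' impurity importance exceeded the *maximum* shadow importance (a "hit").
#' A cumulative two-sided binomial test on the hit count at level `alpha`,
#' Bonferroni-corrected over the currently undecided features, confirms
#' features that hit significantly more than half the time and rejects
#' those that hit significantly less.  Rejected features (and their
#' shadows) drop out of later iterations; features still undecided after
#' `max_iter` iterations are reported as tentative, with a separate
#' median-importance comparison (`tentative_resolved`) that is reported
#' but never auto-confirmed.
#'
#' @param fm A `feature_matrix` from [encode_features()].
#' @param labels Labels tibble (`protein`, `class_index`) or vector.
#' @param max_iter Maximum number of shadow iterations.
#' @param alpha Significance level of the binomial decision test.
#' @param num_trees Trees per forest.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `boruta_result`: list with character vectors `confirmed`,
#'   `rejected`, `tentative`, `tentative_resolved`, the per-feature
#'   `decision` tibble, the per-iteration `log` (tibble `iteration`,
#'   `n_active`, `n_shadow`, `shadow_max`) and `n_iterations`.
#' @export
boruta_filter <- function(fm, labels, max_iter = 100L, alpha = 0.05,
                          num_trees = 300L, seed = 1L) {
  check_count(max_iter, "max_iter")
  check_prob(alpha, "alpha")
  al <- align_labels(fm, labels)
  x <- al$x; lab <- al$labels
  if (length(unique(lab)) < 2) abort("labels must contain at least two classes")
  d <- ncol(x)
  feats <- colnames(x)
  yf <- factor(lab)

  state <- rep("undecided", d)
  hits <- integer(d); n_it <- integer(d)
  imp_hist <- vector("list", d)
  shadow_max_hist <- numeric(0)
  log_rows <- list()

  local_seed(derive_seed(seed, "boruta-shuffle"))
  iter <- 0L
  while (iter < max_iter && any(state == "undecided")) {
    iter <- iter + 1L
    active <- which(state != "rejected")
    xa <- x[, active, drop = FALSE]
    shadow <- apply(xa, 2, sample)      # independent permutation per column
    colnames(shadow) <- paste0("shadow_", seq_along(active))
    colnames(xa) <- paste0("orig_", seq_along(active))
    fit <- ranger::ranger(x = cbind(xa, shadow), y = yf,
                          num.trees = num_trees,
                          importance = "impurity",
                          seed = derive_seed(seed, paste0("boruta-rf-", iter)),
                          num.threads = 1)
    imp <- fit$variable.importance
    imp_orig <- imp[seq_along(active)]
    shadow_max <- max(imp[-seq_along(active)])
    shadow_max_hist <- c(shadow_max_hist, shadow_max)
    for (j in seq_along(active)) {
      imp_hist[[active[j]]] <- c(imp_hist[[active[j]]], imp_orig[j])
    }
    und <- which(state == "undecided")
    hit_now <- imp_orig[match(und, active)] > shadow_max
    hits[und] <- hits[und] + as.integer(hit_now)
    n_it[und] <- n_it[und] + 1L
    log_rows[[iter]] <- tibble(iteration = iter,
                               n_active = length(active),
                               n_shadow = ncol(shadow),
                               shadow_max = shadow_max)
    # cumulative two-sided binomial decision, Bonferroni over undecided
    m <- length(und)
    for (f in und) {
      p_hi <- pbinom(hits[f] - 1L, n_it[f], 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[f], n_it[f], 0.5)
      p_two <- min(1, 2 * min(p_hi, p_lo))
      if (p_two < alpha / m) {
        state[f] <- if (p_hi < p_lo) "confirmed" else "rejected"
      }
    }
  }
  med_imp <- vapply(imp_hist, function(h) {
    if (length(h) == 0) NA_real_ else median(h)
  }, numeric(1))
  tentative <- feats[state == "undecided"]
  resolved <- feats[state == "undecided" &
                      !is.na(med_imp) & med_imp > median(shadow_max_hist)]
  decision <- tibble(feature = feats,
                     decision = ifelse(state == "undecided", "tentative", state),
                     hits = hits, n_iter = n_it,
                     median_importance = med_imp)
  structure(
    list(confirmed = feats[state == "confirmed"],
         rejected = feats[state == "rejected"],
         tentative = tentative,
         tentative_resolved = resolved,
         decision = decision,
         log = dplyr::bind_rows(log_rows),
         n_iterations = iter,
         alpha = alpha, seed = seed),
    class = "boruta_result")
}
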