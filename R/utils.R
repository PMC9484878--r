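#' Derive a stage-specific seed from a global seed
#'
#' All stochastic stages of the pipeline draw their seed from one global
#' seed through this deterministic derivation, so any stage can be re-run
#' in isolation and reproduce its in-pipeline behaviour.  The derivation
#' hashes the stage label onto the seed and reduces modulo a prime below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"boruta"`).
#' @return A positive integer seed, distinct across stage labels.
#' @examples
#' derive_seed(1, "boruta")
#' derive_seed(1, "mcfs")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  p <- 2147483629  # prime < 2^31
  chars <- utf8ToInt(stage)
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% p
  # seed is a small integer in practice; products stay well below 2^53
  as.integer(((abs(seed) %% p) * 131 + h) %% p + 1)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "sublocfs_config_error")
  }
  invisible(as.integer(x))
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
          class = "sublocfs_config_error")
  }
  invisible(as.numeric(x))
}

# seed the RNG for the calling function's scope and restore the caller's
# global RNG state on exit, so seeded stages never perturb user code
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  invisible(seed)
}

# first-colon split of "group:source" feature ids; GO ids keep their own colon
split_feature_id <- function(feature) {
  pos <- regexpr(":", feature, fixed = TRUE)
  list(group = substr(feature, 1, pos - 1),
       source = substr(feature, pos + 1, nchar(feature)))
}
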