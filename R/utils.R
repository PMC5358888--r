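# Internal helpers: classed errors and seed plumbing.

rbf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("rbf_", class), "rbf_error")))
}

#' Derive a module-level seed from a global seed
#'
#' Maps `(seed, tag, index)` deterministically into `[0, 2^31 - 2]` so every
#' stochastic stage of the pipeline draws from its own stream: changing the
#' number of Monte-Carlo walks, or adding a stage, never perturbs the
#' replicate split or the synthetic data.
#'
#' @param seed integer global seed.
#' @param tag character stream label (e.g. `"split"`, `"walks"`).
#' @param index optional integer sub-stream (e.g. metabolite index).
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, tag, index = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  # all products stay well below 2^53, so double arithmetic is exact
  as.integer(((seed %% m) * 69621 + h * 48271 + (index %% m) * 16807) %% m)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# lossless numeric formatting for text serialization
fmt_num <- function(x) sprintf("%.17g", x)
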