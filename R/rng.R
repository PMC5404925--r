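# Deterministic, scoped random number generation.  Every stochastic operation
# takes (or derives) an explicit seed so that identical inputs give
# byte-identical outputs regardless of the caller's RNG state.

.hash_tag <- function(tag) {
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  h
}

#' Derive a child seed from a root seed and a stage tag
#'
#' Stage-level reproducibility: each stochastic stage of a pipeline draws from
#' its own stream, derived deterministically from one root seed, so re-running
#' a single stage reproduces its output exactly.
#'
#' @param seed Integer root seed.
#' @param tag Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  as.integer((abs(as.numeric(seed)) %% 2147483647 + .hash_tag(tag)) %% 2147483647)
}

#' Evaluate code under a fixed seed, restoring the caller's RNG state
#'
#' Fixes the RNG kinds (Mersenne-Twister / Inversion / Rejection) so results
#' are reproducible across sessions, and restores `.Random.seed` afterwards.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

# Negative-binomial draws parameterized by mean and overdispersion alpha,
# var = mu + alpha * mu^2; alpha = 0 is the Poisson limit.
rnb <- function(n, mu, alpha) {
  if (alpha < 0) stop("dispersion alpha must be >= 0")
  if (alpha == 0) stats::rpois(n, lambda = mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}
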