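# Seed handling: every stochastic entry point takes an optional integer seed
# and runs in a local RNG scope, so user-level .Random.seed is never clobbered.

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed (if non-NULL), evaluates `expr`, and restores the caller's
#' `.Random.seed` on exit. With `seed = NULL` the current RNG stream is used
#' and advanced as usual.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive independent child seeds from a root seed
#'
#' All multi-realization routines split their randomness by drawing one child
#' seed per realization from the root seed, so per-realization results do not
#' depend on evaluation order.
#'
#' @param seed Root integer seed (or `NULL` for the current RNG stream).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
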