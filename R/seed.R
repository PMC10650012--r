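# Deterministic seed handling. All stochastic code in the package funnels
# through these helpers so that one root seed reproduces an entire study.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a root seed and a set of integer coordinates
# (e.g. subject, day, side index). A small multiplicative hash keeps children
# well separated and below 2^31.
child_seed <- function(seed, ...) {
  ids <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (k in ids) {
    h <- (h * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(h)
}
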