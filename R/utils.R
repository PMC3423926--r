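#' Evaluate an expression under a temporary RNG state
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper: the global RNG state is saved, `seed` is set, `code` is
#' evaluated, and the previous state is restored. Nothing outside the call
#' sees a changed random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# single %||% used across the package
`%||%` <- function(a, b) if (is.null(a)) b else a
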