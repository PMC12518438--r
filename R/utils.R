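#' Evaluate an expression under a local random seed
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so generators never leak global random state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @keywords internal
abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}
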