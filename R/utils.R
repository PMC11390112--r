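#' Evaluate an expression under a local, named random seed
#'
#' All stochastic operations in the package draw their randomness through
#' this helper so that the global R random stream is never consumed or
#' disturbed: the caller's `.Random.seed` is restored on exit.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic, collision-resistant-enough mapping that keeps derived
#' seeds inside the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param ... Integers (stage index, day index, ...) mixed into the seed.
#' @keywords internal
#' @noRd
deriveSeed <- function(seed, ...) {
  ks <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (k in ks) h <- (h * 69069 + k + 12345) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abortIf <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
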