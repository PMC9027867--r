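#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit `seed` and run
#' through this helper, so nothing depends on (or disturbs) the caller's
#' global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-seed (< 2^31) for pipeline stage `k`.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}

#' Half-up integer rounding
#'
#' Rounds to the nearest integer with ties going away from zero toward the
#' larger integer (0.5 -> 1), unlike [base::round()]'s banker's rounding.
#' Used to convert expected egg abundances to whole eggs before change
#' classification, so tiny float drifts cannot create spurious changes.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.4, 0.5, 1.5, 2.49))
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(..., call. = FALSE)
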