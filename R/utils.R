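#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero (2.5 -> 3, -2.5 -> -3), unlike
#' [base::round()]'s round-half-even. This is the rounding that reproduces the
#' published progressive-ratio requirement series and the printed infusion
#' durations.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector, rounded.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -2.5))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, min = -Inf, max = Inf,
                             strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a finite numeric scalar", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_param(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}
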