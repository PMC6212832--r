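#' Centered moving average
#'
#' Smooths a numeric series with a centered moving average of odd window
#' `window`. Positions whose window would run off either end are returned as
#' `NA`, so the smoothed series never mixes partial windows into extremum
#' detection.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer window width, in samples.
#' @return Numeric vector of `length(x)` with `NA` at the `(window-1)/2`
#'   positions on each end.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)
#' @export
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    abort("`window` must be an odd positive integer.")
  }
  n <- length(x)
  if (window == 1L) return(as.numeric(x))
  if (n < window) return(rep(NA_real_, n))
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  as.numeric(sm)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0L)) {
    abort(sprintf("`%s` must be numeric.", name))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, format(lower), format(upper)))
  }
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L) abort(sprintf("`%s` must be a single value.", name))
  check_number(x, name, lower, upper)
}

# seed handling: every generator takes an explicit integer seed and restores
# the caller's RNG state afterwards (no global RNG side effects)
with_seed <- function(seed, code) {
  if (is.null(seed)) abort("an explicit integer `seed` is required.")
  withr::with_seed(as.integer(seed), code)
}
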