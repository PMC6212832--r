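#' Design parameters for a simulated diauxic growth curve
#'
#' Bundles the parameters of the forward growth model used by
#' [simulate_diauxic_curve()]. Defaults emulate a Bioscreen-style
#' glucose-to-galactose shift: inoculation at about 1e5 cells/ml
#' (OD600 ~ 0.005, below the reader's effective detection limit),
#' glucose growth at 0.5/h until the glucose runs out around OD 0.45,
#' a hard lag, galactose growth at 0.3/h, stationary at OD 1.4, one
#' reading every 15 min, a well background of 0.1 OD and 0.5%
#' multiplicative measurement noise.
#'
#' @param od0 Initial true OD600 (> 0).
#' @param r1 First-phase (glucose) exponential growth rate, 1/h.
#' @param r2 Second-phase (galactose) exponential growth rate, 1/h.
#' @param t_switch Time the first sugar runs out, h.
#' @param lag_true True lag duration: growth is arrested for exactly this
#'   long after `t_switch` (a hard delay, rate 0 during lag).
#' @param od_max Carrying-capacity cap on true OD.
#' @param sample_interval Reading interval, h (default 0.25 = 15 min).
#' @param duration Total simulated time, h; `NULL` picks
#'   `t_switch + lag_true + log(od_max/od(t_switch))/r2 + 3`.
#' @param noise_sd Relative measurement noise: the measured signal is the
#'   distorted true OD times `(1 + eps)` with `eps ~ N(0, noise_sd^2)`.
#'   `0.005` means 0.5% of the signal.
#' @param background Additive well background OD600.
#' @param distort If `TRUE` (default) the true OD is passed through
#'   [distort_od()], so the synthetic data carry the reader nonlinearity
#'   that [correct_od()] removes.
#' @return A list of class `"curve_design"`.
#' @export
curve_design <- function(od0 = 0.005, r1 = 0.5, r2 = 0.3, t_switch = 9,
                         lag_true = 5, od_max = 1.4, sample_interval = 0.25,
                         duration = NULL, noise_sd = 0.005, background = 0.1,
                         distort = TRUE) {
  check_scalar(od0, "od0", lower = .Machine$double.xmin)
  check_scalar(r1, "r1", lower = 0)
  check_scalar(r2, "r2", lower = 0)
  check_scalar(t_switch, "t_switch", lower = 0)
  check_scalar(lag_true, "lag_true", lower = 0)
  check_scalar(od_max, "od_max", lower = od0)
  check_scalar(sample_interval, "sample_interval", lower = 1e-6)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(background, "background", lower = 0)
  if (is.null(duration)) {
    od_s <- min(od0 * exp(r1 * t_switch), od_max)
    rise <- if (r2 > 0) log(od_max / od_s) / r2 else 0
    duration <- t_switch + lag_true + rise + 3
  }
  check_scalar(duration, "duration", lower = sample_interval)
  structure(
    list(od0 = od0, r1 = r1, r2 = r2, t_switch = t_switch,
         lag_true = lag_true, od_max = od_max,
         sample_interval = sample_interval, duration = duration,
         noise_sd = noise_sd, background = background, distort = distort),
    class = "curve_design"
  )
}

# closed-form true OD of the piecewise-exponential diauxic model
diauxic_od_true <- function(t, design) {
  d <- design
  od_s <- min(d$od0 * exp(d$r1 * d$t_switch), d$od_max)
  od <- ifelse(
    t <= d$t_switch,
    d$od0 * exp(d$r1 * t),
    ifelse(
      t <= d$t_switch + d$lag_true,
      od_s,
      od_s * exp(d$r2 * (t - d$t_switch - d$lag_true))
    )
  )
  pmin(od, d$od_max)
}

#' Simulate a diauxic plate-reader growth curve
#'
#' Forward model for the growth measurements the lag estimator analyses:
#' the true OD is piecewise exponential (rate `r1` up to `t_switch`, flat
#' for `lag_true`, rate `r2` after, capped at `od_max`); the measured OD
#' is the distorted true OD times a multiplicative Gaussian noise factor,
#' plus the well background, floored at 0.
#'
#' @param design A [curve_design()].
#' @param seed Integer seed; every stochastic generator in this package
#'   takes an explicit seed and leaves the global RNG untouched.
#' @return A tibble with columns `time_h`, `od_true` (ground truth on the
#'   corrected scale) and `od` (measured).
#' @examples
#' curve <- simulate_diauxic_curve(curve_design(noise_sd = 0), seed = 1)
#' @export
simulate_diauxic_curve <- function(design = curve_design(), seed = 1L) {
  if (!inherits(design, "curve_design")) {
    abort("`design` must be created with `curve_design()`.")
  }
  t <- seq(0, design$duration, by = design$sample_interval)
  od_true <- diauxic_od_true(t, design)
  signal <- if (isTRUE(design$distort)) distort_od(od_true) else od_true
  eps <- if (design$noise_sd > 0) {
    with_seed(seed, rnorm(length(t), 0, design$noise_sd))
  } else {
    rep(0, length(t))
  }
  od_me <- pmax(0, signal * (1 + eps) + design$background)
  tibble(time_h = t, od_true = od_true, od = od_me)
}
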