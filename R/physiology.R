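#' Calibrate an optical oxygen-sensor trace to % air saturation
#'
#' Maps the sensor ratio (indicator phosphorescence / reference
#' fluorescence) to oxygen partial pressure in percent air saturation by
#' a two-point linear map through the calibration wells: the 0%-saturated
#' well's ratio maps to 0 and the air-saturated well's ratio to 100.
#' Values are clipped to \[0, 110\]; clipped points are flagged.
#'
#' @param trace Tibble with columns `time_h`, `ratio`.
#' @param ratio_at_0pct,ratio_at_100pct Calibration-well ratios (must
#'   differ).
#' @return The trace with added `saturation` (%) and `out_of_range`
#'   (logical) columns.
#' @export
calibrate_oxygen <- function(trace, ratio_at_0pct, ratio_at_100pct) {
  stopifnot(is.data.frame(trace), all(c("time_h", "ratio") %in% names(trace)))
  check_scalar(ratio_at_0pct, "ratio_at_0pct")
  check_scalar(ratio_at_100pct, "ratio_at_100pct")
  if (ratio_at_0pct == ratio_at_100pct) {
    abort("calibration anchors are identical: degenerate calibration.")
  }
  sat <- 100 * (trace$ratio - ratio_at_0pct) / (ratio_at_100pct - ratio_at_0pct)
  trace |>
    as_tibble() |>
    mutate(saturation = pmin(pmax(sat, 0), 110),
           out_of_range = sat < 0 | sat > 110)
}

#' Oxygen consumption rate per OD unit
#'
#' The OCR at each time point is minus the discrete derivative of the
#' smoothed oxygen-saturation curve divided by the optical density at
#' that point (consumption reported positive). Uses the same left-
#' endpoint discrete derivative and centered moving-average smoothing as
#' the growth-rate series.
#'
#' @param times Time grid, h.
#' @param saturation Calibrated saturation series (% air saturation).
#' @param od Optical density series on the same grid.
#' @param smooth_window Odd moving-average window (default 5).
#' @return Tibble: `time_h`, `ocr` (%/h per OD; `NA` where OD <= 0 or the
#'   smoothing window is incomplete), `masked` (logical).
#' @export
oxygen_consumption_rate <- function(times, saturation, od, smooth_window = 5L) {
  if (length(times) != length(saturation) || length(times) != length(od)) {
    abort("`times`, `saturation` and `od` must share one grid.")
  }
  sm <- moving_average(saturation, smooth_window)
  ds <- diff(sm) / diff(times)
  od_left <- od[-length(od)]
  masked <- !is.finite(ds) | !(od_left > 0)
  ocr <- ifelse(masked, NA_real_, -ds / od_left)
  tibble(time_h = times[-length(times)], ocr = ocr, masked = masked)
}

#' Adenylate energy charge
#'
#' \deqn{EC = (ATP + 0.5\,ADP) / (ATP + ADP + AMP)}
#'
#' A 0-1 index of cellular energy status: 1 when the adenylate pool is
#' all ATP, 0 when all AMP.
#'
#' @param atp,adp,amp Pool concentrations (same units, all >= 0, not all
#'   zero).
#' @return EC in \[0, 1\]; vectorized.
#' @examples
#' energy_charge(1, 1, 1) # 0.5
#' @export
energy_charge <- function(atp, adp, amp) {
  check_number(atp, "atp", lower = 0)
  check_number(adp, "adp", lower = 0)
  check_number(amp, "amp", lower = 0)
  total <- atp + adp + amp
  if (any(total <= 0)) abort("adenylate pools must not all be zero.")
  (atp + 0.5 * adp) / total
}

#' qPCR expression relative to the reference gene
#'
#' Relative expression from take-off cycles:
#' `amplification ^ (takeoff_ref - takeoff_sample)`, with the reference
#' (ACT1-style) take-off minus the sample take-off in the exponent. Equal
#' take-offs give 1 for any amplification efficiency.
#'
#' @param amplification Per-cycle amplification efficiency (> 0,
#'   typically near 2).
#' @param takeoff_ref Reference-gene take-off cycle.
#' @param takeoff_sample Sample take-off cycle.
#' @return Fold expression relative to the reference; vectorized.
#' @examples
#' relative_expression(2, 25, 22) # 8
#' @export
relative_expression <- function(amplification, takeoff_ref, takeoff_sample) {
  check_number(amplification, "amplification", lower = .Machine$double.xmin)
  check_number(takeoff_ref, "takeoff_ref")
  check_number(takeoff_sample, "takeoff_sample")
  amplification^(takeoff_ref - takeoff_sample)
}

#' Simulate an OxoPlate-style oxygen-sensor trace
#'
#' The oxygen saturation starts at 100% air saturation and decreases at
#' `per_cell_uptake * OD(t)` percent per hour (floored at 0), integrated
#' on the curve's own time grid; the sensor ratio is the linear
#' anchor-interpolated image of the saturation plus Gaussian noise.
#' Calibration-well ratios are returned alongside, so the trace can be
#' fed to [calibrate_oxygen()] and [oxygen_consumption_rate()].
#'
#' @param curve Tibble with `time_h` and an OD column `od_col` (use the
#'   true OD of a simulated curve, or any OD series).
#' @param per_cell_uptake Oxygen uptake, % air saturation per h per OD.
#' @param ratio_at_0pct,ratio_at_100pct Sensor-ratio anchors (distinct).
#' @param noise_sd SD of additive Gaussian ratio noise.
#' @param seed Integer seed.
#' @param od_col OD column name (default `"od_true"`).
#' @return List: `trace` (tibble `time_h`, `ratio`, `saturation_true`,
#'   `od`), `ratio_at_0pct`, `ratio_at_100pct`.
#' @export
simulate_oxygen_trace <- function(curve, per_cell_uptake = 60,
                                  ratio_at_0pct = 3.0, ratio_at_100pct = 0.6,
                                  noise_sd = 0, seed = 1L,
                                  od_col = "od_true") {
  stopifnot(is.data.frame(curve), "time_h" %in% names(curve),
            od_col %in% names(curve))
  check_scalar(per_cell_uptake, "per_cell_uptake", lower = 0)
  if (ratio_at_0pct == ratio_at_100pct) {
    abort("calibration anchors must differ.")
  }
  t <- curve$time_h
  od <- curve[[od_col]]
  n <- length(t)
  sat <- numeric(n)
  sat[1] <- 100
  for (k in seq_len(n - 1)) {
    sat[k + 1] <- max(0, sat[k] - per_cell_uptake * od[k] * (t[k + 1] - t[k]))
  }
  ratio <- ratio_at_0pct + (ratio_at_100pct - ratio_at_0pct) * sat / 100
  if (noise_sd > 0) {
    ratio <- ratio + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  list(
    trace = tibble(time_h = t, ratio = ratio, saturation_true = sat, od = od),
    ratio_at_0pct = ratio_at_0pct,
    ratio_at_100pct = ratio_at_100pct
  )
}
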