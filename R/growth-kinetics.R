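#' Subtract the well background from a growth curve
#'
#' The initial inoculum is below the reader's detection limit, so the
#' first `n_background` readings are averaged to estimate the per-well
#' background OD600, which is then subtracted from the whole series.
#' Subtracted values are floored at a small positive epsilon so logs
#' stay finite. Idempotent: a curve that already carries the
#' `"od_background"` attribute is returned unchanged.
#'
#' @param curve Tibble with columns `time_h` and `od` (measured OD600).
#' @param n_background Number of initial readings averaged (default 3).
#' @param epsilon Floor applied after subtraction.
#' @return The curve with an added `od_sub` column and attributes
#'   `od_background` (the scalar estimate) and `background_subtracted`.
#' @export
subtract_background <- function(curve, n_background = 3L, epsilon = 1e-6) {
  stopifnot(is.data.frame(curve), all(c("time_h", "od") %in% names(curve)))
  if (isTRUE(attr(curve, "background_subtracted"))) return(curve)
  if (nrow(curve) < n_background) {
    abort(sprintf("at least %d readings are needed to estimate the background.",
                  n_background))
  }
  bg <- mean(curve$od[seq_len(n_background)])
  curve <- mutate(as_tibble(curve), od_sub = pmax(.data$od - bg, epsilon))
  attr(curve, "od_background") <- bg
  attr(curve, "background_subtracted") <- TRUE
  curve
}

#' Discrete growth-rate series of a growth curve
#'
#' The specific growth rate is the discrete derivative of `ln(OD)` versus
#' time, `r_k = (ln OD_{k+1} - ln OD_k) / (t_{k+1} - t_k)`, assigned to the
#' left endpoint `t_k`, then smoothed with a centered moving average
#' ([moving_average()]). With `w` intervals per window the smoothed rate
#' telescopes to a log-slope over `w` intervals, which is what makes it
#' usable on noisy plate-reader data.
#'
#' @param curve Tibble with `time_h` and the OD column named by `od_col`
#'   (all values must be positive).
#' @param od_col Name of the OD column to differentiate (default `"od"`).
#' @param smooth_window Odd moving-average window in samples (default 5).
#' @return Tibble with columns `idx` (left-endpoint row index into
#'   `curve`), `time_h`, `od` (left-endpoint OD), `rate`, `rate_smooth`.
#' @export
rate_series <- function(curve, od_col = "od", smooth_window = 5L) {
  stopifnot(is.data.frame(curve), "time_h" %in% names(curve),
            od_col %in% names(curve))
  od <- curve[[od_col]]
  t <- curve$time_h
  if (nrow(curve) < 2L) abort("a rate series needs at least two readings.")
  bad <- which(!is.finite(od) | od <= 0)
  if (length(bad)) {
    abort(sprintf("non-positive or non-finite OD at index %d; subtract the background first.",
                  bad[1]))
  }
  r <- diff(log(od)) / diff(t)
  tibble(
    idx = seq_along(r),
    time_h = t[-length(t)],
    od = od[-length(od)],
    rate = r,
    rate_smooth = moving_average(r, smooth_window)
  )
}

#' Locate the rate extrema of a diauxic growth curve
#'
#' On the smoothed, validity-masked rate series, finds the minimum growth
#' rate `minR` between the two exponential phases and the maximum rate of
#' each phase (`maxR1` before `minR`, `maxR2` after). The split point is
#' the valley of greatest depth: the position `s` maximizing
#' `min(max(rate before s), max(rate after s)) - rate(s)`, which places
#' `minR` between the two highest separated rate maxima. If no valley
#' reaches `min_dip_frac` of the global rate maximum the curve is treated
#' as single-phase and a degenerate summary is returned.
#'
#' @param rates Output of [rate_series()].
#' @param valid Logical mask over rows of `rates`; points below the OD
#'   detection threshold or past the global OD maximum should be `FALSE`.
#' @param min_dip_frac Minimum valley depth, as a fraction of the maximum
#'   valid smoothed rate, for the curve to count as two-phase.
#' @return A list of class `"rate_summary"` with elements `maxR1`, `minR`,
#'   `maxR2`, their `idx_*` row indices (into the original curve), and
#'   `single_phase`. For single-phase curves `minR`/`maxR2` are `NA`.
#' @export
detect_phases <- function(rates, valid = NULL, min_dip_frac = 0.25) {
  stopifnot(is.data.frame(rates), all(c("idx", "rate_smooth") %in% names(rates)))
  v <- rates$rate_smooth
  ok <- !is.na(v)
  if (!is.null(valid)) ok <- ok & valid
  iv <- which(ok)
  if (length(iv) == 0L) abort("no valid rate points.")
  x <- v[iv]
  n <- length(x)
  out <- list(maxR1 = NA_real_, minR = NA_real_, maxR2 = NA_real_,
              idx_maxR1 = NA_integer_, idx_minR = NA_integer_,
              idx_maxR2 = NA_integer_, single_phase = TRUE,
              smooth_window = attr(rates, "smooth_window"))
  class(out) <- "rate_summary"
  if (n < 3L) {
    out$maxR1 <- max(x)
    out$idx_maxR1 <- rates$idx[iv[which.max(x)]]
    return(out)
  }
  pre <- cummax(x)                    # max of x[1..s]
  suf <- rev(cummax(rev(x)))          # max of x[s..n]
  s <- 2:(n - 1)
  depth <- pmin(pre[s - 1], suf[s + 1]) - x[s]
  best <- which(depth == max(depth))
  if (length(best) > 1L) best <- best[order(x[s][best], best)[1]]
  s_star <- s[best]
  dip_needed <- min_dip_frac * max(x)
  if (is.na(dip_needed) || !is.finite(min_dip_frac) || max(depth) < dip_needed) {
    out$maxR1 <- max(x)
    out$idx_maxR1 <- rates$idx[iv[which.max(x)]]
    return(out)
  }
  i1 <- which.max(x[1:(s_star - 1)])
  i2 <- s_star + which.max(x[(s_star + 1):n])
  out$maxR1 <- x[i1]
  out$minR <- x[s_star]
  out$maxR2 <- x[i2]
  out$idx_maxR1 <- rates$idx[iv[i1]]
  out$idx_minR <- rates$idx[iv[s_star]]
  out$idx_maxR2 <- rates$idx[iv[i2]]
  out$single_phase <- FALSE
  out
}

#' Lag time from the tangent-intersection geometry
#'
#' The lag starts where an exponential line tangent to the curve at the
#' `maxR1` point crosses the horizontal line through the `minR` point, and
#' ends where the tangent at the `maxR2` point crosses that same
#' horizontal. With `(t1, OD1)` the curve point at `maxR1`, `(t2, OD2)` at
#' `maxR2` and `ODm` the OD at `minR`:
#' `t_start = t1 + (ln ODm - ln OD1)/maxR1`,
#' `t_end   = t2 + (ln ODm - ln OD2)/maxR2`, and `lag = t_end - t_start`.
#' A negative computed lag is reported as 0 with the `"negative_lag"`
#' flag rather than clamped silently.
#'
#' @param curve Tibble with `time_h` and the working OD column `od_col`
#'   (background-subtracted, corrected).
#' @param summary A two-phase `"rate_summary"` from [detect_phases()].
#' @param od_col Working OD column name.
#' @return A list of class `"lag_result"`: `t_start`, `t_end`, `lag_h`,
#'   `flags` (character), plus the summary used.
#' @export
lag_time <- function(curve, summary, od_col = "od") {
  stopifnot(inherits(summary, "rate_summary"))
  if (isTRUE(summary$single_phase)) {
    abort("single-phase curve: lag time is not applicable.")
  }
  if (summary$maxR1 <= 0 || summary$maxR2 <= 0) {
    abort("non-positive phase maximum rate: tangent cannot intersect the horizontal.")
  }
  od <- curve[[od_col]]
  t <- curve$time_h
  t1 <- t[summary$idx_maxR1]; od1 <- od[summary$idx_maxR1]
  t2 <- t[summary$idx_maxR2]; od2 <- od[summary$idx_maxR2]
  odm <- od[summary$idx_minR]
  t_start <- t1 + (log(odm) - log(od1)) / summary$maxR1
  t_end <- t2 + (log(odm) - log(od2)) / summary$maxR2
  lag <- t_end - t_start
  flags <- character()
  if (lag < 0) {
    flags <- "negative_lag"
    lag <- 0
  }
  structure(list(t_start = t_start, t_end = t_end, lag_h = lag,
                 flags = flags, summary = summary),
            class = "lag_result")
}

#' Fit the lag time of one diauxic growth curve
#'
#' Full pipeline on a single well: background subtraction (mean of the
#' first three readings), OD-nonlinearity correction ([correct_od()]),
#' discrete log-derivative rate series with moving-average smoothing,
#' phase detection and tangent-intersection lag geometry. Rates are
#' computed on the corrected, background-subtracted series by default;
#' set `use_corrected = FALSE` to differentiate the raw
#' background-subtracted measurement instead.
#'
#' The validity mask keeps rate points whose OD is at least `min_od`
#' (below that, background-estimation error dominates the log-derivative)
#' and that precede the global OD maximum (stationary phase corrupts the
#' extrema).
#'
#' @param curve Tibble with `time_h` and `od` (measured OD600).
#' @param smooth_window Odd moving-average window, samples (default 5).
#' @param min_od Detection threshold on the working OD (default 0.1).
#' @param do_subtract_background,do_correct Pipeline switches.
#' @param use_corrected Differentiate the corrected series (default) or
#'   the measured one.
#' @param n_background Readings averaged for the background estimate.
#' @param min_dip_frac Passed to [detect_phases()].
#' @return An object of class `"lag_fit"`; see [tidy.lag_fit()] and
#'   [autoplot.lag_fit()]. Single-phase curves yield `lag_h = NA` with
#'   the `"single_phase"` flag.
#' @examples
#' curve <- simulate_diauxic_curve(curve_design(), seed = 7)
#' fit <- fit_lag(curve)
#' tidy(fit)
#' @export
fit_lag <- function(curve, smooth_window = 5L, min_od = 0.1,
                    do_subtract_background = TRUE, do_correct = TRUE,
                    use_corrected = TRUE, n_background = 3L,
                    min_dip_frac = 0.25) {
  stopifnot(is.data.frame(curve), all(c("time_h", "od") %in% names(curve)))
  curve <- as_tibble(curve)
  if (do_subtract_background) {
    curve <- subtract_background(curve, n_background = n_background)
  } else if (!"od_sub" %in% names(curve)) {
    curve$od_sub <- pmax(curve$od, 1e-6)
  }
  curve$od_work <- if (do_correct && use_corrected) {
    correct_od(curve$od_sub)
  } else {
    curve$od_sub
  }
  rates <- rate_series(curve, od_col = "od_work", smooth_window = smooth_window)
  attr(rates, "smooth_window") <- smooth_window
  i_peak <- which.max(curve$od_work)
  valid <- curve$od_work[rates$idx] >= min_od & rates$idx < i_peak
  summary <- detect_phases(rates, valid = valid, min_dip_frac = min_dip_frac)
  flags <- character()
  lag <- NULL
  if (summary$single_phase) {
    flags <- "single_phase"
  } else {
    lag <- lag_time(curve, summary, od_col = "od_work")
    flags <- lag$flags
  }
  structure(
    list(curve = curve, rates = rates, valid = valid, summary = summary,
         lag = lag, flags = flags,
         params = list(smooth_window = smooth_window, min_od = min_od,
                       use_corrected = use_corrected)),
    class = "lag_fit"
  )
}

#' Maximum specific growth rate of a curve
#'
#' Maximum of the smoothed, validity-masked rate series; used for
#' single-sugar growth-rate assays.
#'
#' @inheritParams fit_lag
#' @return Maximum smoothed rate, 1/h.
#' @export
max_growth_rate <- function(curve, smooth_window = 5L, min_od = 0.1,
                            do_subtract_background = TRUE, do_correct = TRUE) {
  fit <- fit_lag(curve, smooth_window = smooth_window, min_od = min_od,
                 do_subtract_background = do_subtract_background,
                 do_correct = do_correct, min_dip_frac = Inf)
  fit$summary$maxR1
}

#' Fit lag times for every well of a long-format plate
#'
#' @param plate Tibble with columns `time_h`, `well`, `od`.
#' @param ... Passed to [fit_lag()].
#' @return One [tidy()] row per well, with a `well` column.
#' @export
fit_lag_wells <- function(plate, ...) {
  stopifnot(all(c("time_h", "well", "od") %in% names(plate)))
  plate |>
    dplyr::group_split(.data$well) |>
    purrr::map(function(df) {
      res <- tryCatch(tidy(fit_lag(df, ...)),
                      error = function(e) tibble(lag_h = NA_real_,
                                                 flags = conditionMessage(e)))
      mutate(res, well = df$well[1], .before = 1)
    }) |>
    bind_rows()
}

#' @rdname fit_lag
#' @param x A `"lag_fit"` object.
#' @param ... Unused.
#' @export
print.lag_fit <- function(x, ...) {
  cat("<lag_fit>\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a lag fit
#'
#' @param x A `"lag_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `lag_h`, `t_start`, `t_end`, `maxR1`,
#'   `maxR2`, `minR`, `t_maxR1`, `t_maxR2`, `single_phase`, `flags`.
#' @export
tidy.lag_fit <- function(x, ...) {
  s <- x$summary
  t <- x$curve$time_h
  tibble(
    lag_h = if (is.null(x$lag)) NA_real_ else x$lag$lag_h,
    t_start = if (is.null(x$lag)) NA_real_ else x$lag$t_start,
    t_end = if (is.null(x$lag)) NA_real_ else x$lag$t_end,
    maxR1 = s$maxR1,
    maxR2 = s$maxR2,
    minR = s$minR,
    t_maxR1 = if (is.na(s$idx_maxR1)) NA_real_ else t[s$idx_maxR1],
    t_maxR2 = if (is.na(s$idx_maxR2)) NA_real_ else t[s$idx_maxR2],
    single_phase = s$single_phase,
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname tidy.lag_fit
#' @export
glance.lag_fit <- function(x, ...) {
  out <- tidy(x)
  out$n_points <- nrow(x$curve)
  out$n_valid <- sum(x$valid, na.rm = TRUE)
  out$od_background <- attr(x$curve, "od_background") %||% NA_real_
  out
}

#' Plot a lag fit
#'
#' Shows the working OD series on a log scale with the two tangent lines,
#' the horizontal through the `minR` point, and the fitted lag interval.
#'
#' @param object A `"lag_fit"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lag_fit <- function(object, ...) {
  cv <- object$curve
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$time_h, y = .data$od_work)) +
    ggplot2::geom_point(size = 0.6, colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "corrected OD600")
  if (!is.null(object$lag)) {
    s <- object$summary
    odm <- cv$od_work[s$idx_minR]
    tang <- function(idx, r) {
      t0 <- cv$time_h[idx]; o0 <- cv$od_work[idx]
      tibble(time_h = cv$time_h, od_work = o0 * exp(r * (cv$time_h - t0)))
    }
    p <- p +
      ggplot2::geom_hline(yintercept = odm, linetype = 3) +
      ggplot2::geom_line(data = tang(s$idx_maxR1, s$maxR1),
                         colour = "steelblue", linetype = 2) +
      ggplot2::geom_line(data = tang(s$idx_maxR2, s$maxR2),
                         colour = "firebrick", linetype = 2) +
      ggplot2::geom_vline(xintercept = c(object$lag$t_start, object$lag$t_end),
                          colour = "black", linetype = 1, linewidth = 0.3) +
      ggplot2::coord_cartesian(ylim = range(cv$od_work))
  }
  p
}
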