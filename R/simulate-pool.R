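#' Generate per-strain growth parameters for a deletion-collection pool
#'
#' Each mutant gets a glucose growth rate, a galactose growth rate and a
#' glucose-to-galactose lag time. Rates are log-normal around typical
#' rich-medium values (glucose ~0.45/h, galactose ~0.30/h) with a modest
#' spread; lag times have an exponential tail above a common minimum,
#' reflecting that most deletions behave near wild type while a minority
#' switch slowly. Optionally, the first `n_long_lag` strains are planted
#' as long-lag (respiration-defective-like) mutants whose lag is extended
#' by `long_lag_extra` hours — on the order of the per-round galactose
#' window, so the screen's limited galactose doublings can expose them.
#'
#' @param n Number of mutants (a deletion-collection pool is ~4,887).
#' @param seed Integer seed.
#' @param n_long_lag Number of planted long-lag strains (default 0).
#' @param long_lag_extra Added lag for planted strains, h.
#' @param mean_rate_glucose,mean_rate_galactose Median rates, 1/h.
#' @param sdlog_rate Log-scale SD of both rates.
#' @param lag_min,lag_mean_extra Minimum lag and mean of the exponential
#'   excess, h.
#' @return Tibble: `mutant_id`, `rate_glucose`, `rate_galactose`,
#'   `lag_time`, `planted_long_lag`.
#' @export
simulate_strains <- function(n = 4887, seed = 1L, n_long_lag = 0L,
                             long_lag_extra = 5,
                             mean_rate_glucose = 0.45,
                             mean_rate_galactose = 0.30,
                             sdlog_rate = 0.10,
                             lag_min = 1, lag_mean_extra = 0.75) {
  check_scalar(n, "n", lower = 2)
  if (n_long_lag > n) abort("`n_long_lag` cannot exceed `n`.")
  with_seed(seed, {
    out <- tibble(
      mutant_id = sprintf("mut%05d", seq_len(n)),
      rate_glucose = rlnorm(n, log(mean_rate_glucose), sdlog_rate),
      rate_galactose = rlnorm(n, log(mean_rate_galactose), sdlog_rate),
      lag_time = lag_min + rexp(n, rate = 1 / lag_mean_extra),
      planted_long_lag = seq_len(n) <= n_long_lag
    )
    out$lag_time <- out$lag_time + ifelse(out$planted_long_lag, long_lag_extra, 0)
    out
  })
}

#' Design of a pooled serial-transfer selection screen
#'
#' Parameterizes the selection regime: `n_rounds` rounds, each with a
#' glucose phase allowing `doublings_glucose` population doublings and —
#' for the carbon-source-shift condition — a galactose window sized so a
#' typical (reference) strain completes its lag and then
#' `doublings_galactose` doublings. Phase durations follow from the
#' reference rates: `t_glu = doublings_glucose * ln 2 / ref_rate_glucose`
#' and `t_gal = ref_lag + doublings_galactose * ln 2 / ref_rate_galactose`.
#' The glucose-only control condition replaces the galactose window with
#' glucose growth for the same wall-clock time.
#'
#' @param n_rounds Selection rounds (default 3).
#' @param doublings_glucose Glucose doublings per round (default 3).
#' @param doublings_galactose Galactose doublings per round (default 2.5,
#'   the middle of the 2-3 the regime allows).
#' @param condition `"shift"` (glucose then lag-gated galactose) or
#'   `"glucose"` (control: glucose throughout).
#' @param ref_rate_glucose,ref_rate_galactose,ref_lag Reference-strain
#'   parameters; `NULL` means take medians from the strain table at
#'   simulation time.
#' @return A list of class `"pool_design"`.
#' @export
pool_design <- function(n_rounds = 3L, doublings_glucose = 3,
                        doublings_galactose = 2.5,
                        condition = c("shift", "glucose"),
                        ref_rate_glucose = NULL, ref_rate_galactose = NULL,
                        ref_lag = NULL) {
  condition <- match.arg(condition)
  check_scalar(n_rounds, "n_rounds", lower = 1)
  check_scalar(doublings_glucose, "doublings_glucose", lower = 0, upper = 30)
  check_scalar(doublings_galactose, "doublings_galactose", lower = 0, upper = 30)
  structure(
    list(n_rounds = as.integer(n_rounds),
         doublings_glucose = doublings_glucose,
         doublings_galactose = doublings_galactose,
         condition = condition,
         ref_rate_glucose = ref_rate_glucose,
         ref_rate_galactose = ref_rate_galactose,
         ref_lag = ref_lag),
    class = "pool_design"
  )
}

#' Deterministic pooled-competition forward model
#'
#' Propagates strain abundances through the selection regime. In each
#' shift-condition round, strain `i`'s abundance is multiplied by
#' `exp(rate_glucose_i * t_glu) * exp(rate_galactose_i * max(0, t_gal - lag_i))`:
#' the lag acts as a hard growth delay (rate 0) at each entry into
#' galactose. The glucose-only control multiplies by
#' `exp(rate_glucose_i * (t_glu + t_gal))`. Frequencies are renormalized
#' each round; the pool-level fold expansion `G` and total time `T` are
#' returned for enrichment scoring.
#'
#' @param strains Tibble from [simulate_strains()] (or with the same
#'   columns).
#' @param design A [pool_design()].
#' @param f0 Optional initial frequencies (default uniform); must sum to 1.
#' @return A list of class `"pool_sim"`: `freq` (tibble with `mutant_id`,
#'   `f0`, `fT`, `true_rate` — the strain's true time-averaged growth
#'   rate), `G` (pool fold expansion), `T` (total time, h), `t_glu`,
#'   `t_gal`, and the design.
#' @export
simulate_pooled_competition <- function(strains, design = pool_design(),
                                        f0 = NULL) {
  stopifnot(is.data.frame(strains),
            all(c("mutant_id", "rate_glucose", "rate_galactose", "lag_time")
                %in% names(strains)))
  if (nrow(strains) < 2L) abort("a competition needs at least two strains.")
  if (anyDuplicated(strains$mutant_id)) abort("duplicate `mutant_id`.")
  n <- nrow(strains)
  if (is.null(f0)) f0 <- rep(1 / n, n)
  check_number(f0, "f0", lower = 0)
  if (abs(sum(f0) - 1) > 1e-9) abort("`f0` must sum to 1.")

  rg <- design$ref_rate_glucose %||% median(strains$rate_glucose)
  rga <- design$ref_rate_galactose %||% median(strains$rate_galactose)
  rlag <- design$ref_lag %||% median(strains$lag_time)
  t_glu <- design$doublings_glucose * log(2) / rg
  t_gal <- rlag + design$doublings_galactose * log(2) / rga

  log_round <- if (design$condition == "shift") {
    strains$rate_glucose * t_glu +
      strains$rate_galactose * pmax(0, t_gal - strains$lag_time)
  } else {
    strains$rate_glucose * (t_glu + t_gal)
  }
  T_total <- design$n_rounds * (t_glu + t_gal)

  # log-abundances, renormalized per round (renormalization cancels in
  # frequencies; done explicitly to keep numbers in range)
  la <- log(f0)
  for (r in seq_len(design$n_rounds)) {
    la <- la + log_round
    la <- la - max(la)
  }
  fT <- exp(la) / sum(exp(la))
  # pool fold expansion: total final abundance over total initial, in log
  # space for stability
  lw <- log(f0) + design$n_rounds * log_round
  m <- max(lw)
  G <- exp(m + log(sum(exp(lw - m))))

  structure(
    list(freq = tibble(mutant_id = strains$mutant_id, f0 = f0, fT = fT,
                       true_rate = design$n_rounds * log_round / T_total),
         G = G, T = T_total, t_glu = t_glu, t_gal = t_gal, design = design),
    class = "pool_sim"
  )
}

#' Multinomial sequencing of a frequency vector
#'
#' Draws barcode read counts for one sequenced sample: a single
#' multinomial draw of `depth` reads over the supplied frequencies.
#'
#' @param freqs Tibble with `mutant_id` and a frequency column `freq`, or
#'   a named numeric vector summing to 1.
#' @param depth Total reads (>= 1).
#' @param seed Integer seed.
#' @return Tibble: `mutant_id`, `count` (non-negative integers summing to
#'   `depth`).
#' @export
sample_barcode_counts <- function(freqs, depth, seed = 1L) {
  if (is.data.frame(freqs)) {
    stopifnot(all(c("mutant_id", "freq") %in% names(freqs)))
    p <- setNames(freqs$freq, freqs$mutant_id)
  } else {
    p <- freqs
  }
  check_number(p, "freqs", lower = 0)
  check_scalar(depth, "depth", lower = 1)
  if (abs(sum(p) - 1) > 1e-9) abort("frequencies must sum to 1.")
  counts <- with_seed(seed, as.integer(rmultinom(1, size = depth, prob = p)))
  tibble(mutant_id = names(p), count = counts)
}
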