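#' Per-mutant enrichment score (time-averaged growth rate)
#'
#' A mutant's enrichment over a selection experiment is its absolute
#' time-averaged growth rate, inferred from its proportions in the
#' initial and final samples, the pool's total fold expansion and the
#' total time:
#'
#' \deqn{rate = \ln( f_T G / f_0 ) / T}
#'
#' This is the unique dimensionally consistent combination of those
#' three ingredients: `fT * G / f0` is the mutant's own abundance fold
#' change, so a mutant that tracks the pool (fT = f0) grows at the
#' pool-average rate `ln(G)/T`.
#'
#' @param f0 Initial proportion(s), > 0.
#' @param fT Final proportion(s), > 0; for mutants absent from the final
#'   sample use [max_rate_for_dropout()] instead.
#' @param G Pool fold expansion over the whole experiment (> 1 typical).
#' @param T_total Total experiment time, h.
#' @return Rate(s), 1/h.
#' @examples
#' enrichment_score(0.01, 0.01, G = 2^8, T_total = 8) # ln 2
#' @export
enrichment_score <- function(f0, fT, G, T_total) {
  check_number(f0, "f0", lower = .Machine$double.xmin)
  check_number(fT, "fT", lower = .Machine$double.xmin)
  check_scalar(G, "G", lower = .Machine$double.xmin)
  check_scalar(T_total, "T_total", lower = .Machine$double.xmin)
  log(fT * G / f0) / T_total
}

#' Upper bound on the growth rate of a dropout mutant
#'
#' For a mutant present initially but absent from the final sequenced
#' sample, the largest growth rate consistent with its absence is the
#' rate it would have needed to be represented by a single read at the
#' final sequencing depth: `enrichment_score(f0, 1/depth, G, T)`. Deeper
#' sequencing gives a strictly smaller (tighter) bound.
#'
#' @param f0 Initial proportion, > 0.
#' @param read_depth_final Total reads in the final sample (>= 1).
#' @inheritParams enrichment_score
#' @return Rate upper bound(s), 1/h.
#' @export
max_rate_for_dropout <- function(f0, read_depth_final, G, T_total) {
  check_number(read_depth_final, "read_depth_final", lower = 1)
  enrichment_score(f0, 1 / read_depth_final, G, T_total)
}

#' Normalized enrichment
#'
#' Enrichment on the alternative sugar divided by enrichment in the
#' glucose-only control, removing the shared glucose-growth component.
#' Mutants whose glucose rate is zero or negative (possible with noisy
#' counts) have a sign-ambiguous ratio and are returned as `NA`; they are
#' excluded from ratio-based ranking and reported separately.
#'
#' @param rate_condition Rate(s) on the condition of interest, 1/h.
#' @param rate_glucose Rate(s) in the glucose-only control, 1/h.
#' @return Dimensionless score(s); `NA` where `rate_glucose <= 0`.
#' @export
normalized_enrichment <- function(rate_condition, rate_glucose) {
  ifelse(rate_glucose > 0, rate_condition / rate_glucose, NA_real_)
}

#' Score one (condition, replicate, tag) sample pair
#'
#' Computes per-mutant enrichment records from initial/final frequency
#' tables of one sequenced sample pair. Mutants with `fT = 0` are flagged
#' as dropouts and scored with the dropout upper bound; mutants with
#' `f0 = 0` cannot be scored and are returned with `NA` rate and the
#' `absent_at_start` flag.
#'
#' @param f0_tbl,fT_tbl Tibbles with `mutant_id`, `freq` (initial and
#'   final samples, same mutant universe).
#' @param G,T_total Pool fold expansion and total time.
#' @param read_depth_final Final-sample depth (for dropout bounds).
#' @return Tibble: `mutant_id`, `f0`, `fT`, `rate`, `is_dropout`,
#'   `rate_is_upper_bound`, `absent_at_start`.
#' @export
score_sample <- function(f0_tbl, fT_tbl, G, T_total, read_depth_final) {
  stopifnot(all(c("mutant_id", "freq") %in% names(f0_tbl)),
            all(c("mutant_id", "freq") %in% names(fT_tbl)))
  sym <- c(setdiff(f0_tbl$mutant_id, fT_tbl$mutant_id),
           setdiff(fT_tbl$mutant_id, f0_tbl$mutant_id))
  if (length(sym)) {
    abort(sprintf("initial/final mutant universes differ: %s.",
                  paste(utils::head(sym, 5), collapse = ", ")))
  }
  df <- inner_join(
    select(f0_tbl, "mutant_id", f0 = "freq"),
    select(fT_tbl, "mutant_id", fT = "freq"),
    by = "mutant_id"
  )
  df |>
    mutate(
      absent_at_start = .data$f0 <= 0,
      is_dropout = !.data$absent_at_start & .data$fT <= 0,
      rate_is_upper_bound = .data$is_dropout,
      rate = dplyr::case_when(
        absent_at_start ~ NA_real_,
        is_dropout ~ max_rate_for_dropout(pmax(.data$f0, .Machine$double.xmin),
                                          read_depth_final, G, T_total),
        TRUE ~ log(.data$fT * G / .data$f0) / T_total
      )
    )
}

#' Aggregate ranking lists across replicates and tags
#'
#' Each input list — one per (replicate, tag class) within a condition —
#' is ranked by normalized enrichment, strongest first (rank 1), with
#' average ranks for ties. A mutant's final rank in the condition is the
#' arithmetic mean of its rank positions across the lists (two
#' replicates x UP/DN tags gives the construction with eight lists over
#' two conditions). Mutants with `NA` normalized score in a list are
#' excluded from that list's ranking.
#'
#' @param scores Tibble with columns `condition`, `replicate`,
#'   `tag_class`, `mutant_id`, `normalized`.
#' @return Tibble: `condition`, `mutant_id`, `avg_rank`, `n_lists`.
#'   Within each condition, all input lists must share the same mutant
#'   universe; otherwise an error lists the symmetric difference.
#' @export
build_rank_lists <- function(scores) {
  req <- c("condition", "replicate", "tag_class", "mutant_id", "normalized")
  stopifnot(all(req %in% names(scores)))
  scores |>
    group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      lists <- split(df$mutant_id, paste(df$replicate, df$tag_class))
      universe <- lists[[1]]
      for (l in lists[-1]) {
        sym <- c(setdiff(universe, l), setdiff(l, universe))
        if (length(sym)) {
          abort(sprintf("mutant universes differ across lists: %s.",
                        paste(utils::head(sym, 5), collapse = ", ")))
        }
      }
      df |>
        group_by(.data$replicate, .data$tag_class) |>
        mutate(rank_pos = ifelse(is.na(.data$normalized), NA_real_,
                                 rank(-.data$normalized, na.last = "keep",
                                      ties.method = "average"))) |>
        group_by(.data$mutant_id) |>
        summarise(avg_rank = mean(.data$rank_pos, na.rm = TRUE),
                  n_lists = sum(!is.na(.data$rank_pos)), .groups = "drop")
    }) |>
    ungroup() |>
    mutate(avg_rank = ifelse(is.nan(.data$avg_rank), NA_real_, .data$avg_rank))
}

#' Select the strongly and weakly enriched extreme sets
#'
#' Builds the two candidate distributions and takes `n` mutants from each
#' end. The strongly enriched distribution contains every mutant whose
#' enrichment could be calculated plus the mutants that dropped out in
#' the glucose-only control (scored by their upper bound); the weakly
#' enriched distribution contains the calculable mutants plus those that
#' dropped out under the condition. Each distribution is ordered by the
#' aggregated rank list; the top `n` of the strong distribution and the
#' bottom `n` of the weak distribution are returned, with provenance
#' flags.
#'
#' @param rank_list Output of [build_rank_lists()] for one condition
#'   (columns `mutant_id`, `avg_rank`).
#' @param records Mutant-level flags: tibble with `mutant_id`,
#'   `dropout_condition`, `dropout_glucose` (logical).
#' @param n Set size (default 200).
#' @return List with tibbles `strong` and `weak` (`mutant_id`,
#'   `avg_rank`, `via_dropout_bound`), each of `n` rows, disjoint.
#' @export
select_extremes <- function(rank_list, records, n = 200L) {
  stopifnot(all(c("mutant_id", "avg_rank") %in% names(rank_list)),
            all(c("mutant_id", "dropout_condition", "dropout_glucose")
                %in% names(records)))
  df <- rank_list |>
    inner_join(records, by = "mutant_id") |>
    filter(!is.na(.data$avg_rank)) |>
    mutate(computable = !.data$dropout_condition & !.data$dropout_glucose)
  strong_cand <- df |>
    filter(.data$computable | .data$dropout_glucose) |>
    arrange(.data$avg_rank, .data$mutant_id)
  weak_cand <- df |>
    filter(.data$computable | .data$dropout_condition) |>
    arrange(.data$avg_rank, .data$mutant_id)
  if (n > nrow(strong_cand) || n > nrow(weak_cand)) {
    abort(sprintf("n = %d exceeds a candidate distribution (strong %d, weak %d).",
                  n, nrow(strong_cand), nrow(weak_cand)))
  }
  strong <- strong_cand |>
    slice_head(n = n) |>
    mutate(via_dropout_bound = .data$dropout_glucose) |>
    select("mutant_id", "avg_rank", "via_dropout_bound")
  weak <- weak_cand |>
    slice_tail(n = n) |>
    mutate(via_dropout_bound = .data$dropout_condition) |>
    select("mutant_id", "avg_rank", "via_dropout_bound")
  overlap <- intersect(strong$mutant_id, weak$mutant_id)
  if (length(overlap)) {
    warn(sprintf("%d mutants fall in both extreme sets (n too large for pool).",
                 length(overlap)))
  }
  list(strong = strong, weak = weak)
}
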