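#' Simulate a full pooled Bar-Seq screen at the count level
#'
#' Runs the deterministic pooled competition for the carbon-source-shift
#' condition and the glucose-only control, then draws multinomial
#' sequencing counts for the initial and final samples of every
#' (condition, replicate, tag class) combination. Replicates and UP/DN
#' tags are independent sequencing draws of the same underlying
#' frequencies (the tag PCRs are independent measurements of one pool).
#'
#' @param strains Tibble from [simulate_strains()].
#' @param depth Reads per sequenced sample (default 1e6).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param seed Integer seed; all sample draws derive sub-seeds from it.
#' @param design_shift,design_glucose [pool_design()]s for the two
#'   conditions.
#' @return List: `counts` (tibble with `condition`, `replicate`,
#'   `tag_class`, `timepoint`, `mutant_id`, `count`), `meta` (tibble with
#'   per-condition `G`, `T_total`, `depth`), `sims` (the two
#'   `"pool_sim"` objects, carrying per-strain true rates).
#' @export
simulate_barseq_screen <- function(strains, depth = 1e6, n_replicates = 2L,
                                   seed = 1L,
                                   design_shift = pool_design(condition = "shift"),
                                   design_glucose = pool_design(condition = "glucose")) {
  sims <- list(
    shift = simulate_pooled_competition(strains, design_shift),
    glucose = simulate_pooled_competition(strains, design_glucose)
  )
  grid <- tidyr::expand_grid(
    condition = names(sims),
    replicate = seq_len(n_replicates),
    tag_class = c("UP", "DN"),
    timepoint = c("initial", "final")
  )
  sub_seeds <- with_seed(seed, sample.int(2^30, nrow(grid)))
  counts <- purrr::pmap(c(grid, list(s = sub_seeds)),
    function(condition, replicate, tag_class, timepoint, s) {
      sim <- sims[[condition]]
      p <- if (timepoint == "initial") sim$freq$f0 else sim$freq$fT
      sample_barcode_counts(setNames(p, sim$freq$mutant_id), depth, seed = s) |>
        mutate(condition = condition, replicate = replicate,
               tag_class = tag_class, timepoint = timepoint, .before = 1)
    }) |>
    bind_rows()
  meta <- tibble(
    condition = names(sims),
    G = vapply(sims, function(s) s$G, numeric(1)),
    T_total = vapply(sims, function(s) s$T, numeric(1)),
    depth = depth
  )
  list(counts = counts, meta = meta, sims = sims)
}

#' Score a screen's count tables into enrichment records and ranks
#'
#' Converts per-sample counts into frequencies, scores every (condition,
#' replicate, tag) sample pair with [score_sample()] (dropout bounds
#' where the final count is zero), normalizes each condition's rates
#' against the matching glucose-only sample, aggregates ranking lists
#' with [build_rank_lists()], and derives mutant-level dropout flags for
#' [select_extremes()].
#'
#' @param screen Output of [simulate_barseq_screen()], or a list with the
#'   same `counts`/`meta` shape from real data.
#' @param condition Condition to normalize against glucose (default
#'   `"shift"`).
#' @return List: `records` (per-list enrichment records with
#'   `normalized`), `rank_list` (aggregated ranks for `condition`),
#'   `flags` (mutant-level `dropout_condition`/`dropout_glucose`).
#' @export
screen_scores <- function(screen, condition = "shift") {
  counts <- screen$counts
  meta <- screen$meta
  freqs <- counts |>
    group_by(.data$condition, .data$replicate, .data$tag_class,
             .data$timepoint) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
  score_one <- function(df) {
    m <- meta[meta$condition == df$condition[1], ]
    score_sample(
      filter(df, .data$timepoint == "initial"),
      filter(df, .data$timepoint == "final"),
      G = m$G, T_total = m$T_total, read_depth_final = m$depth
    )
  }
  records <- freqs |>
    dplyr::group_split(.data$condition, .data$replicate, .data$tag_class) |>
    purrr::map(function(df) {
      score_one(df) |>
        mutate(condition = df$condition[1], replicate = df$replicate[1],
               tag_class = df$tag_class[1], .before = 1)
    }) |>
    bind_rows()
  glu <- records |>
    filter(.data$condition == "glucose") |>
    select("replicate", "tag_class", "mutant_id", rate_glucose = "rate",
           dropout_glucose = "is_dropout")
  rec <- records |>
    filter(.data$condition == !!condition) |>
    left_join(glu, by = c("replicate", "tag_class", "mutant_id")) |>
    mutate(normalized = normalized_enrichment(.data$rate, .data$rate_glucose))
  rank_list <- build_rank_lists(rec)
  flags <- rec |>
    group_by(.data$mutant_id) |>
    summarise(dropout_condition = any(.data$is_dropout),
              dropout_glucose = any(.data$dropout_glucose),
              .groups = "drop")
  list(records = rec, rank_list = rank_list, flags = flags)
}
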