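test_that("enrichment score is the time-averaged growth rate", {
  # a mutant tracking a pool that doubled 8 times in 8 h grows at ln 2
  expect_equal(enrichment_score(0.01, 0.01, G = 2^8, T_total = 8), log(2))
  expect_equal(enrichment_score(0.3, 0.3, G = 1, T_total = 5), 0)
  expect_error(enrichment_score(0, 0.1, 2, 1), "f0")
  expect_error(enrichment_score(0.1, 0, 2, 1), "fT")
  # scale invariance: frequencies from scaled counts are unchanged
  cnts <- c(30, 50, 20)
  f_a <- cnts / sum(cnts)
  f_b <- (cnts * 17) / sum(cnts * 17)
  expect_equal(enrichment_score(f_a[1], f_b[1], 4, 10),
               enrichment_score(f_a[1], f_a[1], 4, 10))
})

test_that("dropout bound is monotone in depth and zero at the uniform edge", {
  b1 <- max_rate_for_dropout(1e-4, 1e5, G = 50, T_total = 30)
  b2 <- max_rate_for_dropout(1e-4, 1e6, G = 50, T_total = 30)
  expect_lt(b2, b1)
  # f0 = 1/N, depth = N, G = 1: a non-grower is exactly at the detection edge
  expect_equal(max_rate_for_dropout(1 / 500, 500, G = 1, T_total = 10), 0)
})

test_that("dropout bound is a valid upper bound for a strain below one expected read", {
  # a pool with one strain whose true final expected reads are 0.5: the
  # canonical case of a mutant absent from the final sample
  n <- 100; depth <- 5e4
  G <- 40; T_total <- 36
  f0 <- rep(1 / n, n)
  fT <- rep(1 / n, n)
  fT[1] <- 0.5 / depth
  fT <- fT / sum(fT)
  true_rate <- log(fT[1] * G / f0[1]) / T_total
  ids <- sprintf("m%03d", seq_len(n))
  n_checked <- 0; n_valid <- 0
  for (s in 1:200) {
    fTc <- sample_barcode_counts(setNames(fT, ids), depth, seed = s)
    f0c <- sample_barcode_counts(setNames(f0, ids), depth, seed = s + 1000)
    if (fTc$count[1] > 0 || f0c$count[1] == 0) next # no dropout this trial
    bound <- max_rate_for_dropout(f0c$count[1] / depth, depth, G, T_total)
    n_checked <- n_checked + 1
    n_valid <- n_valid + (bound >= true_rate)
  }
  expect_gt(n_checked, 50)
  expect_gte(n_valid / n_checked, 0.99)
})

test_that("normalized enrichment is a ratio with NA on non-positive control", {
  expect_equal(normalized_enrichment(0.3, 0.3), 1)
  expect_equal(normalized_enrichment(c(0.2, 0.1), c(0.4, 0.4)), c(0.5, 0.25))
  expect_true(is.na(normalized_enrichment(0.2, 0)))
  expect_true(is.na(normalized_enrichment(0.2, -0.1)))
})

test_that("rank aggregation averages rank positions with average ties", {
  mk <- function(rep, tag, ids, scores) {
    tibble::tibble(condition = "shift", replicate = rep, tag_class = tag,
                   mutant_id = ids, normalized = scores)
  }
  # identical lists: averaging is idempotent
  one <- mk(1, "UP", c("a", "b", "c"), c(3, 2, 1))
  two <- dplyr::bind_rows(one, mk(1, "DN", c("a", "b", "c"), c(3, 2, 1)))
  rl <- build_rank_lists(two)
  expect_equal(rl$avg_rank[match(c("a", "b", "c"), rl$mutant_id)], c(1, 2, 3))
  # reversed orders average to the middle
  rev2 <- dplyr::bind_rows(one, mk(2, "UP", c("a", "b", "c"), c(1, 2, 3)))
  rl2 <- build_rank_lists(rev2)
  expect_equal(rl2$avg_rank, rep(2, 3))
  # ties share average ranks
  tied <- mk(1, "UP", c("a", "b", "c"), c(5, 5, 1))
  rl3 <- build_rank_lists(tied)
  expect_equal(rl3$avg_rank[match(c("a", "b", "c"), rl3$mutant_id)],
               c(1.5, 1.5, 3))
  # differing universes are an error naming the difference
  bad <- dplyr::bind_rows(one, mk(2, "UP", c("a", "b", "zzz"), c(1, 2, 3)))
  expect_error(build_rank_lists(bad), "zzz")
})

test_that("rank aggregation is equivariant under mutant relabeling", {
  withr::local_seed(2)
  ids <- sprintf("m%02d", 1:12)
  sc <- tidyr::expand_grid(condition = "shift", replicate = 1:2,
                           tag_class = c("UP", "DN")) |>
    dplyr::rowwise() |>
    dplyr::reframe(mutant_id = ids, normalized = rnorm(12),
                   condition = condition, replicate = replicate,
                   tag_class = tag_class)
  rl <- build_rank_lists(sc)
  perm <- sample(ids)
  relabel <- setNames(perm, ids)
  sc2 <- dplyr::mutate(sc, mutant_id = relabel[mutant_id])
  rl2 <- build_rank_lists(sc2)
  expect_equal(rl2$avg_rank[match(relabel[rl$mutant_id], rl2$mutant_id)],
               rl$avg_rank)
})

test_that("extreme sets honor dropout provenance rules", {
  ids <- sprintf("m%02d", 1:10)
  rank_list <- tibble::tibble(mutant_id = ids, avg_rank = 1:10)
  # no dropouts: head and tail of the rank list
  recs <- tibble::tibble(mutant_id = ids, dropout_condition = FALSE,
                         dropout_glucose = FALSE)
  ex <- select_extremes(rank_list, recs, n = 3)
  expect_equal(ex$strong$mutant_id, ids[1:3])
  expect_equal(ex$weak$mutant_id, ids[8:10])
  expect_false(any(ex$strong$via_dropout_bound))
  # a condition dropout ranked last joins the weak set via its bound,
  # and is excluded from the strong candidate distribution
  recs2 <- dplyr::mutate(recs, dropout_condition = mutant_id == "m10")
  ex2 <- select_extremes(rank_list, recs2, n = 3)
  expect_true("m10" %in% ex2$weak$mutant_id)
  expect_true(ex2$weak$via_dropout_bound[ex2$weak$mutant_id == "m10"])
  # a glucose dropout is excluded from the weak candidates
  recs3 <- dplyr::mutate(recs, dropout_glucose = mutant_id == "m09")
  ex3 <- select_extremes(rank_list, recs3, n = 3)
  expect_false("m09" %in% ex3$weak$mutant_id)
  expect_equal(ex3$weak$mutant_id, c("m07", "m08", "m10"))
  expect_error(select_extremes(rank_list, recs, n = 11), "exceeds")
})

test_that("rerunning extreme selection reproduces identical membership", {
  st <- simulate_strains(n = 300, seed = 9, n_long_lag = 20)
  scr <- simulate_barseq_screen(st, depth = 5e4, n_replicates = 2, seed = 9)
  sc1 <- screen_scores(scr)
  sc2 <- screen_scores(scr)
  ex1 <- select_extremes(sc1$rank_list, sc1$flags, n = 30)
  ex2 <- select_extremes(sc2$rank_list, sc2$flags, n = 30)
  expect_identical(ex1, ex2)
  # planted slow switchers rank below the no-lag strains
  planted <- st$mutant_id[st$planted_long_lag]
  expect_gt(mean(planted %in% ex1$weak$mutant_id), 0.5)
})
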