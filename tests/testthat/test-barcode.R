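test_that("catalogue loading validates barcodes and reports offending rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  cat_obj <- small_catalogue(5)
  write_catalogue(cat_obj, f)
  loaded <- load_catalogue(f)
  expect_equal(loaded$entries, cat_obj$entries)

  bad <- cat_obj$entries
  bad$up_barcode[2] <- sub(".$", "N", bad$up_barcode[2])
  readr::write_tsv(bad, f)
  expect_error(load_catalogue(f), "row 2")

  dup <- cat_obj$entries
  dup$dn_barcode[3] <- dup$dn_barcode[1]
  readr::write_tsv(dup, f)
  expect_error(load_catalogue(f), "m001.*m003")
})

test_that("barcode extraction locates primers within the shared tolerance", {
  cat_obj <- small_catalogue(5)
  p <- cat_obj$primers$up
  bc <- cat_obj$entries$up_barcode[1]
  read <- paste0(p[["left"]], bc, p[["right"]])
  expect_equal(extract_barcode(read, p), bc)
  # substitution inside the barcode is preserved in the candidate
  bc_mut <- mutate_barcode(bc, 1, "sub")
  expect_equal(extract_barcode(paste0(p[["left"]], bc_mut, p[["right"]]), p),
               bc_mut)
  expect_equal(nchar(bc_mut), 20L)
  # no primers -> no candidate
  expect_true(is.na(extract_barcode(strrep("A", 60), p)))
})

test_that("assignment respects the separate substitution and indel budgets", {
  sub_at <- function(bc, positions) {
    ch <- strsplit(bc, "")[[1]]
    for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  cat_obj <- small_catalogue(30)
  bc <- cat_obj$entries$up_barcode[7]
  expect_equal(assign_barcode(bc, cat_obj, "up"), "m007")
  expect_equal(assign_barcode(sub_at(bc, c(3, 11)), cat_obj, "up"), "m007")
  # the printed two-mismatch limit, with the indel budget switched off
  expect_true(is.na(assign_barcode(sub_at(bc, c(3, 11, 17)), cat_obj, "up",
                                   max_gaps = 0L)))
  # under the default budgets a third substitution can be re-explained as
  # a deletion+insertion pair (2 gaps), so it still assigns uniquely...
  expect_equal(assign_barcode(sub_at(bc, c(3, 11, 17)), cat_obj, "up"), "m007")
  # ...but a fourth would need 4 gaps and is out of budget
  expect_true(is.na(assign_barcode(sub_at(bc, c(3, 7, 11, 17)),
                                   cat_obj, "up")))
  withr::local_seed(5)
  expect_equal(assign_barcode(mutate_barcode(bc, 3, "del"), cat_obj, "up"),
               "m007")
  expect_true(is.na(assign_barcode(mutate_barcode(bc, 4, "del"),
                                   cat_obj, "up")))
})

test_that("ambiguous best hits are left unassigned", {
  entries <- tibble::tibble(
    mutant_id = c("a", "b"),
    # barcodes differing at positions 3 and 20 only
    up_barcode = c("AAAAAAAAAAAAAAAAAAAA", "AACAAAAAAAAAAAAAAAAG"),
    dn_barcode = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA")
  )
  cat_obj <- structure(list(entries = entries,
                            primers = small_catalogue(2)$primers),
                       class = "barcode_catalogue")
  # one substitution away from each barcode: a perfect tie
  cand <- "AACAAAAAAAAAAAAAAAAA"
  expect_true(is.na(assign_barcode(cand, cat_obj, "up")))
  # candidate equal to a's barcode assigns uniquely
  expect_equal(assign_barcode(entries$up_barcode[1], cat_obj, "up"), "a")
})

test_that("fast kernel agrees with the exhaustive cost enumerator", {
  withr::local_seed(11)
  for (i in 1:300) {
    cat_obj <- small_catalogue(sample(5:50, 1), seed = i)
    cand <- random_candidate(cat_obj)
    expect_identical(assign_barcode(cand, cat_obj, "up"),
                     assign_barcode_oracle(cand, cat_obj, "up"),
                     info = sprintf("instance %d: %s", i, cand))
  }
})

test_that("tightening the budgets never converts unassigned to assigned", {
  withr::local_seed(13)
  cat_obj <- small_catalogue(25)
  for (i in 1:80) {
    cand <- random_candidate(cat_obj)
    loose <- assign_barcode(cand, cat_obj, "up", 2L, 3L)
    tight <- assign_barcode(cand, cat_obj, "up", 1L, 1L)
    if (is.na(loose)) expect_true(is.na(tight))
  }
})

test_that("counting conserves reads and is independent of read order", {
  cat_obj <- small_catalogue(40, seed = 21)
  cnt <- tibble::tibble(mutant_id = cat_obj$entries$mutant_id,
                        count = rep(c(0L, 2L, 5L, 11L), 10))
  fq <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, cat_obj, fq, tag = "dn", sub_rate = 0.02,
                   indel_rate = 0.01, seed = 31)
  res <- count_sample(fq, cat_obj, tag = "dn")
  expect_equal(sum(res$count) + attr(res, "n_unassigned"),
               attr(res, "n_total_reads"))
  expect_equal(attr(res, "n_total_reads"), sum(cnt$count))
  # shuffle the records: identical table
  lines <- readLines(fq)
  recs <- split(lines, rep(seq_len(length(lines) / 4), each = 4))
  shuffled <- unlist(recs[sample(length(recs))], use.names = FALSE)
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(shuffled, fq2)
  res2 <- count_sample(fq2, cat_obj, tag = "dn", sample_id = "x")
  expect_equal(res2$count, res$count)
})

test_that("error-free synthetic reads recount exactly; empty FASTQ is all zero", {
  cat_obj <- small_catalogue(20, seed = 22)
  cnt <- tibble::tibble(mutant_id = cat_obj$entries$mutant_id,
                        count = sample.int(8, 20, replace = TRUE) - 1L)
  fq <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, cat_obj, fq, tag = "up", seed = 1)
  res <- count_sample(fq, cat_obj, tag = "up")
  expect_equal(res$count, cnt$count)
  expect_equal(attr(res, "n_unassigned"), 0L)

  writeLines(character(0), fq)
  res0 <- count_sample(fq, cat_obj, tag = "up")
  expect_equal(sum(res0$count), 0L)
  expect_equal(attr(res0, "n_total_reads"), 0L)
  expect_error(synthesize_reads(tibble::tibble(mutant_id = "ghost", count = 1L),
                                cat_obj, fq), "not in catalogue")
})

test_that("low-error reads are assigned to the true mutant at high rate", {
  cat_obj <- small_catalogue(50, seed = 23)
  cnt <- tibble::tibble(mutant_id = cat_obj$entries$mutant_id, count = 20L)
  fq <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(cnt, cat_obj, fq, tag = "up", sub_rate = 0.01, seed = 9)
  res <- count_sample(fq, cat_obj, tag = "up")
  correct <- sum(pmin(res$count, cnt$count))
  expect_gte(correct / sum(cnt$count), 0.98)
})

test_that("frequencies divide counts by the sample total", {
  counts <- tibble::tibble(sample_id = "s1", tag_class = "UP",
                           mutant_id = c("a", "b"), count = c(3L, 1L))
  fr <- frequencies(counts)
  expect_equal(fr$freq, c(0.75, 0.25))
  # single mutant and homogeneity
  expect_equal(frequencies(tibble::tibble(mutant_id = "a", count = 5L))$freq, 1)
  scaled <- dplyr::mutate(counts, count = count * 7L)
  expect_equal(frequencies(scaled)$freq, fr$freq)
  expect_error(frequencies(dplyr::mutate(counts, count = 0L)), "no assigned")
})
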