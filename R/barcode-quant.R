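str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Extract the candidate barcode from an amplicon read
#'
#' Each amplicon is `left primer + 20-nt barcode + right primer`, with the
#' primers common across all mutants. The left primer is located by a
#' bounded-edit semi-global search (same substitution/indel tolerance as
#' barcode assignment), the right primer likewise from the other end, and
#' the enclosed substring is returned. `NA` if either primer is not found
#' within tolerance or the enclosed substring has an implausible length
#' (outside `barcode length +/- max_gaps`).
#'
#' @param read A single ACGTN read sequence (character scalar).
#' @param primer_pair Character vector `c(left, right)` of flanking
#'   primers for the tag class.
#' @param max_mismatches,max_gaps Substitution and indel budgets
#'   (defaults 2 and 3, counted separately).
#' @param barcode_len Expected barcode length (default 20).
#' @return The candidate barcode substring, or `NA_character_`.
#' @export
extract_barcode <- function(read, primer_pair, max_mismatches = 2L,
                            max_gaps = 3L, barcode_len = 20L) {
  stopifnot(is.character(read), length(read) == 1L, length(primer_pair) == 2L)
  e1 <- locate_primer_end_cpp(read, primer_pair[[1]], max_mismatches, max_gaps)
  if (e1 < 0 || e1 >= nchar(read)) return(NA_character_)
  tail_seq <- substr(read, e1 + 1L, nchar(read))
  # right primer: find its start by locating its reversal's end in the
  # reversed tail
  e2r <- locate_primer_end_cpp(str_rev(tail_seq), str_rev(primer_pair[[2]]),
                               max_mismatches, max_gaps)
  if (e2r < 0) return(NA_character_)
  s2 <- nchar(tail_seq) - e2r + 1L # start of right primer within tail
  if (s2 <= 1L) return(NA_character_)
  cand <- substr(tail_seq, 1L, s2 - 1L)
  if (nchar(cand) < barcode_len - max_gaps ||
      nchar(cand) > barcode_len + max_gaps) {
    return(NA_character_)
  }
  cand
}

#' Assign a candidate barcode to a mutant
#'
#' A catalogue entry qualifies if its barcode aligns to the candidate
#' with at most `max_mismatches` substitutions and at most `max_gaps`
#' indels, counted separately. Among qualifying entries the best is the
#' one with the lexicographically smallest (gaps, mismatches) cost; if
#' two or more entries tie at that minimal cost the read is left
#' unassigned — a pooled screen must never transfer counts between
#' mutants by breaking ties arbitrarily.
#'
#' @param candidate Candidate barcode string (non-empty).
#' @param catalogue A `"barcode_catalogue"`.
#' @param tag `"up"` or `"dn"`: which barcode class to match.
#' @param max_mismatches,max_gaps Budgets (defaults 2 and 3).
#' @return The `mutant_id`, or `NA_character_` if unassigned.
#' @export
assign_barcode <- function(candidate, catalogue, tag = c("up", "dn"),
                           max_mismatches = 2L, max_gaps = 3L) {
  tag <- match.arg(tag)
  stopifnot(inherits(catalogue, "barcode_catalogue"))
  if (is.na(candidate) || !nzchar(candidate)) return(NA_character_)
  barcodes <- catalogue$entries[[paste0(tag, "_barcode")]]
  # exact match is unique by catalogue validation
  hit <- match(candidate, barcodes)
  if (!is.na(hit)) return(catalogue$entries$mutant_id[hit])
  costs <- align_barcodes_cpp(barcodes, candidate, max_mismatches, max_gaps)
  feas <- costs[, 1] >= 0
  if (!any(feas)) return(NA_character_)
  key <- costs[, 1] * (max_mismatches + 1) + costs[, 2]
  key[!feas] <- NA
  best <- min(key, na.rm = TRUE)
  winners <- which(!is.na(key) & key == best)
  if (length(winners) != 1L) return(NA_character_)
  catalogue$entries$mutant_id[winners]
}

#' Count barcode reads per mutant in one FASTQ sample
#'
#' Every read either increments exactly one mutant's count or the
#' unassigned tally: the candidate barcode is extracted between the
#' common primers and assigned under the bounded-edit budgets; reads that
#' fail on the forward strand are retried as reverse complements when
#' `revcomp = TRUE` (the default).
#'
#' @param fastq Path to a FASTQ file.
#' @param catalogue A `"barcode_catalogue"`.
#' @param tag `"up"` or `"dn"`.
#' @param sample_id Sample label (default: the file name).
#' @param max_mismatches,max_gaps Budgets (defaults 2 and 3).
#' @param revcomp Also scan the reverse complement (default `TRUE`).
#' @return A tibble of class `"count_table"`: `sample_id`, `tag_class`,
#'   `mutant_id`, `count` (one row per catalogue mutant, zeros included),
#'   with attributes `n_unassigned` and `n_total_reads`; always
#'   `sum(count) + n_unassigned == n_total_reads`.
#' @export
count_sample <- function(fastq, catalogue, tag = c("up", "dn"),
                         sample_id = NULL, max_mismatches = 2L,
                         max_gaps = 3L, revcomp = TRUE) {
  tag <- match.arg(tag)
  stopifnot(inherits(catalogue, "barcode_catalogue"))
  sample_id <- sample_id %||% basename(fastq)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq"),
    error = function(e) {
      abort(sprintf("malformed FASTQ `%s`: %s", fastq, conditionMessage(e)))
    }
  )
  seqs <- as.character(reads)
  primer_pair <- catalogue$primers[[tag]]
  assign_one <- function(s) {
    cand <- extract_barcode(s, primer_pair, max_mismatches, max_gaps)
    if (is.na(cand)) return(NA_character_)
    assign_barcode(cand, catalogue, tag, max_mismatches, max_gaps)
  }
  assigned <- vapply(seqs, assign_one, character(1), USE.NAMES = FALSE)
  if (revcomp && anyNA(assigned)) {
    miss <- which(is.na(assigned))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[miss])))
    assigned[miss] <- vapply(rc, assign_one, character(1), USE.NAMES = FALSE)
  }
  tab <- table(factor(assigned, levels = catalogue$entries$mutant_id))
  out <- tibble(sample_id = sample_id, tag_class = toupper(tag),
                mutant_id = catalogue$entries$mutant_id,
                count = as.integer(tab))
  attr(out, "n_total_reads") <- length(seqs)
  attr(out, "n_unassigned") <- sum(is.na(assigned))
  class(out) <- c("count_table", class(out))
  out
}

#' Convert counts to mutant frequencies
#'
#' The frequency of each deletion mutant is its count divided by the
#' total assigned counts for that sample.
#'
#' @param counts Tibble with `mutant_id` and `count` (and optionally
#'   `sample_id`/`tag_class` grouping columns, handled per group).
#' @return Tibble with a `freq` column replacing `count`; frequencies sum
#'   to 1 within each sample.
#' @export
frequencies <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("mutant_id", "count") %in% names(counts)))
  grp <- intersect(c("sample_id", "tag_class"), names(counts))
  out <- counts |>
    group_by(across(dplyr::all_of(grp))) |>
    mutate(total = sum(.data$count)) |>
    ungroup()
  if (any(out$total == 0)) {
    abort("sample with no assigned reads: frequencies undefined.")
  }
  out |>
    mutate(freq = .data$count / .data$total) |>
    select(-"count", -"total")
}
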