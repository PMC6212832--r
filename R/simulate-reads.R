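#' Synthesize barcode amplicon reads as FASTQ
#'
#' Emits one read per counted barcode molecule: `left primer + barcode +
#' right primer` for the chosen tag class, with independent per-base
#' substitution and indel errors at the stated rates (insertions and
#' deletions each at `indel_rate / 2`). Base qualities are a constant
#' placeholder — quality-aware matching is not modelled. Read headers
#' carry the true mutant id, so counting can be checked against ground
#' truth.
#'
#' @param counts Tibble with `mutant_id`, `count`; every counted mutant
#'   must be present in the catalogue.
#' @param catalogue A `"barcode_catalogue"`.
#' @param path Output FASTQ path.
#' @param tag `"up"` or `"dn"`.
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability (half insertions before
#'   the base, half deletions of the base).
#' @param seed Integer seed.
#' @return `path`, invisibly; the file holds `sum(counts$count)` reads.
#' @export
synthesize_reads <- function(counts, catalogue, path, tag = c("up", "dn"),
                             sub_rate = 0, indel_rate = 0, seed = 1L) {
  tag <- match.arg(tag)
  stopifnot(inherits(catalogue, "barcode_catalogue"),
            all(c("mutant_id", "count") %in% names(counts)))
  check_number(counts$count, "counts$count", lower = 0)
  unknown <- setdiff(counts$mutant_id, catalogue$entries$mutant_id)
  if (length(unknown)) {
    abort(sprintf("mutants not in catalogue: %s.",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  check_scalar(sub_rate, "sub_rate", lower = 0, upper = 1)
  check_scalar(indel_rate, "indel_rate", lower = 0, upper = 1)

  keep <- counts$count > 0
  ids <- rep(counts$mutant_id[keep], counts$count[keep])
  primer_pair <- catalogue$primers[[tag]]
  bc <- catalogue$entries[[paste0(tag, "_barcode")]]
  names(bc) <- catalogue$entries$mutant_id
  templates <- paste0(primer_pair[["left"]], bc[ids], primer_pair[["right"]])

  seqs <- if (sub_rate > 0 || indel_rate > 0) {
    with_seed(seed, mutate_reads(templates, sub_rate, indel_rate))
  } else {
    templates
  }
  n <- length(seqs)
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- sprintf("read%06d %s", seq_len(n), ids)
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(w) {
    strrep("I", w)
  }, character(1)))
  qdna <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qdna, path)
  invisible(path)
}

# per-base substitution / insertion / deletion process, vectorized over
# the concatenated bases of all reads
mutate_reads <- function(templates, sub_rate, indel_rate) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(templates, "", fixed = TRUE)
  lens <- lengths(chars)
  all_ch <- unlist(chars, use.names = FALSE)
  read_of <- rep(seq_along(templates), lens)
  ntot <- length(all_ch)

  sub_hit <- runif(ntot) < sub_rate
  if (any(sub_hit)) {
    repl <- vapply(all_ch[sub_hit],
                   function(b) sample(setdiff(bases, b), 1L), character(1),
                   USE.NAMES = FALSE)
    all_ch[sub_hit] <- repl
  }
  del_hit <- runif(ntot) < indel_rate / 2
  ins_hit <- runif(ntot) < indel_rate / 2
  all_ch[del_hit] <- "" # deletion removes the (possibly substituted) base
  if (any(ins_hit)) {
    all_ch[ins_hit] <- paste0(sample(bases, sum(ins_hit), replace = TRUE),
                              all_ch[ins_hit])
  }
  unname(vapply(split(all_ch, read_of), paste, character(1), collapse = ""))
}
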