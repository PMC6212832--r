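default_primers <- function() {
  list(
    up = c(left = "GATGTCCACGAGGTCTCT", right = "GTCGACCTGCAGCGTACG"),
    dn = c(left = "CGGTGTCGGTCTCGTAGA", right = "CGTACGCTGCAGGTCGAC")
  )
}

new_barcode_catalogue <- function(entries, primers) {
  structure(list(entries = entries, primers = primers),
            class = "barcode_catalogue")
}

#' @export
print.barcode_catalogue <- function(x, ...) {
  cat(sprintf("<barcode_catalogue> %d mutants, UP/DN 20-nt barcodes\n",
              nrow(x$entries)))
  print(x$entries, n = 5)
  invisible(x)
}

validate_catalogue_entries <- function(entries) {
  req <- c("mutant_id", "up_barcode", "dn_barcode")
  if (!all(req %in% names(entries))) {
    abort(sprintf("catalogue must have columns %s.", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(entries$mutant_id)) abort("duplicate `mutant_id` in catalogue.")
  for (cls in c("up_barcode", "dn_barcode")) {
    bc <- entries[[cls]]
    bad <- which(!grepl("^[ACGT]+$", bc))
    if (length(bad)) {
      abort(sprintf("%s: non-ACGT barcode at row %s.", cls,
                    paste(bad, collapse = ", ")))
    }
    dup <- which(duplicated(bc) | duplicated(bc, fromLast = TRUE))
    if (length(dup)) {
      culprits <- entries$mutant_id[dup]
      abort(sprintf("duplicate %s shared by mutants %s (rows %s).", cls,
                    paste(culprits, collapse = ", "),
                    paste(dup, collapse = ", ")))
    }
  }
  invisible(entries)
}

#' Load a barcode catalogue from TSV
#'
#' Reads the mutant-to-barcode map: one row per deletion mutant carrying
#' its unique 20-nt UP and DN barcodes. Duplicated barcodes (within a tag
#' class) and non-ACGT characters are hard errors naming the offending
#' rows, since a shared barcode would silently transfer counts between
#' mutants.
#'
#' @param path TSV file with columns `mutant_id`, `up_barcode`,
#'   `dn_barcode`.
#' @param primers Common flanking primers per tag class, as returned by
#'   `default_primers` structure: `list(up = c(left=, right=), dn = ...)`.
#' @return A `"barcode_catalogue"` object.
#' @export
load_catalogue <- function(path, primers = default_primers()) {
  entries <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  validate_catalogue_entries(entries)
  new_barcode_catalogue(as_tibble(entries), primers)
}

#' Write a barcode catalogue to TSV
#'
#' @param catalogue A `"barcode_catalogue"`.
#' @param path Output TSV path.
#' @export
write_catalogue <- function(catalogue, path) {
  readr::write_tsv(catalogue$entries, path)
  invisible(path)
}

#' Generate a random barcode catalogue for a mutant pool
#'
#' Draws unique random 20-nt UP and DN barcodes for each mutant, flanked
#' by the common primer pairs shared across the pool.
#'
#' @param mutant_ids Character vector of unique mutant ids.
#' @param seed Integer seed.
#' @param barcode_len Barcode length (default 20).
#' @param primers Flanking primers (see [load_catalogue()]).
#' @return A `"barcode_catalogue"`.
#' @export
make_barcode_catalogue <- function(mutant_ids, seed = 1L, barcode_len = 20L,
                                   primers = default_primers()) {
  if (anyDuplicated(mutant_ids)) abort("`mutant_ids` must be unique.")
  n <- length(mutant_ids)
  draw_unique <- function() {
    bc <- character(0)
    while (length(bc) < n) {
      need <- n - length(bc)
      new <- vapply(seq_len(need + 16L), function(i) {
        paste(sample(c("A", "C", "G", "T"), barcode_len, replace = TRUE),
              collapse = "")
      }, character(1))
      bc <- unique(c(bc, new))
    }
    bc[seq_len(n)]
  }
  with_seed(seed, {
    entries <- tibble(mutant_id = mutant_ids,
                      up_barcode = draw_unique(),
                      dn_barcode = draw_unique())
    new_barcode_catalogue(entries, primers)
  })
}
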