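#' Reference enumeration of bounded-edit alignment costs
#'
#' Independent reference implementation used to validate the fast
#' alignment kernel: a set-valued reachability recursion that carries,
#' for every pair of prefixes, the complete set of achievable
#' (mismatches, gaps) pairs within the budgets, encoded as a 12-bit set
#' (mismatches 0..2 crossed with gaps 0..3). The returned set therefore
#' contains every Pareto-minimal feasible cost of a global alignment of
#' `ref` against `query`.
#'
#' Only budgets up to 2 mismatches and 3 gaps (the screen's printed
#' tolerances) are representable; smaller budgets are applied by
#' filtering the final set.
#'
#' @param ref,query Sequences to align globally (character scalars).
#' @param max_mismatches,max_gaps Budgets, at most 2 and 3.
#' @return Tibble with columns `gaps`, `mismatches`, one row per
#'   achievable cost pair (zero rows if no alignment is feasible).
#' @export
enumerate_alignment_costs <- function(ref, query, max_mismatches = 2L,
                                      max_gaps = 3L) {
  if (max_mismatches > 2L || max_gaps > 3L) {
    abort("the reference enumerator supports budgets up to (2 mismatches, 3 gaps).")
  }
  a <- strsplit(ref, "", fixed = TRUE)[[1]]
  b <- strsplit(query, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  # bit p = mm * 4 + g ; g = 3 bits must not carry into the next mm block
  not_g3 <- 1911L # 0xFFF minus bits {3, 7, 11}
  # row i-1 of the reachability table, as a vector over j = 0..m
  prev <- integer(m + 1L)
  prev[1L] <- 1L
  if (m >= 1L) {
    jj <- seq_len(min(m, 3L))
    prev[jj + 1L] <- bitwShiftL(1L, jj)
  }
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- if (i <= 3L) bitwShiftL(1L, i) else 0L
    if (m >= 1L) {
      dd <- prev[seq_len(m)]                # diagonal source D[i-1, j-1]
      mt <- a[i] == b
      diagv <- ifelse(mt, dd, bitwAnd(bitwShiftL(dd, 4L), 4095L))
      upg <- bitwShiftL(bitwAnd(prev[-1L], not_g3), 1L) # D[i-1, j] gap
      cur[-1L] <- bitwOr(diagv, upg)
      # left-gap chain has length <= 3: three OR-propagation passes reach
      # the fixed point
      for (k in 1:3) {
        shifted <- bitwShiftL(bitwAnd(c(0L, cur[-(m + 1L)]), not_g3), 1L)
        cur <- bitwOr(cur, shifted)
      }
    }
    if (all(cur == 0L)) { # every budget exhausted: no alignment feasible
      return(tibble(gaps = integer(0), mismatches = integer(0)))
    }
    prev <- cur
  }
  bits <- which(bitwAnd(prev[m + 1L], bitwShiftL(1L, 0:11)) > 0L) - 1L
  out <- tibble(gaps = bits %% 4L, mismatches = bits %/% 4L)
  filter(out, .data$gaps <= max_gaps, .data$mismatches <= max_mismatches)
}

#' Reference barcode-assignment verdict
#'
#' Applies the same decision rule as [assign_barcode()] — lexicographic
#' (gaps, mismatches) minimal cost, ties unassigned — but on the cost
#' sets produced by the exhaustive reference enumerator
#' [enumerate_alignment_costs()]. Used to cross-check the fast kernel on
#' random instances.
#'
#' @inheritParams assign_barcode
#' @return The `mutant_id`, or `NA_character_`.
#' @export
assign_barcode_oracle <- function(candidate, catalogue, tag = c("up", "dn"),
                                  max_mismatches = 2L, max_gaps = 3L) {
  tag <- match.arg(tag)
  barcodes <- catalogue$entries[[paste0(tag, "_barcode")]]
  best_per <- vapply(barcodes, function(bc) {
    costs <- enumerate_alignment_costs(bc, candidate, max_mismatches, max_gaps)
    if (nrow(costs) == 0L) return(NA_real_)
    min(costs$gaps * (max_mismatches + 1) + costs$mismatches)
  }, numeric(1), USE.NAMES = FALSE)
  if (all(is.na(best_per))) return(NA_character_)
  best <- min(best_per, na.rm = TRUE)
  winners <- which(!is.na(best_per) & best_per == best)
  if (length(winners) != 1L) return(NA_character_)
  catalogue$entries$mutant_id[winners]
}
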