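#' Simulate a strain-by-protein expression matrix with a planted lag signal
#'
#' Emulates normalized proteome data across natural isolates: each
#' protein has one or more peptide rows per strain; a planted subset of
#' proteins is rank-correlated with the strains' lag times at
#' approximately `rho_planted` (via a Gaussian copula on the normal
#' scores of the lag vector, using the Pearson latent correlation
#' `2 sin(pi rho / 6)` so the Spearman coefficient targets
#' `rho_planted`); the remaining proteins are independent of lag.
#' Peptide replicates are noisy copies of their protein value.
#'
#' @param n_strains Number of strains (>= 3; the lag-correlation panel
#'   uses 18).
#' @param n_proteins Total proteins.
#' @param n_planted Number of planted (lag-correlated) proteins; they are
#'   the first `n_planted` ids, prefixed `"resp"` (respiratory-like),
#'   the rest `"null"`.
#' @param rho_planted Target Spearman correlation with lag, in \[-1, 1\].
#' @param peptides_per_protein Maximum peptides per protein; each protein
#'   draws 1..this many.
#' @param noise_sd SD of peptide-level noise around the protein value.
#' @param seed Integer seed.
#' @return List: `expression` (tibble `peptide_id`, `protein_id`, one
#'   column per strain), `lags` (tibble `strain`, `lag_h`, sorted longest
#'   lag first), `planted` (character vector of planted protein ids).
#' @export
simulate_proteome_matrix <- function(n_strains = 18L, n_proteins = 200L,
                                     n_planted = 40L, rho_planted = -0.6,
                                     peptides_per_protein = 3L,
                                     noise_sd = 0.2, seed = 1L) {
  check_scalar(n_strains, "n_strains", lower = 3)
  check_scalar(rho_planted, "rho_planted", lower = -1, upper = 1)
  if (n_planted > n_proteins) abort("`n_planted` cannot exceed `n_proteins`.")
  with_seed(seed, {
    strains <- sprintf("strain%02d", seq_len(n_strains))
    lag <- rlnorm(n_strains, log(4), 0.4)
    # normal scores of the lag ranks: the copula's latent variable
    z_lag <- qnorm((rank(lag, ties.method = "first") - 0.5) / n_strains)
    rho_latent <- 2 * sin(pi * rho_planted / 6)
    protein_ids <- c(sprintf("resp%03d", seq_len(n_planted)),
                     sprintf("null%03d", seq_len(n_proteins - n_planted)))
    planted <- protein_ids[seq_len(n_planted)]
    prot_val <- t(vapply(protein_ids, function(pid) {
      eta <- rnorm(n_strains)
      if (pid %in% planted) {
        rho_latent * z_lag + sqrt(1 - rho_latent^2) * eta
      } else {
        eta
      }
    }, numeric(n_strains)))
    n_pep <- sample.int(peptides_per_protein, n_proteins, replace = TRUE)
    rows <- purrr::map2(protein_ids, seq_len(n_proteins), function(pid, i) {
      k <- n_pep[i]
      vals <- matrix(rep(prot_val[i, ], each = k), nrow = k) +
        matrix(rnorm(k * n_strains, 0, noise_sd), nrow = k)
      out <- as_tibble(setNames(as.data.frame(vals), strains))
      mutate(out, peptide_id = sprintf("%s_pep%d", pid, seq_len(k)),
             protein_id = pid, .before = 1)
    })
    list(
      expression = bind_rows(rows),
      lags = tibble(strain = strains, lag_h = lag) |>
        arrange(dplyr::desc(.data$lag_h)),
      planted = planted
    )
  })
}

#' Average peptide rows into protein-level expression
#'
#' Where several peptides of one protein were measured, their expression
#' is averaged (arithmetic mean per strain, missing values ignored) to
#' give the protein's final expression. Proteins whose values are missing
#' in every strain are dropped, with their ids recorded in the
#' `"dropped"` attribute.
#'
#' @param expression Tibble with `peptide_id`, `protein_id` and one
#'   numeric column per strain.
#' @return Tibble with `protein_id` and the strain columns, one row per
#'   protein.
#' @export
average_peptides <- function(expression) {
  stopifnot(is.data.frame(expression),
            all(c("peptide_id", "protein_id") %in% names(expression)))
  if (nrow(expression) == 0L) abort("empty expression matrix.")
  strain_cols <- setdiff(names(expression), c("peptide_id", "protein_id"))
  out <- expression |>
    group_by(.data$protein_id) |>
    summarise(across(dplyr::all_of(strain_cols),
                     ~ mean(.x, na.rm = TRUE)), .groups = "drop") |>
    mutate(across(dplyr::all_of(strain_cols), ~ ifelse(is.nan(.x), NA_real_, .x)))
  all_na <- rowSums(!is.na(out[strain_cols])) == 0
  if (any(all_na)) {
    warn(sprintf("%d proteins had no measured peptides and were dropped.",
                 sum(all_na)))
  }
  dropped <- out$protein_id[all_na]
  out <- out[!all_na, ]
  attr(out, "dropped") <- dropped
  out
}

#' Spearman correlation of each protein's expression with strain lag times
#'
#' For every protein, correlates its expression across strains with the
#' strains' lag-time vector (longest to shortest lag) using the Spearman
#' rank coefficient with average ranks for ties. Proteins with constant
#' expression, or measured in fewer than `min_strains` strains, get `NA`.
#'
#' @param protein_matrix Output of [average_peptides()].
#' @param lags Tibble with `strain`, `lag_h`; every strain must be a
#'   column of `protein_matrix`.
#' @param min_strains Minimum complete pairs for a coefficient
#'   (default 3).
#' @return Tibble: `protein_id`, `rho`, `n_strains`.
#' @export
spearman_per_protein <- function(protein_matrix, lags, min_strains = 3L) {
  stopifnot(all(c("strain", "lag_h") %in% names(lags)))
  missing_cols <- setdiff(lags$strain, names(protein_matrix))
  if (length(missing_cols)) {
    abort(sprintf("strains missing from expression matrix: %s.",
                  paste(utils::head(missing_cols, 5), collapse = ", ")))
  }
  expr <- as.matrix(protein_matrix[, lags$strain])
  lag_v <- lags$lag_h
  rho <- apply(expr, 1L, function(x) {
    ok <- is.finite(x) & is.finite(lag_v)
    if (sum(ok) < min_strains) return(NA_real_)
    if (length(unique(x[ok])) < 2L) return(NA_real_)
    suppressWarnings(cor(x[ok], lag_v[ok], method = "spearman"))
  })
  tibble(protein_id = protein_matrix$protein_id, rho = unname(rho),
         n_strains = apply(expr, 1L, function(x) sum(is.finite(x))))
}

#' Coefficient distributions for defined gene sets
#'
#' Collects the per-protein correlation coefficients of each supplied
#' gene set and summarises the distribution (n, median, quartiles); the
#' all-proteins set is always included as the reference distribution.
#'
#' @param coefficients Output of [spearman_per_protein()].
#' @param gene_sets Named list of character vectors of protein ids.
#' @return List: `coefficients` (long tibble `set`, `protein_id`, `rho`),
#'   `summary` (tibble `set`, `n`, `median`, `q25`, `q75`). Sets with no
#'   measured protein produce a warning and an empty summary row.
#' @export
geneset_distributions <- function(coefficients, gene_sets = list()) {
  stopifnot(all(c("protein_id", "rho") %in% names(coefficients)))
  sets <- c(list(all_proteins = coefficients$protein_id), gene_sets)
  long <- purrr::imap(sets, function(ids, nm) {
    hit <- filter(coefficients, .data$protein_id %in% ids, !is.na(.data$rho))
    if (nrow(hit) == 0L) {
      warn(sprintf("gene set `%s` has no measured proteins.", nm))
    }
    mutate(hit, set = nm, .before = 1)
  }) |>
    bind_rows()
  summary <- long |>
    group_by(.data$set) |>
    summarise(n = dplyr::n(),
              median = median(.data$rho),
              q25 = quantile(.data$rho, 0.25)[[1]],
              q75 = quantile(.data$rho, 0.75)[[1]],
              .groups = "drop")
  empty <- setdiff(names(sets), summary$set)
  if (length(empty)) {
    summary <- bind_rows(summary,
                         tibble(set = empty, n = 0L, median = NA_real_,
                                q25 = NA_real_, q75 = NA_real_))
  }
  structure(list(coefficients = long, summary = summary),
            class = "geneset_summary")
}

#' @export
print.geneset_summary <- function(x, ...) {
  cat("<geneset_summary>\n")
  print(x$summary)
  invisible(x)
}

#' Violin-style plot of gene-set coefficient distributions
#'
#' @param object A `"geneset_summary"` from [geneset_distributions()].
#' @param ... Unused.
#' @return A ggplot of the per-set Spearman coefficient distributions.
#' @export
autoplot.geneset_summary <- function(object, ...) {
  ggplot2::ggplot(object$coefficients,
                  ggplot2::aes(x = .data$set, y = .data$rho)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = NULL, y = "Spearman correlation with lag time")
}
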