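Package: diauxr
Title: Lag-Phase Kinetics and Pooled Barcode Fitness Screens for Diauxic
    Carbon-Source Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify microbial lag phases during glucose-to-galactose
    shifts and to score pooled barcode (Bar-Seq) fitness screens of deletion
    collections. Implements a diauxic growth-curve lag-time estimator based on
    background subtraction, optical-density nonlinearity correction, discrete
    log-derivative growth rates and tangent-intersection lag geometry; fuzzy
    barcode demultiplexing under separate substitution and indel budgets;
    per-mutant enrichment scoring with dropout upper bounds, normalization
    against a glucose-only control, rank aggregation across replicates and
    tags, and extreme-set selection; microplate oxygen-consumption kinetics,
    adenylate energy charge and qPCR relative expression; and strain-level
    lag-versus-proteome Spearman correlation summaries. A synthetic-data
    module generates every input the pipeline consumes, so the whole analysis
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
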