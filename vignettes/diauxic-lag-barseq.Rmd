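---
title: "Quantifying diauxic lag phases and pooled Bar-Seq fitness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diauxic lag phases and pooled Bar-Seq fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diauxr)
library(dplyr)
```

# The problem

When *Saccharomyces cerevisiae* exhausts glucose and has to switch to a
secondary carbon source such as galactose, growth arrests for a lag phase
whose duration varies enormously between strains and conditions. Because
glucose represses respiration (the Crabtree effect), cells enter the switch
with their respiratory machinery partly dismantled, and the capacity to
respire turns out to be a major determinant of how fast they restart.
`diauxr` implements the computational side of studying this phenomenon:

* a **lag-time estimator** for diauxic plate-reader growth curves;
* scoring of **pooled barcode (Bar-Seq) deletion-collection screens**,
  from raw amplicon reads to ranked gene lists;
* small formula-defined **physiological metrics** (oxygen consumption
  rate, adenylate energy charge, qPCR relative expression);
* **lag-versus-proteome Spearman correlation** summaries across strains;
* a **synthetic-data module** that generates every input the pipeline
  consumes, with the statistical structure the analysis assumes, so the
  whole chain is testable end to end without any external data.

# The lag-time estimator

## Model and geometry

A diauxic curve is treated as two exponential phases separated by an
arrest. The pipeline is:

1. **Background subtraction.** The inoculum (~1e5 cells/ml, OD600
   ~0.005) is below the reader's detection limit, so the mean of the
   first three readings estimates the per-well background, which is
   subtracted everywhere (floored at a small epsilon for log safety).
2. **OD nonlinearity correction.** At high density the reader
   under-reports cell density; the corrected value is
   $OD_{cx} = OD_{me} + 0.499\,OD_{me}^2 + 0.191\,OD_{me}^3$.
   `distort_od()` is the exact Newton-inverted counterpart used by the
   simulator, so synthetic data carry the same nonlinearity the analysis
   removes (round-trip exact to well below 1e-6 on [0, 1.5]).
3. **Rate series.** The specific growth rate is the discrete derivative
   of $\ln OD$ assigned to the left endpoint of each interval, smoothed
   with a centered moving average (odd window, default 5 samples). With
   window $w$ the smoothed rate telescopes into a log-slope over $w$
   intervals, so its noise falls as $1/w$. We differentiate the
   *corrected*, background-subtracted series by default — otherwise the
   correction would have no downstream effect — and expose
   `use_corrected = FALSE` for the raw-measurement variant.
4. **Phase detection.** On the masked smoothed rates, the split point is
   the valley of greatest depth
   $\min(\max r_{before}, \max r_{after}) - r(s)$, which places the
   minimum rate `minR` between the two highest separated rate maxima;
   `maxR1`/`maxR2` are the maxima before and after it. A valley
   shallower than 25% of the global rate maximum means a single-phase
   curve (degenerate summary, lag not applicable).
5. **Tangent-intersection lag.** With $(t_1, OD_1)$ the curve point at
   `maxR1`, $(t_2, OD_2)$ at `maxR2` and $OD_m$ the OD at `minR`, the
   lag starts where the phase-1 tangent crosses the horizontal through
   the `minR` point and ends where the phase-2 tangent does:
   $t_{start} = t_1 + (\ln OD_m - \ln OD_1)/maxR_1$,
   $t_{end} = t_2 + (\ln OD_m - \ln OD_2)/maxR_2$, lag
   $= t_{end}-t_{start}$. On an ideal piecewise-exponential curve this
   recovers the true lag exactly; on a 0.25 h grid the estimator stays
   within a few thousandths of an hour across rates 0.2-0.5/h and lags
   1-10 h. A negative computed lag is reported as 0 with a
   `negative_lag` flag, never clamped silently.

```{r lag-example}
curve <- simulate_diauxic_curve(curve_design(lag_true = 5), seed = 7)
fit <- fit_lag(curve)
tidy(fit)
```

## Numerical choices that matter

* **Validity mask (`min_od`, default 0.1).** The background estimate
  absorbs the inoculum signal (~`od0`), so the subtracted series is
  biased by roughly `od0` and the log-derivative is inflated by a factor
  $(1 + od0/OD)$: ~50% at OD 0.01, ~5% at OD 0.1. Rates are therefore
  only trusted from 0.1 upward (about 20 times the combined inoculum and
  noise floor) and before the global OD maximum, which excludes
  stationary phase. This threshold is deliberately higher than the
  reader's bare detection limit.
* **Smoothing window (default 5 samples = 1.25 h).** Unsmoothed
  15-minute rates are too noisy for extremum picking; much wider windows
  blur the phase joints and bias the tangency points.
* **Extremum points.** Rates are interval quantities; "the curve point
  at the extremum" is the sample at the interval's left endpoint.
* **Tie-breaks.** Equal-depth valleys resolve to the smallest rate, then
  the earliest time; plateau-tied maxima resolve to the earliest sample
  (on an exact exponential every tangency point gives the same
  intersection, so this choice is benign).

The lag is invariant to multiplying the whole curve by a positive
constant up to the granularity with which the absolute detection mask
re-selects points (exactly invariant when the mask is rescaled
alongside), and extending the true lag by $\Delta$ moves the estimate by
$\Delta$ within one sampling interval.

# The Bar-Seq screen

## From reads to counts

Each deletion mutant carries unique 20-nt UP and DN barcodes flanked by
primers common to the whole pool. Candidate barcodes are cut out between
bounded-edit semi-global primer matches and assigned to the catalogue
entry that aligns with at most 2 substitutions and 3 indels, counted
separately — the screen's stated matching tolerances, re-specified as
dynamic programming because seed-based local alignment is not
reproducible at 20 nt. Costs are ordered lexicographically by
(gaps, mismatches); if two entries tie at the minimal cost the read is
left unassigned, because transferring counts between mutants is worse
than losing a read. The same tolerance is used for primer location (one
consistent error model). Reverse-complement scanning is on by default.

One consequence of separate budgets worth knowing: a third substitution
can always be re-explained as a deletion+insertion pair (2 gaps), so a
barcode with three substitutions is still assignable at cost
(2 gaps, 2 mismatches) — the two-mismatch limit binds only together with
the indel budget. The fast C++ kernel is validated against an
independent pure-R enumerator (`enumerate_alignment_costs()`) that
carries the complete set of reachable (mismatch, gap) pairs through a
bitset recursion; the two agree on thousands of random and
boundary-budget instances.

## Enrichment, normalization, ranks, extremes

The enrichment of a mutant over a selection experiment is its absolute
time-averaged growth rate
$$rate = \ln(f_T \, G / f_0)\,/\,T,$$
built from its initial and final pool proportions, the pool's total fold
expansion $G$ and the total time $T$ — the unique dimensionally
consistent combination of the three named ingredients. On noiseless
simulator output this recovers each strain's true time-averaged rate to
machine precision.

Mutants present initially but absent from the final sample are scored by
the **dropout upper bound**: the rate that would put them at exactly one
read at the final depth, `enrichment_score(f0, 1/depth, ...)`. The bound
is sharp by construction: its margin over the true rate is
$\ln(1/\lambda)/T$ where $\lambda$ is the strain's true expected final
read count, so it is deterministically valid for $\lambda < 1$ and its
margin vanishes as $\lambda \to 1$; with a *measured* initial frequency
the validity at the canonical half-expected-read case exceeds 99%, while
strains sitting exactly at the detection edge can violate it at the few
percent level. Mutants absent from the initial sample cannot be scored
and are flagged.

Normalized enrichment divides the rate on the sugar-shift condition by
the matching glucose-only control rate, removing the shared glucose
component; non-positive control rates make the ratio sign-ambiguous and
such mutants are excluded from ratio ranking and flagged. Each
(replicate, tag class) list is ranked by normalized enrichment with
average ranks for ties, and a mutant's condition-level rank is the
arithmetic mean of its positions across lists (two replicates times
UP/DN tags). The strongly enriched candidate distribution comprises the
calculable mutants plus glucose-control dropouts; the weakly enriched
one the calculable mutants plus condition dropouts; the top and bottom
200 of the respective rank-ordered distributions are the extreme sets.

# Physiology metrics

Oxygen calibration is a two-point linear map of the sensor ratio
(0%-well ratio to 0, air-saturated to 100% air saturation, clipped to
[0, 110] with out-of-range flags). Optical oxygen sensors are physically
Stern-Volmer (linear in 1/ratio), but with only two stated calibration
solutions the linear map is the transparent choice; the simulator and
estimator share it, so the pair is self-consistent. OCR is minus the
derivative of the smoothed saturation divided by the OD at that point
(consumption positive), reusing the same moving-average operator as the
growth module. Energy charge is
$(ATP + 0.5\,ADP)/(ATP + ADP + AMP)$; qPCR relative expression is
$amplification^{(\text{reference take-off} - \text{sample take-off})}$.

# Lag-proteome correlation

Peptide rows are averaged per protein and strain (missing values ignored
in the mean; all-missing proteins dropped with a warning; proteins seen
in fewer than 3 strains get no coefficient). Each protein's expression
vector is Spearman-correlated (average-tie ranks) with the strains' lag
vector, and gene-set coefficient distributions are summarised with the
all-proteins set always included as reference. Gene-set membership is
supplied as input, not hardcoded.

```{r proteome-example}
pm <- simulate_proteome_matrix(seed = 11)
co <- spearman_per_protein(average_peptides(pm$expression), pm$lags)
geneset_distributions(co, list(respiration = pm$planted))$summary
```

# What the synthetic data do and do not emulate

The generators define the study conditions the tests run under:

* **Growth curves**: piecewise-exponential truth (rate $r_1$ to the
  sugar switch, hard zero-rate lag, rate $r_2$, capped at `od_max`),
  distorted by the known OD nonlinearity, plus well background (0.1 OD)
  and multiplicative 0.5% measurement noise, sampled every 15 min.
  Defaults (glucose 0.5/h, galactose 0.3/h, lag 5 h, inoculum OD 0.005)
  are typical rich-medium values. The noise is modelled as proportional
  to the blank-subtracted signal: a constant-variance floor would make
  log-derivative rates meaningless near the detection limit regardless
  of the estimator, and signal-proportional variability (mixing,
  pipetting) dominates above it.
* **The pool**: per-strain log-normal glucose and galactose rates
  (medians 0.45 and 0.30/h, log-SD 0.10) and lags with an exponential
  tail above 1 h — most deletions near wild type, a slow-switching
  minority. These distributional defaults are stated configuration, not
  asserted biology. Selection is three rounds of glucose growth
  (3 doublings), then a galactose window sized so the reference strain
  completes its lag plus 2.5 doublings; lag acts as a hard growth delay
  at every entry into galactose. Phase durations follow from the
  reference (median) rates because the regime is specified in doublings.
  Planted "long-lag" mutants have their lag extended by 5 h — on the
  order of the galactose window itself, since a screen that allows only
  2-3 galactose doublings per round is sensitive precisely to lags of
  that magnitude (respiration-deficient strains that barely resume
  growth before the transfer).
* **Sequencing**: multinomial reads per sample; replicates and UP/DN
  tags are independent draws of the same frequencies. FASTQ reads are
  primer+barcode+primer with independent per-base substitution and
  indel errors and constant placeholder qualities.
* **Not modelled**: glucose-repression mechanism, single-cell
  heterogeneity, PCR amplification bias, quality-score structure,
  strain-by-replicate biological variance, mutation accumulation.
  Passing tests therefore demonstrate correctness of the estimators
  under the stated generative assumptions, not robustness to every
  artefact of real screens.

# Problem sizes and runtime

The shipped checks use the study's own scales where they matter:
4,887-mutant pools, 1e6 reads per sample, 2 replicates x UP/DN tags,
200 planted long-lag strains; 100 noisy growth curves at 0.5% noise;
1,000 random barcode instances against catalogues of up to 50 entries;
1,000 dropout trials; 100 seeded correlation panels of 18 strains.
The whole suite runs in a few minutes on one core.

# Known limitations

* The valley-depth phase detector assumes one dominant lag; curves with
  more than two exponential phases return the deepest split only.
* The dropout bound is sharp at the one-read detection edge (see above).
* Barcode assignment treats primer-less reads as unassigned rather than
  attempting barcode-only matching.
* The oxygen model integrates uptake on the sampling grid (forward
  Euler); OCR recovery is exact during constant-OD phases and within a
  few percent while OD grows.
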