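---
title: "Methods: screening for promoter-hypermethylation silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for promoter-hypermethylation silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

## The problem

In colorectal cancer (and many other tumors), promoter CpG methylation can
transcriptionally silence tumor-suppressor genes. Given a cohort profiled
for both promoter methylation (Infinium-style beta values in [0, 1], about
two CpG probes per promoter) and mRNA expression (log2 scale), the screen
asks: for which genes is high promoter methylation consistently accompanied
by low expression? `methylscreen` implements that screen end to end:
cohort-level QC, molecular-feature associations, a per-gene rank-correlation
screen with FDR control, a grid heuristic for nonlinear ("L-shaped")
associations that rank correlation misses, validation in an independent
cohort, CpG-island annotation with a resampling enrichment test, term
over-representation, and survival stratification by a marker gene.

## Cohort model and alignment

Probes map to genes through a probe annotation; a gene's promoter
methylation in a sample is the unweighted mean beta over its probes
(`align_cohort()`, `aggregate = "mean"`). The array design this mirrors
averages about two probes per promoter, and the screen is framed per
promoter, so one value per gene is the primary mode. A `per_probe` mode
keeps every probe and lets a gene inherit its most significant probe; that
choice is mildly anticonservative (a best-of-k selection happens before the
FDR adjustment) and is offered for sensitivity analyses, not as the
default. A sample contributes to a gene whenever at least one probe is
non-missing; all correlations use pairwise-complete pairs, and genes with
fewer than 4 complete pairs are reported untested rather than dropped
silently. Coordinates are 0-based and half-open throughout; the only entry
point for TSS positions is the `tss=` key in FASTA headers.

The retained-promoter fraction is reported by `align_cohort()`. In the
reference colorectal cohort that motivated this design, 11,359 of 14,475
interrogated promoters had expression data, i.e. 78.47%; a companion figure
of 81.92% is sometimes quoted for the same two counts but is arithmetically
inconsistent with them, so this package reports the ratio it actually
computes.

## Statistical primitives

All tests are implemented explicitly so that each can be verified against a
brute-force oracle (the test suite also cross-checks them against
`cor.test`, `p.adjust`, `fisher.test` and the survival package):

* **Spearman correlation** (`spearman_test`): Pearson correlation of
  average ranks (ties get mean ranks); two-sided p from the t
  approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df, `p = 0` at
  `|rho| = 1`. An exact permutation p is available for `n <= 9`. The t
  approximation is used at every n because the screen operates at n ≈ 30,
  where it is accurate and fast.
* **Benjamini–Hochberg adjustment** (`bh_adjust`): classical step-up,
  monotonised from the largest p, capped at 1, returned in input order.
* **Two-sample t** (`two_sample_t`): pooled-variance Student's t by
  default (the convention of the figure legends this mirrors), Welch
  optional.
* **Fisher's exact test** (`fisher_exact_2x2`): two-sided p by the
  point-probability rule (sum of hypergeometric probabilities not exceeding
  the observed table's, with a 1e-7 relative guard against float ties) —
  the common convention, matching `fisher.test`; the central
  (double-one-sided) rule is a documented alternative not implemented. The
  odds ratio reported is the sample cross-product `ad/bc` (`Inf` when
  `bc = 0`), not the conditional MLE.
* **Kaplan–Meier / log-rank** (`km_estimate`, `logrank_test`):
  product-limit estimate; chi-square(1) log-rank from summed O − E with
  hypergeometric variance. Log-rank is used for survival comparisons as
  the conventional choice for dichotomized expression groups.

## The correlation screen and FDR

`correlation_screen()` computes Spearman rho per gene and applies one BH
adjustment jointly over all tested genes; a significant-negative hit needs
`rho < 0` **and** `q < 0.2`. Two-sided p-values are used before the sign
filter (whether the original analyses used one- or two-sided p is not
documented; two-sided plus sign filter is the more conservative and
reproducible choice). The 0.2 FDR default is deliberately liberal: the
screen feeds a validation stage, which is where specificity is bought.

Validation (`cross_cohort_validate()`) restricts to candidates with usable
data in the second cohort, reports that availability fraction, and re-runs
Spearman with a **fresh BH adjustment within the candidate subset** — the
validated fraction is then a statement about the candidate list, not a
genome-wide re-screen. This matches how validated counts are conventionally
quoted (e.g. 382 of 653 available candidates, 58.5%).

## The L-shape heuristic

Rank correlation misses genes that are expressed only when methylation is
low but show no dose–response across the methylated range: the scatter is
L-shaped. `lshape_classify()` min-max normalises expression per gene,
partitions the unit square into a 3×3 grid (beta cuts and normalized
expression cuts at 1/3 and 2/3 by default), counts points per cell, and
scores `sum(w_rc * n_rc) / N`. A gene is flagged when the score reaches
`score_threshold = 0.25` and at most 5% of points sit in the top-right
(high-expression/high-methylation) cell, which directly contradicts
silencing. Points exactly on a cut join the lower-beta / lower-expression
cell, so the partition is deterministic under ties.

The default weights are

```{r}
lshape_config()$weight_matrix
```

The design intent: reward the two arms of the L — the
high-expression/low-beta corner (+1) and, most strongly, the
low-expression/high-beta corner (+3) that is the direct evidence of
silencing — keep the rest of the bottom row mildly positive, and penalise
everything high-beta/high-expression (−10 top-right). Cells away from the
arms are zero or negative for a specific reason: if top-left, mid-left and
bottom-left were all rewarded, any gene whose promoter is simply never
methylated (all points in the left column, expression pure noise) would
score above threshold, and on realistic cohorts that flags the majority of
unmethylated null genes. With these defaults an L-call requires the
methylated, silenced arm to be populated; on the default synthetic cohort
the null flag rate is about 2% while planted L genes are recovered
essentially always. Every parameter (cuts, weights, `min_points = 10`,
veto fraction, threshold) is exposed in `lshape_config()` since the
original tool's internal settings are not published.

Genes with fewer than `min_points` pairs are untested (not errors); the
score is invariant to duplicating the point set.

## CpG islands and enrichment

`ggf_scan()` implements the classical island definition: windows of 200 bp
with GC fraction ≥ 0.5 and observed/expected CpG ratio ≥ 0.6
(`obs_exp = n_CG * L / (n_C * n_G)`, overlapping dinucleotide counting; GC
excludes N bases from both numerator and denominator). Qualifying windows
are merged into maximal islands (union-of-windows convention). A merged
span need not itself satisfy the thresholds, so each island re-reports GC
and Obs/Exp over its full span plus a `merged_pass` column, and the scan is
verified against brute-force window enumeration on random sequences.

A gene is island-associated when an island overlaps a promoter window of
(−2000, +500) bp around the TSS (truncated at sequence edges). The window
is a design choice — wide enough to cover typical 27K-array probe placement
— and configurable, because the association convention used upstream of the
published counts is not documented. `island_enrichment()` compares a target
gene set's island fraction with the mean over `n_random_sets = 10`
same-size random draws (seeded, without replacement), Fisher-testing
observed counts against the baseline expressed as counts. Ten sets is a
noisy baseline, so the exact hypergeometric comparison against the full
universe is always computed alongside.

## Term enrichment

`enrich_terms()` is plain per-term 2×2 Fisher over-representation with one
BH pass across terms and an odds-ratio > 1 direction filter. It
deliberately does **not** reproduce database-backed tools (no EASE-style
count penalty, no term clustering); published term lists depend on the
annotation snapshot used and are not desk-reproducible, so tests use
constructed annotation fixtures only.

## The synthetic cohort generator

`simulate_cohort()` generates cohorts with the statistical structure the
screen assumes, so every stage is testable without external data. Choices,
with the anchors that fixed them:

* **Beta values**: two-component Beta mixtures (low mean 0.1, high mean
  0.8, concentration 10), with a per-probe high-component propensity drawn
  from Beta(0.2, 0.4) and a per-sample global factor (sd 0.15). These
  reproduce the published panel profile: roughly half of probes averaging
  below 0.2, about 30% above 0.5, and per-sample mean betas spreading over
  an interval comparable to the published 0.22–0.43 cell-line range.
* **Controls**: one whole-genome-amplified (unmethylated) control with mean
  beta 0.05 and one in-vitro methylated control with mean 0.86 —
  the published control values — plus one technical replicate (additive
  noise, sd 0.01, Pearson r > 0.99).
* **MSI**: a third of samples are MSI; their high-component weight is
  shifted so the group mean beta rises by `msi_beta_shift = 0.05`.
  The shift acts on the mixture weight, not additively, so values stay in
  [0, 1]. Mutation flags are drawn at typical colorectal frequencies and
  are independent of methylation (null by design).
* **Doubling time**: drawn anti-correlated with per-sample mean beta
  (target r = −0.5, mean 30 h, sd 8 h) — hypermethylated lines grow faster.
* **Planted genes**: 10% monotone-silenced (linear log2-expression decrease
  of 6.2 per beta unit plus N(0, 1) noise, giving Spearman rho ≈ −0.8 at
  n = 30) and 1% L-shaped (expressed high in ~60% of low-methylation
  samples, floor + noise otherwise). Planted genes receive mid-range probe
  propensities so their betas span the axis.
* **Promoters**: 1500 bp, GC ≈ 0.4 background with every CpG dinucleotide
  broken, so the background can never contain an island; island genes
  (66.2% by default, matching the published random-set baseline) get an
  embedded 250 bp segment with GC ≈ 0.62 and Obs/Exp ≈ 2 overlapping the
  TSS.
* **Survival**: exponential event times, baseline hazard 1/1500 per day,
  hazard ratio 3 for the below-median marker group, independent exponential
  censoring at rate 0.3 (rate ≥ 1 censors everything).

What the generator does **not** emulate: linkage between neighbouring
probes, copy-number and purity effects, realistic genome coordinates, batch
structure, or tumor/normal contamination. Passing tests therefore
demonstrate that the pipeline recovers the structure it is designed to
detect under clean conditions — not that it is robust to every artefact of
real Infinium data (which would additionally need the out-of-scope raw-IDAT
normalisation steps).

## Numerical choices and degenerate inputs

* Histogram bins are left-closed, right-open, top bin closed on both sides.
* `two_sample_t` with zero pooled variance returns t = 0, p = 1 when the
  means agree and errors otherwise; correlation tests error on zero
  variance rather than returning NaN.
* Genes whose ranks are degenerate (constant beta or expression) are
  untested in the screen, like the < 4-pair case.
* The replicate appended by the generator is excluded from group tests via
  its `control_role`; unknown-status samples are excluded from both sides
  of every feature association.
* All randomness is seeded: the generator derives stage seeds from the
  config seed with fixed offsets, so stages are reproducible independently
  of call order; `island_enrichment()` requires an explicit seed.

## Problem sizes used by the tests

The suite exercises the screen at its design point — 30 samples, 2,000
genes, 2 probes/gene, 20 replicate cohorts — and the error-rate checks at
1,000–2,000 replicates for test size, 200–500 for power, sizes chosen to
make binomial noise small relative to the margins being asserted. Oracle
equivalence suites run on dozens of random instances each. These are the
package's chosen verification sizes; all scale linearly if heavier
verification is wanted.

## Known limitations

* The L-heuristic's defaults are this package's own calibration of an
  unpublished tool; conclusions about borderline L genes should be checked
  under perturbed weights (all exposed).
* Per-probe mode's best-probe selection precedes the FDR adjustment.
* The resampled island baseline with 10 sets carries Monte-Carlo noise of
  several percentage points; prefer the hypergeometric cross-check when
  the universe flags are complete.
* No Cox modelling: survival analysis is limited to KM + log-rank on a
  dichotomized marker.
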