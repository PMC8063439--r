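# methylscreen

Genes silenced by promoter CpG hypermethylation are recurrent drivers of
colorectal and other cancers, but genome-wide methylation alone does not say
which methylation events matter for transcription. `methylscreen` is an R
package for epigenomics groups that integrates a promoter methylation matrix
(Infinium-style beta values in [0, 1]) with a matched expression matrix
(log2) to screen a cohort for putatively silenced genes, and carries the
result through validation, annotation and survival analysis.

## What it computes

For each gene g with promoter methylation $\beta_{gi}$ (mean over its CpG
probes) and expression $x_{gi}$ over samples $i$:

* **Correlation screen** — Spearman's $\rho_g$ (Pearson on average ranks),
  two-sided p from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, one
  Benjamini–Hochberg pass over all tested genes; a hit needs $\rho_g < 0$
  and $q_g < 0.2$.
* **L-shape heuristic** — for nonlinear silencing invisible to rank
  correlation: min-max-normalised expression vs beta on a 3×3 grid over the
  unit square, score $\sum_{rc} w_{rc} n_{rc} / N$ with configurable
  weights; flagged genes join the candidate set if not already significant.
* **Cross-cohort validation** — candidates with data in a second cohort are
  re-screened there (fresh BH within the candidate set); the package
  reports availability and validated fractions.
* **CpG islands** — Gardiner-Garden–Frommer calling (windows ≥ 200 bp,
  GC ≥ 0.5, Obs/Exp CpG = $n_{CG} L / (n_C n_G) \ge 0.6$, qualifying
  windows merged), island–gene association in a (−2000, +500) bp TSS
  window, and enrichment of a gene set against seeded random same-size
  draws plus an exact hypergeometric cross-check (Fisher's exact test,
  point-probability rule).
* **Term enrichment** — plain per-term Fisher over-representation with BH
  across terms (GMT input).
* **Survival** — Kaplan–Meier curves and the log-rank test for
  marker-dichotomized groups (median or low-tertile split).
* **Synthetic cohorts** — a seeded generator
  (`simulate_cohort()`) producing beta/expression/annotation/FASTA bundles
  with planted monotone and L-shaped silenced genes, control samples
  anchored at mean beta 0.05 / 0.86, MSI-linked hypermethylation, planted
  GGF islands and expression-linked survival, so the whole pipeline is
  testable offline.

See `vignettes/methylscreen-methods.Rmd` for the model, parameter
rationale and limitations.

## Worked example

```r
library(methylscreen)

cfg <- sim_config(seed = 7)          # 30 samples, 2000 genes, defaults
co  <- simulate_cohort(cfg)

qc_controls(co$beta, co$samples)
#> methylation QC
#>  sample_id                 role  mean_beta flagged
#>   CTRL_NEG unmethylated_control 0.04950096   FALSE
#>   CTRL_POS   methylated_control 0.86173151   FALSE
#>  sample_id reference         r flagged
#>   S001_rep      S001 0.9995942   FALSE
#>   no flags raised

scr <- silencing_screen(co$beta, co$expr, co$probes)
scr
#> silencing screen: 2000 genes tested
#>   significant negative correlation (q < 0.2): 235 (11.8%)
#>   L-shape only: 48
#>   candidates: 283 (14.1%)

flags <- associate_islands(ggf_scan(co$promoters), co$promoters)
island_enrichment(flags, scr$table$gene_symbol[scr$table$candidate_flag],
                  seed = 7)
#> island enrichment: 283 target genes
#>   observed island fraction: 64.0%
#>   resampled baseline (10 sets): 66.5% (universe 66.5%)
#>   Fisher vs baseline: p = 0.597; hypergeometric vs universe: p = 0.342

survival_stratify(co$expr, co$samples, co$marker_gene)
#> survival by G0006 expression (median split): low n=15, high n=15
#>   log-rank chi-square = 8.442, p = 0.00367
```

Reading the output: both control samples sit at their expected means and
the technical replicate correlates at r > 0.999, so the cohort passes QC.
The screen tests all 2,000 genes and calls 235 significant negative
correlations at FDR 0.2 — the generator planted 200 monotone-silenced genes,
so roughly all of them plus a controlled share of false discoveries — and
48 further L-shape-only genes (20 planted). The generator assigns islands
independently of silencing, so the candidate set shows no island enrichment
(p ≈ 0.6), while the survival split on the planted marker gene (hazard
ratio 3 for low expressors) is detected at p ≈ 0.004.

The same stages are scriptable from a shell via
`inst/cli/methylscreen.R` (`simulate`, `qc`, `associations`, `screen`,
`islands`, `enrich`, `survival`, `run-all` with a YAML config), and
`run_full()` writes per-stage TSVs plus a single summary file.

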