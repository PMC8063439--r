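Package: methylscreen
Title: Promoter Hypermethylation Silencing Screen for Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates promoter CpG methylation (Infinium-style beta values)
    with mRNA expression to screen for epigenetically silenced genes in cancer
    cohorts. Provides cohort-level methylation QC and molecular-feature
    association tests, a Spearman/FDR negative-correlation screen with an
    L-shape heuristic for nonlinear methylation-expression associations,
    cross-cohort validation, Gardiner-Garden-Frommer CpG-island calling with
    a resampling enrichment test, generic annotation-term over-representation,
    Kaplan-Meier/log-rank survival stratification, and a seeded synthetic
    cohort generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
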