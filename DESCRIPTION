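Package: adgwas
Title: GWAS Meta-Analysis and Polygenic Risk Stratification for Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-effects inverse-variance-weighted meta-analysis of
    case-control and by-proxy GWAS summary statistics, LD clumping and
    follow-up variant selection, genomic-inflation diagnostics, weighted
    polygenic risk scores (PRS), survival-bias-corrected PRS percentile
    stratification within pooled APOE genotype groups, age-at-onset
    comparisons, and a case-only Cox model with a PRS-by-APOE interaction.
    Includes a synthetic cohort and summary-statistics generator emulating
    the data structure of a large Alzheimer's disease case-control study,
    so every pipeline stage is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
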