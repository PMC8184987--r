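---
title: "Methods: meta-analysis, polygenic scoring and APOE-stratified risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis, polygenic scoring and APOE-stratified risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgwas)
```

## What the package computes

`adgwas` re-implements, as reusable and tested components, the statistical
machinery of a large Alzheimer's disease (AD) case-control genetics study:

1. **Meta-analysis.** Per-variant log odds ratios from several GWAS are
   pooled by fixed-effects inverse-variance weighting (IVW). For a variant
   with study estimates $\hat\beta_i$ and standard errors $s_i$,
   $w_i = s_i^{-2}$, $\hat\beta = \sum w_i \hat\beta_i / \sum w_i$,
   $\mathrm{SE} = (\sum w_i)^{-1/2}$, and the two-sided p-value comes from
   the normal distribution of $z = \hat\beta/\mathrm{SE}$. Studies with a
   by-proxy phenotype (parental dementia history) enter after their effects
   and standard errors are multiplied by a rescale factor (default 2, one
   parent transmitting half the genome), which leaves $z$ untouched.
2. **Signal reduction.** Greedy LD clumping (smallest p first, absorbing
   variants within a physical window whose $r^2$ with the sentinel exceeds
   a threshold; defaults $r^2 \ge 0.001$ within 250 kb) and follow-up
   selection of suggestive variants ($p < 10^{-5}$ within 200 kb of a
   sentinel, minus previously established regions). The APOE region is
   special-cased through forced sentinels, keeping only the two
   epsilon-defining SNPs as leads.
3. **Polygenic risk score.** A weighted sum of effect-allele dosages over
   39 genome-wide significant variants (APOE excluded), standardised to
   z-scores, and its per-1-SD odds ratio from logistic regression with
   four ancestry components.
4. **Risk stratification.** Percentile bins whose boundaries are computed
   only on controls aged 55 or younger (a survival-bias correction: older
   controls are depleted of high-risk scores), applied to everyone; pooled
   APOE groups e2e2/e2e3, e3e3, e2e4/e3e4, e4e4 split into 7/25/15/3 PRS
   groups; logistic contrasts against the lowest-risk group; median
   age-at-onset (AAO) comparisons by Wilcoxon rank-sum test; and a
   case-only Cox model of AAO with a PRS-by-APOE interaction (Breslow
   ties).

A synthetic-data module generates per-study summary statistics and
cohorts with this exact structure, so every stage can be exercised and
calibrated end to end without access to the restricted source data.

## The generator and what it emulates

`sim_config()` defaults describe a cohort of 6,331 cases and 6,055
controls, 3,546 of the controls aged 55 or younger — the anchor panel for
percentile boundaries. Disease status follows a logistic liability

$$\operatorname{logit} P(\text{case}) = \alpha
  + \textstyle\sum_i \log(\mathrm{OR}_i)\,(g_i - 2\,\mathrm{maf}_i)
  + \log(\mathrm{OR}_{APOE})
  + \log(\mathrm{OR}_{SD})\, z,$$

with $\alpha$ solved numerically so the expected case count matches the
configured one. The polygenic term $z$ is standard normal and independent
of the typed variants; this deliberate simplification lets a configured
per-SD odds ratio be tested directly without committing to the variance
explained by the 39 typed variants. Genotypes are Hardy-Weinberg binomial
draws (correlated latent Gaussians inside declared LD blocks, with the
latent correlation solved numerically to hit the target dosage $r^2$).
Summary statistics are drawn per variant as
$\hat\beta \sim N(\log \mathrm{OR}, s)$ with
$s = (2\,\mathrm{maf}(1-\mathrm{maf})\,n_{\mathrm{eff}})^{-1/2}$ and
$n_{\mathrm{eff}} = 4/(1/n_{\mathrm{ca}} + 1/n_{\mathrm{co}})$; proxy
studies emit the attenuated scale (beta and se halved).

Case AAO is drawn from a normal with stratum-specific median and common
SD 8 years, truncated to [40, 105]. Stratum medians are configured for the
extreme PRS bins of each pooled APOE group (defaults: 82/83 for
e2e2/e2e3, 82/81 for e3e3, 81/77 for e2e4/e3e4, 78.5/73 for e4e4, in
years, lowest/highest bin) and interpolated linearly in bin index between
them — the interior shape is unconstrained by the source study, so the
simplest interpolation is used. Control ages are a uniform mixture placing
the configured fraction at or below 55. The APOE group odds ratios
(defaults 0.6 / 1 / 3 / 10 vs e3e3) are order-of-magnitude
literature-style placeholders: the source study prints no APOE-vs-e3e3
odds ratios, nothing downstream is calibrated against them, and they are
plain config entries.

What the generator does **not** emulate: genome-wide LD from a reference
panel, imputation error, family structure, age-dependent competing
mortality, or real minor-allele-frequency spectra. Passing recovery tests
therefore show that the estimators are correct and calibrated under the
assumed generative model, not that the pipeline is robust to every
artefact of real array data.

## Choices that matter and why

**Marginal per-SD recovery uses a polygenic-only liability.** The
recovery checks for the per-SD odds ratio (and quantities derived from
it) simulate with the polygenic score as the only non-null liability
term. Logistic odds ratios are non-collapsible: omitting an independent
risk factor (say, a strong APOE effect) from the fitted model attenuates
the marginal coefficient of the score below its conditional generative
value, so a generative per-SD OR is only recoverable by the marginal fit
when no other liability term varies. This is a property of the odds
ratio, not of the implementation, and the configuration was fixed before
any recovery run.

**Quantile convention.** Percentile boundaries use linear interpolation
between order statistics (type 7, the R default), bins are
left-open/right-closed with the lowest bin closed, values exactly on a
cut-point go to the lower bin, and out-of-range scores clamp to the
extreme bins so assignment is total. The convention is documented because
bin membership near a boundary depends on it.

**Statistical engines.** Logistic models are fitted by IRLS
(`stats::glm`, score tolerance 1e-8, 25 iterations), Cox models by
`survival::coxph` with Breslow tie handling, and rank tests by
`stats::wilcox.test`; the package normalises their outputs and their
failure modes. Perfect separation and monotone partial likelihoods are
reported as non-converged fits rather than penalised or silently huge
estimates — transparent failure is preferable for tiny strata. Cox inputs
are canonically sorted before fitting so results are bit-identical under
row permutation. The Hardy-Weinberg exact test (conditional on allele
counts, summing configurations no more probable than the observed one)
is implemented directly in log space since no installed dependency
provides it.

**Wilcoxon mode.** The source analysis names only "a Wilcoxon test"; both
an exact small-sample mode (auto-selected for $n_1+n_2 \le 12$ without
ties) and the tie- and continuity-corrected normal approximation are
exposed, and the mode used is recorded in the result.

**QC thresholds.** Call rate > 95%, MAF > 0.01, HWE exact $p \ge 10^{-4}$
in controls (on hard-called dosages; dosages further than 0.1 from an
integer are treated as missing for HWE only), and no differential
missingness. The differential-missingness statistic and cut-off are not
stated in the source; a two-sided Fisher exact test at $p < 10^{-6}$ is
this package's documented choice.

**PRS standardisation reference.** Per-SD effects use the mean and SD
(n-1 denominator) of all analysed individuals by default; a controls-only
reference is available via the `reference` argument, since the source
study does not state which was used.

**Table reconstruction.** Printed odds ratios and 95% CIs are converted
back to the log scale with $\mathrm{se} = (\log U - \log L)/(2 z_{0.975})$
(symmetry on the log scale). Reconstructed overall odds ratios match the
printed ones to within ±0.015 — the slack implied by 2-decimal rounding of
the inputs — but printed overall p-values are *not* recoverable from
rounded inputs, so nothing asserts them.

**e2e4 pooling.** The e2e4 genotype is pooled with e3e4 even though the
epsilon-2 and epsilon-4 effects oppose; the pooled analysis follows the
source design and no sub-analysis is attempted.

**Onset curves.** Whether the published onset-probability curves are
Kaplan-Meier or Breslow baseline estimates is not stated; `onset_curves()`
exports both, labelled.

## Problem sizes used by the checks

The recovery checks use 200 replicate cohorts of 12,386 individuals for
the per-SD and extreme-percentile contrasts, 500 replicates of 1,718 for
the pathological-series effect, and a stratified case series with 10,000
cases per PRS bin (anchored on 10,000 young controls per group) for the
AAO medians — large enough that the median sampling error (~0.14 years
for a difference of medians) is small against the ±0.5-year check.
Property suites (HWE-oracle agreement up to 200 alleles, clumping
partitions, IVW algebra, type-I calibration at 2,000 null association
tests) run on sizes chosen to make the Monte Carlo error a fraction of
each asserted bound.

## Known limitations

- The shipped 39-variant weight table is synthetic (plausible loci and
  log-OR-scale weights mirroring the canonical table's structure); real
  analyses should supply the published weights via `read_prs_weights()`.
- LD in the generator is block-equicorrelated, adequate for clumping and
  P+T logic tests but not for fine-mapping-style questions.
- No random-effects meta-analysis: heterogeneity (Cochran's Q) is
  reported but never used for filtering, matching the source design.
- Absolute-risk calibration (lifetime risk, competing mortality) is out
  of scope; stratified results are relative odds and onset medians only.
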