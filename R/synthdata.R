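# Synthetic cohorts and per-study summary statistics with the statistical
# structure the analysis pipeline assumes: logistic-liability case-control
# status, HWE genotypes with optional LD blocks, pooled-APOE risk groups,
# an independent standard-normal polygenic score, and stratum-specific
# age-at-onset distributions.

#' Generator configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the discovery case-control study: 6,331 cases and 6,055 controls of whom
#' 3,546 are aged 55 or younger, the replicated risk loci (with their
#' published frequencies and overall odds ratios) as true variant effects,
#' a 1.27 odds ratio per SD of the polygenic score, and stratum
#' age-at-onset medians matching the extreme-group values of the source
#' cohort. The APOE group odds ratios are order-of-magnitude placeholders
#' (the source study prints no APOE-vs-e3e3 ORs) and are editable here.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param n_young_controls Number of controls aged <= 55 (the percentile
#'   anchor panel).
#' @param variant_spec Data frame (variant_id, chrom, pos, effect_allele,
#'   other_allele, maf, true_or) for the simulated dosage matrix.
#' @param apoe_freqs Named genotype probabilities over
#'   e2e2, e2e3, e2e4, e3e3, e3e4, e4e4 (must sum to 1).
#' @param apoe_ors Named odds ratios per pooled APOE group vs e3e3.
#' @param prs_per_sd_or Odds ratio per 1 SD of the extra polygenic score
#'   (a standard-normal liability term independent of the typed variants).
#' @param aao_medians Named list per pooled APOE group of
#'   `c(lowest, highest)` case age-at-onset medians (years) for the extreme
#'   PRS bins; interior bins are interpolated linearly in bin index.
#' @param aao_bins Named integer vector: number of PRS bins per pooled
#'   APOE group used by the AAO model.
#' @param aao_sd Common AAO standard deviation in years (default 8);
#'   draws are truncated to [40, 105].
#' @param pathology_rates `c(any_concomitant, multiple)` Bernoulli rates of
#'   concomitant-pathology flags among pathological-series cases.
#' @param ld_blocks List of `list(variants = ids, r2 = target)` blocks;
#'   variants outside any block are independent.
#' @param seed Mandatory integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 6331L, n_controls = 6055L,
                       n_young_controls = 3546L,
                       variant_spec = default_variant_spec(),
                       apoe_freqs = c(e2e2 = 0.004, e2e3 = 0.077,
                                      e2e4 = 0.020, e3e3 = 0.614,
                                      e3e4 = 0.254, e4e4 = 0.031),
                       apoe_ors = c("e2e2/e2e3" = 0.6, "e3e3" = 1.0,
                                    "e2e4/e3e4" = 3.0, "e4e4" = 10.0),
                       prs_per_sd_or = 1.27,
                       aao_medians = list("e2e2/e2e3" = c(82, 83),
                                          "e3e3" = c(82, 81),
                                          "e2e4/e3e4" = c(81, 77),
                                          "e4e4" = c(78.5, 73)),
                       aao_bins = c("e2e2/e2e3" = 7, "e3e3" = 25,
                                    "e2e4/e3e4" = 15, "e4e4" = 3),
                       aao_sd = 8, pathology_rates = c(0.84, 0.488),
                       ld_blocks = list(), seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (abs(sum(apoe_freqs) - 1) > 1e-8) stop("apoe_freqs must sum to 1")
  if (!setequal(names(apoe_freqs), APOE_LEVELS)) {
    stop("apoe_freqs must name the six APOE genotypes")
  }
  if (any(apoe_ors <= 0) || prs_per_sd_or <= 0) stop("all odds ratios must be positive")
  if (any(variant_spec$maf <= 0 | variant_spec$maf >= 1)) {
    stop("variant minor allele frequencies must lie strictly in (0, 1)")
  }
  if (any(variant_spec$true_or <= 0)) stop("variant odds ratios must be positive")
  if (n_young_controls > n_controls) stop("n_young_controls exceeds n_controls")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_young_controls = as.integer(n_young_controls),
         variant_spec = variant_spec, apoe_freqs = apoe_freqs,
         apoe_ors = apoe_ors, prs_per_sd_or = prs_per_sd_or,
         aao_medians = aao_medians, aao_bins = aao_bins, aao_sd = aao_sd,
         pathology_rates = pathology_rates, ld_blocks = ld_blocks,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default variant specification: the replicated risk loci
#'
#' Uses the packaged table of replicated loci (chromosome, position,
#' alleles, effect-allele frequency and overall odds ratio) as the true
#' effects of the simulated dosage matrix.
#'
#' @return Data frame usable as `variant_spec` in [sim_config()].
#' @export
default_variant_spec <- function() {
  tab <- read_replicated_loci()
  data.frame(variant_id = tab$SNP, chrom = as.character(tab$CHR), pos = tab$BP,
             effect_allele = tab$A1, other_allele = tab$A2,
             maf = tab$FRQ_A1, true_or = tab$OR_OVERALL,
             stringsAsFactors = FALSE)
}

#' Packaged table of replicated risk loci
#'
#' The replicated loci with their printed discovery, follow-up and overall
#' odds ratios and 95% confidence bounds, used both as generator
#' calibration and to reproduce the overall column by IVW meta-analysis of
#' the reconstructed stage estimates.
#'
#' @return Data frame with columns CHR, BP, SNP, A1, A2, FRQ_A1, and
#'   OR/L95/U95 triplets for the DISC, FU and OVERALL stages, plus GROUP.
#' @export
read_replicated_loci <- function() {
  utils::read.delim(system.file("extdata", "replicated_loci.tsv",
                                package = "adgwas", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

# correlation of the latent Gaussians needed so that the thresholded
# alleles at frequencies p1, p2 have (binary) correlation r
latent_rho_for_allele_cor <- function(r, p1, p2) {
  if (r <= 0) return(0)
  th1 <- stats::qnorm(p1); th2 <- stats::qnorm(p2)
  p11 <- function(rho) {
    stats::integrate(function(x) {
      stats::pnorm((th2 - rho * x) / sqrt(1 - rho^2)) * stats::dnorm(x)
    }, -Inf, th1, rel.tol = 1e-9)$value
  }
  target <- r * sqrt(p1 * (1 - p1) * p2 * (1 - p2)) + p1 * p2
  stats::uniroot(function(rho) p11(rho) - target,
                 lower = 1e-6, upper = 0.9999, tol = 1e-8)$root
}

#' Simulate a dosage matrix
#'
#' Hardy-Weinberg genotypes: each variant is the sum of two independent
#' haplotype draws at its allele frequency. Within a declared LD block the
#' haplotype alleles are generated from equicorrelated latent Gaussians
#' whose correlation is solved numerically so the realised dosage r^2
#' matches the target.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals.
#' @return Numeric matrix n x m with variant ids as column names.
#' @export
simulate_genotypes <- function(config, n) {
  spec <- config$variant_spec
  m <- nrow(spec)
  ids <- spec$variant_id
  g <- matrix(NA_real_, n, m, dimnames = list(NULL, ids))
  in_block <- rep(FALSE, m)
  for (blk in config$ld_blocks) {
    j <- match(blk$variants, ids)
    if (anyNA(j)) stop("LD block names a variant absent from variant_spec")
    in_block[j] <- TRUE
    mafs <- spec$maf[j]
    rho <- latent_rho_for_allele_cor(sqrt(blk$r2), mafs[1], mafs[length(mafs)])
    for (hap in 1:2) {
      z0 <- stats::rnorm(n)
      lat <- sqrt(rho) * z0 +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(j)), n)
      alle <- sweep(lat, 2, stats::qnorm(mafs), `<`) * 1
      g[, j] <- if (hap == 1) alle else g[, j] + alle
    }
  }
  free <- which(!in_block)
  if (length(free) > 0) {
    g[, free] <- matrix(
      stats::rbinom(n * length(free), 2, rep(spec$maf[free], each = n)),
      n, length(free))
  }
  g
}

apoe_to_dosages <- function(genotype) {
  e4 <- c(e2e2 = 0, e2e3 = 0, e2e4 = 1, e3e3 = 0, e3e4 = 1, e4e4 = 2)
  e2 <- c(e2e2 = 2, e2e3 = 1, e2e4 = 1, e3e3 = 0, e3e4 = 0, e4e4 = 0)
  list(rs429358 = unname(e4[genotype]), rs7412 = unname(e2[genotype]))
}

# stratum AAO median: linear interpolation in bin index between the
# configured extreme-bin medians
aao_stratum_median <- function(config, group, bin) {
  med <- config$aao_medians[[group]]
  k <- config$aao_bins[[group]]
  if (k == 1) return(med[2])
  med[1] + (bin - 1) / (k - 1) * (med[2] - med[1])
}

rtruncnorm <- function(n, mean, sd, lo = 40, hi = 105) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a case-control cohort
#'
#' Disease status follows a logistic liability
#' `logit P(case) = alpha + sum log(or_i) (g_i - 2 maf_i) + log(apoe_or) +
#' log(prs_per_sd_or) * z`, where z is a standard-normal polygenic score
#' independent of the typed variants, and alpha is solved numerically so
#' the expected case count equals `n_cases`. Control ages are a mixture
#' placing the configured fraction at 55 or younger; case ages at onset
#' are drawn from the stratum AAO model (pooled APOE group x population
#' percentile bin of z), truncated to [40, 105]. Four standard-normal
#' ancestry components, sex, and concomitant-pathology flags are attached.
#'
#' @param config A [sim_config()].
#' @return An `adgwas_cohort` list: `pheno` (one row per individual) and
#'   `dosages` (matrix over the configured variants).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  spec <- config$variant_spec
  g <- simulate_genotypes(config, n)
  apoe <- sample(names(config$apoe_freqs), n, replace = TRUE,
                 prob = config$apoe_freqs)
  pooled <- pool_apoe(apoe)
  z <- stats::rnorm(n)
  eta <- as.numeric(g %*% log(spec$true_or)) -
    sum(2 * spec$maf * log(spec$true_or)) +
    log(config$apoe_ors[as.character(pooled)]) +
    log(config$prs_per_sd_or) * z
  target <- config$n_cases / n
  alpha <- tryCatch(
    stats::uniroot(function(a) mean(stats::plogis(a + eta)) - target,
                   lower = -50, upper = 50, tol = 1e-10)$root,
    error = function(e) stop("cannot solve the intercept: case rate incompatible with effects")
  )
  status <- stats::rbinom(n, 1, stats::plogis(alpha + eta))

  age <- rep(NA_real_, n)
  aao <- rep(NA_real_, n)
  ctrl <- which(status == 0)
  young <- stats::rbinom(length(ctrl), 1, config$n_young_controls / config$n_controls) == 1
  age[ctrl[young]] <- stats::runif(sum(young), 40, 55)
  age[ctrl[!young]] <- stats::runif(sum(!young), 56, 95)
  cases <- which(status == 1)
  if (length(cases) > 0) {
    grp <- as.character(pooled[cases])
    bins <- integer(length(cases))
    meds <- numeric(length(cases))
    for (gname in unique(grp)) {
      i <- grp == gname
      k <- config$aao_bins[[gname]]
      b <- assign_bins(z[cases][i], stats::qnorm(seq_len(k - 1) / k))
      bins[i] <- b
      meds[i] <- aao_stratum_median(config, gname, b)
    }
    aao[cases] <- rtruncnorm(length(cases), meds, config$aao_sd)
    age[cases] <- aao[cases]
  }
  path_any <- rep(NA_integer_, n)
  path_multi <- rep(NA_integer_, n)
  path_any[cases] <- stats::rbinom(length(cases), 1, config$pathology_rates[1])
  path_multi[cases] <- ifelse(
    path_any[cases] == 1,
    stats::rbinom(length(cases), 1,
                  min(1, config$pathology_rates[2] / config$pathology_rates[1])),
    0L)

  ds <- apoe_to_dosages(apoe)
  pheno <- data.frame(
    IID = sprintf("ind%06d", seq_len(n)),
    STATUS = status,
    AGE = age,
    AAO = aao,
    SEX = stats::rbinom(n, 1, 0.5),
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n),
    PC3 = stats::rnorm(n), PC4 = stats::rnorm(n),
    APOE_RS429358_DS = ds$rs429358,
    APOE_RS7412_DS = ds$rs7412,
    APOE = apoe,
    PRS_RAW = z,
    PATH_ANY = path_any,
    PATH_MULTI = path_multi,
    stringsAsFactors = FALSE
  )
  structure(list(pheno = pheno, dosages = g, config = config),
            class = "adgwas_cohort")
}

#' @export
print.adgwas_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases / %d controls, %d variants\n",
              sum(x$pheno$STATUS == 1), sum(x$pheno$STATUS == 0),
              ncol(x$dosages)))
  invisible(x)
}

#' Simulate per-study GWAS summary statistics
#'
#' Per variant, the estimated log odds ratio is drawn
#' `beta_hat ~ Normal(log(true_or), se)` with
#' `se = (2 maf (1 - maf) n_eff)^(-1/2)` and
#' `n_eff = 4 / (1/n_cases + 1/n_controls)`. Proxy-design studies emit
#' `beta/2` and `se/2` (the attenuated parental-history scale), so that
#' [rescale_proxy_effects()] restores the case-control scale; z and p are
#' unaffected by the scaling.
#'
#' @param config A [sim_config()] (supplies the variant spec).
#' @param study A [study_descriptor()].
#' @param seed Seed for this study's draws (default the config seed).
#' @return Summary-statistic data frame as from [read_sumstats()].
#' @export
simulate_sumstats <- function(config, study, seed = config$seed) {
  set.seed(seed)
  spec <- config$variant_spec
  n_eff <- 4 / (1 / study$n_cases + 1 / study$n_controls)
  se <- 1 / sqrt(2 * spec$maf * (1 - spec$maf) * n_eff)
  beta <- stats::rnorm(nrow(spec), log(spec$true_or), se)
  if (study$design == "proxy") {
    beta <- beta / study$proxy_rescale_factor
    se <- se / study$proxy_rescale_factor
  }
  data.frame(
    chrom = as.character(spec$chrom), pos = spec$pos,
    variant_id = spec$variant_id,
    effect_allele = spec$effect_allele, other_allele = spec$other_allele,
    eaf = spec$maf, beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n_effective = n_eff, imputation_r2 = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a stratified case series for age-at-onset recovery
#'
#' Builds, per requested pooled APOE group, `n_per_bin` cases for each of
#' the group's PRS bins (polygenic scores drawn standard-normal, bins by
#' population percentile, AAO from the stratum model) plus an anchor panel
#' of young controls for empirical boundary estimation. This is the
#' construction used to check that the stratification pipeline recovers
#' the configured extreme-bin AAO medians.
#'
#' @param config A [sim_config()].
#' @param groups Pooled APOE groups to include.
#' @param n_per_bin Cases per PRS bin per group.
#' @param n_anchor Young controls per group for boundary anchoring.
#' @return Data frame: STATUS, AGE, AAO, APOE_GROUP, PRS_RAW.
#' @export
simulate_aao_cases <- function(config, groups = c("e2e2/e2e3", "e4e4"),
                               n_per_bin = 10000L, n_anchor = 10000L) {
  set.seed(config$seed)
  rows <- lapply(groups, function(gname) {
    k <- config$aao_bins[[gname]]
    n_cases <- k * n_per_bin
    z <- stats::rnorm(n_cases)
    b <- assign_bins(z, stats::qnorm(seq_len(k - 1) / k))
    aao <- rtruncnorm(n_cases, aao_stratum_median(config, gname, b),
                      config$aao_sd)
    za <- stats::rnorm(n_anchor)
    data.frame(
      STATUS = c(rep(1L, n_cases), rep(0L, n_anchor)),
      AGE = c(aao, stats::runif(n_anchor, 40, 55)),
      AAO = c(aao, rep(NA_real_, n_anchor)),
      APOE_GROUP = gname,
      PRS_RAW = c(z, za),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
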