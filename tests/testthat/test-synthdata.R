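small_config <- function(seed = 1, ...) {
  sim_config(n_cases = 600, n_controls = 600, n_young_controls = 350,
             seed = seed, ...)
}

test_that("generator configs are validated", {
  expect_error(sim_config(), "seed")
  bad_spec <- default_variant_spec()
  bad_spec$maf[1] <- 0
  expect_error(sim_config(seed = 1, variant_spec = bad_spec), "frequencies")
  bad_spec$maf[1] <- 0.2; bad_spec$true_or[1] <- -1
  expect_error(sim_config(seed = 1, variant_spec = bad_spec), "positive")
  expect_error(sim_config(seed = 1, apoe_freqs = c(e3e3 = 1)), "six")
  expect_error(sim_config(seed = 1, n_controls = 100, n_young_controls = 200),
               "exceeds")
})

test_that("identical config and seed give byte-identical output", {
  c1 <- simulate_cohort(small_config(seed = 5))
  c2 <- simulate_cohort(small_config(seed = 5))
  expect_identical(c1$pheno, c2$pheno)
  expect_identical(c1$dosages, c2$dosages)
  s1 <- simulate_sumstats(small_config(seed = 5),
                          study_descriptor("a", "case_control", 1000, 1000))
  s2 <- simulate_sumstats(small_config(seed = 5),
                          study_descriptor("a", "case_control", 1000, 1000))
  expect_identical(s1, s2)
  c3 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(c1$pheno$STATUS, c3$pheno$STATUS))
})

test_that("simulated genotypes match their allele frequencies and HWE", {
  spec <- data.frame(variant_id = paste0("v", 1:20), chrom = "1",
                     pos = 1:20 * 1e5, effect_allele = "A",
                     other_allele = "G", maf = rep(c(0.5, 0.2), 10),
                     true_or = 1)
  cfg <- sim_config(seed = 7, variant_spec = spec)
  set.seed(7)
  g <- simulate_genotypes(cfg, 20000)
  freqs <- colMeans(g) / 2
  expect_true(all(abs(freqs - spec$maf) < 0.01))
  hwe_p <- apply(g, 2, function(v) {
    hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2))
  })
  expect_true(all(hwe_p > 1e-4))
})

test_that("LD blocks realise their target r2", {
  spec <- data.frame(variant_id = c("a", "b", "c"), chrom = "1",
                     pos = c(1e6, 1.01e6, 5e6), effect_allele = "A",
                     other_allele = "G", maf = c(0.3, 0.3, 0.2), true_or = 1)
  cfg <- sim_config(seed = 11, variant_spec = spec,
                    ld_blocks = list(list(variants = c("a", "b"), r2 = 0.8)))
  set.seed(11)
  g <- simulate_genotypes(cfg, 50000)
  expect_lt(abs(compute_ld(g[, "a"], g[, "b"])$r2 - 0.8), 0.05)
  expect_lt(compute_ld(g[, "a"], g[, "c"])$r2, 0.01)
})

test_that("a null generator yields no PRS association", {
  cfg <- sim_config(n_cases = 2000, n_controls = 2000, n_young_controls = 1200,
                    seed = 13, prs_per_sd_or = 1,
                    apoe_ors = c("e2e2/e2e3" = 1, "e3e3" = 1,
                                 "e2e4/e3e4" = 1, "e4e4" = 1))
  cfg$variant_spec$true_or <- 1
  cohort <- simulate_cohort(cfg)
  a <- prs_association(standardize_prs(cohort$pheno$PRS_RAW),
                       cohort$pheno$STATUS,
                       as.matrix(cohort$pheno[, paste0("PC", 1:4)]))
  expect_lt(abs(log(a$or)), 3 * a$se)
})

test_that("cohort structure matches the configured rates", {
  cfg <- sim_config(seed = 17)
  cohort <- simulate_cohort(cfg)
  ph <- cohort$pheno
  n <- nrow(ph)
  expect_equal(n, cfg$n_cases + cfg$n_controls)
  # solved intercept puts the realised case count near its expectation
  expect_lt(abs(sum(ph$STATUS) - cfg$n_cases), 4 * sqrt(n * 0.25))
  # fraction of controls at the anchor age
  young <- mean(ph$AGE[ph$STATUS == 0] <= 55)
  expect_lt(abs(young - cfg$n_young_controls / cfg$n_controls), 0.04)
  # cases carry onset ages in the truncation range, controls do not
  expect_true(all(is.na(ph$AAO[ph$STATUS == 0])))
  expect_true(all(ph$AAO[ph$STATUS == 1] >= 40 & ph$AAO[ph$STATUS == 1] <= 105))
  # APOE dosages decode back to the sampled genotypes
  expect_equal(call_apoe(ph$APOE_RS429358_DS, ph$APOE_RS7412_DS), ph$APOE)
  # pathology flags only among cases, near configured rates
  expect_true(all(is.na(ph$PATH_ANY[ph$STATUS == 0])))
  expect_lt(abs(mean(ph$PATH_ANY[ph$STATUS == 1]) - 0.84), 0.03)
  expect_lt(abs(mean(ph$PATH_MULTI[ph$STATUS == 1]) - 0.488), 0.03)
})

test_that("risk-variant effects are recovered from the simulated cohort", {
  set.seed(19)
  spec <- default_variant_spec()[1:3, ]
  spec$true_or <- c(1.3, 0.8, 1.0)
  betas <- sapply(1:25, function(i) {
    cfg <- sim_config(n_cases = 1500, n_controls = 1500,
                      n_young_controls = 900, seed = 1000 + i,
                      variant_spec = spec, prs_per_sd_or = 1,
                      apoe_ors = c("e2e2/e2e3" = 1, "e3e3" = 1,
                                   "e2e4/e3e4" = 1, "e4e4" = 1))
    cohort <- simulate_cohort(cfg)
    sapply(1:3, function(j) {
      coef(logistic_fit(cbind(1, cohort$dosages[, j]),
                        cohort$pheno$STATUS))[2]
    })
  })
  expect_true(all(abs(rowMeans(betas) - log(spec$true_or)) < 0.05))
})

test_that("simulated summary statistics have the stated sampling model", {
  cfg <- small_config(seed = 23)
  cc <- study_descriptor("cc", "case_control", 6331, 6055)
  ss <- simulate_sumstats(cfg, cc)
  n_eff <- 4 / (1 / 6331 + 1 / 6055)
  expect_equal(ss$se, 1 / sqrt(2 * cfg$variant_spec$maf *
                                 (1 - cfg$variant_spec$maf) * n_eff))
  # proxy study emits halved beta and se; rescaling restores z exactly
  proxy <- study_descriptor("px", "proxy", 42034, 506921)
  sp <- simulate_sumstats(cfg, proxy, seed = 29)
  rescaled <- rescale_proxy_effects(sp, proxy)
  expect_equal(rescaled$beta / rescaled$se, sp$beta / sp$se)
  cc_same <- study_descriptor("cc2", "case_control", 42034, 506921)
  direct <- simulate_sumstats(cfg, cc_same, seed = 29)
  expect_equal(rescaled$beta, direct$beta)
  expect_equal(rescaled$se, direct$se)
})

test_that("the stratified AAO generator hits its configured medians", {
  cfg <- sim_config(seed = 31)
  d <- simulate_aao_cases(cfg, groups = "e4e4", n_per_bin = 4000,
                          n_anchor = 4000)
  expect_equal(sum(d$STATUS == 1), 3 * 4000)
  st <- anchored_percentiles(d$PRS_RAW, d$STATUS, d$AGE, k = 3)
  top <- d$STATUS == 1 & st$bin == 3
  bottom <- d$STATUS == 1 & st$bin == 1
  expect_lt(abs(median(d$AAO[top]) - 73), 0.5)
  expect_lt(abs(median(d$AAO[bottom]) - 78.5), 0.5)
})

test_that("meta-analysis of three simulated studies recovers planted signals", {
  spec <- default_variant_spec()
  cfg <- sim_config(seed = 37, variant_spec = spec)
  studies <- list(
    study_descriptor("cc1", "case_control", 6331, 6055),
    study_descriptor("cc2", "case_control", 30344, 52427),
    study_descriptor("px", "proxy", 42034, 506921))
  tables <- lapply(seq_along(studies), function(i) {
    ss <- simulate_sumstats(cfg, studies[[i]], seed = 37 + i)
    if (studies[[i]]$design == "proxy") {
      ss <- rescale_proxy_effects(ss, studies[[i]])
    }
    ss
  })
  names(tables) <- c("cc1", "cc2", "px")
  meta <- meta_analyse(tables)
  # pooled estimates tighter than any single study
  expect_true(all(meta$se < sapply(meta$variant_id, function(id) {
    min(sapply(tables, function(t) t$se[match(id, t$variant_id)]))
  })))
  expect_equal(exp(meta$beta), spec$true_or, tolerance = 0.05)
})
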