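test_that("se_from_ci recovers log-scale standard errors", {
  expect_equal(se_from_ci(1.11, 1.06, 1.16), 0.0230, tolerance = 1e-3)
  expect_equal(se_from_ci(0.95, 0.93, 0.96), 0.0081, tolerance = 1e-2)
  expect_error(se_from_ci(2, 2, 2), "zero-width")
  expect_error(se_from_ci(1.1, 1.2, 1.05), "lower bound exceeds")
  expect_error(se_from_ci(-1, 0.5, 2), "positive")
})

test_that("ivw_meta satisfies its defining invariants", {
  m1 <- ivw_meta(0.13, 0.05)
  expect_equal(m1$beta_combined, 0.13)
  expect_equal(m1$se_combined, 0.05)
  m2 <- ivw_meta(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(m2$beta_combined, 0.2)
  expect_equal(m2$se_combined, sqrt(1 / 200))
  expect_equal(m2$z, m2$beta_combined / m2$se_combined)
  expect_equal(m2$p, 2 * pnorm(-abs(m2$z)))
  expect_error(ivw_meta(numeric(0), numeric(0)), "at least one")
  expect_error(ivw_meta(c(0.1, 0.2), c(0.1, 0)), "positive")
})

test_that("ivw_meta is order-invariant, associative, and se-monotone", {
  set.seed(19)
  for (r in 1:10) {
    k <- sample(3:6, 1)
    beta <- rnorm(k); se <- runif(k, 0.01, 0.5)
    perm <- sample(k)
    m <- ivw_meta(beta, se)
    expect_equal(ivw_meta(beta[perm], se[perm])$beta_combined, m$beta_combined)
    # combining a combined result with the remaining studies = combining all
    m12 <- ivw_meta(beta[1:2], se[1:2])
    m_split <- ivw_meta(c(m12$beta_combined, beta[-(1:2)]),
                        c(m12$se_combined, se[-(1:2)]))
    expect_equal(m_split$beta_combined, m$beta_combined, tolerance = 1e-12)
    expect_equal(m_split$se_combined, m$se_combined, tolerance = 1e-12)
    # precision only accumulates
    expect_lte(m$se_combined, min(se))
    expect_lte(m$se_combined, ivw_meta(beta[-1], se[-1])$se_combined)
  }
})

test_that("the overall column of the replicated loci is reproduced by IVW", {
  tab <- read_replicated_loci()
  rep_rows <- tab[tab$GROUP %in% c("novel", "known"), ]
  for (i in seq_len(nrow(rep_rows))) {
    m <- ivw_meta(
      c(log(rep_rows$OR_DISC[i]), log(rep_rows$OR_FU[i])),
      c(se_from_ci(rep_rows$OR_DISC[i], rep_rows$L95_DISC[i], rep_rows$U95_DISC[i]),
        se_from_ci(rep_rows$OR_FU[i], rep_rows$L95_FU[i], rep_rows$U95_FU[i])))
    expect_lt(abs(exp(m$beta_combined) - rep_rows$OR_OVERALL[i]), 0.015)
  }
})

test_that("meta_analyse combines matching variants across tables", {
  t1 <- data.frame(chrom = "1", pos = c(10L, 20L), variant_id = c("a", "b"),
                   effect_allele = "A", other_allele = "G",
                   beta = c(0.1, 0.2), se = c(0.1, 0.1))
  t2 <- data.frame(chrom = "1", pos = 10L, variant_id = "a",
                   effect_allele = "A", other_allele = "G",
                   beta = 0.3, se = 0.1)
  out <- meta_analyse(list(s1 = t1, s2 = t2))
  expect_equal(out$beta[out$variant_id == "a"], 0.2)
  expect_equal(out$n_studies, c(2, 1))
})

test_that("genomic lambda is definitional and calibrated under the null", {
  expect_equal(genomic_lambda(rep(0.5, 100)), 1)
  # chi-square statistics all at twice the null median -> lambda 2
  p2 <- pchisq(2 * qchisq(0.5, 1), 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(rep(p2, 10)), 2, tolerance = 1e-9)
  set.seed(23)
  expect_equal(genomic_lambda(runif(20000)), 1, tolerance = 0.02)
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("compute_ld handles complete LD, independence and degenerate input", {
  x <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  ld <- compute_ld(x, x)
  expect_equal(ld$r2, 1)
  expect_equal(ld$d_prime, 1)
  # perfect negative correlation is also complete LD
  ld2 <- compute_ld(x, 2 - x)
  expect_equal(ld2$r2, 1)
  expect_equal(ld2$d_prime, 1)
  set.seed(29)
  r2s <- replicate(20, {
    compute_ld(rbinom(10000, 2, 0.3), rbinom(10000, 2, 0.3))$r2
  })
  expect_gte(mean(r2s < 0.001), 0.95)
  expect_error(compute_ld(rep(1, 10), x), "zero dosage variance")
  expect_error(compute_ld(1:3, 1:4), "length")
})

test_that("d_prime reflects haplotype-level association beyond r2", {
  # AB/ab coupling haplotypes only: D' = 1 and r2 = 1
  hap <- rbinom(5000, 1, 0.5)
  ld <- compute_ld(2 * hap, 2 * hap)
  expect_equal(ld$d_prime, 1)
  # haplotypes where allele A only ever occurs on a B background:
  # D' = 1 while r2 stays well below 1
  set.seed(31)
  n <- 5000
  hapA1 <- rbinom(n, 1, 0.1); hapA2 <- rbinom(n, 1, 0.1)
  hapB1 <- ifelse(hapA1 == 1, 1, rbinom(n, 1, 0.3))
  hapB2 <- ifelse(hapA2 == 1, 1, rbinom(n, 1, 0.3))
  ld <- compute_ld(hapA1 + hapA2, hapB1 + hapB2)
  expect_gt(ld$d_prime, 0.9)
  expect_lt(ld$r2, 0.5)
})

test_that("greedy clumping follows p-order, window and r2 rules", {
  recs <- data.frame(
    variant_id = c("A", "B", "C"), chrom = "1",
    pos = c(1e6, 1e6 + 1e4, 2e6), p = c(1e-10, 1e-8, 1e-9))
  ld <- data.frame(id_a = "A", id_b = "B", r2 = 0.5)
  cl <- ld_clump(recs, ld)
  sent <- vapply(cl, `[[`, character(1), "sentinel")
  expect_setequal(sent, c("A", "C"))
  expect_setequal(cl[[which(sent == "A")]]$members, c("A", "B"))
  # independent variants give singletons
  cl0 <- ld_clump(recs, data.frame(id_a = character(0), id_b = character(0),
                                   r2 = numeric(0)))
  expect_equal(length(cl0), 3)
  # window rule dominates even at high r2
  recs2 <- data.frame(variant_id = c("X", "Y"), chrom = "2",
                      pos = c(1e6, 1.3e6), p = c(1e-12, 1e-9))
  cl2 <- ld_clump(recs2, data.frame(id_a = "X", id_b = "Y", r2 = 0.9),
                  window_bp = 250000)
  expect_equal(length(cl2), 2)
  expect_error(
    ld_clump(recs, data.frame(id_a = character(0), id_b = character(0),
                              r2 = numeric(0)), missing_ld = "error"),
    "missing LD")
})

test_that("clumps partition the input and sentinels are mutually independent", {
  set.seed(37)
  for (r in 1:5) {
    n <- 40
    recs <- data.frame(
      variant_id = paste0("v", 1:n),
      chrom = as.character(sample(1:3, n, replace = TRUE)),
      pos = sample(1:5e6, n), p = runif(n)^4)
    pairs <- t(combn(n, 2))
    ld <- data.frame(id_a = paste0("v", pairs[, 1]),
                     id_b = paste0("v", pairs[, 2]),
                     r2 = ifelse(runif(nrow(pairs)) < 0.1, runif(nrow(pairs)), 0))
    cl <- ld_clump(recs, ld, r2_threshold = 0.2, window_bp = 1e6)
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members, recs$variant_id)
    expect_equal(anyDuplicated(members), 0)
    lookup <- adgwas:::make_ld_lookup(ld)
    sent <- do.call(rbind, lapply(cl, function(x) {
      data.frame(id = x$sentinel, chrom = x$chrom, pos = x$pos)
    }))
    if (nrow(sent) > 1) {
      for (i in 1:(nrow(sent) - 1)) for (j in (i + 1):nrow(sent)) {
        same_chr <- sent$chrom[i] == sent$chrom[j]
        close <- same_chr && abs(sent$pos[i] - sent$pos[j]) <= 1e6
        if (close) expect_lt(lookup(sent$id[i], sent$id[j]), 0.2)
      }
    }
  }
})

test_that("forced sentinels override p-ordering inside their region", {
  recs <- data.frame(variant_id = c("lead", "forced"), chrom = "19",
                     pos = c(100, 200), p = c(1e-300, 1e-5))
  ld <- data.frame(id_a = "lead", id_b = "forced", r2 = 0.8)
  cl <- ld_clump(recs, ld, r2_threshold = 0.5, forced_sentinels = "forced")
  expect_true("forced" %in% vapply(cl, `[[`, character(1), "sentinel"))
})

test_that("follow-up selection applies threshold, proximity and exclusions", {
  recs <- data.frame(
    variant_id = c("in", "far", "weak", "excluded"),
    chrom = "1", pos = c(1150000, 1500000, 1100000, 1050000),
    p = c(5e-6, 5e-6, 2e-5, 1e-9))
  sentinels <- data.frame(chrom = "1", pos = 1e6)
  excl <- data.frame(chrom = "1", start = 1040000, end = 1060000)
  sel <- select_followup(recs, sentinels, excluded_regions = excl)
  expect_equal(sel, "in")
})
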