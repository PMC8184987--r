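# Fixed-effects inverse-variance-weighted meta-analysis, genomic-inflation
# diagnostics, LD estimation, greedy clumping and follow-up variant
# selection.

#' Back-calculate a log-scale standard error from an OR confidence interval
#'
#' Assumes the interval is symmetric on the log scale:
#' se = (log upper - log lower) / (2 * z).
#'
#' @param or_point Point odds ratio (positive).
#' @param lower,upper Confidence bounds (positive, lower < upper).
#' @param level Confidence level, default 0.95.
#' @return Standard error on the log-OR scale.
#' @examples
#' se_from_ci(1.11, 1.06, 1.16)  # ~0.0230
#' @export
se_from_ci <- function(or_point, lower, upper, level = 0.95) {
  if (any(c(or_point, lower, upper) <= 0)) stop("odds ratios must be positive")
  if (lower > upper) stop("lower bound exceeds upper bound")
  if (lower == upper) stop("zero-width interval: se is not recoverable")
  if (lower > or_point || upper < or_point) stop("point estimate outside the interval")
  (log(upper) - log(lower)) / (2 * stats::qnorm((1 + level) / 2))
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-study log odds ratios with weights 1/se^2. The combined
#' estimate is the precision-weighted mean, its standard error the inverse
#' square root of the total weight, and the p-value the two-sided normal
#' tail of z = beta/se. Cochran's Q heterogeneity is reported but never
#' used for filtering.
#'
#' @param beta Per-study log odds ratios.
#' @param se Per-study standard errors (all positive).
#' @param study Optional study labels.
#' @return An `ivw_meta` list: `beta_combined`, `se_combined`, `z`, `p`,
#'   `q`, `q_df`, `q_p`, `per_study`, `n_studies`.
#' @examples
#' ivw_meta(c(0.1, 0.3), c(0.1, 0.1))  # beta 0.2, se ~0.0707
#' @export
ivw_meta <- function(beta, se, study = NULL) {
  if (length(beta) == 0) stop("at least one study is required")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("all standard errors must be positive")
  if (is.null(study)) study <- paste0("study", seq_along(beta))
  w <- 1 / se^2
  beta_c <- sum(w * beta) / sum(w)
  se_c <- 1 / sqrt(sum(w))
  z <- beta_c / se_c
  q <- sum(w * (beta - beta_c)^2)
  q_df <- length(beta) - 1L
  structure(
    list(beta_combined = beta_c, se_combined = se_c, z = z,
         p = 2 * stats::pnorm(-abs(z)),
         q = q, q_df = q_df,
         q_p = if (q_df > 0) stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
         per_study = data.frame(study = study, beta = beta, se = se, weight = w),
         n_studies = length(beta)),
    class = "ivw_meta"
  )
}

#' @export
print.ivw_meta <- function(x, ...) {
  ci <- wald_or_ci(x$beta_combined, x$se_combined)
  cat(sprintf("IVW fixed-effects meta (%d studies): OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$n_studies, ci["or"], ci["lower"], ci["upper"], x$p))
  cat(sprintf("  Cochran Q = %.2f on %d df (p = %.3g)\n", x$q, x$q_df, x$q_p))
  invisible(x)
}

#' Meta-analyse a set of harmonised summary-statistics tables
#'
#' Variants are matched on `variant_id`; each variant present in at least
#' one study is combined with [ivw_meta()] over the studies carrying it.
#'
#' @param tables Named list of summary-statistic data frames (already
#'   harmonised to a common effect allele and, for proxy studies, already
#'   rescaled).
#' @return Data frame with one row per variant: variant_id, chrom, pos,
#'   effect_allele, other_allele, beta, se, z, p, n_studies.
#' @export
meta_analyse <- function(tables) {
  if (is.null(names(tables))) names(tables) <- paste0("study", seq_along(tables))
  all_ids <- unique(unlist(lapply(tables, `[[`, "variant_id")))
  rows <- lapply(all_ids, function(id) {
    bs <- lapply(names(tables), function(nm) {
      t <- tables[[nm]]
      i <- match(id, t$variant_id)
      if (is.na(i)) return(NULL)
      list(study = nm, beta = t$beta[i], se = t$se[i],
           chrom = t$chrom[i], pos = t$pos[i],
           ea = t$effect_allele[i], oa = t$other_allele[i])
    })
    bs <- Filter(Negate(is.null), bs)
    m <- ivw_meta(vapply(bs, `[[`, numeric(1), "beta"),
                  vapply(bs, `[[`, numeric(1), "se"),
                  vapply(bs, `[[`, character(1), "study"))
    data.frame(variant_id = id, chrom = bs[[1]]$chrom, pos = bs[[1]]$pos,
               effect_allele = bs[[1]]$ea, other_allele = bs[[1]]$oa,
               beta = m$beta_combined, se = m$se_combined, z = m$z, p = m$p,
               n_studies = m$n_studies, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor (lambda, median method)
#'
#' lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1). Values near 1
#' indicate a calibrated test statistic; inflation above ~1.05 suggests
#' confounding or polygenicity.
#'
#' @param p_values P-values in (0, 1].
#' @return The inflation factor.
#' @export
genomic_lambda <- function(p_values) {
  if (length(p_values) == 0) stop("p_values must be non-empty")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Pairwise linkage disequilibrium from dosages
#'
#' r^2 is the squared Pearson correlation of the dosage vectors. D' is
#' estimated from hard-called genotypes by EM haplotype-frequency
#' estimation, normalised by its theoretical bound.
#'
#' @param dosages_a,dosages_b Equal-length dosage vectors in [0, 2].
#' @return List with `r2` and `d_prime`, both in [0, 1].
#' @export
compute_ld <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) stop("dosage vectors differ in length")
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) stop("need at least two complete pairs")
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) stop("zero dosage variance: LD undefined")
  r2 <- stats::cor(a, b)^2

  ga <- hard_call(a); gb <- hard_call(b)
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  # EM for the AB haplotype frequency under random mating
  pAB <- pA * pB
  n <- length(ga)
  for (iter in 1:100) {
    # expected count of AB haplotypes; only double heterozygotes are ambiguous
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    num <- pAB * pab
    den <- num + pAb * paB
    frac <- if (den > 0) num / den else 0.5
    nAB <- sum((ga == 2) * gb + (gb == 2) * ga * (ga < 2)) +
      sum(ga == 1 & gb == 1) * frac
    new_pAB <- nAB / (2 * n)
    new_pAB <- min(max(new_pAB, max(0, pA + pB - 1)), min(pA, pB))
    if (abs(new_pAB - pAB) < 1e-12) { pAB <- new_pAB; break }
    pAB <- new_pAB
  }
  d <- pAB - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) min(1, abs(d) / dmax) else 0
  list(r2 = r2, d_prime = d_prime)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unassigned variant as a clump sentinel
#' and absorbs all unassigned variants on the same chromosome within the
#' physical window whose r^2 with the sentinel reaches the threshold. Every
#' variant ends up in exactly one clump. Ties at equal p are broken by
#' genomic coordinate (smaller wins); output is ordered by sentinel
#' position. Variants listed in `forced_sentinels` are promoted to
#' sentinels first regardless of p (used for the APOE region, where only
#' the epsilon-defining SNPs are retained as leads).
#'
#' @param records Data frame with variant_id, chrom, pos, p.
#' @param ld_r2 Function `(id_a, id_b) -> r2` or a long-format data frame
#'   (id_a, id_b, r2). Missing pairs are treated as r2 = 0 by default.
#' @param r2_threshold Clumping r^2 threshold (default 0.001).
#' @param window_bp Physical window, inclusive (default 250000).
#' @param forced_sentinels Optional variant ids promoted to sentinels.
#' @param missing_ld `"zero"` (default) or `"error"`.
#' @return List of clumps, each `list(sentinel, members, sentinel_p)`.
#' @export
ld_clump <- function(records, ld_r2, r2_threshold = 0.001,
                     window_bp = 250000L, forced_sentinels = character(0),
                     missing_ld = c("zero", "error")) {
  missing_ld <- match.arg(missing_ld)
  lookup <- make_ld_lookup(ld_r2, missing_ld)
  ord <- order(records$p, records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(records))
  clumps <- list()
  sentinel_queue <- c(
    which(records$variant_id %in% forced_sentinels),
    which(!records$variant_id %in% forced_sentinels)
  )
  for (i in sentinel_queue) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    in_window <- !assigned &
      records$chrom == records$chrom[i] &
      abs(records$pos - records$pos[i]) <= window_bp
    members <- which(in_window)
    if (length(members) > 0) {
      r2 <- vapply(members, function(j) {
        lookup(records$variant_id[i], records$variant_id[j])
      }, numeric(1))
      members <- members[r2 >= r2_threshold]
      assigned[members] <- TRUE
    }
    clumps[[length(clumps) + 1L]] <- list(
      sentinel = records$variant_id[i],
      members = records$variant_id[c(i, members)],
      sentinel_p = records$p[i],
      chrom = records$chrom[i],
      pos = records$pos[i]
    )
  }
  pos <- vapply(clumps, `[[`, numeric(1), "pos")
  chrom <- vapply(clumps, `[[`, character(1), "chrom")
  clumps[order(chrom, pos)]
}

make_ld_lookup <- function(ld_r2, missing_ld = "zero") {
  if (is.function(ld_r2)) return(ld_r2)
  if (is.data.frame(ld_r2)) {
    key <- c(paste(ld_r2$id_a, ld_r2$id_b), paste(ld_r2$id_b, ld_r2$id_a))
    val <- c(ld_r2$r2, ld_r2$r2)
    return(function(a, b) {
      if (a == b) return(1)
      i <- match(paste(a, b), key)
      if (is.na(i)) {
        if (missing_ld == "error") stop(sprintf("missing LD for pair %s / %s", a, b))
        return(0)
      }
      val[i]
    })
  }
  stop("ld_r2 must be a function or a long-format data frame (id_a, id_b, r2)")
}

#' Select variants for follow-up genotyping
#'
#' Returns every variant with p below the suggestive threshold lying within
#' the physical window of any sentinel, excluding variants inside regions
#' already established in earlier studies.
#'
#' @param records Data frame with variant_id, chrom, pos, p.
#' @param sentinels Data frame with chrom, pos of the sentinel variants.
#' @param p_threshold Suggestive-association threshold (default 1e-5).
#' @param window_bp Window around each sentinel (default 200000, inclusive).
#' @param excluded_regions Optional data frame (chrom, start, end) of
#'   regions to exclude.
#' @return Character vector of selected variant ids.
#' @export
select_followup <- function(records, sentinels, p_threshold = 1e-5,
                            window_bp = 200000L, excluded_regions = NULL) {
  near <- vapply(seq_len(nrow(records)), function(i) {
    any(sentinels$chrom == records$chrom[i] &
          abs(sentinels$pos - records$pos[i]) <= window_bp)
  }, logical(1))
  sel <- records$p < p_threshold & near
  if (!is.null(excluded_regions) && nrow(excluded_regions) > 0) {
    excluded <- vapply(seq_len(nrow(records)), function(i) {
      any(excluded_regions$chrom == records$chrom[i] &
            records$pos[i] >= excluded_regions$start &
            records$pos[i] <= excluded_regions$end)
    }, logical(1))
    sel <- sel & !excluded
  }
  records$variant_id[sel]
}
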