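# Reading, writing, harmonising and quality-filtering GWAS summary
# statistics, plus variant-level QC of dosage matrices. Coordinates are
# 1-based GRCh37 throughout. Files are tab-separated text with a header;
# gzip input is read transparently.

#' Default summary-statistics column dialect
#'
#' Maps canonical field names to the column names found in a file. Override
#' entries to read files with other headers. `beta` and `or` are
#' alternatives: when only `or` resolves, effect sizes are converted with
#' `beta = log(OR)`.
#'
#' @return Named character vector mapping canonical -> file column names.
#' @export
sumstats_dialect <- function() {
  c(chrom = "CHR", pos = "BP", variant_id = "SNP", effect_allele = "A1",
    other_allele = "A2", eaf = "FRQ_A1", beta = "BETA", or = "OR",
    se = "SE", p = "P", n_effective = "N", imputation_r2 = "INFO",
    ci_lower = "L95", ci_upper = "U95")
}

#' Read GWAS summary statistics
#'
#' Reads a delimited text table of per-variant association results into a
#' normalised data frame (one row per variant). OR columns are converted to
#' log odds ratios; when a standard error is absent but a 95% CI is present
#' the SE is back-calculated with [se_from_ci()]; when a p-value is absent
#' it is filled from the Wald z. Malformed rows (non-positive OR or SE,
#' missing alleles) are collected and attached as attribute `"bad_rows"`
#' rather than silently dropped.
#'
#' @param path Path to a tab-separated file (optionally gzipped).
#' @param dialect Column mapping, see [sumstats_dialect()].
#' @return Data frame with columns chrom, pos, variant_id, effect_allele,
#'   other_allele, eaf, beta, se, p, n_effective, imputation_r2.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  col <- function(field) {
    nm <- dialect[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NULL
  }
  required <- c("chrom", "pos", "variant_id", "effect_allele", "other_allele")
  for (f in required) {
    if (is.null(col(f))) stop(sprintf("missing required column '%s' (mapped to '%s')",
                                      f, dialect[[f]]))
  }
  beta <- col("beta"); or <- col("or")
  if (is.null(beta) && is.null(or)) stop("missing effect column: need BETA or OR")
  bad <- integer(0)
  if (is.null(beta)) {
    bad <- which(!is.na(or) & or <= 0)
    beta <- ifelse(or > 0, log(or), NA_real_)
  }
  se <- col("se")
  if (is.null(se)) {
    lo <- col("ci_lower"); hi <- col("ci_upper")
    if (is.null(lo) || is.null(hi)) stop("missing SE column and no CI columns to impute it from")
    se <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  }
  bad <- union(bad, which(!is.na(se) & se <= 0))
  p <- col("p")
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(
    chrom = as.character(col("chrom")),
    pos = as.integer(col("pos")),
    variant_id = as.character(col("variant_id")),
    effect_allele = toupper(as.character(col("effect_allele"))),
    other_allele = toupper(as.character(col("other_allele"))),
    eaf = if (is.null(col("eaf"))) NA_real_ else as.numeric(col("eaf")),
    beta = as.numeric(beta),
    se = as.numeric(se),
    p = as.numeric(p),
    n_effective = if (is.null(col("n_effective"))) NA_real_ else as.numeric(col("n_effective")),
    imputation_r2 = if (is.null(col("imputation_r2"))) NA_real_ else as.numeric(col("imputation_r2")),
    stringsAsFactors = FALSE
  )
  bad <- union(bad, which(out$effect_allele == out$other_allele))
  keep <- setdiff(seq_len(nrow(out)), bad)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "bad_rows") <- out[bad, , drop = FALSE]
  res
}

#' Write summary statistics
#'
#' Inverse of [read_sumstats()] under the default dialect; a read-write-read
#' cycle round-trips to identical records.
#'
#' @param records Data frame as returned by [read_sumstats()].
#' @param path Output path.
#' @export
write_sumstats <- function(records, path) {
  out <- data.frame(
    CHR = records$chrom, BP = records$pos, SNP = records$variant_id,
    A1 = records$effect_allele, A2 = records$other_allele,
    FRQ_A1 = records$eaf, BETA = records$beta, SE = records$se,
    P = records$p, N = records$n_effective, INFO = records$imputation_r2
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Describe a contributing study
#'
#' @param name Study label.
#' @param design `"case_control"` or `"proxy"` (parental-history phenotype).
#' @param n_cases,n_controls Sample sizes.
#' @param proxy_rescale_factor Multiplier applied by
#'   [rescale_proxy_effects()] to bring proxy effects onto the direct
#'   case-control scale; the default 2 reflects that each parent transmits
#'   half the genome.
#' @return A `study_descriptor` list.
#' @export
study_descriptor <- function(name, design = c("case_control", "proxy"),
                             n_cases, n_controls, proxy_rescale_factor = 2) {
  design <- match.arg(design)
  if (proxy_rescale_factor <= 0) stop("proxy_rescale_factor must be positive")
  structure(list(name = name, design = design, n_cases = n_cases,
                 n_controls = n_controls,
                 proxy_rescale_factor = proxy_rescale_factor),
            class = "study_descriptor")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  a1 %in% names(COMPLEMENT) & COMPLEMENT[a1] == a2
}

#' Harmonise effect alleles against a reference panel
#'
#' Aligns each record's effect allele to the reference record at the same
#' chrom:pos. A flipped record has its beta negated and eaf complemented.
#' Strand-ambiguous palindromic variants (A/T, C/G) with eaf in [0.4, 0.6]
#' are dropped, as are variants whose alleles cannot be reconciled even
#' after strand complementation; dropped variants are reported in the
#' `"dropped"` attribute with a reason.
#'
#' @param records,reference Summary-statistic data frames keyed by chrom:pos.
#' @param ambiguous_eaf_window Frequency window within which palindromic
#'   variants are considered unresolvable (default `c(0.4, 0.6)`).
#' @return Harmonised subset of `records` with attribute `"dropped"`.
#' @export
harmonize_alleles <- function(records, reference,
                              ambiguous_eaf_window = c(0.4, 0.6)) {
  key <- paste(records$chrom, records$pos, sep = ":")
  rkey <- paste(reference$chrom, reference$pos, sep = ":")
  idx <- match(key, rkey)
  drop_reason <- rep(NA_character_, nrow(records))
  out <- records
  for (i in seq_len(nrow(records))) {
    j <- idx[i]
    if (is.na(j)) { drop_reason[i] <- "not_in_reference"; next }
    a1 <- records$effect_allele[i]; a2 <- records$other_allele[i]
    r1 <- reference$effect_allele[j]; r2 <- reference$other_allele[j]
    snv <- all(c(a1, a2, r1, r2) %in% names(COMPLEMENT))
    if (snv && is_palindromic(a1, a2)) {
      eaf <- records$eaf[i]
      if (!is.na(eaf) && eaf >= ambiguous_eaf_window[1] &&
          eaf <= ambiguous_eaf_window[2]) {
        drop_reason[i] <- "ambiguous_palindrome"; next
      }
    }
    if (a1 == r1 && a2 == r2) next                     # already aligned
    if (a1 == r2 && a2 == r1) {                        # flipped
      out$effect_allele[i] <- r1; out$other_allele[i] <- r2
      out$beta[i] <- -out$beta[i]
      out$eaf[i] <- 1 - out$eaf[i]
      next
    }
    if (snv) {                                         # try strand complement
      c1 <- unname(COMPLEMENT[a1]); c2 <- unname(COMPLEMENT[a2])
      if (c1 == r1 && c2 == r2) {
        out$effect_allele[i] <- r1; out$other_allele[i] <- r2
        next
      }
      if (c1 == r2 && c2 == r1) {
        out$effect_allele[i] <- r1; out$other_allele[i] <- r2
        out$beta[i] <- -out$beta[i]
        out$eaf[i] <- 1 - out$eaf[i]
        next
      }
    }
    drop_reason[i] <- "irreconcilable_alleles"
  }
  keep <- is.na(drop_reason)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- data.frame(
    variant_id = records$variant_id[!keep],
    reason = drop_reason[!keep], stringsAsFactors = FALSE)
  res
}

#' Rescale by-proxy effect estimates to the case-control scale
#'
#' Parental-history (by-proxy) GWAS effects are attenuated relative to a
#' direct case-control design; this multiplies beta and se by the study's
#' rescale factor, leaving z = beta/se (and hence p) unchanged. Records are
#' tagged so a second application is rejected.
#'
#' @param records Summary-statistic data frame.
#' @param descriptor A [study_descriptor()] with `design = "proxy"`.
#' @return Rescaled records with attribute `"proxy_rescaled" = TRUE`.
#' @export
rescale_proxy_effects <- function(records, descriptor) {
  if (!inherits(descriptor, "study_descriptor")) stop("descriptor must be a study_descriptor")
  if (descriptor$design != "proxy") {
    stop("rescale_proxy_effects applies only to proxy-design studies")
  }
  if (isTRUE(attr(records, "proxy_rescaled"))) {
    stop("records are already rescaled to the case-control scale")
  }
  f <- descriptor$proxy_rescale_factor
  records$beta <- records$beta * f
  records$se <- records$se * f
  attr(records, "proxy_rescaled") <- TRUE
  records
}

#' Default variant-QC thresholds
#'
#' @param call_rate Minimum per-variant call rate (default 0.95).
#' @param maf Minimum minor allele frequency (default 0.01).
#' @param hwe_p Hardy-Weinberg exact-test floor in controls (default 1e-4).
#' @param diff_missing_p Floor for the two-sided Fisher test of differential
#'   missingness between cases and controls (default 1e-6).
#' @param imputation_r2 Minimum imputation quality when available
#'   (default 0.30).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.95, maf = 0.01, hwe_p = 1e-4,
                          diff_missing_p = 1e-6, imputation_r2 = 0.30) {
  list(call_rate = call_rate, maf = maf, hwe_p = hwe_p,
       diff_missing_p = diff_missing_p, imputation_r2 = imputation_r2)
}

# round dosages to hard genotype calls; intermediate dosages are treated as
# missing (the HWE exact test needs genotype counts)
hard_call <- function(dosage, margin = 0.1) {
  g <- round(dosage)
  g[abs(dosage - g) > margin] <- NA
  g
}

#' Variant-level quality control of a dosage matrix
#'
#' Applies, independently per variant: call rate, minor allele frequency,
#' exact Hardy-Weinberg equilibrium in controls (on hard-called genotypes),
#' differential missingness between cases and controls (Fisher exact test),
#' and optionally an imputation-quality floor. A variant may fail several
#' rules; the report lists each failure set.
#'
#' @param dosages Numeric matrix, individuals x variants, entries in [0, 2]
#'   or NA; column names identify variants.
#' @param status 0/1 case indicator per individual.
#' @param thresholds See [qc_thresholds()].
#' @param imputation_r2 Optional per-variant imputation quality vector.
#' @return A `qc_report`: `n_input`, `n_pass`, `pass` (variant ids),
#'   `failures` (named list of variant-id vectors per rule).
#' @export
variant_qc <- function(dosages, status, thresholds = qc_thresholds(),
                       imputation_r2 = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("var", seq_len(ncol(dosages)))
  }
  m <- ncol(dosages)
  ids <- colnames(dosages)
  is_case <- status == 1
  failures <- list(call_rate = character(0), maf = character(0),
                   hwe = character(0), diff_missing = character(0),
                   imputation = character(0))
  for (j in seq_len(m)) {
    d <- dosages[, j]
    obs <- !is.na(d)
    cr <- mean(obs)
    if (cr <= thresholds$call_rate) failures$call_rate <- c(failures$call_rate, ids[j])
    if (any(obs)) {
      af <- mean(d[obs]) / 2
      if (min(af, 1 - af) <= thresholds$maf) failures$maf <- c(failures$maf, ids[j])
    } else {
      failures$maf <- c(failures$maf, ids[j])
    }
    g <- hard_call(d[!is_case])
    g <- g[!is.na(g)]
    if (length(g) > 0) {
      p_hwe <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
      if (p_hwe < thresholds$hwe_p) failures$hwe <- c(failures$hwe, ids[j])
    }
    miss_case <- sum(!obs & is_case); n_case <- sum(is_case)
    miss_ctrl <- sum(!obs & !is_case); n_ctrl <- sum(!is_case)
    tab <- matrix(c(miss_case, n_case - miss_case,
                    miss_ctrl, n_ctrl - miss_ctrl), nrow = 2)
    p_dm <- stats::fisher.test(tab)$p.value
    if (p_dm < thresholds$diff_missing_p) {
      failures$diff_missing <- c(failures$diff_missing, ids[j])
    }
    if (!is.null(imputation_r2) && !is.na(imputation_r2[j]) &&
        imputation_r2[j] < thresholds$imputation_r2) {
      failures$imputation <- c(failures$imputation, ids[j])
    }
  }
  failed <- unique(unlist(failures))
  structure(
    list(n_input = m, n_pass = m - length(failed),
         pass = setdiff(ids, failed), failures = failures),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Variant QC: %d of %d variants pass\n", x$n_pass, x$n_input))
  for (rule in names(x$failures)) {
    if (length(x$failures[[rule]]) > 0) {
      cat(sprintf("  %-13s %d failed\n", rule, length(x$failures[[rule]])))
    }
  }
  invisible(x)
}
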