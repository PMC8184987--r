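# Weighted polygenic risk scores: scoring, standardisation, association
# with disease overall and in subgroups, and the pruning-and-thresholding
# sensitivity sweep.

#' Read a PRS weight table
#'
#' Tab-separated file with columns SNP, A1 (effect allele), WEIGHT (log-OR
#' scale) and SOURCE.
#'
#' @param path File path. The default is the packaged synthetic 39-variant
#'   table (see [default_prs_weights()]).
#' @return Data frame with variant_id, effect_allele, weight, source.
#' @export
read_prs_weights <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "WEIGHT")
  if (!all(need %in% names(raw))) {
    stop("weight table must have columns SNP, A1, WEIGHT (and optionally SOURCE)")
  }
  out <- data.frame(
    variant_id = as.character(raw$SNP),
    effect_allele = toupper(as.character(raw$A1)),
    weight = as.numeric(raw$WEIGHT),
    source = if ("SOURCE" %in% names(raw)) as.character(raw$SOURCE) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$variant_id)) stop("duplicate variant ids in weight table")
  out
}

#' Packaged synthetic 39-variant weight table
#'
#' A synthetic stand-in for the canonical 39-variant external weight table
#' (genome-wide significant AD loci excluding APOE, weighted by effect
#' sizes from earlier independent studies). The variant ids, alleles and
#' weights here are plausible but synthetic; they exercise the scoring
#' machinery and are not the published weights.
#'
#' @return Data frame as from [read_prs_weights()].
#' @export
default_prs_weights <- function() {
  read_prs_weights(system.file("extdata", "prs_weights_synthetic.tsv",
                               package = "adgwas", mustWork = TRUE))
}

#' Compute raw polygenic risk scores
#'
#' score_j = sum_i weight_i * dosage_ij, after orienting each stored dosage
#' to the weight table's effect allele (dosage -> 2 - dosage when the
#' matrix stores the other allele). A missing dosage is imputed as twice
#' the in-sample effect-allele frequency; the count of imputed entries is
#' attached as attribute `"n_imputed"`.
#'
#' @param dosages Numeric matrix, individuals x variants, with variant ids
#'   as column names.
#' @param weights Weight table from [read_prs_weights()].
#' @param stored_allele Optional named character vector giving the allele
#'   the matrix counts for each variant; variants whose stored allele is
#'   not the effect allele are flipped.
#' @return Numeric vector of raw scores.
#' @export
compute_prs <- function(dosages, weights, stored_allele = NULL) {
  dosages <- as.matrix(dosages)
  missing_ids <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing_ids) > 0) {
    stop("weight-table variants absent from dosage matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  g <- dosages[, weights$variant_id, drop = FALSE]
  if (!is.null(stored_allele)) {
    flip <- stored_allele[weights$variant_id] != weights$effect_allele
    flip[is.na(flip)] <- FALSE
    if (any(flip)) g[, flip] <- 2 - g[, flip]
  }
  n_imputed <- 0L
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) {
      eaf <- mean(g[!miss, j]) / 2
      g[miss, j] <- 2 * eaf
      n_imputed <- n_imputed + sum(miss)
    }
  }
  scores <- as.numeric(g %*% weights$weight)
  attr(scores, "n_imputed") <- n_imputed
  scores
}

#' Standardise raw PRS values
#'
#' z = (raw - mean) / sd with the mean and SD (n-1 denominator) computed on
#' a reference subset and applied to everyone. The default reference is all
#' analysed individuals; a controls-only reference is selected by passing
#' the control indices.
#'
#' @param raw Raw score vector.
#' @param reference Integer/logical index of the reference subset
#'   (default: everyone).
#' @return A `prs_scores` list: `raw`, `z`, `reference_mean`,
#'   `reference_sd`.
#' @export
standardize_prs <- function(raw, reference = seq_along(raw)) {
  ref <- raw[reference]
  if (length(ref) < 2) stop("reference subset must have at least two individuals")
  m <- mean(ref); s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stop("reference subset has zero score variance")
  structure(
    list(raw = raw, z = (raw - m) / s, reference_mean = m, reference_sd = s),
    class = "prs_scores"
  )
}

#' @export
print.prs_scores <- function(x, ...) {
  cat(sprintf("PRS for %d individuals: reference mean %.4g, SD %.4g\n",
              length(x$raw), x$reference_mean, x$reference_sd))
  invisible(x)
}

#' Association of the PRS with disease
#'
#' Logistic regression of case status on the standardised score, adjusted
#' for ancestry covariates; the score coefficient is reported as an odds
#' ratio per 1-SD increase with a Wald confidence interval.
#'
#' @param scores A `prs_scores` object (or numeric z-score vector).
#' @param status 0/1 case indicator.
#' @param covariates Matrix of ancestry components (typically n x 4).
#' @param level Confidence level, default 0.95.
#' @return List: `or`, `lower`, `upper`, `beta`, `se`, `p`, `fit`.
#' @export
prs_association <- function(scores, status, covariates = NULL, level = 0.95) {
  z <- if (inherits(scores, "prs_scores")) scores$z else as.numeric(scores)
  if (stats::var(z) == 0) stop("scores are constant: association undefined")
  design <- cbind(`(Intercept)` = 1, prs = z)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("PC", seq_len(ncol(covariates)))
    }
    design <- cbind(design, covariates)
  }
  fit <- logistic_fit(design, status)
  ci <- wald_or_ci(fit$coefficients["prs"], fit$standard_errors["prs"], level)
  zstat <- fit$coefficients["prs"] / fit$standard_errors["prs"]
  list(or = unname(ci["or"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]),
       beta = unname(fit$coefficients["prs"]),
       se = unname(fit$standard_errors["prs"]),
       p = unname(2 * stats::pnorm(-abs(zstat))),
       fit = fit)
}

#' Subgroup PRS associations
#'
#' Fits [prs_association()] separately per case subgroup (sex, age-at-onset
#' band, pathology stratum, ...). Controls are shared across case
#' subgroups: each fit uses the subgroup's cases together with all
#' controls, matching the design in which every patient stratum is
#' compared with the same control panel. Subgroups without both classes
#' are skipped with a diagnostic row.
#'
#' @param scores `prs_scores` or numeric z-scores for all individuals.
#' @param status 0/1 case indicator.
#' @param covariates Ancestry covariate matrix.
#' @param subgroup Factor/character per individual; NA excludes an
#'   individual from every subgroup fit. For cases this is the case
#'   stratum; control labels are ignored (controls enter every fit).
#' @return Data frame with one row per subgroup: subgroup, n_cases,
#'   n_controls, or, lower, upper, p, skipped.
#' @export
subgroup_prs_analysis <- function(scores, status, covariates = NULL, subgroup) {
  z <- if (inherits(scores, "prs_scores")) scores$z else as.numeric(scores)
  levels_ <- unique(stats::na.omit(subgroup[status == 1]))
  rows <- lapply(levels_, function(g) {
    use <- (status == 0) | (status == 1 & !is.na(subgroup) & subgroup == g)
    n_ca <- sum(status[use] == 1); n_co <- sum(status[use] == 0)
    if (n_ca == 0 || n_co == 0) {
      return(data.frame(subgroup = g, n_cases = n_ca, n_controls = n_co,
                        or = NA_real_, lower = NA_real_, upper = NA_real_,
                        p = NA_real_, skipped = TRUE))
    }
    a <- prs_association(z[use], status[use],
                         if (is.null(covariates)) NULL else covariates[use, , drop = FALSE])
    data.frame(subgroup = g, n_cases = n_ca, n_controls = n_co,
               or = a$or, lower = a$lower, upper = a$upper, p = a$p,
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-at-onset bands used for subgroup analyses
#'
#' Early onset before 65, intermediate 65-85, late onset after 85.
#'
#' @param aao Age at onset in years.
#' @return Character vector in {"<65", "65-85", ">85"}.
#' @export
aao_band <- function(aao) {
  ifelse(is.na(aao), NA_character_,
         ifelse(aao < 65, "<65", ifelse(aao > 85, ">85", "65-85")))
}

#' Pruning-and-thresholding sweep
#'
#' For each p-value threshold: clump the summary statistics at strict
#' settings (default r^2 = 0.001, 1 Mb window), keep the independent
#' sentinel variants with p below the threshold, and use their betas as
#' weights. Tables are nested: a looser threshold's table contains every
#' variant of a stricter one.
#'
#' @param sumstats Summary-statistic data frame (variant_id, chrom, pos,
#'   effect_allele, beta, p).
#' @param ld_r2 LD provider as in [ld_clump()].
#' @param thresholds Increasing p-value thresholds.
#' @param clump_r2 Clumping threshold (default 0.001).
#' @param clump_window Clumping window in bp (default 1e6).
#' @return Named list mapping each threshold to a weight table
#'   (variant_id, effect_allele, weight, source = "pt_sweep").
#' @export
pt_sweep <- function(sumstats, ld_r2, thresholds,
                     clump_r2 = 0.001, clump_window = 1000000L) {
  clumps <- ld_clump(sumstats, ld_r2, r2_threshold = clump_r2,
                     window_bp = clump_window)
  sentinels <- vapply(clumps, `[[`, character(1), "sentinel")
  sp <- vapply(clumps, `[[`, numeric(1), "sentinel_p")
  out <- lapply(sort(thresholds), function(th) {
    sel <- sentinels[sp < th]
    i <- match(sel, sumstats$variant_id)
    tab <- data.frame(variant_id = sel,
                      effect_allele = sumstats$effect_allele[i],
                      weight = sumstats$beta[i],
                      source = rep("pt_sweep", length(sel)),
                      stringsAsFactors = FALSE)
    if (nrow(tab) == 0) warning(sprintf("no variants pass threshold %g", th))
    tab
  })
  names(out) <- format(sort(thresholds), scientific = TRUE, trim = TRUE)
  out
}
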