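# Survival-bias-corrected PRS percentile stratification, APOE genotype
# calling and pooling, risk-group contrasts, age-at-onset comparisons, and
# the case-only Cox model with a PRS x APOE interaction.

APOE_LEVELS <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
APOE_POOLED_LEVELS <- c("e2e2/e2e3", "e3e3", "e2e4/e3e4", "e4e4")

#' Call an APOE genotype from the two epsilon-defining SNP dosages
#'
#' The three common APOE haplotypes are defined by rs429358 and rs7412:
#' epsilon-4 carries the rs429358 C allele, epsilon-2 the rs7412 T allele,
#' and epsilon-3 neither. Dosages must be within 0.1 of an integer to be
#' hard-callable. The rs429358-C / rs7412-T double heterozygote is resolved
#' as e2e4 (the rare epsilon-1 haplotype is assumed absent).
#'
#' @param rs429358_dosage Dosage of the rs429358 C allele in [0, 2].
#' @param rs7412_dosage Dosage of the rs7412 T allele in [0, 2].
#' @return Character vector of genotype labels in
#'   {e2e2, e2e3, e2e4, e3e3, e3e4, e4e4}, NA where not callable.
#' @examples
#' call_apoe(2, 0)  # "e4e4"
#' call_apoe(1, 1)  # "e2e4"
#' @export
call_apoe <- function(rs429358_dosage, rs7412_dosage) {
  n4 <- hard_call(rs429358_dosage)
  n2 <- hard_call(rs7412_dosage)
  out <- rep(NA_character_, length(n4))
  bad <- !is.na(n4) & !is.na(n2) & (n4 + n2 > 2)
  if (any(bad)) stop("inconsistent APOE genotype: epsilon-2 + epsilon-4 allele count exceeds 2")
  ok <- !is.na(n4) & !is.na(n2)
  n3 <- 2 - n4[ok] - n2[ok]
  lab <- character(sum(ok))
  lab[n4[ok] == 2] <- "e4e4"
  lab[n4[ok] == 1 & n3 == 1] <- "e3e4"
  lab[n4[ok] == 1 & n2[ok] == 1] <- "e2e4"
  lab[n4[ok] == 0 & n2[ok] == 0] <- "e3e3"
  lab[n2[ok] == 1 & n3 == 1] <- "e2e3"
  lab[n2[ok] == 2] <- "e2e2"
  out[ok] <- lab
  out
}

#' Pool APOE genotypes into the four analysis groups
#'
#' e2e2 and e2e3 are pooled (protective), e3e3 is the neutral reference
#' pool, e2e4 and e3e4 are pooled as single-epsilon-4 carriers, and e4e4
#' stands alone.
#'
#' @param genotype Genotype labels from [call_apoe()].
#' @return Factor with levels e2e2/e2e3, e3e3, e2e4/e3e4, e4e4.
#' @export
pool_apoe <- function(genotype) {
  map <- c(e2e2 = "e2e2/e2e3", e2e3 = "e2e2/e2e3", e3e3 = "e3e3",
           e2e4 = "e2e4/e3e4", e3e4 = "e2e4/e3e4", e4e4 = "e4e4")
  factor(unname(map[genotype]), levels = APOE_POOLED_LEVELS)
}

#' Survival-bias-corrected percentile stratification
#'
#' Computes PRS percentile boundaries on the anchoring subset -- controls
#' young enough (age <= `anchor_max_age`) to be unaffected by
#' risk-dependent mortality and onset -- and assigns every individual,
#' anchor or not, by those same boundaries. Scores beyond the extreme
#' boundaries clamp to the extreme bins; values exactly on a cut-point go
#' to the lower bin.
#'
#' @param scores `prs_scores` object or numeric z-score vector.
#' @param status 0/1 case indicator.
#' @param age Age in years (age at examination for controls).
#' @param k Number of percentile bins (50 for 2-percentile bins).
#' @param anchor_max_age Anchor age ceiling, default 55.
#' @return A `prs_strata` list: `boundaries` (cut-points), `anchor_n`,
#'   `anchor_rule`, `bin` (1..k per individual), `k`.
#' @export
anchored_percentiles <- function(scores, status, age, k, anchor_max_age = 55) {
  z <- if (inherits(scores, "prs_scores")) scores$z else as.numeric(scores)
  anchor <- which(status == 0 & !is.na(age) & age <= anchor_max_age)
  if (length(anchor) == 0) stop("no anchoring controls aged <= anchor_max_age")
  if (length(anchor) < k) stop("anchor subset smaller than the number of bins")
  boundaries <- quantile_boundaries(z[anchor], k)
  structure(
    list(boundaries = boundaries,
         anchor_n = length(anchor),
         anchor_rule = sprintf("controls aged <= %g", anchor_max_age),
         bin = assign_bins(z, boundaries),
         k = k),
    class = "prs_strata"
  )
}

#' @export
print.prs_strata <- function(x, ...) {
  cat(sprintf("PRS strata: %d bins anchored on %d individuals (%s)\n",
              x$k, x$anchor_n, x$anchor_rule))
  invisible(x)
}

#' Combined APOE x PRS stratum assignment
#'
#' Within each pooled APOE group, individuals are split into the configured
#' number of PRS groups (canonically 7/25/15/3 for e2e2\\/e2e3, e3e3,
#' e2e4\\/e3e4 and e4e4) using boundaries anchored on young controls of
#' that group.
#'
#' @param scores `prs_scores` or z-score vector.
#' @param status 0/1 case indicator.
#' @param age Ages in years.
#' @param apoe_pooled Factor from [pool_apoe()].
#' @param bins_per_group Named integer vector of PRS group counts per
#'   pooled APOE group.
#' @param anchor_max_age Anchor age ceiling, default 55.
#' @return Data frame with apoe_group, prs_bin, combined_group per
#'   individual (NA rows where APOE is missing).
#' @export
combined_strata <- function(scores, status, age, apoe_pooled,
                            bins_per_group = c("e2e2/e2e3" = 7, "e3e3" = 25,
                                               "e2e4/e3e4" = 15, "e4e4" = 3),
                            anchor_max_age = 55) {
  z <- if (inherits(scores, "prs_scores")) scores$z else as.numeric(scores)
  n <- length(z)
  bin <- rep(NA_integer_, n)
  for (g in levels(apoe_pooled)) {
    idx <- which(!is.na(apoe_pooled) & apoe_pooled == g)
    if (length(idx) == 0) next
    st <- anchored_percentiles(z[idx], status[idx], age[idx],
                               k = bins_per_group[[g]],
                               anchor_max_age = anchor_max_age)
    bin[idx] <- st$bin
  }
  data.frame(
    apoe_group = as.character(apoe_pooled),
    prs_bin = bin,
    combined_group = ifelse(is.na(apoe_pooled), NA_character_,
                            paste0(as.character(apoe_pooled), ":", bin)),
    stringsAsFactors = FALSE
  )
}

#' Risk contrasts between strata
#'
#' One logistic fit per non-reference group: case status on a group
#' indicator (group vs reference members only) plus ancestry covariates.
#'
#' @param group Character/factor stratum label per individual.
#' @param status 0/1 case indicator.
#' @param covariates Ancestry covariate matrix.
#' @param reference Label of the reference stratum (e.g. the lowest-PRS
#'   group).
#' @param level Confidence level, default 0.95.
#' @return Data frame: group, reference, n_cases, n_controls, or, lower,
#'   upper, p, skipped.
#' @export
group_contrasts <- function(group, status, covariates = NULL,
                            reference, level = 0.95) {
  group <- as.character(group)
  if (!reference %in% group) stop("reference group is empty")
  ref_idx <- which(group == reference)
  if (length(unique(status[ref_idx])) < 2) {
    stop("reference group must contain both cases and controls")
  }
  others <- setdiff(sort(unique(stats::na.omit(group))), reference)
  rows <- lapply(others, function(g) {
    use <- which(group %in% c(g, reference))
    ind <- as.numeric(group[use] == g)
    n_ca <- sum(status[use][ind == 1] == 1)
    n_co <- sum(status[use][ind == 1] == 0)
    if (length(unique(status[use])) < 2 || length(unique(ind)) < 2) {
      return(data.frame(group = g, reference = reference, n_cases = n_ca,
                        n_controls = n_co, or = NA_real_, lower = NA_real_,
                        upper = NA_real_, p = NA_real_, skipped = TRUE))
    }
    design <- cbind(`(Intercept)` = 1, group = ind)
    if (!is.null(covariates)) design <- cbind(design, as.matrix(covariates)[use, , drop = FALSE])
    fit <- logistic_fit(design, status[use])
    ci <- wald_or_ci(fit$coefficients["group"], fit$standard_errors["group"], level)
    zst <- fit$coefficients["group"] / fit$standard_errors["group"]
    data.frame(group = g, reference = reference, n_cases = n_ca,
               n_controls = n_co, or = unname(ci["or"]),
               lower = unname(ci["lower"]), upper = unname(ci["upper"]),
               p = unname(2 * stats::pnorm(-abs(zst))), skipped = !fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare age at onset between two case groups
#'
#' Medians, their difference (a - b), and a two-sided Wilcoxon rank-sum
#' p-value.
#'
#' @param aao_a,aao_b Ages at onset (years) of the two case groups.
#' @return List: `median_a`, `median_b`, `difference`, `test`
#'   (an `adgwas_ranktest`).
#' @export
aao_compare <- function(aao_a, aao_b) {
  if (length(aao_a) == 0 || length(aao_b) == 0) stop("both groups must be non-empty")
  test <- wilcoxon_rank_sum(aao_a, aao_b)
  list(median_a = stats::median(aao_a), median_b = stats::median(aao_b),
       difference = stats::median(aao_a) - stats::median(aao_b),
       test = test)
}

#' Case-only Cox model of age at onset with a PRS x APOE interaction
#'
#' All individuals are cases (event = 1). Terms: centred PRS main effect,
#' pooled-APOE indicators (reference e2e2/e2e3), PRS x APOE interactions,
#' and ancestry covariates. Because the PRS is centred, the APOE main
#' effects are at-mean-PRS effects.
#'
#' @param aao Ages at onset in years.
#' @param prs_z Standardised PRS.
#' @param apoe_pooled Factor from [pool_apoe()].
#' @param covariates Ancestry covariate matrix.
#' @return List: `fit` (an `adgwas_fit`), `interaction_terms`,
#'   `interaction_p` (Wald p per interaction term).
#' @export
cox_prs_apoe <- function(aao, prs_z, apoe_pooled, covariates = NULL) {
  apoe_pooled <- droplevels(factor(apoe_pooled, levels = APOE_POOLED_LEVELS))
  prs_c <- prs_z - mean(prs_z)
  x <- cbind(prs = prs_c)
  if (nlevels(apoe_pooled) > 1) {
    mm <- stats::model.matrix(~apoe_pooled)[, -1, drop = FALSE]
    colnames(mm) <- paste0("apoe:", levels(apoe_pooled)[-1])
    inter <- mm * prs_c
    colnames(inter) <- paste0("prs:x:", levels(apoe_pooled)[-1])
    x <- cbind(x, mm, inter)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("PC", seq_len(ncol(covariates)))
    }
    x <- cbind(x, covariates)
  }
  fit <- cox_ph_fit(aao, rep(1, length(aao)), x)
  iterms <- grep("^prs:x:", names(fit$coefficients), value = TRUE)
  zst <- fit$coefficients[iterms] / fit$standard_errors[iterms]
  list(fit = fit, interaction_terms = iterms,
       interaction_p = 2 * stats::pnorm(-abs(zst)))
}

#' Onset-probability curves by stratum
#'
#' For each stratum, exports both the Kaplan-Meier estimate and the Breslow
#' baseline-hazard estimate from a stratified Cox null model, as the
#' cumulative probability that a case has developed disease by each age.
#'
#' @param aao Ages at onset (all cases, event = 1).
#' @param group Stratum label per case.
#' @param ages Age grid (default the observed onset ages).
#' @return Data frame: age, group, p_onset_km, p_onset_breslow.
#' @export
onset_curves <- function(aao, group, ages = sort(unique(aao))) {
  group <- as.character(group)
  rows <- lapply(sort(unique(group)), function(g) {
    t_g <- aao[group == g]
    km <- survival::survfit(survival::Surv(t_g, rep(1, length(t_g))) ~ 1)
    s_km <- stats::approx(km$time, km$surv, xout = ages, method = "constant",
                          yleft = 1, rule = 2)$y
    # Breslow: case-only null model, cumulative hazard -> survival
    cf <- survival::coxph(survival::Surv(t_g, rep(1, length(t_g))) ~ 1,
                          ties = "breslow")
    bh <- survival::basehaz(cf, centered = TRUE)
    h <- stats::approx(bh$time, bh$hazard, xout = ages, method = "constant",
                       yleft = 0, rule = 2)$y
    data.frame(age = ages, group = g, p_onset_km = 1 - s_km,
               p_onset_breslow = 1 - exp(-h))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
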