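# Core estimators and tests shared by every pipeline stage. These are thin,
# strict wrappers around the standard R fitting machinery (glm, coxph,
# wilcox.test, quantile) that normalise their output into a single result
# class and turn silent pathologies (separation, singular designs, monotone
# partial likelihoods) into explicit flags or errors.

#' Construct a fit result
#'
#' Container for a fitted regression model on the log-odds or log-hazard
#' scale. Standard errors are always the square roots of the covariance
#' diagonal.
#'
#' @param coefficients Named numeric vector of coefficients.
#' @param covariance Variance-covariance matrix of the coefficients.
#' @param log_likelihood Maximised log-likelihood (partial likelihood for Cox).
#' @param converged Logical convergence flag.
#' @param n_iterations Number of iterations used by the optimiser.
#' @param model Character label, e.g. `"logistic"` or `"cox"`.
#' @return An object of class `adgwas_fit`.
#' @keywords internal
new_fit_result <- function(coefficients, covariance, log_likelihood,
                           converged, n_iterations, model = "logistic") {
  se <- sqrt(pmax(diag(as.matrix(covariance)), 0))
  names(se) <- names(coefficients)
  structure(
    list(
      coefficients = coefficients,
      standard_errors = se,
      covariance = covariance,
      log_likelihood = log_likelihood,
      converged = converged,
      n_iterations = n_iterations,
      model = model
    ),
    class = "adgwas_fit"
  )
}

#' @export
print.adgwas_fit <- function(x, ...) {
  cat(sprintf("<%s fit>  converged: %s  iterations: %d\n",
              x$model, x$converged, x$n_iterations))
  print(summary(x), ...)
  invisible(x)
}

#' @export
coef.adgwas_fit <- function(object, ...) object$coefficients

#' @export
vcov.adgwas_fit <- function(object, ...) object$covariance

#' Summarise a fit as a coefficient table
#'
#' @param object An `adgwas_fit`.
#' @param ... Unused.
#' @return Data frame with estimate, SE, z and two-sided p per term.
#' @export
summary.adgwas_fit <- function(object, ...) {
  z <- object$coefficients / object$standard_errors
  data.frame(
    term = names(object$coefficients),
    estimate = unname(object$coefficients),
    se = unname(object$standard_errors),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL
  )
}

#' @export
confint.adgwas_fit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm((1 + level) / 2)
  est <- object$coefficients
  if (!missing(parm)) est <- est[parm]
  se <- object$standard_errors[names(est)]
  cbind(lower = est - zq * se, upper = est + zq * se)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression for a binary outcome on a design
#' matrix supplied by the caller (including the intercept column). Wald
#' standard errors come from the observed information at the optimum.
#' Perfect or quasi-perfect separation is reported through
#' `converged = FALSE` rather than returned as a silently diverging fit.
#'
#' @param design Numeric matrix, n rows by p columns, including an intercept
#'   column; must have full column rank.
#' @param outcome Binary 0/1 vector of length n with both classes present.
#' @param tol Convergence tolerance on the score (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 25).
#' @return An [`adgwas_fit`][new_fit_result] on the log-odds scale.
#' @examples
#' x <- cbind(1, c(rep(1, 15), rep(0, 15)))
#' y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
#' coef(logistic_fit(x, y))[2]  # log OR of the 2x2 table = log(4)
#' @export
logistic_fit <- function(design, outcome, tol = 1e-8, max_iter = 25) {
  design <- as.matrix(design)
  outcome <- as.numeric(outcome)
  n <- nrow(design)
  p <- ncol(design)
  if (length(outcome) != n) stop("design and outcome lengths differ")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (n < p) stop("more parameters than observations")
  if (length(unique(outcome)) < 2) stop("outcome has a single class")
  if (qr(design)$rank < p) {
    stop("singular design: columns are linearly dependent (constant non-intercept column?)")
  }
  if (is.null(colnames(design))) {
    colnames(design) <- c("(Intercept)", paste0("x", seq_len(p - 1L)))[seq_len(p)]
  }

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(design, outcome, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(design * w, design)
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p, dimnames = list(colnames(design), colnames(design)))
  })
  dimnames(cov) <- list(colnames(design), colnames(design))
  loglik <- sum(outcome * log(pmax(mu, .Machine$double.xmin)) +
                  (1 - outcome) * log(pmax(1 - mu, .Machine$double.xmin)))
  # separation manifests as boundary fitted values; flag as non-converged
  separated <- sep_warn || any(mu < 1e-10) || any(mu > 1 - 1e-10)
  new_fit_result(beta, cov, loglik,
                 converged = fit$converged && !separated && all(is.finite(beta)),
                 n_iterations = fit$iter, model = "logistic")
}

#' Odds ratio with a Wald confidence interval
#'
#' @param beta Log odds ratio.
#' @param se Standard error of `beta` (must be non-negative).
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric vector `(or, lower, upper)`.
#' @examples
#' wald_or_ci(0.0677, 0.0120)  # ~1.07 [1.04, 1.10]
#' @export
wald_or_ci <- function(beta, se, level = 0.95) {
  beta <- unname(beta); se <- unname(se)
  if (se < 0) stop("se must be non-negative")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  zq <- stats::qnorm((1 + level) / 2)
  c(or = exp(beta), lower = exp(beta - zq * se), upper = exp(beta + zq * se))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test comparing two samples.
#' By default an exact p-value is computed for small tie-free samples
#' (n1 + n2 <= 12) and the normal approximation with tie and continuity
#' correction is used otherwise; the mode actually used is recorded.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return An `adgwas_ranktest` list: `statistic` (rank-sum of `x`),
#'   `p_value`, `medians`, `n1`, `n2`, `mode`, `degenerate`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  degenerate <- length(unique(c(x, y))) == 1L
  use_exact <- switch(mode,
    auto = (n1 + n2 <= 12) && !ties,
    exact = TRUE,
    normal = FALSE
  )
  if (use_exact && ties) {
    use_exact <- FALSE  # exact distribution undefined under ties
  }
  rk <- rank(c(x, y))
  statistic <- sum(rk[seq_len(n1)])
  if (degenerate) {
    p <- 1
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                         alternative = "two.sided")
    )
    p <- min(1, wt$p.value)
  }
  structure(
    list(statistic = statistic, p_value = p,
         medians = c(stats::median(x), stats::median(y)),
         n1 = n1, n2 = n2,
         mode = if (use_exact) "exact" else "normal",
         degenerate = degenerate),
    class = "adgwas_ranktest"
  )
}

#' @export
print.adgwas_ranktest <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (%s): W1 = %g, medians %.3g vs %.3g, p = %.4g\n",
    x$mode, x$statistic, x$medians[1], x$medians[2], x$p_value))
  invisible(x)
}

#' Cox proportional hazards fit (Breslow ties)
#'
#' Partial-likelihood Cox regression with the Breslow approximation for tied
#' event times. Rows are canonically re-ordered before fitting so the output
#' is invariant (to the last bit) under permutation of the input rows.
#' Monotone likelihoods (one covariate pattern's events all preceding
#' another's) are reported as `converged = FALSE`.
#'
#' @param time Positive event/censoring times (e.g. age at onset in years).
#' @param event 0/1 event indicator; at least one event required.
#' @param covariates Numeric matrix of covariates, full column rank.
#' @return An [`adgwas_fit`][new_fit_result] on the log-hazard scale.
#' @export
cox_ph_fit <- function(time, event, covariates) {
  covariates <- as.matrix(covariates)
  n <- length(time)
  if (nrow(covariates) != n || length(event) != n) stop("input lengths differ")
  if (any(time <= 0)) stop("all times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  if (sum(event) == 0) stop("at least one event is required")
  if (qr(covariates)$rank < ncol(covariates) ||
      any(apply(covariates, 2, stats::var) == 0)) {
    stop("singular covariate matrix (constant or collinear column)")
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }
  ord <- do.call(order, c(list(time, event),
                          lapply(seq_len(ncol(covariates)),
                                 function(j) covariates[, j])))
  time <- time[ord]; event <- event[ord]
  covariates <- covariates[ord, , drop = FALSE]

  inf_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariates,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        inf_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- fit$coefficients
  names(beta) <- colnames(covariates)
  cov <- fit$var
  dimnames(cov) <- list(colnames(covariates), colnames(covariates))
  converged <- !inf_warn && all(is.finite(beta)) && all(abs(beta) < 15)
  new_fit_result(beta, cov, fit$loglik[2],
                 converged = converged, n_iterations = fit$iter,
                 model = "cox")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic genotype table: given the observed
#' allele counts, sums the probabilities of all heterozygote counts no more
#' probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts.
#' @return Exact two-sided p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa      # minor allele count
  # heterozygote count shares the parity of the minor allele count
  het_values <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log probability of each heterozygote count conditional on allele counts
  logp <- vapply(het_values, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_com <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_com + 1) +
      h * log(2) -
      (lgamma(2 * n + 1) - lgamma(n_rare + 1) - lgamma(2 * n - n_rare + 1))
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[het_values == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Interior quantile boundaries
#'
#' k-1 interior cut-points of the empirical distribution at probabilities
#' i/k, using linear interpolation between order statistics (type 7). The
#' convention matters because percentile-bin membership near a boundary
#' depends on it; bins formed from these boundaries are left-open /
#' right-closed with the lowest bin closed on both ends.
#'
#' @param values Non-empty numeric vector.
#' @param k Number of bins (>= 2).
#' @return Numeric vector of k-1 non-decreasing cut-points, with attribute
#'   `degenerate = TRUE` when there are fewer than `k` distinct values.
#' @examples
#' quantile_boundaries(1:100, 4)  # 25.75 50.50 75.25
#' @export
quantile_boundaries <- function(values, k) {
  if (length(values) == 0) stop("values must be non-empty")
  if (k < 2) stop("k must be at least 2")
  b <- unname(stats::quantile(values, probs = seq_len(k - 1) / k,
                              type = 7, names = FALSE))
  degenerate <- length(unique(values)) < k
  attr(b, "degenerate") <- degenerate
  b
}

#' Assign values to bins given boundaries
#'
#' Intervals are left-open/right-closed; the lowest bin is closed on both
#' ends and out-of-range values clamp to the extreme bins, so assignment is
#' total and monotone.
#'
#' @param values Numeric vector.
#' @param boundaries Non-decreasing cut-points (length k-1 for k bins).
#' @return Integer bin index in 1..k per value.
#' @export
assign_bins <- function(values, boundaries) {
  k <- length(boundaries) + 1L
  idx <- findInterval(values, boundaries, left.open = TRUE) + 1L
  pmin(pmax(idx, 1L), k)
}
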