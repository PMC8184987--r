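# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# HWE exact p by direct factorial enumeration (integer choose(), not the
# package's log-gamma recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- sapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    exp(lchoose(n, hr) + lchoose(n - hr, h) + h * log(2) -
          lchoose(2 * n, n_rare))
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# exact two-sided Wilcoxon p by enumerating all rank assignments
wilcoxon_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  obs <- sum(rank(c(x, y))[seq_len(n1)])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(seq_len(n)[combos], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# 1-D grid-search maximiser of the Breslow log partial likelihood for a
# single binary covariate, all events
breslow_loglik <- function(beta, time, x) {
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# a small cohort with a known 2x2 structure for contrast tests
expand_2x2 <- function(a, b, c, d) {
  list(
    exposed = c(rep(1, a + b), rep(0, c + d)),
    case = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
}
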