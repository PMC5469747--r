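# Convergence diagnostics for the pooled movement parameters.

# Split-Rhat (potential scale reduction) over a list of per-chain draws.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(v) {
    n <- length(v) %/% 2
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size using Geyer-style truncation of the
# autocorrelation sum (stop at the first negative lag estimate),
# averaged across chains.
ess_basic <- function(draws_by_chain) {
  total <- sum(lengths(draws_by_chain))
  rho_sum <- mean(vapply(draws_by_chain, function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(0)
    ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    neg <- which(ac < 0)
    if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
    sum(ac)
  }, numeric(1)))
  max(1, total / (1 + 2 * max(0, rho_sum)))
}

mcmc_diagnostics <- function(par_mats) {
  pn <- colnames(par_mats[[1]])
  rhat <- vapply(pn, function(p)
    split_rhat(lapply(par_mats, function(m) m[, p])), numeric(1))
  ess <- vapply(pn, function(p)
    ess_basic(lapply(par_mats, function(m) m[, p])), numeric(1))
  list(rhat = rhat, ess = ess, converged = all(rhat < 1.1, na.rm = TRUE))
}
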