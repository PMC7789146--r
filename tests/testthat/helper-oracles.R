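# Independent numerical oracles for the random-intercept logistic model.
# Dense trapezoid integration on a fixed grid over u in [-10*sigma, 10*sigma];
# deliberately shares no code with the package's adaptive quadrature.

oracle_family_integrals <- function(beta0, sigma, k, n, npts = 20001) {
  stopifnot(sigma > 0)
  u <- seq(-10 * sigma, 10 * sigma, length.out = npts)
  du <- u[2] - u[1]
  p <- plogis(beta0 + u)
  trapz <- function(g) (sum(g) - (g[1] + g[length(g)]) / 2) * du
  sapply(seq_along(k), function(i) {
    logf <- k[i] * log(p) + (n[i] - k[i]) * log1p(-p) +
      dnorm(u, 0, sigma, log = TRUE)
    m <- max(logf)
    f <- exp(logf - m)
    c(logL = m + log(trapz(f)), post_mean = trapz(f * p) / trapz(f))
  })
}

oracle_marginal_loglik <- function(beta0, sigma, k, n, npts = 20001) {
  sum(oracle_family_integrals(beta0, sigma, k, n, npts)["logL", ])
}

oracle_posterior_mean <- function(beta0, sigma, k, n, npts = 20001) {
  unname(oracle_family_integrals(beta0, sigma, k, n, npts)["post_mean", ])
}

# closed-form logistic log-likelihood (sigma = 0 reduction)
logistic_loglik <- function(beta0, k, n) {
  p <- plogis(beta0)
  sum(k * log(p) + (n - k) * log(1 - p))
}
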