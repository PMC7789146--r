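# Random-intercept logistic model for family longevity indicators.
#
# Member j of family i carries Y_ij = I(P_ij >= c); conditional on the
# family effect u_i ~ N(0, sigma^2),
#     P(Y_ij = 1 | u_i) = plogis(beta0 + u_i),
# and members are independent. The family likelihood depends on the data
# only through (k_i, n_i) = (number of long-lived members, family size):
#     L_i = \int p(u)^k (1 - p(u))^(n - k) dnorm(u, 0, sigma) du.
# Integrals are evaluated by adaptive Gauss-Hermite quadrature centered at
# each family's posterior mode (Newton in one dimension; the integrand is
# log-concave so the mode is unique).

# posterior mode and curvature-based scale for each (k, n); vectorized
agq_mode <- function(beta0, sigma, k, n) {
  u <- rep(0, length(k))
  p <- plogis(beta0 + u)
  for (it in 1:200) {
    g <- k - n * p - u / sigma^2
    h <- n * p * (1 - p) + 1 / sigma^2
    step <- pmax(pmin(g / h, 3), -3)   # damped: integrand is log-concave
    u <- u + step
    p <- plogis(beta0 + u)
    if (max(abs(step)) < 1e-12) break
  }
  list(mode = u, tau = 1 / sqrt(n * p * (1 - p) + 1 / sigma^2))
}

# per-family log marginal likelihood and posterior mean of p, jointly
agq_core <- function(beta0, sigma, k, n, order) {
  if (sigma < 1e-8) {
    logL <- k * plogis(beta0, log.p = TRUE) + (n - k) * plogis(-beta0, log.p = TRUE)
    return(list(logL = logL, post_mean = rep(plogis(beta0), length(k))))
  }
  gh <- gh_rule(order)
  md <- agq_mode(beta0, sigma, k, n)
  U <- outer(sqrt(2) * md$tau, gh$x) + md$mode        # families x nodes
  log_p <- plogis(beta0 + U, log.p = TRUE)
  log_q <- plogis(-(beta0 + U), log.p = TRUE)
  logH <- k * log_p + (n - k) * log_q + dnorm(U, 0, sigma, log = TRUE)
  A <- sweep(logH, 2, log(gh$w) + gh$x^2, "+")
  m <- apply(A, 1, max)
  W <- exp(A - m)
  denom <- rowSums(W)
  list(logL = log(sqrt(2) * md$tau) + m + log(denom),
       post_mean = rowSums(W * exp(log_p)) / denom)
}

as_family_stats <- function(data) {
  if (all(c("k", "n") %in% names(data))) {
    st <- tibble::as_tibble(data)
    if (!"family_id" %in% names(st)) {
      st$family_id <- as.character(seq_len(nrow(st)))
    }
  } else {
    st <- family_stats(data)
  }
  if (any(st$n < 1) || any(st$k < 0) || any(st$k > st$n)) {
    abort("Family statistics must satisfy 0 <= k <= n, n >= 1.")
  }
  st
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Sums, over families, the log of the binomial-kernel likelihood integrated
#' against the normal random-effect density. At `sigma = 0` this reduces
#' exactly to the ordinary logistic log-likelihood with success probability
#' `plogis(beta0)`.
#'
#' @param beta0 Fixed intercept on the log-odds scale.
#' @param sigma Random-effect standard deviation, `>= 0`.
#' @param data Either a tibble of per-family statistics with columns `k`,
#'   `n` (see [family_stats()]) or an annotated individuals tibble.
#' @param quadrature_order Number of Gauss-Hermite nodes (`>= 2`). The
#'   default (60) keeps the adaptive quadrature within 1e-6 of exact
#'   integration over the whole plausible parameter range.
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(beta0, sigma, data, quadrature_order = 60) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (quadrature_order < 2) abort("`quadrature_order` must be >= 2.")
  st <- as_family_stats(data)
  logL <- agq_core(beta0, sigma, st$k, st$n, quadrature_order)$logL
  if (any(!is.finite(logL))) {
    bad <- st$family_id[!is.finite(logL)]
    abort(sprintf("Non-finite marginal likelihood for family(ies): %s.",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  sum(logL)
}

#' Fit the random-intercept logistic longevity model
#'
#' Maximizes the marginal likelihood over `(beta0, log sigma)` with BFGS,
#' multi-started from the pooled-prevalence intercept and random-effect SDs
#' of 0.5, 1 and 2 (the log transform keeps the `sigma -> 0` boundary
#' interior). Data in which every indicator is 0 or every indicator is 1
#' are rejected: the intercept diverges and all family scores would
#' degenerate to a constant.
#'
#' @inheritParams marginal_loglik
#' @param init Optional starting values `c(beta0, sigma)`.
#' @param tol Convergence tolerance on the log-likelihood; a refit from the
#'   returned optimum must not improve it by more than `tol`.
#' @return An object of class `mlrc_fit` with elements `beta0`, `sigma`,
#'   `loglik`, `converged`, `n_families`, `n_individuals`,
#'   `quadrature_order` and the per-family statistics `stats`.
#' @seealso [score_mlrc()], [posterior_mean_p()], [tidy()], [glance()]
#' @export
fit_mlrc <- function(data, init = NULL, quadrature_order = 60, tol = 1e-6) {
  st <- as_family_stats(data)
  if (nrow(st) < 2) abort("At least 2 families are required.")
  K <- sum(st$k); N <- sum(st$n)
  if (K == 0 || K == N) {
    abort(paste0("All longevity indicators are ",
                 if (K == 0) "0" else "1",
                 ": the intercept diverges and no family ranking exists."))
  }
  b0_start <- qlogis(min(max(K / N, 1e-4), 1 - 1e-4))
  starts <- list(c(b0_start, log(0.5)), c(b0_start, log(1)), c(b0_start, log(2)))
  if (!is.null(init)) {
    if (length(init) != 2 || init[2] <= 0) {
      abort("`init` must be c(beta0, sigma) with sigma > 0.")
    }
    starts <- c(list(c(init[1], log(init[2]))), starts)
  }
  negll <- function(th) {
    -marginal_loglik(th[1], exp(th[2]), st, quadrature_order)
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(optim(s, negll, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("Marginal likelihood optimization failed from every start.")
  # polish until a refit no longer improves the log-likelihood: the
  # likelihood is nearly flat in log(sigma) when clustering is weak, so a
  # single BFGS pass can stop short of the ridge top
  improved <- Inf
  for (round in 1:5) {
    polish <- optim(best$par, negll, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-12))
    improved <- best$value - polish$value
    if (polish$value < best$value) best <- polish
    if (improved <= max(tol, 1e-8)) break
  }
  converged <- best$convergence == 0 && improved <= max(tol, 1e-8)
  if (!converged) {
    warn("mLRC fit did not converge cleanly; inspect the returned fit.")
  }
  structure(
    list(beta0 = best$par[1], sigma = exp(best$par[2]),
         loglik = -best$value, converged = converged,
         n_families = nrow(st), n_individuals = N,
         quadrature_order = quadrature_order, stats = st),
    class = "mlrc_fit")
}

#' Posterior mean longevity probability for a family
#'
#' Computes \eqn{\hat p_i = E[\mathrm{plogis}(\beta_0 + u) \mid k, n]}, the
#' expectation of the family's longevity probability under the posterior of
#' its random effect given `k` long-lived members out of `n`. This is the
#' mLRC score: a shrunken version of the proportion `k/n` whose pull toward
#' the population level weakens as `n` grows. `n = 0` returns the prior
#' mean. Values are strictly inside `(0, 1)`.
#'
#' @param fit An [mlrc_fit][fit_mlrc] object (or a list with `beta0`,
#'   `sigma`).
#' @param k,n Number of long-lived members and family sizes (vectorized).
#' @param quadrature_order Gauss-Hermite order; defaults to the fit's.
#' @return Numeric vector of posterior mean probabilities.
#' @export
posterior_mean_p <- function(fit, k, n, quadrature_order = NULL) {
  order <- quadrature_order %||% fit$quadrature_order %||% 60
  if (length(k) != length(n)) {
    nlen <- max(length(k), length(n))
    k <- rep_len(k, nlen); n <- rep_len(n, nlen)
  }
  if (any(n < 0) || any(k < 0) || any(k > n)) {
    abort("Require 0 <= k <= n.")
  }
  out <- agq_core(fit$beta0, fit$sigma, k, n, order)$post_mean
  if (any(!is.finite(out)) || any(out <= 0) || any(out >= 1)) {
    bad <- which(!is.finite(out) | out <= 0 | out >= 1)[1]
    abort(sprintf("Posterior integral degenerate for (k = %d, n = %d).",
                  k[bad], n[bad]))
  }
  out
}

#' Model-based LRC score (mLRC)
#'
#' Scores every family by the posterior mean of its longevity probability
#' under the fitted random-intercept logistic model. Families sharing the
#' same `(k, n)` receive identical scores, so the posterior integral is
#' evaluated once per distinct pair.
#'
#' @param individuals Annotated individuals tibble (or a `k`/`n` statistics
#'   tibble with a `family_id` column).
#' @param fit An [mlrc_fit][fit_mlrc]; fitted on `individuals` when `NULL`.
#' @param threshold Longevity threshold recorded in the output (metadata
#'   only; indicators must already be computed).
#' @param quadrature_order Gauss-Hermite order used when fitting.
#' @return A score tibble with columns `family_id`, `size`, `score`
#'   (`"mLRC"`), `value`, `threshold`, and the fit in attribute `fit`.
#' @export
score_mlrc <- function(individuals, fit = NULL, threshold = 0.9,
                       quadrature_order = 60) {
  st <- as_family_stats(individuals)
  if (is.null(fit)) {
    fit <- fit_mlrc(st, quadrature_order = quadrature_order)
  }
  key <- dplyr::distinct(st, .data$k, .data$n)
  key$p <- posterior_mean_p(fit, key$k, key$n)
  st <- dplyr::left_join(st, key, by = c("k", "n"))
  out <- new_score_set(st$family_id, st$n, st$p, "mLRC", threshold)
  attr(out, "fit") <- fit
  out
}

#' @export
print.mlrc_fit <- function(x, ...) {
  cat("Random-intercept logistic longevity model (marginal ML)\n")
  cat(sprintf("  beta0 = %.4f   sigma = %.4f\n", x$beta0, x$sigma))
  cat(sprintf("  log-likelihood = %.4f   converged: %s\n",
              x$loglik, x$converged))
  cat(sprintf("  %d families, %d individuals, %d quadrature nodes\n",
              x$n_families, x$n_individuals, x$quadrature_order))
  invisible(x)
}

#' Tidy a fitted longevity model
#'
#' @param x An [mlrc_fit][fit_mlrc] object.
#' @param ... Unused.
#' @return One row per parameter with columns `term`, `estimate`.
#' @method tidy mlrc_fit
#' @export
tidy.mlrc_fit <- function(x, ...) {
  tibble::tibble(term = c("beta0", "sigma"),
                 estimate = c(x$beta0, x$sigma))
}

#' @rdname tidy.mlrc_fit
#' @return For `glance()`: a one-row tibble with fit-level summaries.
#' @method glance mlrc_fit
#' @export
glance.mlrc_fit <- function(x, ...) {
  tibble::tibble(beta0 = x$beta0, sigma = x$sigma, logLik = x$loglik,
                 converged = x$converged, n_families = x$n_families,
                 n_individuals = x$n_individuals,
                 quadrature_order = x$quadrature_order)
}

#' Write a fit summary as a key-value text file
#'
#' @param fit An [mlrc_fit][fit_mlrc].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mlrc_summary <- function(fit, path) {
  lines <- sprintf(
    "%s: %s",
    c("beta0", "sigma", "loglik", "converged", "n_families",
      "n_individuals", "quadrature_order"),
    c(format(fit$beta0, digits = 10), format(fit$sigma, digits = 10),
      format(fit$loglik, digits = 10), fit$converged, fit$n_families,
      fit$n_individuals, fit$quadrature_order))
  writeLines(lines, path)
  invisible(path)
}
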