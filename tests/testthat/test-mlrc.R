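test_that("sigma = 0 collapses to the plain logistic model exactly", {
  st <- tibble::tibble(k = c(1L, 0L, 2L), n = c(1L, 2L, 3L))
  expect_equal(marginal_loglik(0, 0, st[1, ]), log(0.5))
  for (b0 in c(-2, -0.5, 1)) {
    expect_identical(marginal_loglik(b0, 0, st), logistic_loglik(b0, st$k, st$n))
    fit0 <- list(beta0 = b0, sigma = 0, quadrature_order = 30)
    expect_equal(posterior_mean_p(fit0, st$k, st$n),
                 rep(plogis(b0), 3))
  }
})

test_that("adaptive quadrature matches dense-trapezoid integration", {
  # spot value from the oracle
  expect_equal(marginal_loglik(-1, 1.5, tibble::tibble(k = 2L, n = 3L)),
               oracle_marginal_loglik(-1, 1.5, 2, 3),
               tolerance = 1e-8)
  # grid of (k, n, beta0, sigma)
  grid <- expand.grid(n = c(1, 3, 8, 14), beta0 = c(-2, 0.5),
                      sigma = c(0.5, 2))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    k <- unique(c(0, 1, n %/% 2, n))
    got_ll <- vapply(k, function(kk) {
      marginal_loglik(grid$beta0[i], grid$sigma[i],
                      tibble::tibble(k = kk, n = n))
    }, 0)
    want_ll <- vapply(k, function(kk) {
      oracle_marginal_loglik(grid$beta0[i], grid$sigma[i], kk, n)
    }, 0)
    expect_lt(max(abs(got_ll - want_ll)), 1e-6)
    fit <- list(beta0 = grid$beta0[i], sigma = grid$sigma[i])
    expect_lt(max(abs(
      posterior_mean_p(fit, k, rep(n, length(k)), quadrature_order = 60) -
        oracle_posterior_mean(grid$beta0[i], grid$sigma[i],
                              k, rep(n, length(k))))), 1e-6)
  }
})

test_that("posterior mean is monotone in k and shrinks with family size", {
  fit <- list(beta0 = -1, sigma = 1)
  # increasing in k at fixed n
  p_by_k <- posterior_mean_p(fit, 0:5, rep(5, 6))
  expect_true(all(diff(p_by_k) > 0))
  expect_gt(posterior_mean_p(fit, 2, 2), posterior_mean_p(fit, 1, 2))
  # all-long-lived families: larger families are stronger evidence
  p_full <- posterior_mean_p(fit, c(2, 5, 14), c(2, 5, 14))
  expect_true(all(diff(p_full) > 0))
  # no long-lived members: larger families are pulled further down
  p_empty <- posterior_mean_p(fit, c(0, 0, 0), c(2, 5, 14))
  expect_true(all(diff(p_empty) < 0))
  # n = 0 returns the prior mean of p
  expect_equal(posterior_mean_p(fit, 0, 0),
               oracle_posterior_mean(-1, 1, 0, 0), tolerance = 1e-7)
  expect_true(all(p_by_k > 0 & p_by_k < 1))
})

test_that("doubling the quadrature order leaves results unchanged", {
  st <- tibble::tibble(k = c(0L, 2L, 5L, 14L, 1L), n = c(2L, 2L, 10L, 14L, 8L))
  for (sigma in c(0.3, 1.5, 3)) {
    l1 <- marginal_loglik(-2, sigma, st)
    l2 <- marginal_loglik(-2, sigma, st, quadrature_order = 120)
    expect_lt(abs(l1 - l2), 1e-6)
    p1 <- posterior_mean_p(list(beta0 = -2, sigma = sigma), st$k, st$n)
    p2 <- posterior_mean_p(list(beta0 = -2, sigma = sigma), st$k, st$n,
                           quadrature_order = 120)
    expect_lt(max(abs(p1 - p2)), 1e-6)
  }
})

test_that("marginal ML recovers generating parameters and finds a maximum", {
  b0 <- -2; s0 <- 1.5
  set.seed(42)
  u <- rnorm(800, 0, s0)
  k <- rbinom(800, 8, plogis(b0 + u))
  fit <- fit_mlrc(tibble::tibble(k = k, n = 8L))
  expect_true(fit$converged)
  expect_lt(abs(fit$beta0 - b0), 0.25)
  expect_lt(abs(fit$sigma - s0), 0.25)
  # self-consistency: stored loglik is the marginal loglik at the optimum,
  # and the optimum is a maximum along both coordinate axes
  expect_equal(fit$loglik,
               marginal_loglik(fit$beta0, fit$sigma, fit$stats), tolerance = 1e-9)
  eps <- 1e-3
  for (d in list(c(eps, 0), c(-eps, 0), c(0, eps), c(0, -eps))) {
    expect_lte(marginal_loglik(fit$beta0 + d[1], fit$sigma + d[2], fit$stats),
               fit$loglik + 1e-9)
  }
})

test_that("independent Bernoulli data drive sigma to zero", {
  set.seed(7)
  k <- rbinom(1500, 4, 0.5)
  fit <- suppressWarnings(fit_mlrc(tibble::tibble(k = k, n = 4L)))
  expect_lt(abs(fit$beta0), 0.1)
  expect_lt(fit$sigma, 0.15)
})

test_that("degenerate indicator patterns are rejected", {
  expect_error(fit_mlrc(tibble::tibble(k = c(0L, 0L), n = c(3L, 5L))),
               "indicators are 0")
  expect_error(fit_mlrc(tibble::tibble(k = c(3L, 5L), n = c(3L, 5L))),
               "indicators are 1")
  expect_error(fit_mlrc(tibble::tibble(k = 1L, n = 2L)), "At least 2")
  expect_error(marginal_loglik(0, -1, tibble::tibble(k = 1L, n = 2L)),
               "sigma")
})

test_that("estimates agree with an independent mixed-model implementation", {
  set.seed(33)
  u <- rnorm(400, 0, 1.2)
  n <- rep(c(2L, 5L, 9L), length.out = 400)
  k <- rbinom(400, n, plogis(-1.5 + u))
  fit <- fit_mlrc(tibble::tibble(k = k, n = n))
  df <- data.frame(fam = rep(seq_along(n), n),
                   y = unlist(mapply(function(kk, nn) {
                     c(rep(1, kk), rep(0, nn - kk))
                   }, k, n, SIMPLIFY = FALSE)))
  ref <- lme4::glmer(y ~ 1 + (1 | fam), data = df, family = binomial,
                     nAGQ = 25)
  expect_equal(fit$beta0, unname(lme4::fixef(ref)), tolerance = 0.02)
  expect_equal(fit$sigma,
               sqrt(unname(lme4::VarCorr(ref)$fam[1])), tolerance = 0.03)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("mLRC scores depend on the data only through (k, n)", {
  ind <- make_individuals(c(2, 2, 3, 14, 14), ages = rep(70, 35))
  set.seed(5)
  ind$longevous <- 0L
  # families 1 and 2 both (k=1, n=2); families 4 and 5 both (k=3, n=14)
  ind$longevous[ind$family_id == "fam01"][1] <- 1L
  ind$longevous[ind$family_id == "fam02"][2] <- 1L
  ind$longevous[ind$family_id == "fam03"][1] <- 1L
  ind$longevous[ind$family_id == "fam04"][c(1, 5, 9)] <- 1L
  ind$longevous[ind$family_id == "fam05"][c(2, 3, 14)] <- 1L
  sc <- suppressWarnings(score_mlrc(ind))
  v <- setNames(sc$value, sc$family_id)
  expect_identical(v[["fam01"]], v[["fam02"]])
  expect_identical(v[["fam04"]], v[["fam05"]])
})

test_that("fitted-model scores shrink the proportion toward the population", {
  set.seed(12)
  pop <- generate_population(
    sim_config(family_sizes = c(`2` = 80, `3` = 60, `8` = 40, `14` = 40)),
    seed = 8)
  lrc <- score_lrc(pop$individuals)
  ml <- score_mlrc(pop$individuals)
  fit <- attr(ml, "fit")
  expect_gt(fit$sigma, 0)
  j <- dplyr::inner_join(lrc, ml, by = "family_id",
                         suffix = c("_lrc", "_ml"))
  expect_true(all(j$value_ml[j$value_lrc == 1] < 1 &
                    j$value_ml[j$value_lrc == 1] <
                      j$value_lrc[j$value_lrc == 1]))
  expect_true(all(j$value_ml[j$value_lrc == 0] > 0 &
                    j$value_ml[j$value_lrc == 0] >
                      j$value_lrc[j$value_lrc == 0]))
})

test_that("fit objects tidy, glance, print and serialize", {
  st <- tibble::tibble(k = c(0L, 1L, 2L, 1L, 0L, 2L),
                       n = c(2L, 2L, 2L, 3L, 3L, 3L))
  fit <- suppressWarnings(fit_mlrc(st))
  td <- tidy(fit)
  expect_equal(td$term, c("beta0", "sigma"))
  gl <- glance(fit)
  expect_equal(gl$n_families, 6)
  expect_equal(gl$n_individuals, 15)
  expect_output(print(fit), "beta0")
  path <- withr::local_tempfile(fileext = ".txt")
  write_mlrc_summary(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^beta0: ", lines)))
  expect_true(any(grepl("^converged: ", lines)))
})
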