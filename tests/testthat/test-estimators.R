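test_that("Wald ratios follow first-order arithmetic", {
  w <- wald_ratio(gamma = 0.1, s_gamma = 0.01, Gamma = -0.05, s_Gamma = 0.02)
  expect_equal(w$beta, -0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$ci_low, -0.5 - 1.959964 * 0.2)
  w0 <- wald_ratio(0.1, 0.01, 0, 0.02)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)
  # joint negation leaves the ratio unchanged
  expect_equal(wald_ratio(-0.1, 0.01, 0.05, 0.02)$beta, w$beta)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "gamma = 0")
})

test_that("IVW equals the zero-intercept weighted least-squares slope", {
  for (s in 1:50) {
    h <- make_harmonised(sample(3:15, 1), seed = s,
                         Gamma = NULL)
    est <- mr_ivw(h)
    fit <- lm(Gamma ~ 0 + gamma, data = h, weights = 1 / h$s_Gamma^2)
    expect_equal(est$beta, unname(coef(fit)["gamma"]), tolerance = 1e-10)
  }
})

test_that("IVW degenerate and symmetric cases behave", {
  h1 <- make_harmonised(1, gamma = 0.1, s_gamma = 0.01, Gamma = -0.05,
                        s_Gamma = 0.02)
  est1 <- mr_ivw(h1)
  w <- wald_ratio(0.1, 0.01, -0.05, 0.02)
  expect_identical(est1$beta, w$beta)
  expect_identical(est1$se, w$se)
  # equal weights, ratios -0.4 and -0.6 average to -0.5
  h2 <- make_harmonised(2, gamma = c(0.1, 0.1), s_gamma = c(0.01, 0.01),
                        Gamma = c(-0.04, -0.06), s_Gamma = c(0.02, 0.02))
  expect_equal(mr_ivw(h2)$beta, -0.5)
  expect_error(mr_ivw(make_harmonised(0)), "empty")
  expect_message(mr_ivw(h1, "multiplicative"), "falls back to fixed")
})

test_that("fixed and multiplicative IVW share the point estimate", {
  for (s in 1:10) {
    h <- make_harmonised(10, seed = s)
    h$Gamma <- h$Gamma + rnorm(10, 0, 0.05)  # induce heterogeneity
    f <- mr_ivw(h, "fixed")
    m <- mr_ivw(h, "multiplicative")
    expect_equal(f$beta, m$beta)
    expect_gte(m$se, f$se)
    expect_equal(f$Q, m$Q)
  }
})

test_that("IVW agrees with an independent fixed-effect meta of Wald ratios", {
  h <- make_harmonised(12, seed = 9)
  est <- mr_ivw(h)
  ratios <- h$Gamma / h$gamma
  ses <- h$s_Gamma / abs(h$gamma)
  fit <- metafor::rma(yi = ratios, sei = ses, method = "FE")
  expect_equal(est$beta, as.numeric(fit$b), tolerance = 1e-10)
  expect_equal(est$se, fit$se, tolerance = 1e-10)
  expect_equal(est$Q, fit$QE, tolerance = 1e-10)
})

test_that("MR-Egger recovers an exact linear relationship", {
  h <- make_harmonised(6, gamma = seq(0.02, 0.12, length.out = 6),
                       s_gamma = rep(0.005, 6), Gamma = NULL,
                       s_Gamma = rep(0.02, 6))
  h$Gamma <- 0.015 + 0.4 * h$gamma  # exact line, positive gammas
  e <- mr_egger(h)
  expect_equal(e$beta[e$method == "egger_slope"], 0.4, tolerance = 1e-10)
  expect_equal(e$beta[e$method == "egger_intercept"], 0.015, tolerance = 1e-10)
  expect_error(mr_egger(make_harmonised(2)), "at least 3")
})

test_that("MR-Egger is invariant to instrument allele orientation", {
  h <- make_harmonised(8, seed = 11)
  flipped <- h
  flipped$gamma[1:3] <- -flipped$gamma[1:3]
  flipped$Gamma[1:3] <- -flipped$Gamma[1:3]
  expect_equal(mr_egger(flipped)$beta, mr_egger(h)$beta, tolerance = 1e-12)
})

test_that("the weighted median interpolates the 50th weight percentile", {
  h <- make_harmonised(3, gamma = c(0.1, 0.1, 0.1), s_gamma = rep(0.01, 3),
                       Gamma = c(-0.07, -0.05, -0.01), s_Gamma = rep(0.02, 3))
  wm <- weighted_median(h, n_boot = 200, seed = 4)
  expect_equal(wm$beta, -0.5)
  # permuting the instruments leaves the estimate unchanged (the bootstrap
  # stream pairs with input positions, so only the point estimate is exact)
  wm2 <- weighted_median(h[c(3, 1, 2), ], n_boot = 200, seed = 4)
  expect_equal(wm2$beta, wm$beta)
  expect_error(weighted_median(h, n_boot = 10), "seed")
})

test_that("the weighted median resists a minority pleiotropic instrument", {
  withr::with_seed(21, {
    n <- 10
    gamma <- runif(n, 0.05, 0.12)
    h <- make_harmonised(n, gamma = gamma, s_gamma = rep(0.004, n),
                         Gamma = -0.3 * gamma, s_Gamma = rep(0.01, n))
    clean_med <- weighted_median(h, n_boot = 100, seed = 1)$beta
    # plant one outlier carrying ~20% of total weight
    hp <- h
    hp$s_Gamma[1] <- 0.005
    hp$s_Gamma[-1] <- 0.011
    hp$Gamma[1] <- hp$Gamma[1] + 2 * hp$gamma[1]
    w <- hp$gamma^2 / hp$s_Gamma^2
    expect_gt(w[1] / sum(w), 0.15)
    wm_p <- weighted_median(hp, n_boot = 100, seed = 1)$beta
    ivw_p <- mr_ivw(hp)$beta
    expect_lt(abs(wm_p - clean_med), 0.05)
    expect_gt(abs(ivw_p - clean_med), 0.2)
  })
})

test_that("unweighted pooling collapses to the per-allele average", {
  h <- make_harmonised(4, gamma = runif(4, 0.02, 0.1), s_gamma = rep(0.01, 4),
                       Gamma = rep(-0.03, 4), s_Gamma = rep(0.02, 4))
  u <- unweighted_ivw(h)
  expect_equal(u$beta, -0.03)
  expect_equal(u$se, 0.02 / 2)
  h1 <- h[1, ]
  u1 <- unweighted_ivw(h1)
  expect_equal(u1$beta, h1$Gamma)
  expect_equal(u1$se, h1$s_Gamma)
  # reduces to IVW when every gamma is 1
  h2 <- make_harmonised(5, seed = 2)
  h2$gamma <- 1
  expect_equal(unweighted_ivw(h2)$beta, mr_ivw(h2)$beta, tolerance = 1e-12)
  expect_equal(unweighted_ivw(h2)$se, mr_ivw(h2)$se, tolerance = 1e-12)
})

test_that("estimates are scale-equivariant in the exposure units", {
  h <- make_harmonised(8, seed = 5)
  c_scale <- 2.5
  hs <- h
  hs$gamma <- hs$gamma * c_scale
  hs$s_gamma <- hs$s_gamma * c_scale
  expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c_scale, tolerance = 1e-12)
  expect_equal(mr_ivw(hs)$se, mr_ivw(h)$se / c_scale, tolerance = 1e-12)
  expect_equal(weighted_median(hs, 100, 3)$beta,
               weighted_median(h, 100, 3)$beta / c_scale, tolerance = 1e-12)
})

test_that("fit_mr bundles the estimator suite with broom methods", {
  h <- make_harmonised(10, seed = 6)
  fit <- fit_mr(h, seed = 2, n_boot = 100)
  td <- tidy(fit)
  expect_setequal(td$method, c("ivw_fixed", "egger_slope", "egger_intercept",
                               "weighted_median"))
  expect_equal(td$or, exp(td$beta))
  gl <- glance(fit)
  expect_equal(gl$n_snps, 10L)
  expect_s3_class(autoplot(fit), "ggplot")
})
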