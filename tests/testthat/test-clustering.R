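# small exposure + trait panels built from one simulation, for matrix tests
make_trait_panels <- function(seed = 1, n_traits = 3, n_snps = 10) {
  sims <- lapply(seq_len(n_traits), function(t) {
    simulate_two_sample(sim_scenario(seed = seed, n_snps = n_snps,
                                     beta_causal = -0.1 * t))
  })
  panels <- lapply(sims, `[[`, "outcome")
  names(panels) <- paste0("trait_", seq_len(n_traits))
  list(exposure = sims[[1]]$exposure, panels = panels)
}

test_that("the trait matrix is complete, oriented, and drops partial traits", {
  tp <- make_trait_panels(seed = 3)
  ids <- tp$exposure$variant_id
  z <- build_trait_matrix(tp$panels, tp$exposure, ids)
  expect_equal(dim(z), c(10, 3))
  expect_equal(rownames(z), ids)
  expect_equal(attr(z, "dropped_traits"), character(0))
  # a trait missing one instrument is dropped with a message
  broken <- tp$panels
  broken$trait_2 <- broken$trait_2[-4, ]
  expect_message(z2 <- build_trait_matrix(broken, tp$exposure, ids),
                 "trait_2")
  expect_equal(colnames(z2), c("trait_1", "trait_3"))
  # flipping alleles in one panel pre-build leaves the matrix unchanged
  flipped <- tp$panels
  f <- flipped$trait_1
  tmp <- f$effect_allele
  f$effect_allele <- f$other_allele; f$other_allele <- tmp
  f$beta <- -f$beta; f$eaf <- 1 - f$eaf
  flipped$trait_1 <- f
  z3 <- build_trait_matrix(flipped, tp$exposure, ids)
  expect_equal(z3, z, tolerance = 1e-12)
  expect_error(build_trait_matrix(tp$panels[1], tp$exposure, ids), ">= 2")
})

test_that("identical rows collapse to a single cluster", {
  z <- matrix(rep(c(1, 2, 3, 4, 0.5), each = 12), nrow = 12)
  rownames(z) <- paste0("v", 1:12)
  fit <- fit_directional_mixture(z, K = 5, n_starts = 5, seed = 2)
  expect_equal(fit$K_effective, 1)
  expect_equal(unname(unique(fit$labels)), "1")
  expect_equal(unname(rowSums(fit$probabilities)), rep(1, 12),
               tolerance = 1e-8)
})

test_that("planted clusters are recovered and isotropic rows become noise", {
  tm <- simulate_trait_matrix(40, 12,
                              list(list(size = 12, concentration = 200),
                                   list(size = 10, concentration = 200)),
                              seed = 5)
  fit <- fit_directional_mixture(tm$z, K = 10, n_starts = 15, seed = 9)
  expect_equal(fit$K_effective, 2)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(tm$labels, fit$labels), 0.9)
  expect_gte(mean(fit$labels[tm$labels == "noise"] == "noise"), 0.9)
})

test_that("antipodal direction bundles form two distinct clusters", {
  withr::with_seed(8, {
    dirv <- rnorm(15); dirv <- dirv / sqrt(sum(dirv^2))
  })
  tm <- simulate_trait_matrix(
    50, 15,
    list(list(size = 14, concentration = 500, direction = dirv),
         list(size = 12, concentration = 500, direction = -dirv)),
    seed = 11)
  fit <- fit_directional_mixture(tm$z, K = 10, n_starts = 15, seed = 3)
  expect_equal(fit$K_effective, 2)
  lab1 <- fit$labels[tm$labels == "1"]
  lab2 <- fit$labels[tm$labels == "2"]
  expect_equal(length(unique(lab1)), 1)
  expect_equal(length(unique(lab2)), 1)
  expect_false(unique(lab1) == unique(lab2))
})

test_that("row permutation and positive row rescaling leave labels intact", {
  tm <- simulate_trait_matrix(30, 10,
                              list(list(size = 10, concentration = 300),
                                   list(size = 8, concentration = 300)),
                              seed = 6)
  fit <- fit_directional_mixture(tm$z, K = 6, n_starts = 10, seed = 4)
  perm <- withr::with_seed(2, sample.int(30))
  fit_p <- fit_directional_mixture(tm$z[perm, ], K = 6, n_starts = 10, seed = 4)
  # same partition up to cluster relabelling
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(fit$labels[perm], fit_p$labels), 1)
  scaled <- tm$z * withr::with_seed(3, runif(30, 0.2, 5))
  fit_s <- fit_directional_mixture(scaled, K = 6, n_starts = 10, seed = 4)
  expect_equal(unname(fit_s$labels), unname(fit$labels))
})

test_that("EM log-likelihood never decreases and noise grows as signal fades", {
  occupancy <- vapply(c(2000, 50, 5), function(conc) {
    tm <- simulate_trait_matrix(36, 12,
                                list(list(size = 12, concentration = conc),
                                     list(size = 12, concentration = conc)),
                                seed = 7)
    fit <- fit_directional_mixture(tm$z, K = 8, n_starts = 10, seed = 5)
    expect_true(all(diff(fit$loglik_trace) >=
                      -1e-6 * (abs(fit$loglik_trace[-length(fit$loglik_trace)]) + 1)))
    mean(fit$labels == "noise")
  }, numeric(1))
  # 12 of 36 rows are true noise, so occupancy starts near 1/3 under strong
  # signal and approaches 1 when the bundles dissolve into the background
  expect_true(all(diff(occupancy) >= 0))
  expect_lt(occupancy[1], 0.45)
  expect_gt(occupancy[3], 0.8)
})

test_that("per-cluster MR reduces to the primary IVW on one full cluster", {
  h <- make_harmonised(14, seed = 19)
  labels <- setNames(rep("1", 14), h$variant_id)
  est <- cluster_mr(h, labels, "1")
  expect_equal(est$beta, mr_ivw(h)$beta)
  expect_equal(est$cluster_size, 14)
  expect_error(cluster_mr(h, labels, "2"), "no members")
})

test_that("cluster-restricted MR recovers distinct planted ratios", {
  withr::with_seed(23, {
    n <- 24
    gamma <- runif(n, 0.05, 0.12)
    s_Gamma <- rep(0.01, n)
    truth <- rep(c(-0.5, 0.3), each = 12)
    h <- make_harmonised(n, gamma = gamma, s_gamma = rep(0.004, n),
                         Gamma = truth * gamma + rnorm(n, 0, s_Gamma),
                         s_Gamma = s_Gamma)
    labels <- setNames(rep(c("1", "2"), each = 12), h$variant_id)
    e1 <- cluster_mr(h, labels, "1")
    e2 <- cluster_mr(h, labels, "2")
    expect_lt(abs(e1$beta - (-0.5)), 3 * e1$se)
    expect_lt(abs(e2$beta - 0.3), 3 * e2$se)
    expect_equal(e1$cluster_size, 12)
  })
})

test_that("a 14-variant cluster among 26 instruments yields one estimate", {
  h <- make_harmonised(26, seed = 29)
  labels <- setNames(c(rep("1", 14), rep("noise", 12)), h$variant_id)
  est <- cluster_mr(h, labels, "1")
  expect_equal(est$cluster_size, 14)
  expect_equal(est$n_snps, 14L)
  expect_equal(est$beta, mr_ivw(h[1:14, ])$beta)
})

test_that("mixture tidiers expose labels, probabilities and fit summary", {
  tm <- simulate_trait_matrix(20, 8, list(list(size = 10, concentration = 300)),
                              seed = 12)
  fit <- fit_directional_mixture(tm$z, K = 4, n_starts = 8, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 20)
  expect_true(all(abs(td$noise_prob + td$top_cluster_prob) <= 1 + 1e-8))
  gl <- glance(fit)
  expect_equal(gl$K, 4)
  expect_s3_class(autoplot(fit), "ggplot")
})
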