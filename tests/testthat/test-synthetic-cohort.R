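test_that("block covariance reproduces independence, single-block, and PSD cases", {
  expect_equal(plant_block_covariance(4, 2, 0, 0), diag(4),
               ignore_attr = TRUE)
  S1 <- plant_block_covariance(4, 1, 0.6)
  expect_true(all(S1[upper.tri(S1)] == 0.6))
  expect_equal(diag(S1), rep(1, 4), ignore_attr = TRUE)
  S <- plant_block_covariance(264, 8, 0.5, 0.1)
  expect_true(isSymmetric(S))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(plant_block_covariance(4, 2, 0.1, 0.5), "intra_r")
})

test_that("generated series are deterministic and converge to the target correlation", {
  cfg <- cohort_config(n_group_a = 2, n_group_b = 2, n_nodes = 12,
                       n_timepoints = 5000, n_modules = 3,
                       intra_module_r = 0.6, inter_module_r = 0,
                       topology_gap = -0.2, seed = 42)
  truth <- synthetic_truth(cfg)
  p1 <- generate_timeseries(truth)
  p2 <- generate_timeseries(truth)
  expect_identical(p1$subjects, p2$subjects)

  R <- cor(p1$subjects[[1]])  # group A subject, intra_r = 0.6
  module <- rep(1:3, each = 4)
  same <- outer(module, module, "==") & upper.tri(R)
  expect_lt(max(abs(R[same] - 0.6)), 0.05)

  # independence case: identity covariance
  cfg0 <- cohort_config(n_group_a = 2, n_group_b = 2, n_nodes = 12,
                        n_timepoints = 5000, n_modules = 3,
                        intra_module_r = 1e-9, inter_module_r = 0,
                        topology_gap = 1e-10, seed = 7)
  R0 <- cor(generate_timeseries(synthetic_truth(cfg0))$subjects[[1]])
  expect_lt(mean(abs(R0[upper.tri(R0)])), 0.1)
})

test_that("gray-matter patches expose archetype structure and the zero-variance rule", {
  cfg <- cohort_config(n_group_a = 2, n_group_b = 2, n_nodes = 40,
                       n_modules = 4, n_timepoints = 100,
                       zero_var_fraction = 0.05, gm_noise_sd = 0.3, seed = 3)
  ps <- generate_gm_patches(synthetic_truth(cfg))
  expect_length(ps$zero_variance_nodes, round(0.05 * 40))
  expect_true(all(apply(ps$patches[[1]][, ps$zero_variance_nodes], 2, sd) == 0))

  # noiseless patches: nodes sharing an archetype are identical -> similarity 1
  cfg0 <- cohort_config(n_group_a = 2, n_group_b = 2, n_nodes = 8,
                        n_modules = 2, n_timepoints = 100,
                        zero_var_fraction = 0, gm_noise_sd = 0, seed = 5)
  ps0 <- generate_gm_patches(synthetic_truth(cfg0))
  P <- ps0$patches[[1]]
  expect_equal(cube_similarity(P[, 1], P[, 2]), 1, tolerance = 1e-12)
})

test_that("clinical scores follow the planted linear model on nodal efficiency", {
  cfg <- cohort_config(n_group_a = 3, n_group_b = 3, n_nodes = 10,
                       n_modules = 2, n_timepoints = 100,
                       clinical_beta = c(n003 = 1), clinical_noise_sd = 0,
                       seed = 9)
  truth <- synthetic_truth(cfg)
  E <- matrix(runif(6 * 10), 6, 10,
              dimnames = list(sprintf("sub%02d", 1:6), sprintf("n%03d", 1:10)))
  clin <- generate_clinical(truth, E, noise_sd = 0)
  expect_equal(clin$tremor, unname(E[, "n003"]))  # one-hot beta, no noise

  beta <- c(n001 = 2, n004 = -3)
  clin2 <- generate_clinical(truth, E, beta = beta, noise_sd = 0)
  fit <- suppressWarnings(fit_mlrm(E[, names(beta)], clin2$tremor))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit$fit)[-1]), unname(beta), tolerance = 1e-8)
})

test_that("clinical noise calibrated for population R^2 = 0.8 recovers R^2 in [0.6, 0.95]", {
  # simulation oracle at n = 16: R^2 of the true-predictor fit across seeds
  set.seed(101)
  r2s <- replicate(100, {
    E <- matrix(rnorm(16 * 5, mean = 0.5, sd = 0.1), 16, 5)
    beta <- c(8, -6, 5, -4, 3)
    lp <- as.numeric(E %*% beta)
    y <- lp + rnorm(16, sd = sd(lp) * sqrt((1 - 0.8) / 0.8))
    summary(lm(y ~ E))$r.squared
  })
  expect_gt(mean(r2s >= 0.6 & r2s <= 0.95), 0.8)
  expect_true(median(r2s) > 0.6 && median(r2s) < 0.95)
})

test_that("a larger topology gap widens the expected AUC local-efficiency group difference", {
  grid <- seq(0.1, 0.3, by = 0.1)
  gap_diff <- function(gap, seed) {
    cfg <- cohort_config(n_group_a = 4, n_group_b = 4, n_nodes = 32,
                         n_timepoints = 150, n_modules = 4,
                         intra_module_r = 0.6, inter_module_r = 0.05,
                         topology_gap = gap, seed = seed)
    panel <- generate_timeseries(synthetic_truth(cfg))
    aucs <- vapply(panel$subjects, function(X) {
      pr <- efficiency_profile(cor(X), grid)
      pr$auc_e_loc
    }, numeric(1))
    mean(aucs[panel$group == "A"]) - mean(aucs[panel$group == "B"])
  }
  seeds <- 1:20
  d_small <- vapply(seeds, function(s) gap_diff(-0.15, s), numeric(1))
  d_large <- vapply(seeds, function(s) gap_diff(-0.40, s), numeric(1))
  expect_gt(mean(d_large), mean(d_small))
  expect_gt(mean(d_small), 0)  # planted direction: patients lower
})

test_that("generated matrices satisfy downstream preconditions", {
  cfg <- small_cohort(seed = 12)
  truth <- synthetic_truth(cfg)
  panel <- generate_timeseries(truth)
  expect_true(all(vapply(panel$subjects, function(X) all(is.finite(X)), logical(1))))
  for (S in list(truth$target_covariance_a, truth$target_covariance_b)) {
    expect_true(isSymmetric(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_equal(unname(diag(S)), rep(1, nrow(S)))
  }
})
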