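test_that("noise-free piecewise data collapse the estimator to exact least squares", {
  scen <- sim_scenario("pmm", n_subjects = 50, seed = 2,
                       truth = list(B = diag(rep(1e-8, 4)), sigma = 1e-4))
  dat <- simulate_longdata(scen)
  fit <- trajmix_fit(dat, model_spec(2),
                     saem_control(seed = 3, compute_se = FALSE,
                                  compute_loglik = FALSE))
  expect_lt(max(abs(fit$theta[1:4] - c(-1.21, -0.03, -0.32, -3))), 1e-2)
})

test_that("fits are bit-reproducible under a fixed seed", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 30, seed = 6))
  f1 <- trajmix_fit(dat, model_spec(2), quick_control(seed = 4))
  f2 <- trajmix_fit(dat, model_spec(2), quick_control(seed = 4))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$trace, f2$trace)
  f3 <- trajmix_fit(dat, model_spec(2), quick_control(seed = 5))
  expect_false(identical(f3$theta, f1$theta))
})

test_that("the estimated covariance respects the model's sparsity mask exactly", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 40, seed = 8))
  fit <- trajmix_fit(dat, model_spec(2), quick_control(seed = 9))
  B <- fit$estimates$B
  off <- abs(B[upper.tri(B)])
  ## only the slope1-slope2 covariance may be non-zero
  expect_identical(unname(B[1, 2:4]), c(0, 0, 0))
  expect_identical(unname(B[2, 4]), 0)
  expect_identical(unname(B[3, 4]), 0)

  dats <- simulate_longdata(sim_scenario("smm", n_subjects = 40, seed = 8))
  fits <- trajmix_fit(dats, model_spec(1), quick_control(seed = 9))
  expect_equal(dim(fits$estimates$B), c(2L, 2L))
})

test_that("Wald p-values follow the normal reference distribution", {
  expect_equal(unname(wald_pvalues(0, 1)), 1)
  expect_equal(unname(wald_pvalues(1.959964, 1)), 0.05, tolerance = 1e-6)
  expect_gt(unname(wald_pvalues(0.5, 1e6 * 0.5)), 0.999)
  expect_true(is.na(wald_pvalues(1, NA)))
  expect_true(is.na(wald_pvalues(1, 0)))
})

test_that("coefficient of variation matches the reported convention", {
  ## 100 * SE / |estimate|, printed to one decimal
  expect_equal(sprintf("%.1f", cv_percent(1.07196, 4.7e-2)), "4.4")
  expect_equal(sprintf("%.1f", cv_percent(0.146, 0.0071)), "4.9")
  expect_true(all(cv_percent(c(-2, 3), c(1, 1)) >= 0))
})

test_that("empirical Bayes estimates recover subject effects and center at zero", {
  ## strong-signal regime: modes pin down each subject's random effects
  B <- diag(c(0.5, 0.01, 0.05, 0.5)^2)
  scen <- sim_scenario("pmm", n_subjects = 40, seed = 12,
                       truth = list(B = B, sigma = 1e-4))
  dat <- simulate_longdata(scen)
  fit <- trajmix_fit(dat, model_spec(2),
                     saem_control(seed = 13, compute_se = FALSE,
                                  compute_loglik = FALSE))
  eta_hat <- ranef_estimates(fit, type = "mode")
  eta_true <- attr(dat, "truth")$eta
  ## compare subject-specific parameter totals (fixed + random), which are
  ## what the data identify
  psi_hat <- subject_parameters(fit, type = "mode")
  psi_true <- sweep(eta_true, 2, c(-1.21, -0.03, -0.32, -3), "+")
  expect_lt(max(abs(psi_hat[, 1] - psi_true[, 1])), 1e-2)
  expect_lt(max(abs(psi_hat[, 3] - psi_true[, 3])), 1e-2)
  ## shrinkage centering at realistic noise
  dat2 <- simulate_longdata(sim_scenario("smm", n_subjects = 150, seed = 14))
  fit2 <- trajmix_fit(dat2, model_spec(1),
                      saem_control(K1 = 150, K2 = 150, seed = 15,
                                   compute_se = FALSE, compute_loglik = FALSE))
  em <- colMeans(ranef_estimates(fit2, type = "mean", n_iter = 100))
  expect_true(all(abs(em) < 3 * c(1.46, 0.51) / sqrt(150)))
})

test_that("a non-finite likelihood at the initials raises an actionable error", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 10, seed = 1))
  spec <- model_spec(2, start = c(1e300, 0, 1e300, -3))  # squared residuals overflow
  expect_error(suppressWarnings(trajmix_fit(dat, spec, quick_control())), "start")
})

test_that("small-iteration traces expose the SA parameter path", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 25, seed = 20))
  fit <- trajmix_fit(dat, model_spec(2), quick_control(seed = 21))
  expect_equal(nrow(fit$trace), 140)
  expect_true(all(is.finite(fit$trace)))
  expect_true(all(c("alpha.changepoint", "omega2.slope1", "sigma2") %in%
                    colnames(fit$trace)))
})
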