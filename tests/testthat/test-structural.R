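test_that("sigmoidal mean satisfies its closed-form identities", {
  ## intercept and half-decline identities, plus a hand-computed point
  expect_equal(smm_mean(0, -1.03, 0.37, 4, 1.69), -1.03)
  expect_equal(smm_mean(4, -1.03, 0.37, 4, 1.69), (-1.03 + 0.37) / 2)
  expect_equal(smm_mean(8, -1.03, 0.37, 4, 1.69),
               0.37 + (-1.03 - 0.37) / (1 + 2^1.69), tolerance = 1e-12)
  expect_equal(smm_mean(8, -1.03, 0.37, 4, 1.69), 0.0388, tolerance = 1e-3)
  expect_error(smm_mean(1, 0, 1, -1, 1), "midpoint")
  expect_error(smm_mean(-1, 0, 1, 2, 1), "time-before-zero")
})

test_that("sigmoidal mean declines monotonically toward time zero", {
  set.seed(42)
  s <- seq(0, 24, by = 0.25)
  for (rep in 1:20) {
    last <- runif(1, -3, 0); first <- last + runif(1, 0.5, 3)
    mid <- runif(1, 1, 10); hill <- runif(1, 0.3, 4)
    f <- smm_mean(s, last, first, mid, hill)
    ## increasing in time-before-zero = declining toward zero
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("abrupt piecewise mean is continuous and matches hand evaluation", {
  expect_equal(pmm_abrupt_mean(0, -1.21, -0.03, -0.32, -3), -1.21)
  expect_equal(pmm_abrupt_mean(-5, -1.21, -0.03, -0.32, -3), -0.19,
               tolerance = 1e-12)
  expect_equal(pmm_abrupt_mean(-1, -1.21, -0.03, -0.32, -3), -0.89,
               tolerance = 1e-12)
  ## continuity at the changepoint from either branch
  eps <- 1e-9
  expect_equal(pmm_abrupt_mean(-3 - eps, -1.21, -0.03, -0.32, -3),
               pmm_abrupt_mean(-3 + eps, -1.21, -0.03, -0.32, -3),
               tolerance = 1e-7)
})

test_that("transition cubic solves the four boundary constraints", {
  tc <- transition_cubic(-1.21, -0.03, -0.32, -3, 2)
  a <- unname(tc$coefficients)
  g <- function(t) a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3
  gp <- function(t) a[2] + 2 * a[3] * t + 3 * a[4] * t^2
  expect_equal(gp(-3), -0.03, tolerance = 1e-10)
  expect_equal(gp(-1), -0.32, tolerance = 1e-10)
  expect_equal(unname(g(-3)), tc$lambda + (-0.03) * (-3), tolerance = 1e-10)
  expect_equal(unname(g(-1)), -1.21 + (-0.32) * (-1), tolerance = 1e-10)
  ## equal slopes degenerate to the straight line
  tc2 <- transition_cubic(-1.0, -0.2, -0.2, -4, 3)
  expect_equal(unname(tc2$coefficients[c("a2", "a3")]), c(0, 0),
               tolerance = 1e-10)
  expect_error(transition_cubic(-1, -0.1, -0.2, -3, 0), "abrupt")
})

test_that("transition cubic agrees with an independent Hermite-form solve", {
  set.seed(11)
  for (rep in 1:10) {
    p <- list(last = runif(1, -2, 0), s1 = runif(1, -0.2, 0.1),
              s2 = runif(1, -0.6, -0.1), cp = runif(1, -8, -2),
              v = runif(1, 0.5, 4))
    got <- transition_cubic(p$last, p$s1, p$s2, p$cp, p$v)$coefficients
    want <- hermite_cubic_oracle(p$last, p$s1, p$s2, p$cp, p$v)
    expect_equal(unname(got), want, tolerance = 1e-8)
  }
})

test_that("smooth piecewise mean is C1 and reduces to the abrupt model", {
  tt <- seq(-12, 0, by = 1e-2)
  p <- c(-1.21, -0.03, -0.32, -3)
  expect_identical(pmm_smooth_mean(tt, p[1], p[2], p[3], p[4], 0),
                   pmm_abrupt_mean(tt, p[1], p[2], p[3], p[4]))
  ## uniform convergence as the window shrinks
  expect_lt(max(abs(pmm_smooth_mean(tt, p[1], p[2], p[3], p[4], 1e-6) -
                      pmm_abrupt_mean(tt, p[1], p[2], p[3], p[4]))), 1e-4)
  ## value and slope continuity across the window boundaries
  grid <- seq(-3.05, -0.95, by = 1e-4)
  f <- pmm_smooth_mean(grid, p[1], p[2], p[3], p[4], 2)
  expect_lt(max(abs(diff(f))), 1e-3)          # no value jumps at step 1e-4
  expect_lt(max(abs(diff(diff(f)))), 1e-6)    # no slope jumps
  ## the lambda constraint makes the two extended lines intersect at the
  ## middle of the window; the cubic passes v*(slope2 - slope1)/8 from that
  ## intersection (closed form, checked against the polynomial solve)
  lambda <- p[1] + (p[3] - p[2]) * (p[4] + 1)
  mid_t <- p[4] + 1
  expect_equal(lambda + p[2] * mid_t, p[1] + p[3] * mid_t, tolerance = 1e-12)
  v_star <- lambda + p[2] * mid_t
  expect_equal(pmm_smooth_mean(mid_t, p[1], p[2], p[3], p[4], 2),
               v_star + 2 * (p[3] - p[2]) / 8, tolerance = 1e-10)
  a <- unname(transition_cubic(p[1], p[2], p[3], p[4], 2)$coefficients)
  expect_equal(a[1] + a[2] * mid_t + a[3] * mid_t^2 + a[4] * mid_t^3,
               v_star + 2 * (p[3] - p[2]) / 8, tolerance = 1e-10)
})

test_that("evaluators are deterministic and vectorisation-exact", {
  tt <- seq(-10, 0, by = 0.37)
  batch <- pmm_smooth_mean(tt, -1.2, -0.05, -0.4, -4, 1.5)
  point <- vapply(tt, function(t1) pmm_smooth_mean(t1, -1.2, -0.05, -0.4, -4, 1.5),
                  numeric(1))
  expect_identical(batch, point)
  s <- seq(0, 20, by = 0.41)
  batch <- smm_mean(s, -1, 0.4, 3, 1.7)
  point <- vapply(s, function(s1) smm_mean(s1, -1, 0.4, 3, 1.7), numeric(1))
  expect_identical(batch, point)
})

test_that("parameter linking applies covariates and the random-effect mask", {
  link <- param_link(alpha = c(-1, 0.4, 4, 1.7), random = c(TRUE, TRUE, FALSE, FALSE),
                     B = diag(2), sigma = 0.3)
  expect_equal(link_parameters(link), c(-1, 0.4, 4, 1.7))
  link2 <- param_link(alpha = c(-1, 0.4, 4, 1.7),
                      beta = list(par3 = c(x = 0.2)),
                      random = c(TRUE, TRUE, FALSE, FALSE),
                      B = diag(2), sigma = 0.3)
  expect_equal(link_parameters(link2, covariates = list(x = 1))[3], 4.2)
  ## a random effect supplied for a marginal parameter is rejected
  expect_error(link_parameters(link, eta = c(0.1, 0.2, 0.3, 0)),
               "without\\s+.*random effect|random effects supplied")
  expect_error(link_parameters(link2, covariates = list(), eta = c(0, 0)),
               "missing covariate")
  ## eta enters only the random parameters
  expect_equal(link_parameters(link, eta = c(0.5, -0.5)),
               c(-0.5, -0.1, 4, 1.7))
})
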