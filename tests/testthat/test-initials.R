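flat_table <- function(value = 0.7) {
  long_data(data.frame(ID = rep(1:20, each = 6),
                       time = rep(seq(-10, 0, by = 2), 20),
                       y = value),
            "ID", "y", "time")
}

test_that("sigmoidal initials: flat and exactly linear data trigger the 300 rule", {
  st <- smm_start(flat_table())
  expect_equal(unname(st$start[1]), 0.7)
  expect_equal(unname(st$start[2]), 0.7)
  expect_equal(unname(st$start[3]), 300)

  lin <- long_data(data.frame(ID = rep(1:20, each = 6),
                              time = rep(seq(-10, 0, by = 2), 20),
                              y = rep(0.5 + 0.1 * seq(-10, 0, by = 2), 20)),
                   "ID", "y", "time")
  expect_equal(unname(smm_start(lin)$start[3]), 300)
  expect_error(smm_start(flat_table()[flat_table()$time == 0, ]), "constant")
})

test_that("sigmoidal initials recover level bands and curvature on scenario data", {
  dat <- simulate_longdata(sim_scenario("smm", n_subjects = 200, seed = 1))
  st <- smm_start(dat)
  expect_equal(unname(st$start[3]), 2)          # curved, not nearly linear
  expect_lt(abs(st$start[1] - (-1.03)), 0.5)    # last level near asymptote
  expect_lt(abs(st$start[2] - 0.37), 0.5)       # first level near asymptote
  expect_true(st$start[4] %in% c(0.5, 1.05))
  ## oracle: band means computed directly on the table
  p <- ecdf(dat$time)(dat$time)
  expect_equal(unname(st$start[1]),
               mean(dat$outcome[p >= 0.925 & p <= 0.975]))
  expect_equal(unname(st$start[2]),
               mean(dat$outcome[p >= 0.025 & p <= 0.075]))
  ## deterministic
  expect_identical(st, smm_start(dat))
})

test_that("piecewise initials: degenerate single-slope data", {
  lin <- long_data(data.frame(ID = rep(1:20, each = 11),
                              time = rep(seq(-10, 0, by = 1), 20),
                              y = rep(0.5 - 0.21 * seq(-10, 0, by = 1) * -1, 20)),
                   "ID", "y", "time")
  st <- pmm_start(lin)
  expect_equal(unname(st$start[2]), unname(st$start[3]), tolerance = 1e-6)
  rng <- range(lin$time)
  expect_gt(unname(st$start[4]), rng[1])
  expect_lt(unname(st$start[4]), rng[2])
})

test_that("piecewise initials find an exact two-phase break at the 60th percentile", {
  tt <- seq(-10, 0, length.out = 100)
  cp_true <- unname(quantile(tt, 0.6, type = 7))
  y <- pmm_abrupt_mean(tt, -1.21, -0.03, -0.32, cp_true)
  dat <- long_data(data.frame(ID = rep(1:5, each = 100), time = rep(tt, 5),
                              y = rep(y, 5)),
                   "ID", "y", "time")
  st <- pmm_start(dat)
  expect_equal(unname(st$start[4]), cp_true, tolerance = 1e-8)
  ## slope starts match an independent least-squares oracle on each side
  pre <- tt < cp_true
  o1 <- unname(coef(lm(y[pre] ~ tt[pre]))[2])
  o2 <- unname(coef(lm(y[!pre] ~ tt[!pre]))[2])
  expect_equal(unname(st$start[2]), o1, tolerance = 1e-8)
  expect_equal(unname(st$start[3]), o2, tolerance = 1e-8)
  expect_lt(abs(st$start[2] - (-0.03)), 0.02)
  expect_lt(abs(st$start[3] - (-0.32)), 0.02)
})

test_that("piecewise initials land near the generative changepoint on scenario data", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 200, seed = 1))
  st <- pmm_start(dat)
  expect_lt(abs(st$start[4] - (-3)), 2)
  expect_identical(st, pmm_start(dat))
})

test_that("user-supplied starts bypass the heuristics verbatim", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 30, seed = 2))
  spec <- model_spec(2, start = c(-1.2, -0.05, -0.3, -2.5))
  st <- auto_start(dat, spec)
  expect_equal(unname(st$start), c(-1.2, -0.05, -0.3, -2.5))
  expect_equal(st$provenance, rep("user", 4))
  expect_error(model_spec(2, start = c(1, 2, 3)), "length 4")
})
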