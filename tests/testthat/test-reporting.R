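## one small fitted model with a covariate, shared across reporting tests
fit_with_covariate <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      set.seed(55)
      n <- 100
      x <- as.numeric(1:n)          # covariate values 1..100 across subjects
      rows <- lapply(1:n, function(i) {
        tt <- seq(-8, 0, by = 1)
        y <- pmm_abrupt_mean(tt, -1.2 - 0.002 * x[i], -0.03, -0.32, -3) +
          rnorm(length(tt), 0, 0.15)
        data.frame(ID = i, time = tt, y = y, grp = x[i])
      })
      dat <- long_data(do.call(rbind, rows), "ID", "y", "time",
                       covariates = "grp")
      val <<- trajmix_fit(dat, model_spec(2, predictor_par1 = "grp"),
                          quick_control(seed = 56))
    }
    val
  }
})

test_that("marginal trajectory equals the structural curve at the fixed effects", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 30, seed = 40))
  fit <- trajmix_fit(dat, model_spec(2), quick_control(seed = 41))
  tab <- marginal_trajectory(fit, times = seq(-12, 0, by = 1))
  al <- fit$estimates$alpha
  expect_equal(tab$pred,
               pmm_abrupt_mean(tab$time, al[1], al[2], al[3], al[4]))
})

test_that("sigmoidal marginal trajectory honours the half-decline identity", {
  dat <- simulate_longdata(sim_scenario("smm", n_subjects = 60, seed = 42))
  fit <- trajmix_fit(dat, model_spec(1),
                     saem_control(K1 = 100, K2 = 120, seed = 43,
                                  compute_se = FALSE, compute_loglik = FALSE))
  al <- fit$estimates$alpha
  t_half <- fit$shift - al[["midpoint"]]
  tab <- marginal_trajectory(fit, times = t_half)
  expect_equal(tab$pred, unname((al[["last.level"]] + al[["first.level"]]) / 2),
               tolerance = 1e-10)
})

test_that("group contrasts use type-7 percentiles and honour overrides", {
  fit <- fit_with_covariate()
  tab <- group_contrast(fit, "grp")
  expect_equal(sort(unique(tab$value)), c(10.9, 90.1))
  tab2 <- group_contrast(fit, "grp", probs = c(0.25, 0.75))
  expect_equal(sort(unique(tab2$value)),
               unname(quantile(1:100, c(0.25, 0.75), type = 7)))
  expect_error(group_contrast(fit, "nope"), "not a covariate")
  ## a zero covariate effect makes the two trajectories coincide
  fit0 <- fit
  fit0$state$b[[1]]["grp"] <- 0
  tab0 <- group_contrast(fit0, "grp")
  sp <- split(tab0$pred, tab0$group)
  expect_equal(unname(sp[[1]]), unname(sp[[2]]))
})

test_that("binary group variables are contrasted at their two levels", {
  set.seed(60)
  rows <- lapply(1:40, function(i) {
    g <- i %% 2
    tt <- seq(-6, 0, by = 1)
    data.frame(ID = i, time = tt,
               y = pmm_abrupt_mean(tt, -1 - 0.3 * g, -0.03, -0.3, -3) +
                 rnorm(length(tt), 0, 0.1),
               g = g)
  })
  dat <- long_data(do.call(rbind, rows), "ID", "y", "time", covariates = "g")
  fit <- trajmix_fit(dat, model_spec(2, predictor_par1 = "g"),
                     quick_control(seed = 61))
  tab <- group_contrast(fit, "g")
  expect_equal(sort(unique(tab$value)), c(0, 1))
})

test_that("profiles must cover every model covariate", {
  fit <- fit_with_covariate()
  expect_error(marginal_trajectory(fit, profile = list(other = 1)),
               "missing a value for covariate 'grp'")
  tab <- marginal_trajectory(fit, profile = list(grp = 50))
  expect_equal(nrow(tab), length(seq(floor(min(fit$setup$t_raw)),
                                     ceiling(max(fit$setup$t_raw)))))
})

test_that("spaghetti plots sample deterministically and label axes by raw names", {
  dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 50, seed = 45))
  sp <- spaghetti_plot(dat, n_shown = 70, seed = 3)
  expect_length(sp$ids, 50)                      # fewer subjects than requested
  big <- simulate_longdata(sim_scenario("pmm", n_subjects = 90, seed = 46))
  s1 <- spaghetti_plot(big, n_shown = 70, seed = 3)
  s2 <- spaghetti_plot(big, n_shown = 70, seed = 3)
  expect_identical(s1$ids, s2$ids)
  expect_length(s1$ids, 70)
  expect_equal(s1$plot$labels$x, "time")
  expect_equal(s1$plot$labels$y, "outcome")
  s3 <- spaghetti_plot(big, seed = 3, xlabel = "Years before death")
  expect_equal(s3$plot$labels$x, "Years before death")
})

test_that("the text summary carries the documented tables and timing line", {
  fit <- fit_with_covariate()
  txt <- render_summary(fit)
  expect_true(any(grepl("Variance of random effects", txt)))
  header <- txt[grep("Variance of random effects", txt) + 1]
  expect_true(grepl("Parameter", header) && grepl("Estimate", header) &&
                grepl("SE", header) && grepl("CV\\(%\\)", header))
  expect_true(any(grepl("^The program took [0-9.]+ seconds$", txt)))
  expect_true(any(grepl("omega2.last.level", txt)))
  expect_true(any(grepl("cov.slope1.slope2", txt)))
  expect_true(any(grepl("beta.grp\\(last.level\\)", txt)))
  expect_output(print(fit), "The program took")
})

test_that("convergence plots build from the stored trace", {
  fit <- fit_with_covariate()
  p <- convergence_plot(fit)
  expect_s3_class(p, "ggplot")
})
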