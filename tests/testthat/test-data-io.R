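make_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("long CSV data load, parse and round-trip exactly", {
  df <- data.frame(ID = c(1000, 1000, 1001, 1001),
                   time = c(-10.00, -9.08, -5.5, -3.25),
                   cognition = c(0.45, 0.27, 0.1, -0.4),
                   ageDeath = c(91, 91, 88, 88))
  path <- make_csv(df)
  ld <- read_long_data(path, id = "ID", outcome = "cognition", time = "time")
  expect_s3_class(ld, "trajmix_data")
  expect_equal(ld$time[1], -10.0)
  expect_equal(ld$cognition[1], 0.45)
  expect_equal(attr(ld, "n_subjects"), 2)
  expect_equal(attr(ld, "n_obs_per_subject"), c(2L, 2L))
  ## round trip preserves all retained rows and values
  out <- tempfile(fileext = ".csv")
  write_long_data(ld, out)
  ld2 <- read_long_data(out, id = "ID", outcome = "cognition", time = "time")
  expect_equal(as.data.frame(ld2), as.data.frame(ld), ignore_attr = TRUE)
})

test_that("missing columns and degenerate files raise informative errors", {
  df <- data.frame(ID = 1, time = -1, cognition = 0.2)
  path <- make_csv(df)
  expect_error(read_long_data(path, id = "ID", outcome = "cognitoin", time = "time"),
               "cognitoin")
  empty <- tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_long_data(empty, id = "ID", outcome = "y", time = "t"))
  expect_error(read_long_data(tempfile(), id = "ID", outcome = "y", time = "t"),
               "not found")
  allna <- data.frame(ID = c(1, 2), time = c(NA_real_, NA_real_), y = c(1, 2))
  expect_error(long_data(allna, "ID", "y", "time"), "no usable rows")
})

test_that("rows with missing values are dropped with an accounted count", {
  df <- data.frame(ID = c(1, 1, 1, 2, 2),
                   time = c(-3, -2, NA, -4, -1),
                   y = c(0.1, NA, 0.3, 0.2, 0.5))
  expect_message(ld <- long_data(df, "ID", "y", "time"), "dropped 2 of 5")
  expect_equal(attr(ld, "n_dropped") + nrow(ld), nrow(df))
  expect_equal(nrow(ld), 3)
})

test_that("centered covariates are derived correctly", {
  df <- data.frame(ID = 1, time = -1, y = 0, ageDeath = 91)
  ld <- long_data(df, "ID", "y", "time")
  ld <- center_covariate(ld, "ageDeath", 90)
  expect_equal(ld$ageDeath90, 1)
  ld <- center_covariate(ld, "ageDeath", 0, new_name = "copy")
  expect_equal(ld$copy, ld$ageDeath)
  ld$ageDeath[1] <- 90
  expect_equal(center_covariate(ld, "ageDeath", 90)$ageDeath90, 0)
  ld$chr <- "a"
  expect_error(center_covariate(ld, "chr", 0), "not numeric")
})

test_that("time-varying covariates are rejected", {
  df <- data.frame(ID = c(1, 1), time = c(-2, -1), y = c(0, 1), x = c(3, 4))
  expect_error(long_data(df, "ID", "y", "time", covariates = "x"),
               "varies within subject")
})

test_that("data warnings fire at the documented thresholds and never raise", {
  small <- do.call(rbind, lapply(1:30, function(i) {
    data.frame(ID = i, time = -(4:0), y = rnorm(5))
  }))
  w <- data_warnings(long_data(small, "ID", "y", "time"))
  expect_true(any(grepl("small sample", w)))

  big <- do.call(rbind, lapply(1:1200, function(i) {
    data.frame(ID = i, time = -(4:0), y = rnorm(5), x1 = i %% 2)
  }))
  spec1 <- model_spec(2, predictor_all = "x1")
  expect_length(data_warnings(long_data(big, "ID", "y", "time"), spec1), 0)

  mid <- do.call(rbind, lapply(1:100, function(i) {
    cbind(data.frame(ID = i, time = -(4:0), y = rnorm(5)),
          as.data.frame(as.list(stats::setNames(rep(i %% 3, 8), paste0("x", 1:8)))))
  }))
  spec8 <- model_spec(2, predictor_all = paste0("x", 1:8))
  w <- data_warnings(long_data(mid, "ID", "y", "time"), spec8)
  expect_true(any(grepl("many fixed effects", w)))

  dup <- data.frame(ID = c(1, 1), time = c(-1, -1), y = c(0, 1))
  w <- data_warnings(long_data(dup, "ID", "y", "time"))
  expect_true(any(grepl("duplicate", w)))
})
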