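#' Automated initial values for the sigmoidal mixed model
#'
#' Data-driven starting values for the four main SMM parameters. The last and
#' first levels are the mean outcome over the observations whose time lies in
#' a narrow percentile band around the 95th and 5th percentiles of the time
#' distribution (a point percentile has measure zero, so a band of half-width
#' `band` percentile ranks is used). The midpoint start is 300 when the pooled
#' trajectory is nearly linear and 2 otherwise; "nearly linear" means the
#' pooled simple linear trend has R-squared of at least `linear_r2`, or the
#' mid-band mean lies within `linear_frac` of the outcome range from the
#' linear interpolation of the two extreme band means. The Hill-slope start is
#' picked from the candidate pair {0.5, 1.05} by pooled residual sum of
#' squares of the four-parameter curve, preferring 1.05 on ties.
#'
#' The midpoint and Hill slope are expressed on the positive time-before-zero
#' scale used internally by the SMM.
#'
#' @param data A `trajmix_data` object (see [long_data()]).
#' @param band Percentile-rank half-width of the level bands (default 0.025).
#' @param linear_r2,linear_frac Thresholds of the near-linearity rule.
#' @return A `trajmix_start` object: `start` (named 4-vector) with a
#'   per-entry `provenance` attribute.
#' @export
smm_start <- function(data, band = 0.025, linear_r2 = 0.99, linear_frac = 0.05) {
  tv <- data[[attr(data, "time_col")]]
  y <- data[[attr(data, "outcome_col")]]
  if (length(unique(tv)) < 2) {
    stop("smm_start(): the time column is constant; initial values need at least two distinct times",
         call. = FALSE)
  }
  p <- stats::ecdf(tv)(tv)
  band_mean <- function(center) {
    sel <- p >= center - band & p <= center + band
    if (!any(sel)) sel <- which.min(abs(p - center))
    list(y = mean(y[sel]), t = mean(tv[sel]))
  }
  hi <- band_mean(0.95)   # times nearest zero (e.g. death): last level
  lo <- band_mean(0.05)   # most remote times: first level
  mid <- band_mean(0.50)

  linear <- .nearly_linear(tv, y, lo, mid, hi, linear_r2, linear_frac)
  midpoint <- if (linear) 300 else 2

  ## internal positive time-before-zero scale
  s <- .time_before_zero(tv)$s
  rss <- function(hill) {
    sum((y - smm_mean(s, hi$y, lo$y, midpoint, hill))^2)
  }
  hill <- if (rss(0.5) < rss(1.05)) 0.5 else 1.05

  start <- c(hi$y, lo$y, midpoint, hill)
  names(start) <- model_param_names(1)
  structure(
    list(start = start,
         provenance = c("percentile-level", "percentile-level",
                        "linearity-rule", "linearity-rule")),
    class = "trajmix_start"
  )
}

.nearly_linear <- function(tv, y, lo, mid, hi, linear_r2, linear_frac) {
  if (stats::var(y) == 0) return(TRUE)
  fit <- stats::lm.fit(cbind(1, tv), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (is.finite(r2) && r2 >= linear_r2) return(TRUE)
  rng <- abs(hi$y - lo$y)
  if (rng == 0) return(TRUE)
  if (hi$t == lo$t) return(FALSE)
  w <- (mid$t - lo$t) / (hi$t - lo$t)
  interp <- lo$y + w * (hi$y - lo$y)
  abs(mid$y - interp) <= linear_frac * rng
}

## map observation times to the positive time-before-zero scale s = shift - t,
## shifted (and reported) so that min(s) >= 0 under mixed-sign input
.time_before_zero <- function(tv) {
  shift <- max(0, max(tv))
  list(s = shift - tv, shift = shift)
}

#' Automated initial values for the piecewise mixed models
#'
#' Starting values for the abrupt and smooth piecewise models. The last level
#' (intercept) start is the mean outcome in the band around the 95th
#' percentile of the time distribution. The time axis is split at its
#' 20/40/60/80th percentiles, a within-subject-centered least-squares trend
#' (the fixed-effects slope, immune to between-subject level heterogeneity)
#' is fitted within each quintile band, and the changepoint start is the lower bound of
#' the band with the steepest (largest absolute) slope; when several bands tie
#' for the fastest slope the earliest one is taken, since the changepoint
#' marks the onset of the fast phase. The two slope starts are
#' within-subject-centered trends fitted on the data before and after that
#' approximate changepoint. The within-subject estimator is used instead of
#' full per-band random-effects fits: it captures the same slope information
#' a random-intercept model would, at no dependency cost.
#'
#' @inheritParams smm_start
#' @return A `trajmix_start` object (parameter order: last level, slope1,
#'   slope2, changepoint).
#' @export
pmm_start <- function(data, band = 0.025) {
  tv <- data[[attr(data, "time_col")]]
  y <- data[[attr(data, "outcome_col")]]
  id <- data[[attr(data, "id_col")]]
  if (length(unique(tv)) < 5) {
    stop("pmm_start(): need at least 5 distinct time values to form quintile bands",
         call. = FALSE)
  }
  p <- stats::ecdf(tv)(tv)
  sel <- p >= 0.95 - band & p <= 0.95 + band
  if (!any(sel)) sel <- which.min(abs(p - 0.95))
  last_level <- mean(y[sel])

  bands <- .band_slopes(tv, y, id, probs = seq(0.2, 0.8, by = 0.2))
  if (is.null(bands)) {
    warning("pmm_start(): empty quintile band; falling back to tertiles")
    bands <- .band_slopes(tv, y, id, probs = c(1 / 3, 2 / 3))
    if (is.null(bands)) {
      stop("pmm_start(): cannot form time bands with at least two distinct times each",
           call. = FALSE)
    }
  }
  slopes <- bands$slopes
  ## steepest |slope|; ties broken toward the earliest tied band (onset)
  best <- max(abs(slopes))
  cand <- which(abs(slopes) >= best * (1 - 1e-8))
  pick <- cand[which.min(bands$lower[cand])]
  changepoint <- bands$lower[pick]
  ## keep the start strictly inside the observed time range
  changepoint <- max(changepoint, min(tv) + 0.05 * diff(range(tv)))

  pre <- tv < changepoint
  slope1 <- .within_subject_slope(tv[pre], y[pre], id[pre])
  slope2 <- .within_subject_slope(tv[!pre], y[!pre], id[!pre])
  pooled <- .within_subject_slope(tv, y, id)
  if (is.na(slope1)) slope1 <- pooled
  if (is.na(slope2)) slope2 <- pooled

  start <- c(last_level, slope1, slope2, changepoint)
  names(start) <- model_param_names(2)
  structure(
    list(start = start,
         provenance = c("percentile-level", "segment-slope",
                        "segment-slope", "segment-slope")),
    class = "trajmix_start"
  )
}

.ols_slope <- function(tv, y) {
  if (length(tv) < 2 || length(unique(tv)) < 2) return(NA_real_)
  stats::cov(tv, y) / stats::var(tv)
}

## Slope of the within-subject (fixed-effects) trend: time and outcome are
## centered within subject before pooling, which removes between-subject
## level heterogeneity from the slope exactly as a random-intercept model
## would. Falls back to the plain pooled slope when subjects contribute no
## within-subject time variation (e.g. one observation each).
.within_subject_slope <- function(tv, y, id) {
  if (length(tv) < 2 || length(unique(tv)) < 2) return(NA_real_)
  td <- tv - stats::ave(tv, id)
  yd <- y - stats::ave(y, id)
  den <- sum(td * td)
  if (den < 1e-12) return(.ols_slope(tv, y))
  sum(td * yd) / den
}

.band_slopes <- function(tv, y, id, probs) {
  breaks <- unique(c(min(tv), stats::quantile(tv, probs, names = FALSE), max(tv)))
  if (length(breaks) < 3) return(NULL)
  idx <- findInterval(tv, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  slopes <- lower <- numeric(nb)
  for (b in seq_len(nb)) {
    sl <- .within_subject_slope(tv[idx == b], y[idx == b], id[idx == b])
    if (is.na(sl)) return(NULL)
    slopes[b] <- sl
    lower[b] <- breaks[b]
  }
  list(slopes = slopes, lower = lower, breaks = breaks)
}

#' Automated initial values for any trajmix model
#'
#' Dispatches to [smm_start()] for model 1 and [pmm_start()] for models 2-3,
#' unless the specification carries user initials, which are passed through
#' verbatim (provenance `"user"`) after an order/length check.
#'
#' @param data A `trajmix_data` object.
#' @param spec A [model_spec()] object.
#' @return A `trajmix_start` object.
#' @export
auto_start <- function(data, spec) {
  if (spec$model == 0) {
    tv <- data[[attr(data, "time_col")]]
    y <- data[[attr(data, "outcome_col")]]
    sl <- .ols_slope(tv, y)
    start <- c(intercept = mean(y) - sl * mean(tv), slope = sl)
    return(structure(list(start = start, provenance = rep("segment-slope", 2)),
                     class = "trajmix_start"))
  }
  if (!is.null(spec$start)) {
    start <- spec$start
    if (spec$model == 1 && start[3] < 0) {
      message("auto_start(): negative user midpoint start interpreted on the ",
              "positive time-before-zero scale (using ", abs(start[3]), ")")
      start[3] <- abs(start[3])
    }
    names(start) <- spec$param_names
    return(structure(list(start = start, provenance = rep("user", 4)),
                     class = "trajmix_start"))
  }
  if (spec$model == 1) smm_start(data) else pmm_start(data)
}

#' @export
print.trajmix_start <- function(x, ...) {
  cat("trajmix initial values:\n")
  for (k in seq_along(x$start)) {
    cat(sprintf("  %-12s %10.4f  [%s]\n", names(x$start)[k], x$start[k],
                x$provenance[k]))
  }
  invisible(x)
}

## Method-of-moments style defaults for the variance parameters, built from
## the residuals of the structural curve at the starting values.
start_variances <- function(data, spec, start) {
  tv <- data[[attr(data, "time_col")]]
  y <- data[[attr(data, "outcome_col")]]
  s <- if (spec$model == 1) .time_before_zero(tv)$s else tv
  phi <- matrix(rep(start, each = length(s)), ncol = spec$npar)
  f <- .engine_mean(spec$model, s, phi, v = spec$v)
  V <- stats::var(y - f)
  if (!is.finite(V) || V <= 0) V <- max(stats::var(y), 1e-4)
  half_range <- max(1, diff(range(tv)) / 2)
  if (spec$model == 0) {
    B0 <- diag(c(0.5 * V, 0.1 * V / half_range^2))
  } else if (spec$model == 1) {
    B0 <- diag(c(0.5 * V, 0.1 * V))
  } else {
    B0 <- diag(c(0.5 * V, 0.1 * V / half_range^2, 0.1 * V / half_range^2,
                 (0.25 * diff(range(tv)))^2))
  }
  list(B = B0, sigma2 = max(0.25 * V, 1e-4))
}
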