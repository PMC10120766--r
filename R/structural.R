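#' Four-parameter sigmoidal mean trajectory
#'
#' Evaluates the mean function of the sigmoidal mixed model (SMM) on the
#' positive time-before-zero scale (e.g. years before death). The curve equals
#' `last_level` at `t = 0` and tends to `first_level` as `t` grows, declining
#' (or rising) through a logistic transition centred at `midpoint` with
#' steepness governed by the Hill slope.
#'
#' @param t Non-negative times on the time-before-zero scale. Vectorised.
#' @param last_level Level of the outcome at `t = 0` (e.g. level at death).
#' @param first_level Asymptotic level for large `t` (level before decline).
#' @param midpoint Time at which half of the total change has occurred;
#'   must be strictly positive.
#' @param hill Hill slope controlling the steepness of the transition.
#'
#' All parameters are recycled against `t`, so subject-specific parameter
#' vectors of the same length as `t` are accepted.
#'
#' @return Numeric vector of mean outcome values, one per element of `t`.
#' @examples
#' smm_mean(8, last_level = -1.03, first_level = 0.37, midpoint = 4, hill = 1.69)
#' @export
smm_mean <- function(t, last_level, first_level, midpoint, hill) {
  if (any(!is.finite(midpoint)) || any(midpoint <= 0)) {
    stop("smm_mean(): 'midpoint' must be strictly positive", call. = FALSE)
  }
  if (any(t < 0, na.rm = TRUE)) {
    stop("smm_mean(): 't' must be on the positive time-before-zero scale (t >= 0)",
         call. = FALSE)
  }
  ratio <- (t / midpoint)^hill
  first_level + (last_level - first_level) / (1 + ratio)
}

#' Piecewise linear mean trajectory with an abrupt changepoint
#'
#' Two straight lines joined continuously at `changepoint`. The segment
#' containing time zero has slope `slope2` and passes through
#' `(0, last_level)`; the other segment has slope `slope1`. With time aligned
#' at death (negative times), `slope1` is the pre-changepoint slope and
#' `slope2` the terminal slope.
#'
#' @param t Observation times on the data timescale (may be negative).
#' @param last_level Outcome level at time zero (the intercept).
#' @param slope1 Slope of the segment on the far side of the changepoint
#'   (not containing time zero).
#' @param slope2 Slope of the segment between the changepoint and time zero.
#' @param changepoint Time at which the slope changes.
#' @return Numeric vector of mean outcome values.
#' @examples
#' pmm_abrupt_mean(c(-5, -1), -1.21, slope1 = -0.03, slope2 = -0.32, changepoint = -3)
#' @export
pmm_abrupt_mean <- function(t, last_level, slope1, slope2, changepoint) {
  adj <- last_level + slope2 * t
  far <- last_level + slope2 * changepoint + slope1 * (t - changepoint)
  ifelse(t >= changepoint, adj, far)
}

#' Cubic transition polynomial of the smooth piecewise model
#'
#' Solves the four linear constraints that define the cubic bridging the two
#' linear phases of the smooth piecewise model over the window
#' `[changepoint, changepoint + v]`: the cubic matches the value and slope of
#' the entering line at the start of the window and of the exiting line at its
#' end. The entering line is the `slope1` phase shifted so that the two
#' extended lines intersect at the middle of the window; its intercept is the
#' constrained value `lambda = last_level + (slope2 - slope1) * (changepoint + v/2)`.
#'
#' The coefficients are obtained from the explicit 4x4 linear system in the
#' monomial basis `(1, t, t^2, t^3)`.
#'
#' @inheritParams pmm_abrupt_mean
#' @param v Length of the transition window; must be strictly positive
#'   (with `v = 0` the model is the abrupt one and no cubic exists).
#' @return A list with elements `coefficients` (named `a0`..`a3`) and
#'   `lambda` (intercept of the extended entering line).
#' @export
transition_cubic <- function(last_level, slope1, slope2, changepoint, v) {
  if (!is.finite(v) || v <= 0) {
    stop("transition_cubic(): 'v' must be strictly positive; use the abrupt model for v = 0",
         call. = FALSE)
  }
  lambda <- last_level + (slope2 - slope1) * (changepoint + v / 2)
  t0 <- changepoint
  t1 <- changepoint + v
  A <- rbind(
    c(1, t0, t0^2,     t0^3),
    c(1, t1, t1^2,     t1^3),
    c(0, 1,  2 * t0, 3 * t0^2),
    c(0, 1,  2 * t1, 3 * t1^2)
  )
  b <- c(
    lambda + slope1 * t0,
    last_level + slope2 * t1,
    slope1,
    slope2
  )
  a <- solve(A, b)
  names(a) <- c("a0", "a1", "a2", "a3")
  list(coefficients = a, lambda = lambda)
}

## Hermite-form evaluation of the same cubic, vectorised over subjects.
## Algebraically identical to the monomial solve in transition_cubic();
## used in the hot path of the SAEM engine.
.smooth_window_value <- function(t, last_level, slope1, slope2, changepoint, v) {
  lambda <- last_level + (slope2 - slope1) * (changepoint + v / 2)
  u <- (t - changepoint) / v
  y0 <- lambda + slope1 * changepoint
  y1 <- last_level + slope2 * (changepoint + v)
  m0 <- slope1 * v
  m1 <- slope2 * v
  u2 <- u * u
  u3 <- u2 * u
  y0 * (2 * u3 - 3 * u2 + 1) + m0 * (u3 - 2 * u2 + u) +
    y1 * (-2 * u3 + 3 * u2) + m1 * (u3 - u2)
}

#' Piecewise linear mean trajectory with a smooth cubic transition
#'
#' Extends [pmm_abrupt_mean()] by replacing the kink at the changepoint with a
#' third-degree polynomial over the window `[changepoint, changepoint + v]`,
#' yielding a globally C1 trajectory. The segment after the window (the one
#' containing time zero when times are negative) has slope `slope2` and passes
#' through `(0, last_level)`; the segment before the window has slope
#' `slope1`, positioned so that the two extended lines cross at the middle of
#' the window. Setting `v = 0` recovers the abrupt model exactly.
#'
#' @inheritParams pmm_abrupt_mean
#' @param v Non-negative length of the transition window, on the timescale of
#'   `t`.
#' @return Numeric vector of mean outcome values.
#' @export
pmm_smooth_mean <- function(t, last_level, slope1, slope2, changepoint, v) {
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("pmm_smooth_mean(): 'v' must be non-negative", call. = FALSE)
  }
  if (all(v == 0)) {
    return(pmm_abrupt_mean(t, last_level, slope1, slope2, changepoint))
  }
  lambda <- last_level + (slope2 - slope1) * (changepoint + v / 2)
  before <- lambda + slope1 * t
  after <- last_level + slope2 * t
  inside <- .smooth_window_value(t, last_level, slope1, slope2, changepoint, v)
  out <- ifelse(t < changepoint, before, ifelse(t > changepoint + v, after, inside))
  ## guard against v = 0 mixed into vectorised input
  if (any(v == 0)) {
    ab <- pmm_abrupt_mean(t, last_level, slope1, slope2, changepoint)
    zero <- rep_len(v == 0, length(out))
    out[zero] <- ab[zero]
  }
  out
}

#' Construct a parameter link (fixed effects, covariates, random effects)
#'
#' Describes how the four structural parameters of a model are built from
#' population means `alpha`, covariate effects `beta`, and subject-level
#' random effects with covariance `B`.
#'
#' @param alpha Numeric vector of length 4: population means of the structural
#'   parameters, in the model's parameter order.
#' @param beta Optional list of up to 4 named numeric vectors
#'   (`par1` .. `par4`); each names the covariates acting on that parameter
#'   and gives their coefficients. Missing entries mean no covariates.
#' @param random Logical vector of length 4: which structural parameters carry
#'   a random effect. The sigmoidal model uses `c(TRUE, TRUE, FALSE, FALSE)`
#'   (midpoint and Hill slope are marginal); the piecewise models use all
#'   four.
#' @param B Covariance matrix of the random effects, dimension equal to
#'   `sum(random)`; must be symmetric positive semi-definite.
#' @param sigma Residual standard deviation, strictly positive.
#' @return An object of class `trajmix_link`.
#' @export
param_link <- function(alpha, beta = NULL, random, B, sigma) {
  stopifnot(length(alpha) == 4, is.numeric(alpha),
            length(random) == 4, is.logical(random))
  q <- sum(random)
  B <- as.matrix(B)
  if (!all(dim(B) == q)) {
    stop("param_link(): 'B' must be ", q, "x", q,
         " to match the random-effect mask", call. = FALSE)
  }
  if (max(abs(B - t(B))) > 1e-10) {
    stop("param_link(): 'B' must be symmetric", call. = FALSE)
  }
  if (min(eigen(B, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("param_link(): 'B' must be positive semi-definite", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("param_link(): 'sigma' must be strictly positive", call. = FALSE)
  }
  beta_full <- vector("list", 4)
  names(beta_full) <- paste0("par", 1:4)
  if (!is.null(beta)) {
    for (k in seq_len(4)) {
      nm <- paste0("par", k)
      bk <- beta[[nm]]
      if (!is.null(bk)) {
        if (is.null(names(bk)) || any(names(bk) == "")) {
          stop("param_link(): covariate coefficients for ", nm,
               " must be a named numeric vector", call. = FALSE)
        }
        beta_full[[nm]] <- bk
      }
    }
  }
  structure(
    list(alpha = as.numeric(alpha), beta = beta_full, random = random,
         B = B, sigma = sigma),
    class = "trajmix_link"
  )
}

#' Assemble subject-specific structural parameters
#'
#' Computes `psi_k = alpha_k + beta_k' x_k + eta_k` for each of the four
#' structural parameters, where the random-effect term only enters parameters
#' flagged random in the link.
#'
#' @param link A [param_link()] object.
#' @param covariates Named list or vector of covariate values for one subject;
#'   must contain every covariate referenced in the link.
#' @param eta Numeric vector of random effects: either of length
#'   `sum(link$random)` (one entry per random parameter, in order) or of
#'   length 4, in which case entries for non-random parameters must be zero.
#' @return Numeric vector of length 4 of structural parameters.
#' @export
link_parameters <- function(link, covariates = NULL, eta = NULL) {
  stopifnot(inherits(link, "trajmix_link"))
  q <- sum(link$random)
  if (is.null(eta)) eta <- numeric(q)
  if (length(eta) == 4 && q < 4) {
    if (any(eta[!link$random] != 0)) {
      stop("link_parameters(): random effects supplied for parameters without ",
           "a random effect (positions ",
           paste(which(!link$random & eta != 0), collapse = ", "), ")",
           call. = FALSE)
    }
    eta <- eta[link$random]
  }
  if (length(eta) != q) {
    stop("link_parameters(): 'eta' must have length ", q, call. = FALSE)
  }
  psi <- link$alpha
  for (k in seq_len(4)) {
    bk <- link$beta[[k]]
    if (!is.null(bk) && length(bk)) {
      for (nm in names(bk)) {
        xv <- covariates[[nm]]
        if (is.null(xv) || is.na(xv)) {
          stop("link_parameters(): missing covariate value for '", nm, "'",
               call. = FALSE)
        }
        psi[k] <- psi[k] + bk[[nm]] * as.numeric(xv)
      }
    }
  }
  psi[link$random] <- psi[link$random] + eta
  psi
}

## Names of the four structural parameters, per model id.
model_param_names <- function(model) {
  if (model == 1) c("last.level", "first.level", "midpoint", "hill.slope")
  else c("last.level", "slope1", "slope2", "changepoint")
}

## Random-effect mask per model id.
model_random_mask <- function(model) {
  if (model == 1) c(TRUE, TRUE, FALSE, FALSE) else rep(TRUE, 4)
}

## Free-covariance mask on the random sub-vector, per model id:
## SMM B is full 2x2; PMM B is diagonal apart from the slope1-slope2 entry.
model_cov_mask <- function(model) {
  if (model == 1) {
    matrix(TRUE, 2, 2)
  } else {
    m <- diag(4) > 0
    m[2, 3] <- m[3, 2] <- TRUE
    m
  }
}

## Vectorised structural mean over observations. phi is an n_obs x 4 matrix of
## subject parameters expanded per observation; for model 1, t must already be
## on the positive time-before-zero scale.
structural_mean <- function(model, t, phi, v = 0) {
  if (model == 1) {
    smm_mean(t, phi[, 1], phi[, 2], phi[, 3], phi[, 4])
  } else if (model == 2) {
    pmm_abrupt_mean(t, phi[, 1], phi[, 2], phi[, 3], phi[, 4])
  } else {
    pmm_smooth_mean(t, phi[, 1], phi[, 2], phi[, 3], phi[, 4], v)
  }
}
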