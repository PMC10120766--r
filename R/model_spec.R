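#' Specify a structural model and its covariate structure
#'
#' @param model Integer model id: `1` = sigmoidal mixed model (SMM),
#'   `2` = piecewise mixed model with abrupt changepoint (PMM-abrupt),
#'   `3` = piecewise model with smooth cubic transition (PMM-smooth).
#' @param predictor_all Character vector of covariates attached to all four
#'   structural parameters.
#' @param predictor_par1,predictor_par2,predictor_par3,predictor_par4
#'   Covariates attached to individual parameters. A covariate listed both
#'   globally and per-parameter enters each parameter once. Parameter order:
#'   model 1 — last level, first (initial) level, midpoint, Hill slope;
#'   models 2 and 3 — last level (intercept at time zero), slope1 (slope
#'   before the changepoint), slope2 (slope between the changepoint and time
#'   zero), changepoint.
#' @param start Optional numeric vector of four user initial values, in the
#'   parameter order above; bypasses the automated initial-value heuristics.
#' @param v Length of the smooth transition window (model 3 only), in the
#'   units of the time variable. Default 2.
#' @return A `trajmix_spec` object.
#' @export
model_spec <- function(model, predictor_all = NULL,
                       predictor_par1 = NULL, predictor_par2 = NULL,
                       predictor_par3 = NULL, predictor_par4 = NULL,
                       start = NULL, v = 2) {
  if (!length(model) == 1 || !model %in% 1:3) {
    stop("model_spec(): 'model' must be 1 (SMM), 2 (PMM-abrupt) or 3 (PMM-smooth)",
         call. = FALSE)
  }
  model <- as.integer(model)
  per_par <- list(predictor_par1, predictor_par2, predictor_par3, predictor_par4)
  predictors <- lapply(per_par, function(p) unique(c(predictor_all, p)))
  names(predictors) <- model_param_names(model)
  if (!is.null(start)) {
    if (length(start) != 4 || !is.numeric(start) || any(!is.finite(start))) {
      stop("model_spec(): 'start' must be a finite numeric vector of length 4",
           call. = FALSE)
    }
    start <- as.numeric(start)
  }
  if (model == 3 && (!is.finite(v) || v < 0)) {
    stop("model_spec(): 'v' must be non-negative", call. = FALSE)
  }
  structure(
    list(model = model,
         npar = 4L,
         param_names = model_param_names(model),
         predictors = predictors,
         random = model_random_mask(model),
         cov_mask = model_cov_mask(model),
         start = start,
         v = if (model == 3) v else 0),
    class = "trajmix_spec"
  )
}

## Internal linear-mixed-model specification (random intercept and slope,
## identity mean): a degenerate special case used to validate the SAEM
## machinery against closed-form linear-model results.
.linear_spec <- function(predictor_all = NULL) {
  preds <- list(intercept = predictor_all, slope = predictor_all)
  structure(
    list(model = 0L, npar = 2L, param_names = c("intercept", "slope"),
         predictors = preds, random = c(TRUE, TRUE),
         cov_mask = matrix(TRUE, 2, 2), start = NULL, v = 0),
    class = "trajmix_spec"
  )
}

#' @export
print.trajmix_spec <- function(x, ...) {
  labels <- c("sigmoidal mixed model (SMM)",
              "piecewise mixed model, abrupt changepoint (PMM-abrupt)",
              "piecewise mixed model, smooth transition (PMM-smooth)")
  cat("trajmix model specification:", labels[x$model], "\n")
  for (k in seq_len(4)) {
    p <- x$predictors[[k]]
    cat(sprintf("  %-12s %s%s\n", x$param_names[k],
                if (x$random[k]) "[random] " else "[marginal] ",
                if (length(p)) paste("~", paste(p, collapse = " + ")) else ""))
  }
  if (x$model == 3) cat("  transition window v =", x$v, "\n")
  invisible(x)
}

#' Tuning parameters of the SAEM algorithm
#'
#' @param K1 Number of burn-in iterations with constant step size
#'   (`gamma_k = 1`), during which the Metropolis-Hastings proposal scales are
#'   adapted.
#' @param K2 Number of stochastic-approximation iterations with decreasing
#'   step `gamma_k = (k - K1)^(-a)`.
#' @param a Step-decay exponent, in `(0.5, 1]` (Robbins-Monro condition).
#' @param n_chains Number of parallel Metropolis chains per subject; default
#'   `max(1, ceiling(50 / n_subjects))`, i.e. one chain for 50+ subjects.
#' @param mh_steps Metropolis-Hastings sweeps per SAEM iteration.
#' @param tol Convergence tolerance: largest per-iteration relative parameter
#'   change allowed over the trailing window.
#' @param window Number of trailing stochastic-approximation iterations
#'   examined by the convergence diagnostic.
#' @param seed Integer seed controlling all randomness of the fit.
#' @param compute_se Accumulate the Louis-type information and report
#'   standard errors, CV% and Wald p-values.
#' @param compute_loglik Estimate the marginal log-likelihood (and AIC/BIC)
#'   by importance sampling after the fit.
#' @param is_samples Number of importance-sampling draws per subject.
#' @param adapt_target Target Metropolis acceptance rate for the random-walk
#'   kernels during burn-in.
#' @param anneal Simulated-annealing coefficient in `[0, 1)` applied during
#'   burn-in: variance parameters may not shrink by more than this factor per
#'   iteration, which keeps the conditional chains exploring before the
#'   stochastic averaging starts. `0` disables the constraint.
#' @return A `trajmix_control` list.
#' @export
saem_control <- function(K1 = 600, K2 = 800, a = 1, n_chains = NULL,
                         mh_steps = 2, tol = 1e-3, window = 50, seed = 123,
                         compute_se = TRUE, compute_loglik = TRUE,
                         is_samples = 500, adapt_target = 0.35, anneal = 0) {
  stopifnot(K1 >= 1, K2 >= 1, a > 0.5, a <= 1, mh_steps >= 1,
            tol > 0, window >= 2, is_samples >= 10)
  structure(
    list(K1 = as.integer(K1), K2 = as.integer(K2), a = a,
         n_chains = n_chains, mh_steps = as.integer(mh_steps),
         tol = tol, window = as.integer(window), seed = as.integer(seed),
         compute_se = isTRUE(compute_se),
         compute_loglik = isTRUE(compute_loglik),
         is_samples = as.integer(is_samples), adapt_target = adapt_target,
         anneal = anneal),
    class = "trajmix_control"
  )
}
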