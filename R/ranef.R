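#' Empirical Bayes estimates of the subject random effects
#'
#' Returns, for each subject, the conditional mode (`type = "mode"`, a
#' Laplace-style point estimate) or the conditional mean (`type = "mean"`,
#' averaged over Metropolis-Hastings draws at the fitted parameters) of the
#' random-effect vector given the subject's data.
#'
#' @param fit A `trajmix_fit` object.
#' @param type `"mean"` or `"mode"`.
#' @param n_iter Number of Metropolis sweeps for `type = "mean"` (the first
#'   quarter is discarded as burn-in).
#' @param seed Seed for the `type = "mean"` draws.
#' @return A matrix with one row per subject (in the order of first
#'   appearance) and one column per random effect.
#' @export
ranef_estimates <- function(fit, type = c("mean", "mode"), n_iter = 200,
                            seed = fit$control$seed + 1) {
  type <- match.arg(type)
  state <- fit$state; setup <- fit$setup; spec <- fit$spec
  R <- which(spec$random); q <- length(R)
  pn <- spec$param_names
  if (type == "mode") {
    cm <- .conditional_modes(state, setup, spec)
    out <- cm$modes
  } else {
    out <- .mh_means(state, setup, spec, n_iter = n_iter, seed = seed)
  }
  dimnames(out) <- list(setup$ids, pn[R])
  out
}

## posterior means by continued Metropolis sampling at the fitted parameters
.mh_means <- function(state, setup, spec, n_iter, seed) {
  set.seed(seed)
  R <- which(spec$random); q <- length(R)
  N <- setup$N
  subj <- setup$subj
  B <- state$B; sigma2 <- state$sigma2
  Binv <- solve(B)
  cholB <- chol(B + diag(1e-12, q))
  sdB <- sqrt(pmax(diag(B), 1e-12))
  m_sub <- vapply(seq_len(spec$npar), function(k) drop(setup$X[[k]] %*% state$b[[k]]),
                  numeric(N))
  if (N == 1) m_sub <- matrix(m_sub, 1, spec$npar)
  eta <- rowsum(state$eta, state$subj_u) / state$C
  resid_of <- function(eta) {
    phi <- m_sub
    phi[, R] <- phi[, R] + eta
    setup$y - .engine_mean(spec$model, setup$t, phi[subj, , drop = FALSE], spec$v)
  }
  rss_of <- function(res) {
    r2 <- res * res; r2[is.na(r2)] <- Inf
    drop(rowsum(r2, subj))
  }
  rss <- rss_of(resid_of(eta))
  prior_q <- rowSums((eta %*% Binv) * eta)
  burn <- ceiling(n_iter / 4)
  acc_sum <- matrix(0, N, q)
  keep <- matrix(0, N, q)
  kept <- 0L
  s_comp <- state$scales$comp
  for (it in seq_len(n_iter)) {
    for (cc in seq_len(q)) {
      eta_p <- eta
      eta_p[, cc] <- eta[, cc] + s_comp[cc] * sdB[cc] * stats::rnorm(N)
      rss_p <- rss_of(resid_of(eta_p))
      prior_p <- rowSums((eta_p %*% Binv) * eta_p)
      la <- (rss - rss_p) / (2 * sigma2) + (prior_q - prior_p) / 2
      acc <- !is.na(la) & (log(stats::runif(N)) < la)
      eta[acc, cc] <- eta_p[acc, cc]
      rss[acc] <- rss_p[acc]
      prior_q[acc] <- prior_p[acc]
    }
    if (it > burn) {
      keep <- keep + eta
      kept <- kept + 1L
    }
  }
  keep / kept
}

#' Subject-specific structural parameters
#'
#' Assembles each subject's structural parameter vector
#' `psi_i = alpha + beta' x_i + eta_i` at the fitted fixed effects and the
#' empirical Bayes random effects.
#'
#' @inheritParams ranef_estimates
#' @return A matrix with one row per subject and one column per structural
#'   parameter (model order).
#' @export
subject_parameters <- function(fit, type = c("mean", "mode"), ...) {
  type <- match.arg(type)
  eta <- ranef_estimates(fit, type = type, ...)
  setup <- fit$setup; spec <- fit$spec
  R <- which(spec$random)
  N <- setup$N
  psi <- vapply(seq_len(spec$npar), function(k) drop(setup$X[[k]] %*% fit$state$b[[k]]),
                numeric(N))
  if (N == 1) psi <- matrix(psi, 1, spec$npar)
  psi[, R] <- psi[, R] + eta
  dimnames(psi) <- list(setup$ids, spec$param_names)
  psi
}

#' Fitted values of a trajmix model
#'
#' @param object A `trajmix_fit` object.
#' @param type `"individual"` (at the empirical Bayes subject parameters) or
#'   `"population"` (random effects set to zero).
#' @param eb_type Empirical Bayes flavour passed to [subject_parameters()].
#' @param ... Unused.
#' @return Numeric vector of fitted values in the row order of the (sorted)
#'   model data.
#' @export
fitted.trajmix_fit <- function(object, type = c("individual", "population"),
                               eb_type = "mode", ...) {
  type <- match.arg(type)
  setup <- object$setup; spec <- object$spec
  if (type == "population") {
    N <- setup$N
    psi <- vapply(seq_len(spec$npar), function(k) drop(setup$X[[k]] %*% object$state$b[[k]]),
                  numeric(N))
    if (N == 1) psi <- matrix(psi, 1, spec$npar)
  } else {
    psi <- subject_parameters(object, type = eb_type)
  }
  .engine_mean(spec$model, setup$t, psi[setup$subj, , drop = FALSE], spec$v)
}

#' @export
residuals.trajmix_fit <- function(object, type = c("individual", "population"),
                                  ...) {
  object$setup$y - fitted(object, type = match.arg(type), ...)
}
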