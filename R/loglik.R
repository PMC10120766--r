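## Importance-sampling estimate of the marginal log-likelihood
##   sum_i log  int  p(y_i | eta_i) p(eta_i) d eta_i
## with a Gaussian proposal centred at each subject's conditional mode with
## the curvature of the conditional log-density at the mode (falling back to
## the random-effect prior when that curvature is not positive definite).

## conditional mode and curvature of eta_i for every subject
.conditional_modes <- function(state, setup, spec) {
  R <- which(spec$random); q <- length(R)
  N <- setup$N
  B <- state$B
  Binv <- solve(B)
  sigma2 <- state$sigma2
  m_sub <- vapply(seq_len(spec$npar), function(k) drop(setup$X[[k]] %*% state$b[[k]]),
                  numeric(N))
  if (N == 1) m_sub <- matrix(m_sub, 1, spec$npar)
  modes <- matrix(0, N, q)
  Hs <- array(0, dim = c(N, q, q))
  ok_H <- logical(N)
  ## average over chains for a warm start
  eta0 <- rowsum(state$eta, state$subj_u) / state$C
  for (i in seq_len(N)) {
    rows <- which(setup$subj == i)
    ti <- setup$t[rows]; yi <- setup$y[rows]
    mi <- m_sub[i, ]
    neg <- function(et) {
      ph <- mi; ph[R] <- ph[R] + et
      f <- .engine_mean(spec$model, ti, matrix(ph, length(ti), length(ph),
                                               byrow = TRUE), spec$v)
      r <- yi - f
      val <- sum(r * r) / (2 * sigma2) + 0.5 * drop(et %*% Binv %*% et)
      if (!is.finite(val)) 1e12 else val
    }
    opt <- stats::optim(eta0[i, ], neg, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    modes[i, ] <- opt$par
    Hi <- .num_hess(neg, opt$par, rel = 1e-4, floor_h = 1e-6)
    ev <- tryCatch(eigen(Hi, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (min(ev) > 1e-10) {
      Hs[i, , ] <- Hi
      ok_H[i] <- TRUE
    } else {
      Hs[i, , ] <- Binv
    }
  }
  if (!all(ok_H)) {
    ## prior used as proposal where the conditional curvature is degenerate
    modes[!ok_H, ] <- 0
  }
  list(modes = modes, H = Hs, ok = ok_H, m_sub = m_sub)
}

#' Importance-sampling marginal log-likelihood
#'
#' Estimates the marginal log-likelihood of a fitted model by importance
#' sampling with a per-subject Gaussian proposal centred at the conditional
#' mode of the random effects. When the random-effect variances are all
#' (numerically) zero the integral collapses and the closed-form Gaussian
#' residual log-likelihood is returned.
#'
#' @param fit A `trajmix_fit` object.
#' @param n_samples Number of importance draws per subject.
#' @param seed Integer seed making the estimate reproducible.
#' @return The estimated log-likelihood, with attributes `mc_se` (Monte Carlo
#'   standard error) and `df` (number of free parameters).
#' @export
marginal_loglik <- function(fit, n_samples = 500, seed = 1) {
  state <- fit$state; setup <- fit$setup; spec <- fit$spec
  R <- which(spec$random); q <- length(R)
  N <- setup$N
  B <- state$B; sigma2 <- state$sigma2
  df <- length(state$theta)

  if (max(diag(B)) < 1e-8) {
    m_sub <- vapply(seq_len(spec$npar), function(k) drop(setup$X[[k]] %*% state$b[[k]]),
                    numeric(N))
    if (N == 1) m_sub <- matrix(m_sub, 1, spec$npar)
    f <- .engine_mean(spec$model, setup$t, m_sub[setup$subj, , drop = FALSE],
                      spec$v)
    ll <- sum(stats::dnorm(setup$y, f, sqrt(sigma2), log = TRUE))
    return(structure(ll, mc_se = 0, df = df))
  }

  set.seed(seed)
  cm <- .conditional_modes(state, setup, spec)
  ## proposal pieces: covariance chol factors, precisions and log-determinants
  Lp <- array(0, dim = c(N, q, q))
  Prec <- array(0, dim = c(N, q, q))
  logdetS <- numeric(N)
  for (i in seq_len(N)) {
    Hi <- matrix(cm$H[i, , ], q, q)
    Si <- tryCatch(solve(Hi), error = function(e) B)
    Li <- tryCatch(chol(Si), error = function(e) {
      Si <<- B
      chol(B)
    })
    Lp[i, , ] <- Li
    Prec[i, , ] <- chol2inv(Li)
    logdetS[i] <- 2 * sum(log(diag(Li)))
  }
  Binv <- solve(B)
  logdetB <- determinant(B, logarithm = TRUE)$modulus[1]

  lw <- matrix(NA_real_, N, n_samples)
  subj <- setup$subj
  for (m in seq_len(n_samples)) {
    z <- matrix(stats::rnorm(N * q), N, q)
    d <- matrix(0, N, q)                       # Lp' z per subject, vectorised
    for (jc in seq_len(q)) {
      for (lr in seq_len(jc)) d[, jc] <- d[, jc] + Lp[, lr, jc] * z[, lr]
    }
    eta_m <- cm$modes + d
    phi <- cm$m_sub
    phi[, R] <- phi[, R] + eta_m
    f <- .engine_mean(spec$model, setup$t, phi[subj, , drop = FALSE], spec$v)
    r2 <- (setup$y - f)^2
    r2[is.na(r2)] <- Inf
    rss_i <- drop(rowsum(r2, subj))
    ll_y <- -0.5 * rss_i / sigma2 - 0.5 * .obs_per_subject(subj) * log(2 * pi * sigma2)
    quad_prior <- rowSums((eta_m %*% Binv) * eta_m)
    ll_prior <- -0.5 * quad_prior - 0.5 * (q * log(2 * pi) + logdetB)
    quad_prop <- numeric(N)
    for (jc in seq_len(q)) for (lr in seq_len(q)) {
      quad_prop <- quad_prop + d[, jc] * Prec[, jc, lr] * d[, lr]
    }
    ll_prop <- -0.5 * quad_prop - 0.5 * (q * log(2 * pi) + logdetS)
    lw[, m] <- ll_y + ll_prior - ll_prop
  }
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  wbar <- rowMeans(w)
  ll_i <- mx + log(wbar)
  se_i <- apply(w, 1, stats::sd) / (wbar * sqrt(n_samples))
  structure(sum(ll_i), mc_se = sqrt(sum(se_i^2)), df = df)
}

.obs_per_subject <- function(subj) {
  as.numeric(table(subj))
}

#' @export
logLik.trajmix_fit <- function(object, ...) {
  ll <- object$loglik
  if (is.null(ll)) stop("log-likelihood was not computed for this fit; ",
                        "rerun with compute_loglik = TRUE or call marginal_loglik()",
                        call. = FALSE)
  structure(as.numeric(ll), df = attr(ll, "df"), nobs = object$n_obs,
            class = "logLik")
}
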