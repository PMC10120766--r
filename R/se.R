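## Louis-type standard errors: the observed Fisher information is assembled as
##   I(theta) = -E[H_c | y] - E[s_c s_c' | y] + sum_i E[s_i | y] E[s_i | y]'
## with the conditional expectations approximated by the stochastic averages
## accumulated over the SA phase. The complete-data log-likelihood separates
## into a Gaussian random-effect part (exactly quadratic in the simulated
## effects, so its expected Hessian is an explicit function of the accumulated
## first and second moments) and a residual part (expected Hessian taken at
## the accumulated conditional means of the subject parameters).

.num_hess <- function(fn, x, rel = 1e-4, floor_h = 1e-7) {
  p <- length(x)
  h <- pmax(rel * abs(x), floor_h)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

## Expected complete log-likelihood of the random-effect block as a function
## of the stacked fixed effects of random parameters and the free entries of B.
.make_EQ1 <- function(state, setup, spec) {
  R <- which(spec$random)
  q <- length(R)
  X <- setup$X
  pR <- vapply(X[R], ncol, 1L)
  off <- c(0, cumsum(pR))
  free_cov <- state$free_cov
  N <- setup$N
  S2 <- state$S2; s_phi <- state$s_phi
  function(par) {
    B <- matrix(0, q, q)
    for (jj in seq_along(free_cov)) {
      l <- free_cov[[jj]][1]; m <- free_cov[[jj]][2]
      B[l, m] <- B[m, l] <- par[sum(pR) + jj]
    }
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(-1e12)
    M <- vapply(seq_along(R), function(a_i) {
      drop(X[[R[a_i]]] %*% par[(off[a_i] + 1):off[a_i + 1]])
    }, numeric(N))
    Q <- S2 - crossprod(M, s_phi) - crossprod(s_phi, M) + crossprod(M)
    -N / 2 * determinant(B, logarithm = TRUE)$modulus[1] -
      0.5 * sum(diag(solve(B, Q)))
  }
}

## Expected residual log-likelihood as a function of the coefficients of the
## parameters without random effects and sigma^2, with the nonlinear residual
## term evaluated at the accumulated conditional parameter means and anchored
## to the accumulated residual sum of squares at the estimate.
.make_EQ2 <- function(state, setup, spec) {
  R <- which(spec$random); Fx <- which(!spec$random)
  X <- setup$X
  N <- setup$N; n_obs <- setup$n_obs
  phi_bar <- matrix(0, N, spec$npar)
  phi_bar[, R] <- state$s_phi
  rss_at <- function(bF) {
    pos <- 1L
    ph <- phi_bar
    for (k in Fx) {
      nk <- ncol(X[[k]])
      ph[, k] <- drop(X[[k]] %*% bF[pos:(pos + nk - 1L)])
      pos <- pos + nk
    }
    r <- setup$y - .engine_mean(spec$model, setup$t, ph[setup$subj, , drop = FALSE],
                                spec$v)
    val <- sum(r * r)
    if (!is.finite(val)) 1e12 else val
  }
  bF_hat <- unlist(state$b[Fx], use.names = FALSE)
  rss0 <- rss_at(bF_hat)
  s_rss <- state$s_rss
  function(par) {
    pF <- length(par) - 1L
    sigma2 <- par[pF + 1L]
    if (sigma2 <= 0) return(-1e12)
    rss_tilde <- rss_at(par[seq_len(pF)]) - rss0 + s_rss
    -n_obs / 2 * log(2 * pi * sigma2) - rss_tilde / (2 * sigma2)
  }
}

## Assemble Louis standard errors on the theta scale used in traces
## (fixed effects, free variance/covariance entries, sigma^2).
louis_se <- function(state, setup, spec) {
  if (is.null(state$Smean)) return(NULL)
  R <- which(spec$random); Fx <- which(!spec$random)
  X <- setup$X
  pR_tot <- sum(vapply(X[R], ncol, 1L))
  pF_tot <- if (length(Fx)) sum(vapply(X[Fx], ncol, 1L)) else 0L
  nB <- length(state$free_cov)
  p <- pR_tot + pF_tot + nB + 1L
  H <- matrix(0, p, p)

  ## random-effect block: (b_R, B_free)
  EQ1 <- .make_EQ1(state, setup, spec)
  par1 <- c(unlist(state$b[R], use.names = FALSE),
            vapply(state$free_cov, function(fc) state$B[fc[1], fc[2]], 0))
  idx1 <- c(seq_len(pR_tot), pR_tot + pF_tot + seq_len(nB))
  H[idx1, idx1] <- .num_hess(EQ1, par1)

  ## residual block: (b_F, sigma^2)
  if (length(Fx)) {
    EQ2 <- .make_EQ2(state, setup, spec)
    par2 <- c(unlist(state$b[Fx], use.names = FALSE), state$sigma2)
    idx2 <- c(pR_tot + seq_len(pF_tot), p)
    H[idx2, idx2] <- .num_hess(EQ2, par2)
  } else {
    s2 <- state$sigma2
    H[p, p] <- setup$n_obs / (2 * s2^2) - state$s_rss / s2^3
  }

  info <- -H - state$Gss + crossprod(state$Smean)
  se <- rep(NA_real_, p)
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V)))) {
    warning("standard errors unavailable: the observed information matrix is singular")
  } else {
    dv <- diag(V)
    bad <- dv <= 0
    if (any(bad)) {
      warning("standard errors unavailable for ", sum(bad),
              " parameter(s): non-positive information")
    }
    se[!bad] <- sqrt(dv[!bad])
  }
  ## theta packing order is: parameters 1..4 in order (alpha then betas),
  ## then free B entries, then sigma2 -- remap the (b_R, b_F) stacking
  nm <- names(state$theta)
  se_theta <- rep(NA_real_, length(nm))
  pos_R <- 0L; pos_F <- 0L
  cursor <- 1L
  for (k in seq_len(spec$npar)) {
    nk <- ncol(X[[k]])
    if (spec$random[k]) {
      se_theta[cursor:(cursor + nk - 1L)] <- se[pos_R + seq_len(nk)]
      pos_R <- pos_R + nk
    } else {
      se_theta[cursor:(cursor + nk - 1L)] <- se[pR_tot + pos_F + seq_len(nk)]
      pos_F <- pos_F + nk
    }
    cursor <- cursor + nk
  }
  se_theta[cursor:(cursor + nB - 1L)] <- se[pR_tot + pF_tot + seq_len(nB)]
  se_theta[length(nm)] <- se[p]
  names(se_theta) <- nm
  list(se = se_theta, info = info)
}

#' Two-sided Wald p-values
#'
#' Computes `p = 2 * (1 - Phi(|estimate| / SE))` for each estimate. Missing or
#' non-positive standard errors yield a missing p-value, never zero.
#'
#' @param estimates Numeric vector of estimates.
#' @param ses Numeric vector of standard errors (same length).
#' @return Numeric vector of p-values.
#' @export
wald_pvalues <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  p <- 2 * stats::pnorm(-abs(estimates / ses))
  p[is.na(ses) | !(ses > 0)] <- NA_real_
  names(p) <- names(estimates)
  p
}

## coefficient of variation (%), as printed in the variance tables
cv_percent <- function(estimates, ses) {
  ifelse(is.na(ses) | estimates == 0, NA_real_, 100 * ses / abs(estimates))
}
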