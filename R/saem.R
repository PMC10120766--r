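## ---------------------------------------------------------------------------
## SAEM engine: maximum-likelihood estimation of the structural mixed models.
##
## E-step: Metropolis-Hastings simulation of the subject random effects eta_i
##   from p(eta_i | y_i; theta), with three kernels (independent prior draw,
##   componentwise random walk, joint random walk), random-walk scales adapted
##   toward a target acceptance rate during the burn-in phase only.
## SA-step: Robbins-Monro averaging of the complete-data sufficient statistics
##   with step gamma_k = 1 for k <= K1 and (k - K1)^(-a) afterwards.
## M-step: closed-form generalized-least-squares update of the fixed effects
##   of parameters carrying random effects, moment update of B under the
##   model's sparsity mask, residual-variance update, and a damped
##   derivative-free step for parameters without random effects (SMM midpoint
##   and Hill slope and their covariate effects).
## ---------------------------------------------------------------------------

## Structural mean that never throws inside the sampler: invalid parameter
## regions (non-positive SMM midpoint) yield NA, which the caller rejects.
.engine_mean <- function(model, t, phi, v = 0) {
  if (model == 0) {
    phi[, 1] + phi[, 2] * t
  } else if (model == 1) {
    mid <- phi[, 3]
    bad <- !(mid > 0)
    if (!any(bad)) return(phi[, 2] + (phi[, 1] - phi[, 2]) / (1 + (t / mid)^phi[, 4]))
    f <- rep(NA_real_, nrow(phi))
    ok <- !bad
    f[ok] <- phi[ok, 2] + (phi[ok, 1] - phi[ok, 2]) /
      (1 + (t[ok] / mid[ok])^phi[ok, 4])
    f
  } else if (model == 2) {
    pmm_abrupt_mean(t, phi[, 1], phi[, 2], phi[, 3], phi[, 4])
  } else {
    pmm_smooth_mean(t, phi[, 1], phi[, 2], phi[, 3], phi[, 4], v)
  }
}

## Prepare engine-scale data from a validated table and a model spec.
.engine_setup <- function(data, spec) {
  idc <- attr(data, "id_col"); tc <- attr(data, "time_col")
  oc <- attr(data, "outcome_col")
  ids <- data[[idc]]
  ord <- order(match(ids, unique(ids)))
  data <- data[ord, , drop = FALSE]
  ids <- data[[idc]]
  subj <- match(ids, unique(ids))
  N <- max(subj)
  tv <- data[[tc]]
  y <- data[[oc]]
  shift <- 0
  t_eng <- tv
  if (spec$model == 1) {
    tb <- .time_before_zero(tv)
    t_eng <- tb$s
    shift <- tb$shift
  }
  first <- !duplicated(subj)
  X <- vector("list", spec$npar)
  for (k in seq_len(spec$npar)) {
    preds <- spec$predictors[[k]]
    Xi <- matrix(1, N, 1)
    colnames(Xi) <- "(alpha)"
    if (length(preds)) {
      for (pcol in preds) {
        if (!pcol %in% names(data)) {
          stop("predictor column '", pcol, "' not found in the data", call. = FALSE)
        }
        if (!is.numeric(data[[pcol]])) {
          stop("predictor column '", pcol, "' must be numeric", call. = FALSE)
        }
        .check_subject_constant(data, idc, pcol)
      }
      Xi <- cbind(Xi, as.matrix(data[first, preds, drop = FALSE]))
      colnames(Xi) <- c("(alpha)", preds)
    }
    X[[k]] <- Xi
  }
  list(y = y, t = t_eng, t_raw = tv, subj = subj, N = N, n_obs = length(y),
       X = X, shift = shift, ids = unique(ids), data = data)
}

## Flatten the engine parameters into the named theta vector used for traces,
## convergence monitoring and standard errors.
.theta_pack <- function(b, B, sigma2, spec, free_cov) {
  pn <- spec$param_names
  out <- c()
  for (k in seq_len(spec$npar)) {
    bk <- b[[k]]
    nms <- names(bk)
    lbl <- c(paste0("alpha.", pn[k]),
             if (length(bk) > 1) paste0("beta.", nms[-1], "(", pn[k], ")"))
    out <- c(out, stats::setNames(bk, lbl))
  }
  R <- which(spec$random)
  for (fc in free_cov) {
    l <- fc[1]; m <- fc[2]
    lbl <- if (l == m) paste0("omega2.", pn[R[l]]) else
      paste0("cov.", pn[R[l]], ".", pn[R[m]])
    out <- c(out, stats::setNames(B[l, m], lbl))
  }
  c(out, sigma2 = sigma2)
}

## Free entries of the random-effect covariance under the model's mask.
.free_cov_entries <- function(mask) {
  q <- nrow(mask)
  out <- list()
  for (l in seq_len(q)) for (m in l:q) if (mask[l, m]) out <- c(out, list(c(l, m)))
  out
}

.near_psd <- function(B) {
  e <- eigen(B, symmetric = TRUE)
  if (min(e$values) >= 0) return(B)
  e$vectors %*% diag(pmax(e$values, 1e-12), nrow(B)) %*% t(e$vectors)
}

## Main engine. `setup` from .engine_setup, start values from the
## initial-values module. Returns the raw fit state.
saem_engine <- function(setup, spec, start, B0, sigma2_0, control) {
  set.seed(control$seed)
  y <- setup$y; t_eng <- setup$t; subj <- setup$subj
  N <- setup$N; n_obs <- setup$n_obs; X <- setup$X
  model <- spec$model; v <- spec$v
  R <- which(spec$random); q <- length(R)
  Fx <- which(!spec$random)
  mask <- spec$cov_mask
  free_cov <- .free_cov_entries(mask)

  C <- control$n_chains
  if (is.null(C)) C <- max(1L, ceiling(50 / N))
  C <- as.integer(C)
  U <- N * C
  subj_u <- rep(seq_len(N), C)                      # subject of each unit
  unit_of_obs <- rep(subj, C) + rep((seq_len(C) - 1L) * N, each = n_obs)
  y_rep <- rep(y, C); t_rep <- rep(t_eng, C)
  Xu <- lapply(X, function(Xi) Xi[subj_u, , drop = FALSE])
  n_per_subj <- as.numeric(table(subj))

  ## starting parameter state
  npar <- spec$npar
  b <- vector("list", npar)
  for (k in seq_len(npar)) {
    b[[k]] <- c(start[k], numeric(ncol(X[[k]]) - 1))
    names(b[[k]]) <- colnames(X[[k]])
  }
  B <- as.matrix(B0)
  sigma2 <- sigma2_0
  eta <- matrix(0, U, q)

  mean_units <- function(b) {
    m <- matrix(0, U, npar)
    for (k in seq_len(npar)) m[, k] <- drop(Xu[[k]] %*% b[[k]])
    m
  }
  phi_units <- function(m, eta) { m[, R] <- m[, R] + eta; m }
  resid_of <- function(phi) {
    f <- .engine_mean(model, t_rep, phi[unit_of_obs, , drop = FALSE], v)
    y_rep - f
  }
  rss_of <- function(resid) {
    r2 <- resid * resid
    r2[is.na(r2)] <- Inf
    drop(rowsum(r2, unit_of_obs))
  }

  m_u <- mean_units(b)
  resid <- resid_of(phi_units(m_u, eta))
  rss_u <- rss_of(resid)
  if (any(!is.finite(rss_u))) {
    stop("SAEM: the likelihood is not finite at the initial values; ",
         "supply initial values via the 'start' option", call. = FALSE)
  }
  Binv <- solve(B)
  prior_q <- rowSums((eta %*% Binv) * eta)

  ## adaptive random-walk scales (relative to the current sd of each effect)
  s_comp <- rep(1, q)
  s_joint <- 0.4
  acc_comp <- rep(0, q); acc_joint <- 0

  K1 <- control$K1; K2 <- control$K2; K <- K1 + K2
  theta0 <- .theta_pack(b, B, sigma2, spec, free_cov)
  p_theta <- length(theta0)
  trace <- matrix(NA_real_, K, p_theta, dimnames = list(NULL, names(theta0)))

  ## SA statistics
  s_phi <- matrix(0, N, q)
  S2 <- matrix(0, q, q)
  s_rss <- 0
  warned_psd <- FALSE

  ## Louis information accumulators (over the SA phase)
  do_se <- control$compute_se
  se_idx <- NULL; Smean <- NULL; Gss <- NULL
  if (do_se) {
    pb_R <- sum(vapply(X[R], ncol, 1L))
    pb_F <- if (length(Fx)) sum(vapply(X[Fx], ncol, 1L)) else 0L
    p_se <- pb_R + pb_F + length(free_cov) + 1L
    Smean <- matrix(0, N, p_se)
    Gss <- matrix(0, p_se, p_se)
  }

  bF_vec <- function(b) unlist(b[Fx], use.names = FALSE)
  bF_assign <- function(b, vec) {
    pos <- 1L
    for (k in Fx) {
      nk <- length(b[[k]])
      b[[k]][] <- vec[pos:(pos + nk - 1L)]
      pos <- pos + nk
    }
    b
  }

  accept_units <- function(logacc) {
    !is.na(logacc) & (log(stats::runif(U)) < logacc)
  }

  cp_lo <- stats::quantile(setup$t_raw, 0.025, names = FALSE)
  cp_hi <- stats::quantile(setup$t_raw, 0.975, names = FALSE)

  for (k_it in seq_len(K)) {
    gamma <- if (k_it <= K1) 1 else (k_it - K1)^(-control$a)
    sdB <- sqrt(pmax(diag(B), 1e-12))
    cholB <- tryCatch(chol(B), error = function(e) chol(.near_psd(B) + diag(1e-12, q)))

    for (sweep in seq_len(control$mh_steps)) {
      ## kernel 1: independent draw from the random-effect prior
      eta_p <- matrix(stats::rnorm(U * q), U, q) %*% cholB
      resid_p <- resid_of(phi_units(m_u, eta_p))
      rss_p <- rss_of(resid_p)
      acc <- accept_units((rss_u - rss_p) / (2 * sigma2))
      if (any(acc)) {
        eta[acc, ] <- eta_p[acc, ]
        rss_u[acc] <- rss_p[acc]
        ao <- acc[unit_of_obs]
        resid[ao] <- resid_p[ao]
        prior_q[acc] <- rowSums((eta[acc, , drop = FALSE] %*% Binv) *
                                  eta[acc, , drop = FALSE])
      }

      ## kernel 2: componentwise random walk
      for (cc in seq_len(q)) {
        eta_p <- eta
        eta_p[, cc] <- eta[, cc] + s_comp[cc] * sdB[cc] * stats::rnorm(U)
        resid_p <- resid_of(phi_units(m_u, eta_p))
        rss_p <- rss_of(resid_p)
        prior_p <- rowSums((eta_p %*% Binv) * eta_p)
        acc <- accept_units((rss_u - rss_p) / (2 * sigma2) +
                              (prior_q - prior_p) / 2)
        rate <- mean(acc)
        if (any(acc)) {
          eta[acc, cc] <- eta_p[acc, cc]
          rss_u[acc] <- rss_p[acc]
          ao <- acc[unit_of_obs]
          resid[ao] <- resid_p[ao]
          prior_q[acc] <- prior_p[acc]
        }
        if (k_it <= K1) {
          s_comp[cc] <- max(1e-3, s_comp[cc] *
                              exp(0.4 * (rate - control$adapt_target)))
        }
        acc_comp[cc] <- acc_comp[cc] + rate
      }

      ## kernel 3: joint random walk along the prior covariance
      eta_p <- eta + s_joint * (matrix(stats::rnorm(U * q), U, q) %*% cholB)
      resid_p <- resid_of(phi_units(m_u, eta_p))
      rss_p <- rss_of(resid_p)
      prior_p <- rowSums((eta_p %*% Binv) * eta_p)
      acc <- accept_units((rss_u - rss_p) / (2 * sigma2) +
                            (prior_q - prior_p) / 2)
      rate <- mean(acc)
      if (any(acc)) {
        eta[acc, ] <- eta_p[acc, , drop = FALSE]
        rss_u[acc] <- rss_p[acc]
        ao <- acc[unit_of_obs]
        resid[ao] <- resid_p[ao]
        prior_q[acc] <- prior_p[acc]
      }
      if (k_it <= K1) {
        s_joint <- max(1e-3, s_joint * exp(0.4 * (rate - control$adapt_target)))
      }
      acc_joint <- acc_joint + rate
    }

    ## ---- stochastic approximation of the sufficient statistics ----
    phiR <- m_u[, R, drop = FALSE] + eta
    phiS <- rowsum(phiR, subj_u) / C
    s_phi <- s_phi + gamma * (phiS - s_phi)
    S2 <- S2 + gamma * (crossprod(phiR) / C - S2)
    s_rss <- s_rss + gamma * (sum(rss_u) / C - s_rss)

    ## ---- Louis score accumulation (SA phase only) ----
    if (do_se && k_it > K1) {
      ## phi = Xb + eta, so the mean residual of the random block is eta itself
      W <- eta %*% Binv
      SbR <- do.call(cbind, lapply(seq_along(R), function(jj) {
        Xu[[R[jj]]] * W[, jj]
      }))
      SFu <- NULL
      if (length(Fx)) {
        Jf <- .bF_jacobian(model, t_rep, m_u, eta, R, Fx, Xu, b, v, unit_of_obs)
        SFu <- rowsum(Jf * (resid / sigma2), unit_of_obs)
      }
      SB <- matrix(0, U, length(free_cov))
      for (jj in seq_along(free_cov)) {
        l <- free_cov[[jj]][1]; m2 <- free_cov[[jj]][2]
        SB[, jj] <- if (l == m2) 0.5 * (W[, l]^2 - Binv[l, l]) else
          W[, l] * W[, m2] - Binv[l, m2]
      }
      s_sig <- matrix(-n_per_subj[subj_u] / (2 * sigma2) + rss_u / (2 * sigma2^2))
      Sunit <- cbind(SbR, SFu, SB, s_sig)
      Ssub <- rowsum(Sunit, subj_u) / C
      Smean <- Smean + gamma * (Ssub - Smean)
      Gss <- Gss + gamma * (crossprod(Sunit) / C - Gss)
    }

    ## ---- M-step ----
    ## fixed effects of random parameters: GLS with the current B
    pR <- vapply(X[R], ncol, 1L)
    off <- c(0, cumsum(pR))
    LHS <- matrix(0, sum(pR), sum(pR))
    RHS <- numeric(sum(pR))
    for (a_i in seq_along(R)) {
      ia <- (off[a_i] + 1):off[a_i + 1]
      for (b_i in seq_along(R)) {
        ib <- (off[b_i] + 1):off[b_i + 1]
        LHS[ia, ib] <- Binv[a_i, b_i] * crossprod(X[[R[a_i]]], X[[R[b_i]]])
        RHS[ia] <- RHS[ia] + Binv[a_i, b_i] *
          drop(crossprod(X[[R[a_i]]], s_phi[, b_i]))
      }
    }
    bR_new <- tryCatch(solve(LHS, RHS), error = function(e) NULL)
    if (!is.null(bR_new)) {
      for (a_i in seq_along(R)) {
        b[[R[a_i]]][] <- bR_new[(off[a_i] + 1):off[a_i + 1]]
      }
    }
    ## the population changepoint stays where both segments are identifiable:
    ## inside the interior quantiles of the observed times, as is standard in
    ## changepoint regression
    if (model %in% c(2L, 3L)) {
      b[[4]][1] <- min(max(b[[4]][1], cp_lo), cp_hi)
    }

    ## covariance of random effects: masked moment update
    M <- vapply(R, function(k) drop(X[[k]] %*% b[[k]]), numeric(N))
    Bfull <- (S2 - crossprod(M, s_phi) - crossprod(s_phi, M) + crossprod(M)) / N
    Bnew <- Bfull
    Bnew[!mask] <- 0
    diag(Bnew) <- pmax(diag(Bnew), 1e-12)
    ## keep masked covariances inside a valid correlation
    for (fc in free_cov) {
      if (fc[1] != fc[2]) {
        l <- fc[1]; m2 <- fc[2]
        lim <- 0.99 * sqrt(Bnew[l, l] * Bnew[m2, m2])
        Bnew[l, m2] <- Bnew[m2, l] <- sign(Bnew[l, m2]) * min(abs(Bnew[l, m2]), lim)
      }
    }
    ev <- eigen(Bnew, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) {
      if (!warned_psd) {
        warning("SAEM: covariance update lost positive semi-definiteness; ",
                "projected to the nearest PSD matrix")
        warned_psd <- TRUE
      }
      Bnew <- .near_psd(Bnew)
      Bnew[!mask] <- 0
      diag(Bnew) <- pmax(diag(Bnew), 1e-12)
    }
    ## simulated-annealing constraint during burn-in: variances may not shrink
    ## faster than geometrically, which keeps the chains exploring and
    ## protects weakly identified components from premature collapse
    if (k_it <= K1 && control$anneal > 0) {
      diag(Bnew) <- pmax(diag(Bnew), control$anneal * diag(B))
    }
    B <- Bnew
    Binv <- tryCatch(solve(B),
                     error = function(e) solve(B + diag(1e-10 * max(diag(B)), q)))

    ## residual variance
    sigma2_new <- max(s_rss / n_obs, 1e-10)
    if (k_it <= K1 && control$anneal > 0) {
      sigma2_new <- max(sigma2_new, control$anneal * sigma2)
    }
    sigma2 <- sigma2_new

    ## parameters without random effects: damped derivative-free step on the
    ## current-draw complete-data criterion
    if (length(Fx)) {
      cur <- bF_vec(b)
      obj <- function(par) {
        bb <- bF_assign(b, par)
        mm <- m_u
        for (k in Fx) mm[, k] <- drop(Xu[[k]] %*% bb[[k]])
        rs <- rss_of(resid_of(phi_units(mm, eta)))
        val <- sum(rs) / C
        if (!is.finite(val)) 1e10 else val
      }
      opt <- stats::optim(cur, obj, method = "Nelder-Mead",
                          control = list(maxit = 10))
      b <- bF_assign(b, cur + gamma * (opt$par - cur))
    }

    m_u <- mean_units(b)
    resid <- resid_of(phi_units(m_u, eta))
    rss_u <- rss_of(resid)
    prior_q <- rowSums((eta %*% Binv) * eta)

    trace[k_it, ] <- .theta_pack(b, B, sigma2, spec, free_cov)
  }

  conv <- .check_convergence(trace, spec, free_cov, control,
                             sd_y = stats::sd(y),
                             t_span = diff(range(setup$t_raw)))

  list(b = b, B = B, sigma2 = sigma2, eta = eta, C = C, subj_u = subj_u,
       trace = trace, converged = conv$converged, conv_stat = conv$stat,
       s_phi = s_phi, S2 = S2, s_rss = s_rss,
       Smean = Smean, Gss = Gss, free_cov = free_cov,
       accept = list(componentwise = acc_comp / K, joint = acc_joint / K),
       scales = list(comp = s_comp, joint = s_joint),
       theta = .theta_pack(b, B, sigma2, spec, free_cov))
}

## Numerical Jacobian of the structural mean with respect to the stacked
## coefficients of the parameters without random effects.
.bF_jacobian <- function(model, t_rep, m_u, eta, R, Fx, Xu, b, v, unit_of_obs) {
  pF <- sum(vapply(b[Fx], length, 1L))
  J <- matrix(0, length(t_rep), pF)
  vec <- unlist(b[Fx], use.names = FALSE)
  pos <- 0L
  phi0 <- m_u
  phi0[, R] <- phi0[, R] + eta
  for (k in Fx) {
    for (j in seq_along(b[[k]])) {
      pos <- pos + 1L
      h <- 1e-4 * max(1, abs(vec[pos]))
      bp <- b; bp[[k]][j] <- bp[[k]][j] + h
      bm <- b; bm[[k]][j] <- bm[[k]][j] - h
      php <- phi0; php[, k] <- drop(Xu[[k]] %*% bp[[k]])
      phm <- phi0; phm[, k] <- drop(Xu[[k]] %*% bm[[k]])
      fp <- .engine_mean(model, t_rep, php[unit_of_obs, , drop = FALSE], v)
      fm <- .engine_mean(model, t_rep, phm[unit_of_obs, , drop = FALSE], v)
      J[, pos] <- (fp - fm) / (2 * h)
    }
  }
  J[!is.finite(J)] <- 0
  J
}

## Convergence diagnostic: largest per-iteration relative parameter change
## over the trailing window of the SA phase. Scales are parameter-aware,
## dimensionally matched, and floored so that the diagnostic measures changes
## material at the scale of the data: outcome-dimension mean parameters
## against max(|value|, 0.1 sd(y)); time-dimension mean parameters (the
## changepoint and its covariate effects) against max(|value|, 0.1 x the
## observed time span); variance-type parameters (variances, masked
## covariances, sigma^2) against max(|value|, (0.1 sd(y))^2).
.check_convergence <- function(trace, spec, free_cov, control, sd_y,
                               t_span = NULL) {
  K <- nrow(trace)
  w <- min(control$window, control$K2 - 1)
  rows <- (K - w):K
  final <- trace[K, ]
  p <- length(final)
  nm <- colnames(trace)
  scale <- numeric(p)
  R <- which(spec$random)
  pn <- spec$param_names
  var_floor <- (0.1 * sd_y)^2
  for (j in seq_len(p)) {
    lab <- nm[j]
    if (startsWith(lab, "omega2.") || lab == "sigma2") {
      scale[j] <- max(abs(final[j]), var_floor)
    } else if (startsWith(lab, "cov.")) {
      pair <- free_cov[[which(vapply(free_cov, function(fc) {
        fc[1] != fc[2] &&
          lab == paste0("cov.", pn[R[fc[1]]], ".", pn[R[fc[2]]])
      }, TRUE))[1]]]
      v1 <- final[paste0("omega2.", pn[R[pair[1]]])]
      v2 <- final[paste0("omega2.", pn[R[pair[2]]])]
      scale[j] <- max(sqrt(abs(v1 * v2)), var_floor)
    } else if (spec$model %in% c(2L, 3L) && grepl("changepoint", lab) &&
               !is.null(t_span)) {
      scale[j] <- max(abs(final[j]), 0.1 * t_span)
    } else {
      scale[j] <- max(abs(final[j]), 0.1 * sd_y)
    }
  }
  dif <- abs(trace[rows[-1], , drop = FALSE] - trace[rows[-length(rows)], , drop = FALSE])
  rel <- sweep(dif, 2, scale, "/")
  stat <- max(rel)
  list(converged = is.finite(stat) && all(is.finite(final)) && stat < control$tol,
       stat = stat)
}
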