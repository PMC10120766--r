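## Shared fixtures and independent oracles used across the test files.
## Everything is generated in code; nothing is read from disk.

## Simulate a random-intercept + random-slope linear mixed model.
make_lmm_data <- function(N = 120, beta = c(2, -0.3), G = matrix(c(1, 0.15, 0.15, 0.04), 2),
                          sigma = 0.5, seed = 7) {
  set.seed(seed)
  L <- chol(G)
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    t_i <- sort(stats::runif(sample(5:10, 1), -12, 0))
    eta <- drop(stats::rnorm(2) %*% L)
    yi <- (beta[1] + eta[1]) + (beta[2] + eta[2]) * t_i +
      stats::rnorm(length(t_i), 0, sigma)
    rows[[i]] <- data.frame(ID = i, time = t_i, outcome = yi)
  }
  do.call(rbind, rows)
}

## Closed-form marginal ML for the linear mixed model: for given variance
## components the fixed effects are profiled by GLS, and the variance
## parameters are maximised numerically over an unconstrained
## log/atanh parameterisation. Completely independent of the SAEM path.
lmm_ml_oracle <- function(data) {
  ids <- unique(data$ID)
  split_rows <- split(seq_len(nrow(data)), data$ID)
  neg_prof <- function(par) {
    out <- tryCatch(.neg_prof_inner(par), error = function(e) 1e12)
    if (!is.finite(out)) 1e12 else out
  }
  .neg_prof_inner <- function(par) {
    v1 <- exp(par[1]); v2 <- exp(par[2]); rho <- tanh(par[3]); s2 <- exp(par[4])
    G <- matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2)
    XtVX <- matrix(0, 2, 2); XtVy <- numeric(2); ldet <- 0
    pieces <- list()
    for (i in seq_along(split_rows)) {
      r <- split_rows[[i]]
      Zi <- cbind(1, data$time[r])
      Vi <- Zi %*% G %*% t(Zi) + diag(s2, length(r))
      ch <- chol(Vi)
      ldet <- ldet + 2 * sum(log(diag(ch)))
      Wi <- chol2inv(ch)
      XtVX <- XtVX + t(Zi) %*% Wi %*% Zi
      XtVy <- XtVy + t(Zi) %*% Wi %*% data$outcome[r]
      pieces[[i]] <- list(Zi = Zi, Wi = Wi, r = r)
    }
    bhat <- solve(XtVX, XtVy)
    quad <- 0
    for (p in pieces) {
      res <- data$outcome[p$r] - p$Zi %*% bhat
      quad <- quad + drop(t(res) %*% p$Wi %*% res)
    }
    0.5 * (ldet + quad + nrow(data) * log(2 * pi))
  }
  opt <- stats::optim(c(0, -3, 0.2, -1), neg_prof, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  par <- opt$par
  v1 <- exp(par[1]); v2 <- exp(par[2]); rho <- tanh(par[3]); s2 <- exp(par[4])
  G <- matrix(c(v1, rho * sqrt(v1 * v2), rho * sqrt(v1 * v2), v2), 2)
  ## fixed effects and their covariance at the optimum
  XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
  for (i in seq_along(split_rows)) {
    r <- split_rows[[i]]
    Zi <- cbind(1, data$time[r])
    Vi <- Zi %*% G %*% t(Zi) + diag(s2, length(r))
    Wi <- chol2inv(chol(Vi))
    XtVX <- XtVX + t(Zi) %*% Wi %*% Zi
    XtVy <- XtVy + t(Zi) %*% Wi %*% data$outcome[r]
  }
  bhat <- solve(XtVX, XtVy)
  list(beta = drop(bhat), beta_se = sqrt(diag(solve(XtVX))),
       G = G, sigma2 = s2, loglik = -neg_prof(par))
}

## Expand the Hermite form of the transition cubic into monomial
## coefficients: an independent route to the same polynomial.
hermite_cubic_oracle <- function(last_level, slope1, slope2, changepoint, v) {
  lambda <- last_level + (slope2 - slope1) * (changepoint + v / 2)
  y0 <- lambda + slope1 * changepoint
  y1 <- last_level + slope2 * (changepoint + v)
  m0 <- slope1 * v
  m1 <- slope2 * v
  ## g(u) in u = (t - cp)/v, then substitute u = (t - cp)/v
  cu <- c(y0,                       # u^0
          m0,                       # u^1
          -3 * y0 - 2 * m0 + 3 * y1 - m1,
          2 * y0 + m0 - 2 * y1 + m1)
  ## binomial expansion of ((t - cp)/v)^k
  a <- numeric(4)
  for (k in 0:3) {
    if (cu[k + 1] == 0) next
    for (j in 0:k) {
      a[j + 1] <- a[j + 1] + cu[k + 1] * choose(k, j) *
        (-changepoint)^(k - j) / v^k
    }
  }
  a
}

## Quick small-iteration control for unit tests of plumbing (not accuracy).
quick_control <- function(seed = 1, ...) {
  saem_control(K1 = 60, K2 = 80, seed = seed, compute_se = FALSE,
               compute_loglik = FALSE, ...)
}
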