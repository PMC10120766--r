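#' Estimated marginal trajectory
#'
#' Evaluates the fitted structural curve at the population fixed effects with
#' random effects set to zero, for a fixed covariate profile (by default the
#' most common profile: mode for discrete covariates, median for continuous
#' ones, computed over subjects).
#'
#' @param fit A `trajmix_fit` object.
#' @param times Evaluation grid on the data timescale; defaults to an annual
#'   grid spanning the observed times.
#' @param profile Optional named list/vector of covariate values; must cover
#'   every covariate in the model.
#' @return A data frame with columns `time` and `pred`.
#' @export
marginal_trajectory <- function(fit, times = NULL, profile = NULL) {
  setup <- fit$setup; spec <- fit$spec
  if (is.null(times)) {
    times <- seq(floor(min(setup$t_raw)), ceiling(max(setup$t_raw)), by = 1)
  }
  profile <- .resolve_profile(fit, profile)
  psi <- .profile_parameters(fit, profile)
  t_eval <- if (spec$model == 1) fit$shift - times else times
  if (spec$model == 1 && any(t_eval < 0)) {
    stop("marginal_trajectory(): requested times lie beyond the fitted ",
         "time-before-zero origin", call. = FALSE)
  }
  phi <- matrix(psi, length(times), fit$spec$npar, byrow = TRUE)
  data.frame(time = times,
             pred = .engine_mean(spec$model, t_eval, phi, spec$v))
}

## covariate profile -> 4-vector of structural parameters (eta = 0)
.profile_parameters <- function(fit, profile) {
  vapply(seq_len(fit$spec$npar), function(k) {
    bk <- fit$state$b[[k]]
    val <- bk[[1]]
    if (length(bk) > 1) {
      for (nm in names(bk)[-1]) {
        if (is.null(profile[[nm]]) || is.na(profile[[nm]])) {
          stop("profile is missing a value for covariate '", nm, "'",
               call. = FALSE)
        }
        val <- val + bk[[nm]] * profile[[nm]]
      }
    }
    val
  }, numeric(1))
}

## most common profile: mode for discrete covariates, median for continuous
.resolve_profile <- function(fit, profile) {
  covars <- unique(unlist(fit$spec$predictors))
  if (!length(covars)) return(list())
  first <- !duplicated(fit$setup$subj)
  defaults <- lapply(covars, function(nm) {
    v <- fit$setup$data[[nm]][first]
    u <- unique(v)
    if (length(u) <= 5) {
      as.numeric(names(sort(table(v), decreasing = TRUE))[1])
    } else {
      stats::median(v)
    }
  })
  names(defaults) <- covars
  if (is.null(profile)) return(defaults)
  for (nm in covars) {
    if (is.null(profile[[nm]])) {
      stop("profile is missing a value for covariate '", nm, "'", call. = FALSE)
    }
  }
  as.list(profile)
}

#' Marginal trajectories contrasted between two covariate groups
#'
#' For a binary covariate the two trajectories are the two observed levels;
#' for a continuous covariate they are its empirical percentile values
#' (linear-interpolation, type-7 convention), by default the 10th and 90th.
#' All other covariates are held at the most common profile.
#'
#' @param fit A `trajmix_fit` object.
#' @param group_var Name of a covariate present in the model.
#' @param probs Percentile pair in (0, 1), increasing.
#' @param times Evaluation grid (see [marginal_trajectory()]).
#' @return A data frame with columns `group` (labelled value), `value`,
#'   `time`, `pred`.
#' @export
group_contrast <- function(fit, group_var, probs = c(0.10, 0.90), times = NULL) {
  covars <- unique(unlist(fit$spec$predictors))
  if (!group_var %in% covars) {
    stop("group_contrast(): '", group_var,
         "' is not a covariate of the fitted model", call. = FALSE)
  }
  stopifnot(length(probs) == 2, probs[1] < probs[2],
            all(probs > 0), all(probs < 1))
  first <- !duplicated(fit$setup$subj)
  v <- fit$setup$data[[group_var]][first]
  u <- sort(unique(v))
  if (length(u) == 2) {
    vals <- u
    labels <- paste0(group_var, " = ", u)
  } else {
    vals <- stats::quantile(v, probs, type = 7, names = FALSE)
    labels <- paste0(group_var, " at p", round(100 * probs), " (", signif(vals, 4), ")")
  }
  base <- .resolve_profile(fit, NULL)
  out <- lapply(seq_along(vals), function(i) {
    prof <- base
    prof[[group_var]] <- vals[i]
    tab <- marginal_trajectory(fit, times = times, profile = prof)
    cbind(group = labels[i], value = vals[i], tab)
  })
  do.call(rbind, out)
}

#' Spaghetti plot of observed individual trajectories
#'
#' Draws one polyline per subject for a random subset of subjects (all of
#' them when there are fewer than `n_shown`). Axis labels default to the raw
#' column names.
#'
#' @param data A `trajmix_data` object.
#' @param n_shown Number of subjects to sample (without replacement).
#' @param seed Seed for the subject sample.
#' @param xlabel,ylabel Optional axis labels.
#' @return A list with `plot` (a ggplot object) and `ids` (the sampled
#'   subject identifiers).
#' @export
spaghetti_plot <- function(data, n_shown = 70, seed = 1,
                           xlabel = NULL, ylabel = NULL) {
  idc <- attr(data, "id_col"); tc <- attr(data, "time_col")
  oc <- attr(data, "outcome_col")
  ids <- unique(data[[idc]])
  set.seed(seed)
  take <- if (length(ids) <= n_shown) ids else sample(ids, n_shown)
  keep <- data[[idc]] %in% take
  dd <- data.frame(id = data[[idc]][keep], time = data[[tc]][keep],
                   outcome = data[[oc]][keep])
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = time, y = outcome, group = id)) +
    ggplot2::geom_line(alpha = 0.45, linewidth = 0.3) +
    ggplot2::labs(x = if (is.null(xlabel)) tc else xlabel,
                  y = if (is.null(ylabel)) oc else ylabel) +
    ggplot2::theme_minimal()
  list(plot = p, ids = take)
}

.trajectory_ggplot <- function(tab, xlabel, ylabel, fit, group = FALSE) {
  tc <- attr(fit$setup$data, "time_col")
  oc <- attr(fit$setup$data, "outcome_col")
  p <- if (group) {
    ggplot2::ggplot(tab, ggplot2::aes(x = time, y = pred, colour = group))
  } else {
    ggplot2::ggplot(tab, ggplot2::aes(x = time, y = pred))
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = if (is.null(xlabel)) tc else xlabel,
                  y = if (is.null(ylabel)) oc else ylabel) +
    ggplot2::theme_minimal()
}

#' Convergence trace plot of the SAEM parameter path
#'
#' @param fit A `trajmix_fit` object.
#' @return A ggplot object, one panel per parameter.
#' @export
convergence_plot <- function(fit) {
  tr <- fit$trace
  long <- data.frame(
    iteration = rep(seq_len(nrow(tr)), ncol(tr)),
    parameter = rep(colnames(tr), each = nrow(tr)),
    value = as.vector(tr)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal()
}

.fmt_num <- function(x, digits = 5) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), format = "g", digits = digits))
}

.fmt_cv <- function(cv) ifelse(is.na(cv), "NA", sprintf("%.1f", cv))

.fmt_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-4, format(p, digits = 2, scientific = TRUE),
                sprintf("%.4f", p)))
}

#' Annotated plain-text summary of a fit
#'
#' Produces the package's standard report: a data and model summary, the
#' initial values, the fixed effects with standard errors, CV% and Wald
#' p-values, the variance-of-random-effects table, the statistical criteria,
#' and the processing-time line.
#'
#' @param fit A `trajmix_fit` object.
#' @return Character vector of report lines (also used by the print method).
#' @export
render_summary <- function(fit) {
  spec <- fit$spec
  labels <- c("Sigmoidal mixed model (SMM)",
              "Piecewise mixed model with abrupt changepoint (PMM-abrupt)",
              "Piecewise mixed model with smooth transition (PMM-smooth)")
  out <- c(
    "----------------------------------------------------",
    paste0("Model: ", labels[spec$model]),
    "----------------------------------------------------",
    sprintf("Data: %d subjects, %d observations (%.1f per subject on average)",
            fit$n_subjects, fit$n_obs, fit$n_obs / fit$n_subjects),
    sprintf("Observed times: %.2f to %.2f", min(fit$setup$t_raw),
            max(fit$setup$t_raw))
  )
  if (spec$model == 1 && fit$shift > 0) {
    out <- c(out, sprintf(
      "Times mapped to time-before-zero with shift %.3f; midpoint is reported on that positive scale",
      fit$shift))
  } else if (spec$model == 1) {
    out <- c(out, "Midpoint and Hill slope are reported on the positive time-before-zero scale")
  }
  if (spec$model == 3) out <- c(out, sprintf("Smooth transition window v = %g", spec$v))
  if (length(fit$data_warnings)) {
    out <- c(out, paste0("Warning: ", fit$data_warnings))
  }
  out <- c(out, "",
           "Initial values (provenance):",
           sprintf("  %-14s %10.4f  [%s]", names(fit$start$start),
                   fit$start$start, fit$start$provenance),
           "",
           "Fixed effects",
           sprintf("  %-32s %10s %10s %7s %9s", "Parameter", "Estimate", "SE",
                   "CV(%)", "p-value"))
  fx <- fit$fixed
  out <- c(out, sprintf("  %-32s %10s %10s %7s %9s", rownames(fx),
                        .fmt_num(fx$estimate), .fmt_num(fx$se, 3),
                        .fmt_cv(fx$cv), .fmt_p(fx$p)))
  out <- c(out, "",
           "Variance of random effects",
           sprintf("  %-14s %-28s %10s %10s %7s", "", "Parameter", "Estimate",
                   "SE", "CV(%)"))
  vc <- fit$varcomp
  lead <- sub("^omega2\\.", "", rownames(vc))
  lead[startsWith(rownames(vc), "cov.")] <- "covar"
  out <- c(out, sprintf("  %-14s %-28s %10s %10s %7s", lead, rownames(vc),
                        .fmt_num(vc$estimate), .fmt_num(vc$se, 3),
                        .fmt_cv(vc$cv)))
  out <- c(out, sprintf("  residual SD    sigma %33s",
                        .fmt_num(fit$estimates$sigma)))
  out <- c(out, "", "Statistical criteria")
  if (!is.null(fit$loglik)) {
    out <- c(out,
             sprintf("  log-likelihood (importance sampling): %.3f (MC SE %.3f)",
                     as.numeric(fit$loglik), attr(fit$loglik, "mc_se")),
             sprintf("  AIC: %.3f   BIC: %.3f", fit$AIC, fit$BIC))
  } else {
    out <- c(out, "  log-likelihood not computed (compute_loglik = FALSE)")
  }
  out <- c(out,
           sprintf("  convergence: %s (max trailing relative change %.2e, tolerance %.0e)",
                   if (isTRUE(fit$converged)) "yes" else "NO",
                   fit$conv_stat, fit$control$tol),
           "",
           sprintf("The program took %.2f seconds", fit$runtime_s))
  out
}
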