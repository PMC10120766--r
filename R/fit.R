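#' Fit a structural mixed model by SAEM
#'
#' Core fitting routine: takes validated data and a model specification,
#' generates initial values (unless the specification carries user starts),
#' runs the SAEM algorithm, and assembles estimates, Louis-type standard
#' errors, Wald p-values and (optionally) the importance-sampling marginal
#' log-likelihood with AIC/BIC.
#'
#' @param data A `trajmix_data` object from [long_data()] or
#'   [read_long_data()].
#' @param spec A [model_spec()] object.
#' @param control A [saem_control()] object.
#' @return A `trajmix_fit` object. Key components: `estimates` (fixed
#'   effects, random-effect covariance `B`, residual SD), `fixed` and
#'   `varcomp` (annotated coefficient tables with SE, CV% and p-values),
#'   `loglik`/`AIC`/`BIC`, `converged`, `trace` (per-iteration parameter
#'   path), `runtime_s`, and the data/algorithm state used by the method
#'   functions.
#' @export
trajmix_fit <- function(data, spec, control = saem_control()) {
  stopifnot(inherits(spec, "trajmix_spec"))
  if (!inherits(data, "trajmix_data")) {
    stop("trajmix_fit(): 'data' must be a trajmix_data object; ",
         "use long_data() or read_long_data() first", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  warn <- data_warnings(data, spec)
  for (w in warn) warning(w, call. = FALSE)

  setup <- .engine_setup(data, spec)
  init <- auto_start(data, spec)
  vstart <- start_variances(data, spec, init$start)
  Rmask <- spec$random
  B0 <- vstart$B

  state <- saem_engine(setup, spec, start = init$start, B0 = B0,
                       sigma2_0 = vstart$sigma2, control = control)

  theta <- state$theta
  se_info <- if (control$compute_se) louis_se(state, setup, spec) else NULL
  ses <- if (is.null(se_info) || is.null(se_info$se)) {
    stats::setNames(rep(NA_real_, length(theta)), names(theta))
  } else {
    se_info$se
  }

  fit <- structure(
    list(spec = spec, control = control, setup = setup, state = state,
         start = init, data_warnings = warn,
         n_subjects = setup$N, n_obs = setup$n_obs,
         shift = setup$shift,
         converged = state$converged, conv_stat = state$conv_stat,
         trace = state$trace),
    class = "trajmix_fit"
  )

  ## annotated tables
  nm <- names(theta)
  is_fixef <- startsWith(nm, "alpha.") | startsWith(nm, "beta.")
  is_var <- startsWith(nm, "omega2.") | startsWith(nm, "cov.")
  fixed <- data.frame(estimate = theta[is_fixef], se = ses[is_fixef],
                      row.names = nm[is_fixef])
  fixed$cv <- cv_percent(fixed$estimate, fixed$se)
  fixed$p <- wald_pvalues(fixed$estimate, fixed$se)
  varcomp <- data.frame(estimate = theta[is_var], se = ses[is_var],
                        row.names = nm[is_var])
  varcomp$cv <- cv_percent(varcomp$estimate, varcomp$se)
  sigma2 <- theta[["sigma2"]]
  fit$fixed <- fixed
  fit$varcomp <- varcomp
  fit$estimates <- list(
    alpha = stats::setNames(vapply(state$b, function(bk) bk[[1]], 0),
                            spec$param_names),
    beta = lapply(state$b, function(bk) bk[-1]),
    B = state$B, sigma2 = sigma2, sigma = sqrt(sigma2),
    sigma2_se = ses[["sigma2"]]
  )
  fit$theta <- theta
  fit$ses <- ses

  if (control$compute_loglik) {
    ll <- marginal_loglik(fit, n_samples = control$is_samples,
                          seed = control$seed + 1L)
    fit$loglik <- ll
    p_free <- attr(ll, "df")
    fit$AIC <- -2 * as.numeric(ll) + 2 * p_free
    fit$BIC <- -2 * as.numeric(ll) + log(setup$N) * p_free
  }

  fit$runtime_s <- proc.time()[["elapsed"]] - t0
  fit
}

#' One-line interface: fit a sigmoidal or changepoint mixed model
#'
#' Convenience front end mirroring the package's one-call workflow: validate
#' the data, build the model specification, fit by SAEM, and optionally
#' prepare marginal-trajectory and spaghetti plots.
#'
#' @param model 1 = sigmoidal mixed model, 2 = piecewise mixed model with
#'   abrupt changepoint, 3 = piecewise model with smooth transition.
#' @param dataset A data frame, a `trajmix_data` object, or the path to a CSV
#'   file.
#' @param ID,outcome,time Names of the identifier, outcome and time columns.
#' @param predictor_all Covariates attached to all four structural
#'   parameters.
#' @param predictor_par1,predictor_par2,predictor_par3,predictor_par4
#'   Covariates attached to individual parameters (see [model_spec()] for the
#'   parameter order).
#' @param start Optional vector of four user initial values (model order).
#' @param v Smooth-transition window length (model 3).
#' @param traj_marg If `TRUE`, compute the estimated marginal trajectory at
#'   the most common covariate profile and attach a plot.
#' @param traj_marg_group Optional covariate name whose groups (binary) or
#'   percentiles (continuous) are contrasted in a second trajectory plot.
#' @param traj_marg_group_val Percentile pair for continuous group contrasts.
#' @param spaghetti If `TRUE`, attach a spaghetti plot of `n_spaghetti`
#'   randomly selected individual trajectories.
#' @param n_spaghetti Number of subjects drawn for the spaghetti plot.
#' @param plot_xlabel,plot_ylabel Optional axis labels; default to the raw
#'   column names.
#' @param control A [saem_control()] object.
#' @return A `trajmix_fit` object; any requested plots are in `$plots` and
#'   trajectory tables in `$trajectories`.
#' @examples
#' \donttest{
#' dat <- simulate_longdata(sim_scenario("pmm", n_subjects = 60, seed = 1))
#' fit <- trajmix(2, dat, ID = "ID", outcome = "outcome", time = "time",
#'                control = saem_control(K1 = 60, K2 = 80,
#'                                       compute_loglik = FALSE))
#' print(fit)
#' }
#' @export
trajmix <- function(model, dataset, ID, outcome, time,
                    predictor_all = NULL,
                    predictor_par1 = NULL, predictor_par2 = NULL,
                    predictor_par3 = NULL, predictor_par4 = NULL,
                    start = NULL, v = 2,
                    traj_marg = FALSE, traj_marg_group = NULL,
                    traj_marg_group_val = c(0.10, 0.90),
                    spaghetti = FALSE, n_spaghetti = 70,
                    plot_xlabel = NULL, plot_ylabel = NULL,
                    control = saem_control()) {
  spec <- model_spec(model, predictor_all = predictor_all,
                     predictor_par1 = predictor_par1,
                     predictor_par2 = predictor_par2,
                     predictor_par3 = predictor_par3,
                     predictor_par4 = predictor_par4,
                     start = start, v = v)
  covars <- unique(unlist(spec$predictors))
  if (is.character(dataset)) {
    dataset <- read_long_data(dataset, id = ID, outcome = outcome, time = time,
                              covariates = if (length(covars)) covars)
  } else if (!inherits(dataset, "trajmix_data")) {
    dataset <- long_data(dataset, id = ID, outcome = outcome, time = time,
                         covariates = if (length(covars)) covars)
  }
  fit <- trajmix_fit(dataset, spec, control)
  fit$plots <- list()
  fit$trajectories <- list()
  if (spaghetti) {
    sp <- spaghetti_plot(dataset, n_shown = n_spaghetti, seed = control$seed,
                         xlabel = plot_xlabel, ylabel = plot_ylabel)
    fit$plots$spaghetti <- sp$plot
    fit$spaghetti_ids <- sp$ids
  }
  if (traj_marg) {
    tab <- marginal_trajectory(fit)
    fit$trajectories$marginal <- tab
    fit$plots$marginal <- .trajectory_ggplot(tab, plot_xlabel, plot_ylabel, fit)
  }
  if (!is.null(traj_marg_group)) {
    tab <- group_contrast(fit, group_var = traj_marg_group,
                          probs = traj_marg_group_val)
    fit$trajectories$group <- tab
    fit$plots$group <- .trajectory_ggplot(tab, plot_xlabel, plot_ylabel, fit,
                                          group = TRUE)
  }
  fit
}

#' @export
print.trajmix_fit <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' @export
summary.trajmix_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.trajmix_fit <- function(object, ...) {
  stats::setNames(object$fixed$estimate, rownames(object$fixed))
}

#' Write the full fit result to a JSON file
#'
#' Serialises estimates, standard errors, CV%, p-values, the information
#' criteria and the convergence record.
#'
#' @param fit A `trajmix_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
fit_to_json <- function(fit, path) {
  payload <- list(
    model = fit$spec$model,
    param_names = fit$spec$param_names,
    estimates = as.list(fit$theta),
    ses = as.list(fit$ses),
    fixed_effects = cbind(parameter = rownames(fit$fixed), fit$fixed),
    variance_of_random_effects = cbind(parameter = rownames(fit$varcomp),
                                       fit$varcomp),
    loglik = if (!is.null(fit$loglik)) as.numeric(fit$loglik),
    AIC = fit$AIC, BIC = fit$BIC,
    converged = fit$converged,
    n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    runtime_s = fit$runtime_s
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
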