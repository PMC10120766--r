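#' Define a simulation scenario for decedent-style longitudinal data
#'
#' Builds the generative configuration used throughout the package's testing
#' and validation: retrospective annual visit schedules aligned at time zero
#' (death) and a sigmoid or broken-stick mean trajectory with Gaussian random
#' effects and residual noise. The default `truth` for each model reproduces
#' the generative values of the package's performance study: for the
#' sigmoidal model, last level -1.03, initial level 0.37, midpoint 4.0 (on the
#' positive time-before-death scale), Hill slope 1.69, random-effect SDs 1.46
#' and 0.51 (uncorrelated) on the two levels, residual SD 0.28; for the
#' piecewise model, last level -1.21, slope1 -0.03, slope2 -0.32, changepoint
#' -3, random-effect SDs 1.70, 0.01, 0.05 and 6.91 with correlation -0.07
#' between the two slopes, residual SD 0.28.
#'
#' @param model `"smm"` (or 1) for the sigmoidal structure, `"pmm"` (or 2)
#'   for the piecewise structure.
#' @param n_subjects Number of subjects.
#' @param n_covariates Number of standard-normal, subject-constant covariates
#'   attached to every structural parameter (0, 1 or 2), each with effect
#'   size `beta`.
#' @param beta Covariate effect size used when `n_covariates > 0`.
#' @param mean_followup,sd_followup Mean and SD (years) of the normal
#'   follow-up span, truncated to `[min_obs, max_span]` by regeneration.
#' @param max_span Maximum retrospective span in years (visits lie in
#'   `[-max_span, 0]`).
#' @param min_obs Minimum number of visits per subject.
#' @param jitter Half-width (years) of the uniform jitter around the annual
#'   visit grid (default 2 months).
#' @param truth Optional list overriding the generative parameters:
#'   `alpha` (4-vector), `B` (random-effect covariance), `sigma` (residual
#'   SD), and optionally `beta` (list per parameter, as in [param_link()]).
#' @param seed Integer seed.
#' @return A `trajmix_scenario` object.
#' @export
sim_scenario <- function(model = c("smm", "pmm"), n_subjects = 100,
                         n_covariates = 0, beta = 0.1,
                         mean_followup = 10, sd_followup = 5, max_span = 24,
                         min_obs = 4, jitter = 2 / 12, truth = NULL, seed = 1) {
  if (is.numeric(model)) model <- c("smm", "pmm")[model]
  model <- match.arg(model)
  stopifnot(n_subjects >= 1, min_obs >= 1, n_covariates %in% 0:2)
  model_id <- if (model == "smm") 1L else 2L
  default_truth <- if (model == "smm") {
    list(alpha = c(-1.03, 0.37, 4.0, 1.69),
         B = diag(c(1.46, 0.51)^2),
         sigma = 0.28)
  } else {
    B <- diag(c(1.70, 0.01, 0.05, 6.91)^2)
    B[2, 3] <- B[3, 2] <- -0.07 * 0.01 * 0.05
    list(alpha = c(-1.21, -0.03, -0.32, -3), B = B, sigma = 0.28)
  }
  if (!is.null(truth)) default_truth[names(truth)] <- truth
  truth <- default_truth
  if (min(eigen(truth$B, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("sim_scenario(): truth$B is not positive semi-definite", call. = FALSE)
  }
  bl <- truth$beta
  if (is.null(bl) && n_covariates > 0) {
    bl <- lapply(1:4, function(k) {
      stats::setNames(rep(beta, n_covariates), paste0("X", seq_len(n_covariates)))
    })
    names(bl) <- paste0("par", 1:4)
  }
  structure(
    list(model = model, model_id = model_id, n_subjects = as.integer(n_subjects),
         n_covariates = as.integer(n_covariates), truth = truth, beta = bl,
         mean_followup = mean_followup, sd_followup = sd_followup,
         max_span = max_span, min_obs = as.integer(min_obs), jitter = jitter,
         seed = as.integer(seed)),
    class = "trajmix_scenario"
  )
}

#' Generate one subject's visit schedule
#'
#' Draws a follow-up span from a normal distribution truncated (by
#' regeneration) to `[min_obs, max_span]` years, lays out annual visits from
#' minus the span to zero, and jitters each visit uniformly within
#' `[-jitter, jitter]` years. Times are clamped to `[-max_span, 0]`.
#'
#' @param scenario A [sim_scenario()] object.
#' @param i Subject index (affects only the random stream position; call
#'   inside an outer `set.seed()` loop or rely on [simulate_longdata()]).
#' @return Sorted numeric vector of at least `min_obs` visit times.
#' @export
generate_visits <- function(scenario, i = 1L) {
  span <- Inf
  repeat {
    span <- stats::rnorm(1, scenario$mean_followup, scenario$sd_followup)
    if (span >= scenario$min_obs && span <= scenario$max_span) break
  }
  years <- seq(-floor(span), 0, by = 1)
  t <- years + stats::runif(length(years), -scenario$jitter, scenario$jitter)
  t <- pmin(0, pmax(-scenario$max_span, t))
  sort(t)
}

#' Simulate a longitudinal dataset from a scenario
#'
#' Draws subject-level random effects from `MVN(0, B)` (with the model's
#' sparsity), builds the subject parameters through [link_parameters()],
#' evaluates the structural trajectory at the generated visit times and adds
#' `N(0, sigma^2)` residual noise. The generative truth (including the drawn
#' random effects) is attached for oracle testing.
#'
#' @param scenario A [sim_scenario()] object.
#' @return A `trajmix_data` object with columns `ID`, `time`, `outcome` and
#'   any covariates, plus a `truth` attribute (`alpha`, `beta`, `B`, `sigma`,
#'   `eta`, `X`).
#' @export
simulate_longdata <- function(scenario) {
  stopifnot(inherits(scenario, "trajmix_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_subjects
  random <- model_random_mask(scenario$model_id)
  q <- sum(random)
  eta <- if (all(scenario$truth$B == 0)) {
    matrix(0, n, q)
  } else {
    L <- chol(scenario$truth$B + diag(1e-12, q))
    matrix(stats::rnorm(n * q), n, q) %*% L
  }
  X <- NULL
  if (scenario$n_covariates > 0) {
    X <- matrix(stats::rnorm(n * scenario$n_covariates), n,
                dimnames = list(NULL, paste0("X", seq_len(scenario$n_covariates))))
  }
  link <- param_link(alpha = scenario$truth$alpha, beta = scenario$beta,
                     random = random, B = scenario$truth$B,
                     sigma = scenario$truth$sigma)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- generate_visits(scenario, i)
    covs <- if (is.null(X)) NULL else as.list(X[i, ])
    psi <- link_parameters(link, covariates = covs, eta = eta[i, ])
    f <- if (scenario$model_id == 1) {
      smm_mean(-t_i, psi[1], psi[2], psi[3], psi[4])
    } else {
      pmm_abrupt_mean(t_i, psi[1], psi[2], psi[3], psi[4])
    }
    y <- f + stats::rnorm(length(t_i), 0, scenario$truth$sigma)
    row <- data.frame(ID = i, time = t_i, outcome = y)
    if (!is.null(X)) row <- cbind(row, as.data.frame(as.list(X[i, ])))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  ld <- long_data(out, id = "ID", outcome = "outcome", time = "time",
                  covariates = if (is.null(X)) NULL else colnames(X))
  attr(ld, "truth") <- list(alpha = scenario$truth$alpha, beta = scenario$beta,
                            B = scenario$truth$B, sigma = scenario$truth$sigma,
                            eta = eta, X = X)
  ld
}

#' Synthetic demonstration dataset of cognitive decline before death
#'
#' Generates the package's demonstration table: a synthetic stand-in for a
#' decedent cohort with annual cognitive testing, 1200 individuals followed on
#' average 7 (SD 5) years with at least 4 visits, columns `ID`, `time`
#' (negative years before death), `cognition` and `ageDeath`. Trajectories
#' follow a broken-stick decline whose last level and changepoint worsen
#' mildly with age at death (drawn normal with mean 90, SD 6, truncated to
#' [65, 108]), so that covariate-adjusted example analyses behave
#' qualitatively like published decedent-cohort analyses. This is simulated
#' data, not a copy of any real cohort or of any distributed dataset.
#'
#' @param seed Integer seed.
#' @return A `trajmix_data` object with 1200 subjects.
#' @export
example_dataset <- function(seed = 42) {
  B <- diag(c(1.04, 0.025, 0.20, 0.77)^2)
  B[2, 3] <- B[3, 2] <- 0.2 * 0.025 * 0.20
  scen <- sim_scenario("pmm", n_subjects = 1200, mean_followup = 7,
                       sd_followup = 5, min_obs = 4,
                       truth = list(alpha = c(-1.2, -0.03, -0.32, -3),
                                    B = B, sigma = 0.28,
                                    beta = list(par1 = c(ageDeath90 = -0.05),
                                                par2 = NULL, par3 = NULL,
                                                par4 = c(ageDeath90 = -0.10))),
                       seed = seed)
  set.seed(seed + 1)
  age <- stats::rnorm(1200, 90, 6)
  while (any(bad <- age < 65 | age > 108)) {
    age[bad] <- stats::rnorm(sum(bad), 90, 6)
  }
  ## re-simulate with the age covariate injected as ageDeath90
  set.seed(seed)
  random <- rep(TRUE, 4)
  L <- chol(B + diag(1e-12, 4))
  eta <- matrix(stats::rnorm(1200 * 4), 1200, 4) %*% L
  link <- param_link(alpha = scen$truth$alpha, beta = scen$truth$beta,
                     random = random, B = B, sigma = 0.28)
  rows <- vector("list", 1200)
  for (i in seq_len(1200)) {
    t_i <- generate_visits(scen, i)
    psi <- link_parameters(link, covariates = list(ageDeath90 = age[i] - 90),
                           eta = eta[i, ])
    y <- pmm_abrupt_mean(t_i, psi[1], psi[2], psi[3], psi[4]) +
      stats::rnorm(length(t_i), 0, 0.28)
    rows[[i]] <- data.frame(ID = 1000 + i, time = round(t_i, 2),
                            cognition = round(y, 2), ageDeath = round(age[i]))
  }
  out <- do.call(rbind, rows)
  long_data(out, id = "ID", outcome = "cognition", time = "time",
            covariates = "ageDeath")
}

#' Read a simulation scenario from a YAML or JSON config file
#'
#' The file may name any argument of [sim_scenario()]; `truth` entries
#' (`alpha`, `B`, `sigma`) override the model defaults. `B` may be given as a
#' full matrix (list of rows) or as `sd` plus optional `corr` entries.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `trajmix_scenario` object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("read_scenario(): file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$model)) stop("read_scenario(): config must name 'model'", call. = FALSE)
  truth <- cfg$truth
  if (!is.null(truth)) {
    if (!is.null(truth$B)) truth$B <- matrix(unlist(truth$B), nrow = length(truth$B))
    truth <- truth[intersect(names(truth), c("alpha", "B", "sigma", "beta"))]
  }
  args <- cfg[intersect(names(cfg), c("model", "n_subjects", "n_covariates", "beta",
                                      "mean_followup", "sd_followup", "max_span",
                                      "min_obs", "jitter", "seed"))]
  args$truth <- truth
  bad <- setdiff(names(cfg), c(names(args), "truth"))
  if (length(bad)) {
    stop("read_scenario(): unknown configuration field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_scenario, args)
}

#' Simulate a scenario to files (dataset CSV plus truth JSON)
#'
#' @param scenario A [sim_scenario()] object or the path to a scenario config
#'   file (see [read_scenario()]).
#' @param csv_path Output CSV path for the simulated dataset.
#' @param truth_path Output JSON path for the generative truth and scenario.
#' @return Invisibly, a list with the data and truth.
#' @export
simulate_scenario_files <- function(scenario, csv_path, truth_path) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  ld <- simulate_longdata(scenario)
  write_long_data(ld, csv_path)
  truth <- attr(ld, "truth")
  payload <- list(
    scenario = list(model = scenario$model, n_subjects = scenario$n_subjects,
                    n_covariates = scenario$n_covariates,
                    mean_followup = scenario$mean_followup,
                    sd_followup = scenario$sd_followup,
                    max_span = scenario$max_span, min_obs = scenario$min_obs,
                    jitter = scenario$jitter, seed = scenario$seed),
    truth = list(alpha = truth$alpha, B = truth$B, sigma = truth$sigma)
  )
  jsonlite::write_json(payload, truth_path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(list(data = ld, truth = payload))
}

#' Rebuild a scenario from a truth JSON written by [simulate_scenario_files()]
#'
#' @param path Path to the truth JSON.
#' @return A `trajmix_scenario` object equal to the one that produced it.
#' @export
scenario_from_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_scenario(model = p$scenario$model, n_subjects = p$scenario$n_subjects,
               n_covariates = p$scenario$n_covariates,
               mean_followup = p$scenario$mean_followup,
               sd_followup = p$scenario$sd_followup,
               max_span = p$scenario$max_span, min_obs = p$scenario$min_obs,
               jitter = p$scenario$jitter, seed = p$scenario$seed,
               truth = list(alpha = p$truth$alpha,
                            B = matrix(unlist(p$truth$B), nrow = length(p$truth$alpha) -
                                         (if (p$scenario$model == "smm") 2 else 0)),
                            sigma = p$truth$sigma))
}
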