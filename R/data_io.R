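#' Validate a long-format longitudinal table
#'
#' Normalises a long-format repeated-measures data frame: one row per
#' subject-visit, with a subject identifier, an observation time (any affine
#' timescale; negative times such as years before death are fine) and a
#' continuous outcome. Rows with a missing identifier, time or outcome are
#' dropped (listwise deletion) with a logged count. Duplicate
#' `(subject, time)` pairs are retained but flagged, since the residual model
#' absorbs them.
#'
#' @param data A data frame.
#' @param id,outcome,time Names of the identifier, outcome and time columns.
#' @param covariates Optional character vector of covariate columns to
#'   validate: they must exist and be constant within subject (time-varying
#'   covariates are rejected).
#' @return A `trajmix_data` object: the cleaned data frame carrying the column
#'   mapping, the number of subjects, the per-subject observation counts and
#'   the number of dropped rows as attributes.
#' @export
long_data <- function(data, id, outcome, time, covariates = NULL) {
  data <- as.data.frame(data)
  for (col in c(id, outcome, time, covariates)) {
    if (!col %in% names(data)) {
      stop("long_data(): column '", col, "' not found in the data", call. = FALSE)
    }
  }
  for (col in c(outcome, time)) {
    if (!is.numeric(data[[col]])) {
      stop("long_data(): column '", col, "' must be numeric", call. = FALSE)
    }
  }
  n_in <- nrow(data)
  keep <- !(is.na(data[[id]]) | is.na(data[[outcome]]) | is.na(data[[time]]))
  if (!is.null(covariates)) {
    for (col in covariates) keep <- keep & !is.na(data[[col]])
  }
  dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) {
    stop("long_data(): no usable rows after removing missing values", call. = FALSE)
  }
  if (dropped > 0) {
    message("long_data(): dropped ", dropped, " of ", n_in,
            " rows with missing id/outcome/time",
            if (!is.null(covariates)) "/covariate" else "")
  }
  data[[id]] <- as.character(data[[id]])
  if (!is.null(covariates)) {
    for (col in covariates) .check_subject_constant(data, id, col)
  }
  counts <- table(data[[id]])
  dup <- anyDuplicated(data[, c(id, time)])
  structure(
    data,
    class = c("trajmix_data", "data.frame"),
    id_col = id, outcome_col = outcome, time_col = time,
    n_subjects = length(counts),
    n_obs_per_subject = as.integer(counts),
    n_dropped = dropped,
    has_duplicate_times = dup > 0
  )
}

## reject time-varying covariates
.check_subject_constant <- function(data, id, col) {
  nvals <- tapply(data[[col]], data[[id]], function(x) length(unique(x)))
  if (any(nvals > 1)) {
    bad <- names(nvals)[which(nvals > 1)[1]]
    stop("long_data(): covariate '", col, "' varies within subject (e.g. subject ",
         bad, "); time-varying covariates are not supported", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a long-format longitudinal CSV file
#'
#' Reads a header-rowed, '.'-decimal CSV and validates it with [long_data()].
#'
#' @param path Path to the CSV file.
#' @inheritParams long_data
#' @return A `trajmix_data` object.
#' @export
read_long_data <- function(path, id, outcome, time, covariates = NULL) {
  if (!file.exists(path)) {
    stop("read_long_data(): file not found: ", path, call. = FALSE)
  }
  data <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("read_long_data(): cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(data) == 0) {
    stop("read_long_data(): '", path, "' contains no data rows", call. = FALSE)
  }
  long_data(data, id = id, outcome = outcome, time = time, covariates = covariates)
}

#' Write a validated longitudinal table back to CSV
#'
#' @param data A `trajmix_data` object (or plain data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Append a centered copy of a covariate
#'
#' Adds `new_name = source - center` to the table, the usual device for making
#' intercept-scale parameters interpretable (e.g. age at death centered at 90).
#'
#' @param data A `trajmix_data` object or data frame.
#' @param source Name of the numeric column to center.
#' @param center Centering constant.
#' @param new_name Name of the new column; defaults to `<source><center>`.
#' @return The input with the extra column, attributes preserved.
#' @export
center_covariate <- function(data, source, center,
                             new_name = paste0(source, center)) {
  if (!source %in% names(data)) {
    stop("center_covariate(): column '", source, "' not found", call. = FALSE)
  }
  if (!is.numeric(data[[source]])) {
    stop("center_covariate(): column '", source, "' is not numeric", call. = FALSE)
  }
  data[[new_name]] <- data[[source]] - center
  data
}

#' Data-quality warnings for a planned model fit
#'
#' Returns (never raises) a character vector of warnings about the data in
#' relation to a model specification: a small-sample warning when there are
#' fewer than `small_n` subjects, a covariate-count warning when the total
#' number of fixed effects exceeds `n_subjects / covariate_ratio`, and a note
#' about duplicated `(subject, time)` rows. Thresholds are conventions of this
#' package (the literature names the warnings but no cutoffs) and can be
#' overridden.
#'
#' @param data A `trajmix_data` object.
#' @param spec Optional [model_spec()]; when supplied, the fixed-effect count
#'   includes its covariate effects.
#' @param small_n Subject-count threshold for the small-sample warning.
#' @param covariate_ratio Subjects-per-fixed-effect threshold.
#' @return Character vector of warnings (possibly empty).
#' @export
data_warnings <- function(data, spec = NULL, small_n = 50, covariate_ratio = 10) {
  out <- character(0)
  n <- attr(data, "n_subjects")
  if (is.null(n)) n <- length(unique(data[[1]]))
  if (n < small_n) {
    out <- c(out, sprintf(
      "small sample: %d subjects (< %d); estimates and standard errors may be unstable",
      n, small_n))
  }
  p_total <- 4L
  if (!is.null(spec)) {
    p_total <- p_total + sum(lengths(spec$predictors))
  }
  if (p_total > n / covariate_ratio) {
    out <- c(out, sprintf(
      "many fixed effects: %d parameters for %d subjects (more than 1 per %d subjects)",
      p_total, n, covariate_ratio))
  }
  if (isTRUE(attr(data, "has_duplicate_times"))) {
    out <- c(out, "duplicate (subject, time) rows present; they are retained and absorbed by the residual error")
  }
  out
}
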