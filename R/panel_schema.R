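#' Declare the roles of columns in a wide-format longitudinal panel
#'
#' A panel schema assigns every analysis column a role: baseline covariate,
#' per-wave exposure, per-wave time-varying confounder, per-wave censoring
#' indicator, outcome, or sampling weight.  Wave labels are free strings whose
#' order in `exposure_waves` is the temporal order, so designs with
#' non-contiguous intervention waves (e.g. waves 1 and 4 of a six-wave panel)
#' are representable without placeholder waves.
#'
#' Censoring indicators are coded 1 = observed at that wave, 0 = censored
#' (dropped out before that wave), and must be monotone within participant.
#' A missing exposure at a wave is treated as censoring at that wave, not
#' silently recoded.
#'
#' Ordinal covariates are expected to arrive already dichotomised or numeric;
#' the schema does not re-encode them.
#'
#' @param baseline_covariates Character vector of baseline covariate columns.
#' @param exposure_waves Named character vector mapping wave label to exposure
#'   column, in temporal order, e.g. `c(t1 = "a_t1", t4 = "a_t4")`.
#' @param censoring Named character vector mapping each wave label to its
#'   censoring-indicator column.
#' @param outcomes Character vector of outcome columns, measured at the final
#'   wave.
#' @param time_varying Named list mapping wave label to the columns of
#'   time-varying confounders measured at that wave (may be empty for a wave
#'   whose lagged confounders are already among the baseline covariates).
#' @param outcome_censoring Optional column indicating observation of the
#'   outcome wave (1 = observed).
#' @param weight_column Optional column of post-stratification weights,
#'   accepted as input (weight construction is out of scope).
#' @param exposure_type `"binary"` or `"continuous"`.
#' @param time_varying_predecessor Optional named character vector mapping a
#'   time-varying column to the column holding the most recent earlier
#'   measurement of the same variable (a baseline covariate or an earlier
#'   wave's time-varying column); used by [carry_forward_time_varying()].
#' @param outcome_domains Optional named character vector mapping outcome
#'   column to a presentation domain label.
#' @return An object of class `panel_schema`.
#' @export
panel_schema <- function(baseline_covariates, exposure_waves, censoring,
                         outcomes, time_varying = NULL, outcome_censoring = NULL,
                         weight_column = NULL,
                         exposure_type = c("binary", "continuous"),
                         time_varying_predecessor = NULL,
                         outcome_domains = NULL) {
  exposure_type <- match.arg(exposure_type)
  waves <- names(exposure_waves)
  if (is.null(waves) || any(waves == "") || anyDuplicated(waves)) {
    stop_sdr("sdrshift_schema_error",
             "exposure_waves must be a named vector with unique wave labels")
  }
  if (length(exposure_waves) < 1L) {
    stop_sdr("sdrshift_schema_error", "at least one exposure wave is required")
  }
  if (is.null(time_varying)) {
    time_varying <- stats::setNames(rep(list(character(0)), length(waves)), waves)
  }
  if (!all(waves %in% names(time_varying))) {
    time_varying[setdiff(waves, names(time_varying))] <- list(character(0))
  }
  time_varying <- time_varying[waves]
  if (!all(waves %in% names(censoring))) {
    stop_sdr("sdrshift_schema_error",
             "censoring must name a column for every exposure wave")
  }
  schema <- structure(
    list(
      baseline_covariates = as.character(baseline_covariates),
      exposure_waves = exposure_waves,
      time_varying = time_varying,
      censoring = censoring[waves],
      outcome_censoring = outcome_censoring,
      outcomes = as.character(outcomes),
      weight_column = weight_column,
      exposure_type = exposure_type,
      time_varying_predecessor = time_varying_predecessor,
      outcome_domains = outcome_domains
    ),
    class = "panel_schema"
  )
  roles <- schema_columns(schema)
  dup <- roles$column[duplicated(roles$column)]
  if (length(dup)) {
    stop_sdr("sdrshift_schema_error",
             "column(s) assigned two roles: %s", paste(unique(dup), collapse = ", "))
  }
  schema
}

# All (column, role) pairs declared by a schema.
schema_columns <- function(schema) {
  mk <- function(cols, role) {
    cols <- as.character(cols %||% character(0))
    if (!length(cols)) return(NULL)
    data.frame(column = cols, role = role, stringsAsFactors = FALSE)
  }
  rows <- list(
    mk(schema$baseline_covariates, "baseline"),
    mk(unname(schema$exposure_waves), "exposure"),
    mk(unlist(schema$time_varying, use.names = FALSE), "time_varying"),
    mk(unname(schema$censoring), "censoring"),
    mk(schema$outcomes, "outcome"),
    mk(schema$outcome_censoring, "censoring"),
    mk(schema$weight_column, "weight")
  )
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out[out$column != "", , drop = FALSE]
}

#' Number of exposure waves declared by a schema
#' @param schema A `panel_schema`.
#' @return Integer count of intervention waves.
#' @export
n_waves <- function(schema) length(schema$exposure_waves)

#' @export
print.panel_schema <- function(x, ...) {
  cat("<panel_schema>\n")
  cat("  baseline covariates:", length(x$baseline_covariates), "\n")
  cat("  exposure waves (", x$exposure_type, "): ",
      paste(sprintf("%s=%s", names(x$exposure_waves), x$exposure_waves), collapse = ", "),
      "\n", sep = "")
  tv <- vapply(x$time_varying, length, 1L)
  cat("  time-varying: ", paste(sprintf("%s:%d", names(tv), tv), collapse = ", "), "\n", sep = "")
  cat("  outcomes:", length(x$outcomes), "\n")
  if (!is.null(x$weight_column)) cat("  weights:", x$weight_column, "\n")
  invisible(x)
}

#' Read or write a panel schema as a YAML sidecar
#'
#' @param path File path of the YAML document.
#' @return `read_panel_schema` returns a `panel_schema`;
#'   `write_panel_schema` returns `path` invisibly.
#' @export
read_panel_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  panel_schema(
    baseline_covariates = unlist(raw$baseline_covariates),
    exposure_waves = unlist(raw$exposure_waves),
    censoring = unlist(raw$censoring),
    outcomes = unlist(raw$outcomes),
    time_varying = lapply(raw$time_varying, function(z) as.character(unlist(z))),
    outcome_censoring = raw$outcome_censoring,
    weight_column = raw$weight_column,
    exposure_type = raw$exposure_type %||% "binary",
    time_varying_predecessor = if (!is.null(raw$time_varying_predecessor)) {
      unlist(raw$time_varying_predecessor)
    },
    outcome_domains = if (!is.null(raw$outcome_domains)) unlist(raw$outcome_domains)
  )
}

#' @rdname read_panel_schema
#' @param schema A `panel_schema` to serialise.
#' @export
write_panel_schema <- function(schema, path) {
  out <- list(
    baseline_covariates = schema$baseline_covariates,
    exposure_waves = as.list(schema$exposure_waves),
    time_varying = lapply(schema$time_varying, as.list),
    censoring = as.list(schema$censoring),
    outcome_censoring = schema$outcome_censoring,
    outcomes = schema$outcomes,
    weight_column = schema$weight_column,
    exposure_type = schema$exposure_type,
    time_varying_predecessor = if (!is.null(schema$time_varying_predecessor)) {
      as.list(schema$time_varying_predecessor)
    },
    outcome_domains = if (!is.null(schema$outcome_domains)) as.list(schema$outcome_domains)
  )
  yaml::write_yaml(out[!vapply(out, is.null, TRUE)], path)
  invisible(path)
}
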