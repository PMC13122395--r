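#' Construct and validate a longitudinal panel dataset
#'
#' Binds a wide-format table (one row per participant) to a [panel_schema()]
#' and checks the structural invariants every downstream stage relies on:
#'
#' * every schema column is present in the table;
#' * censoring indicators are monotone within participant — once censored,
#'   all later waves remain censored and their exposures, time-varying
#'   confounders and outcomes are missing;
#' * for a binary exposure, values are in `{0, 1, NA}`;
#' * a missing exposure at an observed wave is an invariant breach (exposure
#'   missingness must be expressed through the censoring indicators).
#'
#' @param records A data.frame, one row per participant.
#' @param schema A [panel_schema()].
#' @param provenance Character vector log of transformations already applied.
#' @return An object of class `panel_dataset` with elements `records`,
#'   `schema`, `provenance`.
#' @export
panel_dataset <- function(records, schema, provenance = character()) {
  stopifnot(is.data.frame(records), inherits(schema, "panel_schema"))
  records <- as.data.frame(records)
  cols <- schema_columns(schema)$column
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop_sdr("sdrshift_schema_error",
             "schema column(s) absent from data: %s", paste(missing_cols, collapse = ", "))
  }
  problems <- validate_panel_records(records, schema)
  if (length(problems)) {
    stop_sdr("sdrshift_validation_error",
             "panel validation failed:\n%s", paste("-", problems, collapse = "\n"))
  }
  structure(list(records = records, schema = schema, provenance = provenance),
            class = "panel_dataset")
}

# Returns a character vector of violations (empty when valid); each message
# names the offending rows.
validate_panel_records <- function(records, schema) {
  problems <- character()
  waves <- names(schema$exposure_waves)
  cens_cols <- schema$censoring
  all_cens <- c(unname(cens_cols), schema$outcome_censoring)
  n <- nrow(records)

  for (cc in all_cens) {
    v <- records[[cc]]
    bad <- which(!(v %in% c(0, 1)) | is.na(v))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "censoring column '%s' must be 0/1 and non-missing (rows %s)", cc, row_list(bad)))
    }
  }
  if (length(problems)) return(problems)

  cens_mat <- as.matrix(records[, all_cens, drop = FALSE])
  if (ncol(cens_mat) > 1L) {
    for (j in seq_len(ncol(cens_mat) - 1L)) {
      bad <- which(cens_mat[, j] == 0 & cens_mat[, j + 1L] == 1)
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "non-monotone censoring: observed at '%s' after censoring at '%s' (rows %s)",
          all_cens[j + 1L], all_cens[j], row_list(bad)))
      }
    }
  }

  for (k in seq_along(waves)) {
    w <- waves[k]
    a_col <- schema$exposure_waves[[w]]
    a <- records[[a_col]]
    obs <- cens_mat[, k] == 1
    if (schema$exposure_type == "binary") {
      bad <- which(!is.na(a) & !(a %in% c(0, 1)))
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "binary exposure '%s' has values outside {0, 1} (rows %s)", a_col, row_list(bad)))
      }
    }
    bad <- which(obs & is.na(a))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "exposure '%s' missing while censoring indicator says observed; exposure missingness must be handled as censoring (rows %s)",
        a_col, row_list(bad)))
    }
    bad <- which(!obs & !is.na(a))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "exposure '%s' present for rows censored at wave '%s' (rows %s)", a_col, w, row_list(bad)))
    }
    for (tv in schema$time_varying[[w]]) {
      bad <- which(!obs & !is.na(records[[tv]]))
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "time-varying column '%s' present for rows censored at wave '%s' (rows %s)",
          tv, w, row_list(bad)))
      }
    }
  }

  if (!is.null(schema$outcome_censoring)) {
    obs_y <- records[[schema$outcome_censoring]] == 1
    for (yc in schema$outcomes) {
      bad <- which(obs_y & is.na(records[[yc]]))
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "outcome '%s' missing for rows marked observed at the outcome wave (rows %s)",
          yc, row_list(bad)))
      }
      bad <- which(!obs_y & !is.na(records[[yc]]))
      if (length(bad)) {
        problems <- c(problems, sprintf(
          "outcome '%s' present for rows censored before the outcome wave (rows %s)",
          yc, row_list(bad)))
      }
    }
  }
  problems
}

row_list <- function(idx, max_show = 8L) {
  shown <- utils::head(idx, max_show)
  extra <- if (length(idx) > max_show) sprintf(", ... %d more", length(idx) - max_show) else ""
  paste0(paste(shown, collapse = ", "), extra)
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("<panel_dataset> ", nrow(x$records), " participants, ",
      n_waves(x$schema), " exposure wave(s), ",
      length(x$schema$outcomes), " outcome(s)\n", sep = "")
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance) cat("  -", p, "\n")
  }
  invisible(x)
}

add_provenance <- function(data, msg) {
  data$provenance <- c(data$provenance, msg)
  data
}

#' Load a panel from a delimited text file
#'
#' Reads a CSV/TSV table (missing values encoded as empty fields) and
#' validates it against a schema.  Violations are reported with row indices.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [panel_schema()] or the path to a YAML schema sidecar.
#' @param sep Field separator, inferred from the file extension by default.
#' @return A validated [panel_dataset()].
#' @export
load_panel <- function(path, schema, sep = NULL) {
  if (is.character(schema)) schema <- read_panel_schema(schema)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  records <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                               stringsAsFactors = FALSE, check.names = FALSE)
  panel_dataset(records, schema,
                provenance = sprintf("loaded %d rows from '%s'", nrow(records), basename(path)))
}

#' Write a panel and its schema sidecar to text files
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/load round trip reproduces them bit-exactly; missing values are
#' written as empty fields.
#'
#' @param data A [panel_dataset()].
#' @param path Output CSV path.
#' @param schema_path Output YAML path for the schema; defaults to
#'   `<path>.schema.yaml`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path, schema_path = paste0(path, ".schema.yaml")) {
  stopifnot(inherits(data, "panel_dataset"))
  out <- data$records
  for (j in names(out)) {
    if (is.numeric(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = ",", na = "", row.names = FALSE, quote = FALSE)
  write_panel_schema(data$schema, schema_path)
  invisible(path)
}

#' Cohort restriction rules
#'
#' `full_cohort` keeps every participant; `baseline_nonexposed` keeps
#' participants whose baseline exposure is 0 and non-missing — the population
#' for whom *initiation* of the exposure is the relevant transition, used for
#' stochastic gain-type interventions.
#'
#' @param name `"full_cohort"` or `"baseline_nonexposed"`.
#' @param baseline_exposure_column Column holding the baseline exposure.
#' @return An object of class `cohort_rule`.
#' @export
cohort_rule <- function(name = c("full_cohort", "baseline_nonexposed"),
                        baseline_exposure_column = NULL) {
  name <- match.arg(name)
  if (name == "baseline_nonexposed" && is.null(baseline_exposure_column)) {
    stop_sdr("sdrshift_schema_error",
             "baseline_nonexposed rule requires baseline_exposure_column")
  }
  structure(list(name = name, baseline_exposure_column = baseline_exposure_column),
            class = "cohort_rule")
}

#' Restrict a panel to a target cohort
#'
#' @param data A [panel_dataset()].
#' @param rule A [cohort_rule()].
#' @return The restricted [panel_dataset()]; errors if the restriction would
#'   leave an empty cohort (downstream estimation impossible).
#' @export
restrict_cohort <- function(data, rule) {
  stopifnot(inherits(data, "panel_dataset"), inherits(rule, "cohort_rule"))
  if (rule$name == "full_cohort") {
    return(add_provenance(data, "cohort: full baseline cohort"))
  }
  col <- rule$baseline_exposure_column
  if (!col %in% names(data$records)) {
    stop_sdr("sdrshift_schema_error", "baseline exposure column '%s' not found", col)
  }
  keep <- !is.na(data$records[[col]]) & data$records[[col]] == 0
  if (!any(keep)) {
    stop_sdr("sdrshift_empty_cohort_error",
             "baseline_nonexposed restriction on '%s' leaves an empty cohort", col)
  }
  data$records <- data$records[keep, , drop = FALSE]
  rownames(data$records) <- NULL
  add_provenance(data, sprintf("cohort: baseline non-exposed on '%s' (%d rows kept)",
                               col, sum(keep)))
}

#' Impute missing baseline covariates
#'
#' Single imputation for the (typically very sparse) missingness in baseline
#' covariates.  `mean_mode` replaces missing numeric values with the observed
#' mean (the observed mode for 0/1 columns).  `knn_match` replaces each
#' missing value with the value of the nearest observed donor — measured by
#' Euclidean distance over the standardised remaining baseline covariates —
#' so every imputed value is an observed value of that column, the donor
#' property of predictive mean matching.  For large cohorts the donor search
#' uses a seeded random subsample of up to 1000 donors.
#'
#' @param data A [panel_dataset()] whose missingness is confined to baseline
#'   covariates.
#' @param method `"mean_mode"` or `"knn_match"`.
#' @param seed Integer seed making donor matching reproducible.
#' @return A [panel_dataset()] with no missing baseline covariates.
#' @export
impute_baseline <- function(data, method = c("mean_mode", "knn_match"), seed = 1L) {
  stopifnot(inherits(data, "panel_dataset"))
  method <- match.arg(method)
  rec <- data$records
  bl <- data$schema$baseline_covariates
  has_na <- bl[vapply(rec[bl], anyNA, TRUE)]
  if (!length(has_na)) return(data)

  all_missing <- has_na[vapply(rec[has_na], function(v) all(is.na(v)), TRUE)]
  if (length(all_missing)) {
    stop_sdr("sdrshift_validation_error",
             "baseline covariate(s) entirely missing, no donors: %s",
             paste(all_missing, collapse = ", "))
  }

  if (method == "mean_mode") {
    for (j in has_na) {
      v <- rec[[j]]
      obs <- v[!is.na(v)]
      fill <- if (all(obs %in% c(0, 1))) {
        as.numeric(names(sort(table(obs), decreasing = TRUE))[1])
      } else {
        mean(obs)
      }
      v[is.na(v)] <- fill
      rec[[j]] <- v
    }
  } else {
    x <- as.matrix(rec[bl])
    xs <- scale(apply(x, 2, function(v) { v[is.na(v)] <- mean(v, na.rm = TRUE); v }))
    xs[is.nan(xs)] <- 0
    with_seed(seed, {
      for (j in has_na) {
        miss_rows <- which(is.na(rec[[j]]))
        donor_rows <- which(!is.na(rec[[j]]))
        if (length(donor_rows) > 1000L) donor_rows <- sample(donor_rows, 1000L)
        other <- setdiff(seq_along(bl), match(j, bl))
        dx <- xs[donor_rows, other, drop = FALSE]
        for (i in miss_rows) {
          d2 <- colSums((t(dx) - xs[i, other])^2)
          rec[i, j] <- rec[donor_rows[which.min(d2)], j]
        }
      }
    })
  }
  data$records <- rec
  add_provenance(data, sprintf(
    "imputed baseline covariates (%s, single imputation; columns: %s)",
    method, paste(has_na, collapse = ", ")))
}

#' Carry time-varying confounders forward with missingness indicators
#'
#' Among rows observed at a wave, each missing time-varying value is replaced
#' by the most recent observed measurement of the same variable (its
#' predecessor column, recursively across waves, ultimately the baseline
#' value), and a companion 0/1 indicator column (`<column>_cf`, 1 = value was
#' carried forward) is appended to that wave's time-varying set.  Censored
#' rows are untouched.  Applying the operation twice equals applying it once.
#'
#' @param data A [panel_dataset()] whose schema declares
#'   `time_varying_predecessor` links (run [impute_baseline()] first so the
#'   baseline values exist).
#' @return A [panel_dataset()] with filled values and indicator columns.
#' @export
carry_forward_time_varying <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  schema <- data$schema
  rec <- data$records
  pred <- schema$time_varying_predecessor
  changed <- FALSE
  for (w in names(schema$exposure_waves)) {
    obs <- rec[[schema$censoring[[w]]]] == 1
    tv_cols <- setdiff(schema$time_varying[[w]], grep("_cf$", schema$time_varying[[w]], value = TRUE))
    for (tv in tv_cols) {
      ind_col <- paste0(tv, "_cf")
      if (!ind_col %in% names(rec)) {
        rec[[ind_col]] <- as.numeric(obs & is.na(rec[[tv]]))
        rec[[ind_col]][!obs] <- NA
        changed <- TRUE
      }
      miss <- which(obs & is.na(rec[[tv]]))
      if (length(miss)) {
        src <- pred[[tv]]
        if (is.null(src)) {
          stop_sdr("sdrshift_validation_error",
                   "no predecessor declared for time-varying column '%s'", tv)
        }
        fill <- rec[miss, src]
        if (anyNA(fill)) {
          stop_sdr("sdrshift_validation_error",
                   "predecessor '%s' missing for rows needing carry-forward of '%s'; run impute_baseline / order waves correctly",
                   src, tv)
        }
        rec[miss, tv] <- fill
        changed <- TRUE
      }
      if (!ind_col %in% schema$time_varying[[w]]) {
        schema$time_varying[[w]] <- c(schema$time_varying[[w]], ind_col)
      }
    }
  }
  data$records <- rec
  data$schema <- schema
  if (changed) data <- add_provenance(data, "carried forward time-varying confounders with missingness indicators")
  data
}

#' Standardise outcomes to z-scores
#'
#' Each outcome is centred and scaled using the mean and standard deviation
#' (denominator `n - 1`) of its observed values, so estimated effects are in
#' standard-deviation units.  The scaling constants are stored in the
#' provenance log (and in the `outcome_scaling` attribute) for
#' back-transformation.
#'
#' @param data A [panel_dataset()] with numeric outcomes, at least two
#'   observed values per outcome.
#' @return The standardised [panel_dataset()].
#' @export
standardise_outcomes <- function(data) {
  stopifnot(inherits(data, "panel_dataset"))
  rec <- data$records
  scaling <- data.frame(outcome = character(), mean = numeric(), sd = numeric(),
                        stringsAsFactors = FALSE)
  for (yc in data$schema$outcomes) {
    v <- rec[[yc]]
    obs <- v[!is.na(v)]
    if (length(obs) < 2L) {
      stop_sdr("sdrshift_validation_error",
               "outcome '%s' has fewer than 2 observed values", yc)
    }
    s <- stats::sd(obs)
    if (!is.finite(s) || s == 0) {
      stop_sdr("sdrshift_validation_error", "outcome '%s' has zero variance", yc)
    }
    m <- mean(obs)
    rec[[yc]] <- (v - m) / s
    scaling <- rbind(scaling, data.frame(outcome = yc, mean = m, sd = s,
                                         stringsAsFactors = FALSE))
  }
  data$records <- rec
  attr(data, "outcome_scaling") <- scaling
  add_provenance(data, sprintf(
    "standardised %d outcomes to z-scores (observed-case moments; means %s; sds %s)",
    nrow(scaling),
    paste(sprintf("%.4g", scaling$mean), collapse = ","),
    paste(sprintf("%.4g", scaling$sd), collapse = ",")))
}
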