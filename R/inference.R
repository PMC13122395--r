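#' Bonferroni-adjusted Wald intervals for an outcome-wide contrast
#'
#' Recomputes the contrast's interval at per-comparison level `alpha / m`,
#' widening it so that the family of `m` outcome-wise intervals has
#' familywise coverage `1 - alpha`.  With `m = 1` this is the unadjusted
#' interval (z = 1.96); with `m = 24`, z = 3.0357.
#'
#' @param estimate A `policy_contrast` from [estimate_contrast()].
#' @param m Number of comparisons in the family (>= 1).
#' @param alpha Familywise error rate (default 0.05).
#' @return The `policy_contrast` with `conf_low`/`conf_high` replaced by the
#'   adjusted interval and columns `m`, `adj_alpha` appended.
#' @export
bonferroni_interval <- function(estimate, m, alpha = 0.05) {
  stopifnot(inherits(estimate, "policy_contrast"), m >= 1)
  z <- stats::qnorm(1 - alpha / (2 * m))
  estimate$conf_low <- estimate$theta - z * estimate$se
  estimate$conf_high <- estimate$theta + z * estimate$se
  estimate$m <- m
  estimate$adj_alpha <- alpha / m
  attr(estimate, "level") <- 1 - alpha
  attr(estimate, "bonferroni_m") <- m
  estimate
}

#' E-values for unmeasured-confounding sensitivity analysis
#'
#' Converts each standardised-mean-difference contrast to an approximate
#' risk ratio, `RR = exp(0.91 * theta)` (the standard approximate conversion
#' for E-values on standardised mean differences), and computes
#' `E = RR + sqrt(RR * (RR - 1))` for `RR >= 1`, applied to `1/RR` when
#' `RR < 1`.  The point E-value uses `theta`; the bound E-value uses the
#' interval limit closer to the null and is set to 1 when the interval
#' crosses the null.  An estimate is flagged `reliable` only when both the
#' (adjusted) interval excludes zero and the bound E-value exceeds the
#' threshold — E-values at or below 1.10 are treated as insufficiently
#' robust even when the interval excludes zero.
#'
#' @param estimate A `policy_contrast`, normally after
#'   [bonferroni_interval()] so the bound uses the adjusted limits.
#' @param threshold Reliability threshold on the bound E-value
#'   (default 1.10).
#' @return A data.frame of class `evalue_result` with columns `outcome`,
#'   `rr_point`, `evalue_point`, `evalue_bound`, `reliable`.
#' @export
evalue <- function(estimate, threshold = 1.10) {
  stopifnot(inherits(estimate, "policy_contrast"))
  e_from_d <- function(d) {
    rr <- exp(0.91 * d)
    rr_star <- pmax(rr, 1 / rr)
    ifelse(rr_star <= 1, 1, rr_star + sqrt(rr_star * (rr_star - 1)))
  }
  rr_point <- exp(0.91 * estimate$theta)
  ev_point <- e_from_d(estimate$theta)
  crosses <- estimate$conf_low <= 0 & estimate$conf_high >= 0
  limit <- ifelse(estimate$conf_low > 0, estimate$conf_low, estimate$conf_high)
  ev_bound <- ifelse(crosses, 1, e_from_d(limit))
  out <- data.frame(outcome = estimate$outcome,
                    rr_point = rr_point,
                    evalue_point = ev_point,
                    evalue_bound = ev_bound,
                    reliable = !crosses & ev_bound > threshold,
                    stringsAsFactors = FALSE)
  structure(out, class = c("evalue_result", "data.frame"), threshold = threshold)
}

#' Outcome-wide batch estimation with positivity gating
#'
#' Runs the full pipeline for a list of policy contrasts: cohort restriction
#' per contrast (baseline non-exposed for initiation-type stochastic
#' policies, the full cohort otherwise), cross-fitted nuisance estimation,
#' density-ratio positivity gating, SDR estimation for every outcome,
#' Bonferroni adjustment across outcomes, and E-values.  Contrasts whose
#' policy (or non-identity reference) fails the positivity gate yield rows
#' flagged `"not estimated: positivity"` — never silent numbers, because
#' such estimates require extrapolation and should not be interpreted as
#' causal.  Per-contrast failures are caught and aggregated in the metadata
#' without aborting the batch.
#'
#' @param data A prepared [panel_dataset()] (imputed, carried forward,
#'   outcomes standardised).
#' @param contrasts A list; each element is a list or character vector with
#'   the intervention policy first and the reference second, given as
#'   `sdr_policy` objects or policy strings (e.g.
#'   `list(c("ips:5", "identity"))`).  An optional third element `cohort`
#'   (`"auto"`, `"full_cohort"`, `"baseline_nonexposed"`) overrides the
#'   cohort rule.
#' @param spec A [nuisance_spec()].
#' @param baseline_exposure_column Column used for the baseline-non-exposed
#'   restriction.
#' @param alpha Familywise error rate for Bonferroni adjustment.
#' @param evalue_threshold Reliability threshold on the bound E-value.
#' @param floor,fraction_threshold Positivity-gate thresholds, passed to
#'   [positivity_report()].
#' @param seed Master seed; per-contrast nuisance seeds are derived from it.
#' @return An object of class `outcome_wide_report`: a data.frame with one
#'   row per outcome x contrast (`theta`, `se`, adjusted interval, E-values,
#'   `reliable`, `status`, `domain`), with batch metadata in the `meta`
#'   attribute.
#' @export
outcome_wide_run <- function(data, contrasts, spec = nuisance_spec(),
                             baseline_exposure_column = "a0",
                             alpha = 0.05, evalue_threshold = 1.10,
                             floor = 0.02, fraction_threshold = 0.5,
                             seed = 1L) {
  stopifnot(inherits(data, "panel_dataset"))
  outcomes <- data$schema$outcomes
  domains <- data$schema$outcome_domains
  m <- length(outcomes)
  rows <- list()
  failures <- character()
  positivity <- list()

  for (ci in seq_along(contrasts)) {
    spec_pair <- contrasts[[ci]]
    pol <- spec_pair[[1]]
    ref <- spec_pair[[2]]
    if (is.character(pol)) pol <- parse_policy(pol)
    if (is.character(ref)) ref <- parse_policy(ref)
    cohort_mode <- if (length(spec_pair) >= 3L) spec_pair[[3]] else "auto"
    label <- paste(policy_label(pol), "vs", policy_label(ref))

    blank <- function(status) {
      data.frame(outcome = outcomes,
                 domain = if (!is.null(domains)) unname(domains[outcomes]) else NA_character_,
                 contrast = label, theta = NA_real_, se = NA_real_,
                 conf_low = NA_real_, conf_high = NA_real_,
                 evalue_point = NA_real_, evalue_bound = NA_real_,
                 reliable = NA, status = status, n = NA_integer_,
                 stringsAsFactors = FALSE)
    }

    res <- tryCatch({
      rule <- if (cohort_mode == "auto") {
        if (pol$kind == "ips_shift") {
          cohort_rule("baseline_nonexposed", baseline_exposure_column)
        } else {
          cohort_rule("full_cohort")
        }
      } else if (cohort_mode == "baseline_nonexposed") {
        cohort_rule("baseline_nonexposed", baseline_exposure_column)
      } else {
        cohort_rule("full_cohort")
      }
      cohort <- restrict_cohort(data, rule)
      fits <- fit_nuisances(cohort, spec, seed = child_seed(seed, 1000L + ci))

      gate_ok <- TRUE
      for (p in unique(list(pol, ref))) {
        if (p$kind == "identity") next
        rep_p <- positivity_report(cumulative_ratios(cohort, p, fits$g),
                                   floor = floor, fraction_threshold = fraction_threshold)
        positivity[[paste(label, policy_label(p))]] <- rep_p
        if (!rep_p$supported) gate_ok <- FALSE
      }
      if (!gate_ok) {
        blank("not estimated: positivity")
      } else {
        est_d <- estimate_policy_mean(cohort, pol, fits)
        est_r <- estimate_policy_mean(cohort, ref, fits)
        ctr <- estimate_contrast(est_d, est_r)
        ctr <- bonferroni_interval(ctr, m = m, alpha = alpha)
        ev <- evalue(ctr, threshold = evalue_threshold)
        data.frame(outcome = ctr$outcome,
                   domain = if (!is.null(domains)) unname(domains[ctr$outcome]) else NA_character_,
                   contrast = label, theta = ctr$theta, se = ctr$se,
                   conf_low = ctr$conf_low, conf_high = ctr$conf_high,
                   evalue_point = ev$evalue_point, evalue_bound = ev$evalue_bound,
                   reliable = ev$reliable, status = "ok",
                   n = nrow(cohort$records), stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", label, conditionMessage(e)))
      blank(paste("error:", conditionMessage(e)))
    })
    rows[[ci]] <- res
  }

  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(outcome = character(), domain = character(), contrast = character(),
               theta = numeric(), se = numeric(), conf_low = numeric(),
               conf_high = numeric(), evalue_point = numeric(),
               evalue_bound = numeric(), reliable = logical(),
               status = character(), n = integer(), stringsAsFactors = FALSE)
  }
  structure(out, class = c("outcome_wide_report", "data.frame"),
            meta = list(n_input = nrow(data$records), n_outcomes = m,
                        alpha = alpha, evalue_threshold = evalue_threshold,
                        floor = floor, fraction_threshold = fraction_threshold,
                        seed = seed, spec = spec,
                        weight_mode = spec$weight_mode,
                        contrasts = vapply(contrasts, function(z) {
                          p <- z[[1]]; r <- z[[2]]
                          paste(if (is.character(p)) p else policy_label(p), "vs",
                                if (is.character(r)) r else policy_label(r))
                        }, character(1)),
                        failures = failures),
            positivity = positivity)
}

#' @export
print.outcome_wide_report <- function(x, ...) {
  meta <- attr(x, "meta")
  if (is.null(meta)) {
    print.data.frame(x, row.names = FALSE, digits = 3)
    return(invisible(x))
  }
  cat("<outcome_wide_report> ", length(unique(x$contrast)), " contrast(s) x ",
      meta$n_outcomes, " outcomes; Bonferroni m = ", meta$n_outcomes,
      ", E-value threshold ", meta$evalue_threshold, "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  if (length(meta$failures)) {
    cat("failures:\n"); for (f in meta$failures) cat("  -", f, "\n")
  }
  invisible(x)
}

#' Descriptive baseline associations
#'
#' For each outcome, the coefficient of the outcome on the baseline exposure
#' in a weighted linear regression, optionally adjusting for a chosen subset
#' of baseline covariates.  These are cross-sectional associations, clearly
#' labelled descriptive: they do not define a causal contrast and exist to
#' exhibit the association-versus-causation gap (associations are nonzero
#' under a confounded null data-generating process while the causal contrast
#' is ~0).  The default adjusts for nothing beyond the weights — the usual
#' presentation of a descriptive association panel; passing the full
#' baseline covariate set would, on a synthetic cohort whose confounding is
#' an exact linear function of the observed covariates, absorb the
#' confounding entirely and collapse the gap the panel is meant to display.
#'
#' @param data A [panel_dataset()] with outcomes present.
#' @param exposure_column Baseline exposure column (must be among the
#'   baseline covariates).
#' @param covariates Optional character vector of baseline covariates to
#'   adjust for (default: none).
#' @return A data.frame of class `baseline_associations` with columns
#'   `outcome`, `estimate`, `se`.
#' @export
baseline_associations <- function(data, exposure_column = "a0", covariates = NULL) {
  stopifnot(inherits(data, "panel_dataset"))
  schema <- data$schema
  if (!exposure_column %in% schema$baseline_covariates) {
    stop_sdr("sdrshift_schema_error",
             "exposure column '%s' is not among the baseline covariates", exposure_column)
  }
  rec <- data$records
  others <- intersect(covariates %||% character(0),
                      setdiff(schema$baseline_covariates, exposure_column))
  obs <- if (!is.null(schema$outcome_censoring)) rec[[schema$outcome_censoring]] == 1 else
    stats::complete.cases(rec[schema$outcomes])
  X <- cbind(1, as.matrix(rec[obs, c(exposure_column, others)]))
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    stop_sdr("sdrshift_validation_error",
             "missing baseline covariates; run impute_baseline() first")
  }
  Y <- as.matrix(rec[obs, schema$outcomes])
  w <- if (!is.null(schema$weight_column)) rec[[schema$weight_column]][obs] else rep(1, sum(obs))
  sw <- sqrt(w)
  q <- qr(X * sw)
  cf <- qr.coef(q, Y * sw)
  cf[is.na(cf)] <- 0
  resid <- Y * sw - (X * sw) %*% cf
  dfree <- nrow(X) - q$rank
  sigma2 <- colSums(resid^2) / dfree
  xtx_inv <- chol2inv(qr.R(q))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  structure(data.frame(outcome = schema$outcomes,
                       estimate = unname(cf[2, ]), se = unname(se),
                       stringsAsFactors = FALSE),
            class = c("baseline_associations", "data.frame"),
            note = "descriptive cross-sectional associations; not causal estimates")
}
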