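#' Specification of nuisance estimation for the SDR estimator
#'
#' Declares the learner menus for the treatment (propensity), censoring and
#' sequential outcome regressions, the number of cross-fitting folds, and the
#' cumulative density-ratio truncation quantile.  Available learners:
#' `"mean"` (marginal rate / grand mean), `"glm"` (linear or logistic
#' regression), `"ridge"` (L2-penalised linear or logistic regression — the
#' default for the treatment models, because unpenalised MLE overfits badly
#' when initiation events are rare relative to the adjustment set),
#' `"stump"` (depth-2 regression tree), `"xgb"` (shallow gradient-boosted
#' trees).  A menu with several learners is resolved by discrete holdout
#' selection within each training fold.
#'
#' @param treatment_learners,censoring_learners,outcome_learners Character
#'   vectors of learner names (nonempty).
#' @param n_folds Number of cross-fitting folds (>= 2; default 5).
#' @param ratio_truncation Quantile at which cumulative weighted density
#'   ratios are capped (default 0.999, i.e. a 99.9th-percentile cap).
#' @param weight_mode Where post-stratification weights enter: `"final"`
#'   (default: final averaging only) or `"nuisance"` (also weight every
#'   nuisance regression).
#' @return An object of class `nuisance_spec`.
#' @export
nuisance_spec <- function(treatment_learners = "ridge",
                          censoring_learners = "glm",
                          outcome_learners = "glm",
                          n_folds = 5L,
                          ratio_truncation = 0.999,
                          weight_mode = c("final", "nuisance")) {
  weight_mode <- match.arg(weight_mode)
  if (n_folds < 2L) stop_sdr("sdrshift_config_error", "n_folds must be >= 2")
  for (l in list(treatment_learners, censoring_learners, outcome_learners)) {
    if (!length(l)) stop_sdr("sdrshift_config_error", "learner lists must be nonempty")
  }
  structure(list(treatment_learners = treatment_learners,
                 censoring_learners = censoring_learners,
                 outcome_learners = outcome_learners,
                 n_folds = as.integer(n_folds),
                 ratio_truncation = ratio_truncation,
                 weight_mode = weight_mode),
            class = "nuisance_spec")
}

# Assemble the design matrices used by every nuisance model.  History at
# exposure wave t is: baseline covariates + time-varying confounders up to
# and including wave t + all earlier exposures.
build_design <- function(data) {
  schema <- data$schema
  rec <- data$records
  waves <- names(schema$exposure_waves)
  K <- length(waves)
  as_mat <- function(cols) {
    if (!length(cols)) return(matrix(numeric(0), nrow(rec), 0))
    m <- as.matrix(rec[cols])
    storage.mode(m) <- "double"
    m
  }
  X0 <- as_mat(schema$baseline_covariates)
  obs <- lapply(waves, function(w) rec[[schema$censoring[[w]]]] == 1)
  obs_y <- if (!is.null(schema$outcome_censoring)) rec[[schema$outcome_censoring]] == 1 else obs[[K]]
  A <- lapply(waves, function(w) as.numeric(rec[[schema$exposure_waves[[w]]]]))
  TV <- lapply(waves, function(w) as_mat(schema$time_varying[[w]]))

  H <- XA <- vector("list", K)
  hist_mat <- X0
  for (t in seq_len(K)) {
    hist_mat <- cbind(hist_mat, TV[[t]])
    H[[t]] <- hist_mat
    acol <- matrix(A[[t]], ncol = 1, dimnames = list(NULL, paste0(".A_", waves[t])))
    XA[[t]] <- cbind(hist_mat, acol)
    hist_mat <- XA[[t]]
  }
  CZ <- vector("list", K + 1L)
  CZ[[1]] <- X0
  if (K >= 2L) for (t in 2:K) CZ[[t]] <- XA[[t - 1L]]
  CZ[[K + 1L]] <- XA[[K]]

  w <- if (!is.null(schema$weight_column)) as.numeric(rec[[schema$weight_column]]) else rep(1, nrow(rec))
  list(K = K, waves = waves, n = nrow(rec), X0 = X0, H = H, XA = XA, CZ = CZ,
       A = A, obs = obs, obs_y = obs_y, weights = w,
       Y = as_mat(schema$outcomes), outcomes = schema$outcomes,
       exposure_type = schema$exposure_type)
}

check_complete <- function(data) {
  schema <- data$schema
  rec <- data$records
  bl_na <- schema$baseline_covariates[vapply(rec[schema$baseline_covariates], anyNA, TRUE)]
  if (length(bl_na)) {
    stop_sdr("sdrshift_validation_error",
             "missing baseline covariates (%s); run impute_baseline() first",
             paste(utils::head(bl_na, 5), collapse = ", "))
  }
  for (w in names(schema$exposure_waves)) {
    obs <- rec[[schema$censoring[[w]]]] == 1
    for (tv in schema$time_varying[[w]]) {
      if (anyNA(rec[[tv]][obs])) {
        stop_sdr("sdrshift_validation_error",
                 "time-varying column '%s' missing among uncensored rows; run carry_forward_time_varying() first", tv)
      }
    }
  }
  invisible(TRUE)
}

#' Cross-fitted treatment and censoring nuisance models
#'
#' Fits, with V-fold cross-fitting, the per-wave propensity models
#' `g_t = P(A_t = 1 | history)` (binary exposures) and the per-node censoring
#' continuation models `P(observed at node | history so far)` — one node
#' before each exposure wave and one before the outcome wave.  Predictions
#' for each participant come only from models whose training folds excluded
#' that participant.  The adjustment set at wave t is the baseline
#' covariates, all time-varying confounders up to wave t, and all earlier
#' exposures.  A training fold containing a single exposure class falls back
#' to the marginal rate and the fallback is logged.
#'
#' The policy-specific sequential outcome regressions are cross-fitted inside
#' [estimate_policy_mean()] using the fold assignment stored here, since
#' their pseudo-outcomes depend on the policy under evaluation.
#'
#' @param data A validated, imputed, carried-forward [panel_dataset()].
#' @param spec A [nuisance_spec()].
#' @param seed Integer seed controlling fold assignment and learner
#'   selection.
#' @return An object of class `nuisance_fits` holding fold assignments,
#'   propensity matrix `g` (n x K), censoring continuation matrix `pc`
#'   (n x (K+1)), and the learner log.
#' @export
fit_nuisances <- function(data, spec, seed = 1L) {
  stopifnot(inherits(data, "panel_dataset"), inherits(spec, "nuisance_spec"))
  check_complete(data)
  dsg <- build_design(data)
  n <- dsg$n
  K <- dsg$K
  V <- spec$n_folds
  folds <- with_seed(child_seed(seed, 11L), sample(rep(seq_len(V), length.out = n)))
  nw <- if (spec$weight_mode == "nuisance") dsg$weights else NULL

  g <- matrix(NA_real_, n, K)
  pc <- matrix(NA_real_, n, K + 1L)
  log_rows <- list()
  obs_prev <- c(list(rep(TRUE, n)), dsg$obs)  # observed-at-previous-node indicator per censoring node

  for (v in seq_len(V)) {
    train <- folds != v
    hold <- folds == v
    for (t in seq_len(K)) {
      rows <- train & dsg$obs[[t]]
      if (dsg$exposure_type == "binary") {
        f <- fit_menu(spec$treatment_learners, dsg$H[[t]][rows, , drop = FALSE],
                      dsg$A[[t]][rows], "binomial", nw[rows],
                      seed = child_seed(seed, 100L + 10L * v + t))
        pr_rows <- hold & dsg$obs[[t]]
        g[pr_rows, t] <- predict_learner(f, dsg$H[[t]][pr_rows, , drop = FALSE])
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          model = sprintf("g_%s", dsg$waves[t]), fold = v, learner = f$name %||% f$kind,
          fallback = isTRUE(f$fallback))
      }
    }
    for (t in seq_len(K + 1L)) {
      at_risk <- obs_prev[[t]]
      node_obs <- if (t <= K) dsg$obs[[t]] else dsg$obs_y
      rows <- train & at_risk
      y <- as.numeric(node_obs)
      if (all(y[rows] == 1)) {
        pr_rows <- hold & at_risk
        pc[pr_rows, t] <- 1
        next
      }
      f <- fit_menu(spec$censoring_learners, dsg$CZ[[t]][rows, , drop = FALSE],
                    y[rows], "binomial", nw[rows],
                    seed = child_seed(seed, 200L + 10L * v + t))
      pr_rows <- hold & at_risk
      pc[pr_rows, t] <- predict_learner(f, dsg$CZ[[t]][pr_rows, , drop = FALSE])
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        model = sprintf("pc_node%d", t), fold = v, learner = f$name %||% f$kind,
        fallback = isTRUE(f$fallback))
    }
  }
  structure(list(folds = folds, g = g, pc = pc, spec = spec, seed = seed,
                 n = n, K = K, waves = dsg$waves,
                 learner_log = if (length(log_rows)) do.call(rbind, log_rows) else NULL),
            class = "nuisance_fits")
}

#' @export
print.nuisance_fits <- function(x, ...) {
  cat("<nuisance_fits> n =", x$n, ", waves =", paste(x$waves, collapse = ", "),
      ", folds =", x$spec$n_folds, "\n")
  if (!is.null(x$learner_log) && any(x$learner_log$fallback)) {
    cat("  note:", sum(x$learner_log$fallback), "single-class fold(s) fell back to the marginal rate\n")
  }
  invisible(x)
}

# adaptive propensity trimming bound (TMLE-literature rule of thumb)
g_bound <- function(n) 5 / (sqrt(n) * log(n))

# cap positive values at their `q` quantile
trunc_q <- function(x, q) {
  pos <- x[is.finite(x) & x > 0]
  if (!length(pos)) return(x)
  cap <- stats::quantile(pos, q, names = FALSE)
  pmin(x, cap)
}

#' Sequentially doubly robust estimate of a policy-specific mean
#'
#' One-step cross-fitted estimator of `E[Y^d]`, the mean of each outcome in
#' the hypothetical world where exposure follows policy `d` at every
#' intervention wave and no one is lost to follow-up.  The construction,
#' per cross-fitting fold, is a backward recursion over the K exposure waves:
#' the stage-K regression fits the observed outcome on history and exposure;
#' each earlier stage fits the sequentially doubly robust pseudo-outcome
#' `phi_{t+1} = m_bar_{t+1} + r_t u_{t+1} (phi_{t+2} - m_{t+1}^obs)` — the
#' policy-evaluated next-stage regression plus density-ratio- and
#' censoring-weighted downstream corrections — on history and exposure,
#' fitting only on uncensored rows; a final baseline regression carries the
#' value down to the full cohort.  Here `r_t` is the policy density ratio at
#' the observed exposure, `u_t = 1{observed}/P(observed | history)` the
#' censoring weight, and for stochastic policies the policy evaluation
#' `m_bar` is the exact enumeration over the binary exposure (no sampling).
#' The estimate is the mean of the per-participant influence construction,
#' so `mean(influence) = point` and `se = sd(influence)/sqrt(n)`; the
#' estimate is consistent at each stage if either the outcome regression or
#' both the treatment and censoring models are correctly specified.
#' Cumulative weighted ratios are truncated at the spec's quantile.
#' Post-stratification weights multiply the final averaging (default) or
#' additionally every nuisance regression, per the spec's `weight_mode`.
#'
#' Censored participants contribute only through the waves at which they
#' were observed.  Positivity gating is the caller's duty (see
#' [positivity_report()]).
#'
#' @param data The same [panel_dataset()] passed to [fit_nuisances()].
#' @param policy An `sdr_policy`.
#' @param fits A `nuisance_fits` from [fit_nuisances()].
#' @param outcomes Optional character subset of outcome columns.
#' @return An object of class `policy_mean_set`: a data.frame with columns
#'   `outcome`, `point`, `se`, carrying the n x J influence-value matrix in
#'   the `influence` attribute.
#' @export
estimate_policy_mean <- function(data, policy, fits, outcomes = NULL) {
  stopifnot(inherits(data, "panel_dataset"), inherits(policy, "sdr_policy"),
            inherits(fits, "nuisance_fits"))
  dsg <- build_design(data)
  if (dsg$n != fits$n) {
    stop_sdr("sdrshift_validation_error",
             "nuisance fits were computed on %d participants but data has %d rows",
             fits$n, dsg$n)
  }
  if (policy$kind %in% c("ips_shift", "set_all") && dsg$exposure_type != "binary") {
    stop_sdr("sdrshift_policy_error", "%s policy requires a binary exposure", policy$kind)
  }
  if (policy$kind == "additive_shift" && dsg$exposure_type != "continuous") {
    stop_sdr("sdrshift_policy_error", "additive_shift policy requires a continuous exposure")
  }
  K <- dsg$K
  n <- dsg$n
  spec <- fits$spec
  folds <- fits$folds
  V <- spec$n_folds
  if (is.null(outcomes)) outcomes <- dsg$outcomes
  jidx <- match(outcomes, dsg$outcomes)
  Y <- dsg$Y[, jidx, drop = FALSE]
  J <- ncol(Y)
  nw <- if (spec$weight_mode == "nuisance") dsg$weights else NULL

  # per-wave censoring weights u_t (node before wave t) and u_y (outcome node)
  pc <- clip(fits$pc, 0.01, 1)
  u <- matrix(0, n, K + 1L)
  for (t in seq_len(K)) u[, t] <- ifelse(dsg$obs[[t]], 1 / pc[, t], 0)
  u[, K + 1L] <- ifelse(dsg$obs_y, 1 / pc[, K + 1L], 0)

  # per-wave density ratios at the observed exposure
  r <- matrix(0, n, K)
  if (policy$kind == "identity") {
    for (t in seq_len(K)) r[dsg$obs[[t]], t] <- 1
  } else if (policy$kind == "additive_shift") {
    # cap defaults to the sample maximum, restricting the shift to observed support
    policy$support_cap <- policy$support_cap %||%
      max(unlist(lapply(seq_len(K), function(t) dsg$A[[t]][dsg$obs[[t]]])), na.rm = TRUE)
    r <- additive_density_ratios(dsg, policy, spec, folds, nw, fits$seed)
  } else {
    gb <- g_bound(n)
    gcl <- clip(fits$g, gb, 1 - gb)
    for (t in seq_len(K)) {
      ot <- dsg$obs[[t]]
      r[ot, t] <- density_ratio(policy, dsg$A[[t]][ot], gcl[ot, t])
    }
  }
  if (any(!is.finite(r))) {
    stop_sdr("sdrshift_positivity_error",
             "non-finite density ratios encountered; the policy lacks empirical support (see positivity_report)")
  }

  vectorised <- identical(spec$outcome_learners, "glm")
  m_obs <- m_bar <- vector("list", K)
  phi_next <- Y                       # phi_{K+1} = Y (defined on obs_y rows)
  fit_rows_next <- dsg$obs_y

  for (t in rev(seq_len(K))) {
    mo <- mb <- matrix(NA_real_, n, J)
    pred_rows_all <- dsg$obs[[t]]
    for (v in seq_len(V)) {
      tr <- folds != v & fit_rows_next
      pr <- folds == v & pred_rows_all
      if (!any(pr)) next
      Xtr <- dsg$XA[[t]][tr, , drop = FALSE]
      acol <- ncol(dsg$XA[[t]])
      Xpr_obs <- dsg$XA[[t]][pr, , drop = FALSE]
      if (policy$kind == "identity" && dsg$exposure_type == "continuous") {
        if (vectorised) {
          cf <- fit_linear_multi(Xtr, phi_next[tr, , drop = FALSE], nw[tr])
          mo[pr, ] <- predict_linear_multi(cf, Xpr_obs)
        } else {
          for (j in seq_len(J)) {
            f <- fit_menu(spec$outcome_learners, Xtr, phi_next[tr, j], "gaussian", nw[tr],
                          seed = child_seed(fits$seed, 300L + 17L * v + t))
            mo[pr, j] <- predict_learner(f, Xpr_obs)
          }
        }
        mb[pr, ] <- mo[pr, ]
      } else if (policy$kind == "additive_shift") {
        Xpr_shift <- Xpr_obs
        Xpr_shift[, acol] <- apply_additive_shift(policy, Xpr_shift[, acol])
        if (vectorised) {
          cf <- fit_linear_multi(Xtr, phi_next[tr, , drop = FALSE], nw[tr])
          mo[pr, ] <- predict_linear_multi(cf, Xpr_obs)
          mb[pr, ] <- predict_linear_multi(cf, Xpr_shift)
        } else {
          for (j in seq_len(J)) {
            f <- fit_menu(spec$outcome_learners, Xtr, phi_next[tr, j], "gaussian", nw[tr],
                          seed = child_seed(fits$seed, 300L + 17L * v + t))
            mo[pr, j] <- predict_learner(f, Xpr_obs)
            mb[pr, j] <- predict_learner(f, Xpr_shift)
          }
        }
      } else {
        Xpr0 <- Xpr1 <- Xpr_obs
        Xpr0[, acol] <- 0
        Xpr1[, acol] <- 1
        if (vectorised) {
          cf <- fit_linear_multi(Xtr, phi_next[tr, , drop = FALSE], nw[tr])
          mo[pr, ] <- predict_linear_multi(cf, Xpr_obs)
          p0 <- predict_linear_multi(cf, Xpr0)
          p1 <- predict_linear_multi(cf, Xpr1)
        } else {
          p0 <- p1 <- matrix(NA_real_, sum(pr), J)
          for (j in seq_len(J)) {
            f <- fit_menu(spec$outcome_learners, Xtr, phi_next[tr, j], "gaussian", nw[tr],
                          seed = child_seed(fits$seed, 300L + 17L * v + t))
            mo[pr, j] <- predict_learner(f, Xpr_obs)
            p0[, j] <- predict_learner(f, Xpr0)
            p1[, j] <- predict_learner(f, Xpr1)
          }
        }
        gv <- clip(fits$g[pr, t], g_bound(n), 1 - g_bound(n))
        pr1 <- policy_probability(policy, rep(1, sum(pr)), gv)
        mb[pr, ] <- p0 * (1 - pr1) + p1 * pr1
      }
    }
    # SDR pseudo-outcome for the next (earlier) stage
    corr <- trunc_q(r[, t] * u[, t + 1L], spec$ratio_truncation)
    diffmat <- phi_next - mo
    diffmat[!is.finite(diffmat)] <- 0   # censored downstream: weight is 0
    phi_next <- mb + corr * diffmat
    phi_next[!pred_rows_all, ] <- NA_real_
    fit_rows_next <- pred_rows_all
    m_obs[[t]] <- mo
    m_bar[[t]] <- mb
  }

  # baseline regression m0 and the one-step influence construction
  m0 <- matrix(NA_real_, n, J)
  for (v in seq_len(V)) {
    tr <- folds != v & dsg$obs[[1L]]
    pr <- folds == v
    if (vectorised) {
      cf <- fit_linear_multi(dsg$X0[tr, , drop = FALSE], phi_next[tr, , drop = FALSE], nw[tr])
      m0[pr, ] <- predict_linear_multi(cf, dsg$X0[pr, , drop = FALSE])
    } else {
      for (j in seq_len(J)) {
        f <- fit_menu(spec$outcome_learners, dsg$X0[tr, , drop = FALSE],
                      phi_next[tr, j], "gaussian", nw[tr],
                      seed = child_seed(fits$seed, 400L + v))
        m0[pr, j] <- predict_learner(f, dsg$X0[pr, , drop = FALSE])
      }
    }
  }
  u1 <- trunc_q(u[, 1L], spec$ratio_truncation)
  add <- phi_next - m0
  add[!is.finite(add)] <- 0
  D <- m0 + u1 * add

  est <- data.frame(outcome = outcomes, point = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  infl <- matrix(NA_real_, n, J, dimnames = list(NULL, outcomes))
  for (j in seq_len(J)) {
    wm <- weighted_if_mean(D[, j], dsg$weights)
    est$point[j] <- wm$point
    est$se[j] <- wm$se
    infl[, j] <- wm$if_values
  }
  structure(est, class = c("policy_mean_set", "data.frame"),
            influence = infl, policy = policy, n = n,
            participants_tag = sum(folds * seq_len(n)))
}

# Density ratios for an additive shift on a continuous exposure, estimated by
# the classification trick: a logistic model distinguishes (history, shifted
# exposure) from (history, observed exposure) duplicates; its odds at the
# observed pair estimate the policy density ratio.
additive_density_ratios <- function(dsg, policy, spec, folds, nw, seed) {
  n <- dsg$n
  K <- dsg$K
  V <- spec$n_folds
  r <- matrix(0, n, K)
  for (t in seq_len(K)) {
    acol <- ncol(dsg$XA[[t]])
    for (v in seq_len(V)) {
      tr <- which(folds != v & dsg$obs[[t]])
      pr <- which(folds == v & dsg$obs[[t]])
      if (!length(pr)) next
      Xnat <- dsg$XA[[t]][tr, , drop = FALSE]
      Xshift <- Xnat
      Xshift[, acol] <- apply_additive_shift(policy, Xshift[, acol])
      Xstack <- rbind(Xnat, Xshift)
      lab <- c(rep(0, length(tr)), rep(1, length(tr)))
      f <- fit_menu(spec$treatment_learners, Xstack, lab, "binomial",
                    if (!is.null(nw)) rep(nw[tr], 2),
                    seed = child_seed(seed, 500L + 10L * v + t))
      lam <- clip(predict_learner(f, dsg$XA[[t]][pr, , drop = FALSE]), 0.001, 0.999)
      r[pr, t] <- lam / (1 - lam)
    }
  }
  r
}

#' @export
print.policy_mean_set <- function(x, ...) {
  cat("<policy_mean_set> policy:", policy_label(attr(x, "policy")),
      " n =", attr(x, "n"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Contrast of two policy-specific means
#'
#' Computes `theta = E[Y^d] - E[Y^ref]` per outcome with a standard error
#' from the paired per-participant influence-value differences (both
#' estimates must come from the same participants and fold assignment), and
#' a Wald interval at the stated level.
#'
#' @param est_d,est_ref `policy_mean_set` objects from
#'   [estimate_policy_mean()] on the same data and fits.
#' @param level Confidence level (default 0.95).
#' @return An object of class `policy_contrast`: a data.frame with columns
#'   `outcome`, `theta`, `se`, `conf_low`, `conf_high`, carrying the paired
#'   influence matrix and the policy pair as attributes.
#' @export
estimate_contrast <- function(est_d, est_ref, level = 0.95) {
  stopifnot(inherits(est_d, "policy_mean_set"), inherits(est_ref, "policy_mean_set"))
  if (attr(est_d, "n") != attr(est_ref, "n") ||
      !identical(attr(est_d, "participants_tag"), attr(est_ref, "participants_tag"))) {
    stop_sdr("sdrshift_validation_error",
             "policy means were estimated on mismatched participant sets")
  }
  common <- intersect(est_d$outcome, est_ref$outcome)
  n <- attr(est_d, "n")
  di <- attr(est_d, "influence")[, common, drop = FALSE]
  ri <- attr(est_ref, "influence")[, common, drop = FALSE]
  dd <- di - ri
  theta <- colMeans(dd)
  se <- apply(dd, 2, stats::sd) / sqrt(n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(outcome = common, theta = unname(theta), se = unname(se),
                    conf_low = unname(theta - z * se), conf_high = unname(theta + z * se),
                    stringsAsFactors = FALSE)
  structure(out, class = c("policy_contrast", "data.frame"),
            influence = dd, n = n, level = level,
            policy = attr(est_d, "policy"), reference = attr(est_ref, "policy"))
}

#' @export
print.policy_contrast <- function(x, ...) {
  cat("<policy_contrast> ", policy_label(attr(x, "policy")), " vs ",
      policy_label(attr(x, "reference")), ", n = ", attr(x, "n"),
      ", level = ", attr(x, "level"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
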