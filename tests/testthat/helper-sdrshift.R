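# Shared fixtures, all generated in code.  Expensive prepared cohorts are
# cached per session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Generated cohort run through the standard preparation pipeline.
prepared_cohort <- function(n, seed = 1, ...) {
  args <- list(...)
  key <- paste0("coh_", n, "_", seed, "_",
                paste(names(args), vapply(args, paste, "", collapse = "."),
                      sep = "=", collapse = "_"))
  cached(key, {
    cfg <- do.call(dgp_config, c(list(n = n, seed = seed), args))
    coh <- generate_cohort(cfg)
    coh <- impute_baseline(coh, "mean_mode", seed = seed)
    coh <- carry_forward_time_varying(coh)
    list(cfg = cfg, coh = coh)
  })
}

# Baseline non-exposed restriction together with the true propensity matrix
# for the retained rows (rows of `truth` follow the unrestricted cohort).
restricted_with_truth <- function(prep) {
  coh <- prep$coh
  keep <- which(!is.na(coh$records$a0) & coh$records$a0 == 0)
  nb <- restrict_cohort(coh, cohort_rule("baseline_nonexposed", "a0"))
  tru <- attr(coh, "truth")
  list(nb = nb, g_true = cbind(tru$g1[keep], tru$g4[keep]), keep = keep)
}

# A tiny single-wave binary panel with known logistic propensity and linear
# outcome, no censoring; used for the one-wave AIPW cross-check.
make_k1_binary_panel <- function(n = 1500, seed = 4) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  g <- plogis(-1 + 0.8 * x1)
  a <- rbinom(n, 1, g)
  y <- 0.5 * a + 0.7 * x1 - 0.3 * x2 + rnorm(n)
  rec <- data.frame(x1 = x1, x2 = x2, c_t1 = 1, a_t1 = a, c_y = 1, y = y)
  schema <- panel_schema(
    baseline_covariates = c("x1", "x2"),
    exposure_waves = c(t1 = "a_t1"),
    censoring = c(t1 = "c_t1"),
    outcome_censoring = "c_y",
    outcomes = "y"
  )
  list(data = panel_dataset(rec, schema), g = g)
}

# A tiny single-wave continuous-exposure panel with a linear dose effect.
make_continuous_panel <- function(n = 2500, seed = 9, beta = 0.3) {
  set.seed(seed)
  x1 <- rnorm(n)
  a <- 2 + 0.5 * x1 + rnorm(n)
  y <- beta * a + 0.5 * x1 + rnorm(n)
  rec <- data.frame(x1 = x1, c_t1 = 1, a_t1 = a, c_y = 1, y = y)
  schema <- panel_schema(
    baseline_covariates = "x1",
    exposure_waves = c(t1 = "a_t1"),
    censoring = c(t1 = "c_t1"),
    outcome_censoring = "c_y",
    outcomes = "y",
    exposure_type = "continuous"
  )
  list(data = panel_dataset(rec, schema), beta = beta)
}

# Small hand-written two-wave panel with chained time-varying confounders,
# for the carry-forward rules.
make_manual_panel <- function() {
  rec <- data.frame(
    z = c(0.7, 1.2, -0.4),
    c_t1 = c(1, 1, 1), l_t1 = c(NA, 0.5, -0.1), a_t1 = c(0, 1, 0),
    c_t4 = c(1, 1, 1), l_t4 = c(NA, 0.9, 0.3), a_t4 = c(0, 1, 0),
    c_y = c(1, 1, 1), y1 = c(0.1, -0.2, 0.4)
  )
  schema <- panel_schema(
    baseline_covariates = "z",
    exposure_waves = c(t1 = "a_t1", t4 = "a_t4"),
    time_varying = list(t1 = "l_t1", t4 = "l_t4"),
    censoring = c(t1 = "c_t1", t4 = "c_t4"),
    outcome_censoring = "c_y",
    outcomes = "y1",
    time_varying_predecessor = c(l_t1 = "z", l_t4 = "l_t1")
  )
  panel_dataset(rec, schema)
}

# Minimal policy_contrast construction for the inference-layer formula tests.
fake_contrast <- function(outcome, theta, se, conf_low, conf_high) {
  structure(
    data.frame(outcome = outcome, theta = theta, se = se,
               conf_low = conf_low, conf_high = conf_high,
               stringsAsFactors = FALSE),
    class = c("policy_contrast", "data.frame"),
    n = 1000L, level = 0.95,
    policy = policy("ips_shift", delta = 5), reference = policy("identity"))
}
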