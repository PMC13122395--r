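small_schema <- function() {
  panel_schema(
    baseline_covariates = c("x1", "a0"),
    exposure_waves = c(t1 = "a_t1", t4 = "a_t4"),
    time_varying = list(t1 = character(0), t4 = "l_t4"),
    censoring = c(t1 = "c_t1", t4 = "c_t4"),
    outcome_censoring = "c_y",
    outcomes = "y1"
  )
}

test_that("well-formed CSV loads; invariant breaches are reported with rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "x1,a0,c_t1,a_t1,c_t4,l_t4,a_t4,c_y,y1",
    "0.5,0,1,0,1,0.2,0,1,0.1",
    "-1.2,0,1,1,1,0.4,1,1,-0.3",
    "0.3,1,1,0,1,-0.1,0,1,0.8"), csv)
  pd <- load_panel(csv, small_schema())
  expect_s3_class(pd, "panel_dataset")
  expect_equal(nrow(pd$records), 3)

  # exposure missing while the censoring indicator says observed
  writeLines(c(
    "x1,a0,c_t1,a_t1,c_t4,l_t4,a_t4,c_y,y1",
    "0.5,0,1,,1,0.2,0,1,0.1"), csv)
  err <- expect_error(load_panel(csv, small_schema()),
                      class = "sdrshift_validation_error")
  expect_match(conditionMessage(err), "a_t1")
  expect_match(conditionMessage(err), "rows 1")

  # non-monotone censoring: observed at t4 after censoring at t1
  writeLines(c(
    "x1,a0,c_t1,a_t1,c_t4,l_t4,a_t4,c_y,y1",
    "0.5,0,0,,1,0.2,0,1,0.1"), csv)
  expect_error(load_panel(csv, small_schema()),
               class = "sdrshift_validation_error")
  expect_error(panel_dataset(data.frame(x1 = 1), small_schema()),
               class = "sdrshift_schema_error")
})

test_that("write/load round trip reproduces the cohort bit-exactly", {
  prep <- prepared_cohort(300, seed = 21)
  coh <- prep$coh
  csv <- tempfile(fileext = ".csv")
  write_panel(coh, csv)
  back <- load_panel(csv, paste0(csv, ".schema.yaml"))
  expect_equal(back$records, coh$records, tolerance = 0)
  expect_equal(back$schema$baseline_covariates, coh$schema$baseline_covariates)
  expect_equal(back$schema$exposure_waves, coh$schema$exposure_waves)
  expect_equal(back$schema$time_varying, coh$schema$time_varying)
  expect_equal(back$schema$outcome_domains, coh$schema$outcome_domains)
})

test_that("cohort restriction keeps baseline non-exposed rows only", {
  set.seed(5)
  n <- 1000
  rec <- data.frame(
    x1 = rnorm(n), a0 = rbinom(n, 1, 0.2),
    c_t1 = 1, a_t1 = rbinom(n, 1, 0.1),
    c_t4 = 1, l_t4 = rnorm(n), a_t4 = rbinom(n, 1, 0.1),
    c_y = 1, y1 = rnorm(n))
  pd <- panel_dataset(rec, small_schema())
  nb <- restrict_cohort(pd, cohort_rule("baseline_nonexposed", "a0"))
  expect_equal(nrow(nb$records), sum(rec$a0 == 0))
  expect_true(all(nb$records$a0 == 0))
  expect_gt(nrow(nb$records), 700)
  expect_lt(nrow(nb$records), 880)

  full <- restrict_cohort(pd, cohort_rule("full_cohort"))
  expect_equal(full$records, pd$records)

  rec$a0 <- 1
  pd1 <- panel_dataset(rec, small_schema())
  expect_error(restrict_cohort(pd1, cohort_rule("baseline_nonexposed", "a0")),
               class = "sdrshift_empty_cohort_error")
})

test_that("baseline imputation fills by mean/mode or observed donors", {
  rec <- data.frame(
    x1 = c(1, 2, 3, NA), a0 = c(0, 0, 1, 0),
    c_t1 = 1, a_t1 = c(0, 1, 0, 0),
    c_t4 = 1, l_t4 = c(0.1, 0.2, 0.3, 0.4), a_t4 = c(0, 1, 0, 0),
    c_y = 1, y1 = c(0.5, -0.5, 0.2, 0.1))
  pd <- panel_dataset(rec, small_schema())
  imp <- impute_baseline(pd, "mean_mode")
  expect_equal(imp$records$x1[4], 2)          # arithmetic mean of {1,2,3}
  expect_false(anyNA(imp$records$x1))

  # donor matching: every imputed value is an observed value of that column
  set.seed(8)
  n <- 80
  rec2 <- data.frame(
    x1 = round(rnorm(n), 3), a0 = rbinom(n, 1, 0.3),
    c_t1 = 1, a_t1 = rbinom(n, 1, 0.2),
    c_t4 = 1, l_t4 = rnorm(n), a_t4 = rbinom(n, 1, 0.2),
    c_y = 1, y1 = rnorm(n))
  miss <- sample(n, 10)
  observed_vals <- rec2$x1[-miss]
  rec2$x1[miss] <- NA
  pd2 <- panel_dataset(rec2, small_schema())
  imp2 <- impute_baseline(pd2, "knn_match", seed = 3)
  expect_true(all(imp2$records$x1[miss] %in% observed_vals))
  # reproducible under the same seed
  imp2b <- impute_baseline(pd2, "knn_match", seed = 3)
  expect_equal(imp2$records, imp2b$records)

  # no missingness: returned unchanged
  expect_identical(impute_baseline(imp, "mean_mode")$records, imp$records)

  rec2$x1 <- NA_real_
  pd3 <- panel_dataset(rec2, small_schema())
  expect_error(impute_baseline(pd3, "mean_mode"),
               class = "sdrshift_validation_error")
})

test_that("carry-forward fills from the most recent observed measurement", {
  pd <- carry_forward_time_varying(make_manual_panel())
  rec <- pd$records
  # participant 1: both waves missing -> both filled from baseline, indicators 1
  expect_equal(rec$l_t1[1], 0.7)
  expect_equal(rec$l_t4[1], 0.7)
  expect_equal(rec$l_t1_cf[1], 1)
  expect_equal(rec$l_t4_cf[1], 1)
  # fully observed participant: unchanged, indicators 0
  expect_equal(rec$l_t1[2], 0.5)
  expect_equal(rec$l_t4[2], 0.9)
  expect_equal(rec$l_t1_cf[2], 0)
  expect_equal(rec$l_t4_cf[2], 0)
  # indicator columns joined the schema's time-varying sets
  expect_true("l_t1_cf" %in% pd$schema$time_varying$t1)
  expect_true("l_t4_cf" %in% pd$schema$time_varying$t4)
  # idempotent
  expect_equal(carry_forward_time_varying(pd), pd)
})

test_that("outcome standardisation is exact and idempotent", {
  rec <- data.frame(
    x1 = rnorm(3), a0 = 0,
    c_t1 = 1, a_t1 = 0, c_t4 = 1, l_t4 = 0, a_t4 = 0,
    c_y = 1, y1 = c(1, 2, 3))
  pd <- panel_dataset(rec, small_schema())
  st <- standardise_outcomes(pd)
  # sample SD (denominator n - 1) of {1,2,3} is exactly 1
  expect_equal(st$records$y1, c(-1, 0, 1))
  st2 <- standardise_outcomes(st)
  expect_equal(st2$records$y1, st$records$y1, tolerance = 1e-8)

  set.seed(2)
  rec$y1 <- rnorm(3, 5, 2)
  pd2 <- standardise_outcomes(panel_dataset(rec, small_schema()))
  expect_equal(mean(pd2$records$y1), 0, tolerance = 1e-8)
  expect_equal(sd(pd2$records$y1), 1, tolerance = 1e-8)
  scl <- attr(pd2, "outcome_scaling")
  expect_equal(scl$mean, mean(rec$y1))

  rec$y1 <- rep(2, 3)
  err <- expect_error(standardise_outcomes(panel_dataset(rec, small_schema())),
                      class = "sdrshift_validation_error")
  expect_match(conditionMessage(err), "y1")
})

test_that("the preparation pipeline preserves censoring monotonicity and is idempotent", {
  prep <- prepared_cohort(400, seed = 17)
  coh <- prep$coh
  # re-validating the transformed records raises no error
  expect_s3_class(panel_dataset(coh$records, coh$schema), "panel_dataset")
  once <- carry_forward_time_varying(impute_baseline(coh, "mean_mode", seed = 1))
  twice <- carry_forward_time_varying(impute_baseline(once, "mean_mode", seed = 1))
  expect_equal(twice$records, once$records)
  expect_equal(twice$schema, once$schema)
})
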