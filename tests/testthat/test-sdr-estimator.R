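test_that("nuisance specification validates its inputs", {
  expect_error(nuisance_spec(n_folds = 1), class = "sdrshift_config_error")
  expect_error(nuisance_spec(treatment_learners = character(0)),
               class = "sdrshift_config_error")
  expect_s3_class(nuisance_spec(weight_mode = "nuisance"), "nuisance_spec")
})

test_that("censoring models return ~1 when no one is censored", {
  cfg <- dgp_config(n = 1200, attrition_intercept = -Inf,
                    attrition_exposure_coef = 0, seed = 8)
  coh <- impute_baseline(generate_cohort(cfg), "mean_mode", seed = 1)
  coh <- carry_forward_time_varying(coh)
  fits <- fit_nuisances(coh, nuisance_spec(), seed = 2)
  expect_true(all(fits$pc >= 0.999, na.rm = TRUE))
})

test_that("cross-fitted propensities recover the true logistic mechanism", {
  prep <- prepared_cohort(20000, seed = 1)
  rw <- restricted_with_truth(prep)
  fits <- cached("fits20k", fit_nuisances(rw$nb, nuisance_spec(), seed = 1))
  obs1 <- rw$nb$records$c_t1 == 1
  rmse <- sqrt(mean((fits$g[obs1, 1] - rw$g_true[obs1, 1])^2))
  expect_lt(rmse, 0.02)
  obs4 <- rw$nb$records$c_t4 == 1
  rmse4 <- sqrt(mean((fits$g[obs4, 2] - rw$g_true[obs4, 2])^2))
  expect_lt(rmse4, 0.05)
  # fallback to marginal rate is triggered and logged for single-class folds
  cfg0 <- dgp_config(n = 400, init_intercept = -30, persistence = 0,
                     baseline_exposure_intercept = -30, seed = 3)
  coh0 <- carry_forward_time_varying(
    impute_baseline(generate_cohort(cfg0), "mean_mode", seed = 1))
  fits0 <- fit_nuisances(coh0, nuisance_spec(), seed = 1)
  expect_true(any(fits0$learner_log$fallback))
})

test_that("single-wave estimator agrees with a hand-rolled AIPW", {
  k1 <- make_k1_binary_panel()
  fits <- fit_nuisances(k1$data, nuisance_spec(treatment_learners = "glm"), seed = 3)
  pol <- policy("ips_shift", delta = 2)
  est <- estimate_policy_mean(k1$data, pol, fits)

  rec <- k1$data$records
  gfit <- stats::glm(a_t1 ~ x1 + x2, stats::binomial, rec)
  g <- stats::fitted(gfit)
  mfit <- stats::lm(y ~ x1 + x2 + a_t1, rec)
  m_obs <- stats::fitted(mfit)
  m1 <- stats::predict(mfit, transform(rec, a_t1 = 1))
  m0 <- stats::predict(mfit, transform(rec, a_t1 = 0))
  pd1 <- 1 - (1 - g) / 2
  mbar <- m0 * (1 - pd1) + m1 * pd1
  rr <- ifelse(rec$a_t1 == 1, pd1 / g, 0.5)
  theta_hand <- mean(mbar + rr * (rec$y - m_obs))
  expect_lt(abs(est$point - theta_hand), 3 * est$se)

  # identity policy mean tracks the raw outcome mean when nothing is censored
  eid <- estimate_policy_mean(k1$data, policy("identity"), fits)
  expect_lt(abs(eid$point - mean(rec$y)), 3 * eid$se)
})

test_that("set-to-zero recovers the oracle loss on the full cohort", {
  prep <- prepared_cohort(8000, seed = 23)
  fits <- fit_nuisances(prep$coh, nuisance_spec(), seed = 2)
  e0 <- estimate_policy_mean(prep$coh, policy("set_all", value = 0), fits)
  eid <- estimate_policy_mean(prep$coh, policy("identity"), fits)
  ctr <- estimate_contrast(e0, eid)
  o0 <- oracle_policy_mean(prep$cfg, policy("set_all", value = 0),
                           n_mc = 100000, seed = 31, cohort = "full")
  oid <- oracle_policy_mean(prep$cfg, policy("identity"),
                            n_mc = 100000, seed = 31, cohort = "full")
  truth <- o0$mean - oid$mean
  # stopping everyone harms the effectful outcomes (oracle direction)...
  expect_true(all(truth[13:18] < 0))
  # ...and the estimator recovers the oracle gap
  for (j in c(1, 14, 16)) {
    expect_lt(abs(ctr$theta[j] - truth[j]),
              3 * (ctr$se[j] + sqrt(o0$mc_se[j]^2 + oid$mc_se[j]^2)))
  }
})

test_that("point estimates are stable across fold assignments", {
  prep <- prepared_cohort(4000, seed = 19)
  rw <- restricted_with_truth(prep)
  pol <- policy("ips_shift", delta = 5)
  f1 <- fit_nuisances(rw$nb, nuisance_spec(), seed = 101)
  f2 <- fit_nuisances(rw$nb, nuisance_spec(), seed = 707)
  e1 <- estimate_policy_mean(rw$nb, pol, f1, outcomes = "y_o14")
  e2 <- estimate_policy_mean(rw$nb, pol, f2, outcomes = "y_o14")
  expect_lt(abs(e1$point - e2$point), 3 * e1$se)
})

test_that("participant order does not change the point estimate", {
  prep <- prepared_cohort(1500, seed = 14)
  rw <- restricted_with_truth(prep)
  fits <- fit_nuisances(rw$nb, nuisance_spec(), seed = 4)
  pol <- policy("ips_shift", delta = 2)
  e1 <- estimate_policy_mean(rw$nb, pol, fits, outcomes = c("y_o01", "y_o14"))
  set.seed(1)
  perm <- sample(nrow(rw$nb$records))
  nb_p <- rw$nb
  nb_p$records <- nb_p$records[perm, , drop = FALSE]
  fits_p <- fits
  fits_p$g <- fits$g[perm, , drop = FALSE]
  fits_p$pc <- fits$pc[perm, , drop = FALSE]
  fits_p$folds <- fits$folds[perm]
  e2 <- estimate_policy_mean(nb_p, pol, fits_p, outcomes = c("y_o01", "y_o14"))
  expect_equal(e2$point, e1$point, tolerance = 1e-8)

  # influence values average exactly to the point estimate
  expect_equal(unname(colMeans(attr(e1, "influence"))), e1$point)
})

test_that("mismatched participant sets and policy/exposure mismatches error", {
  prep <- prepared_cohort(1500, seed = 14)
  rw <- restricted_with_truth(prep)
  f1 <- fit_nuisances(rw$nb, nuisance_spec(), seed = 1)
  f2 <- fit_nuisances(rw$nb, nuisance_spec(), seed = 2)
  pol <- policy("ips_shift", delta = 2)
  e1 <- estimate_policy_mean(rw$nb, pol, f1)
  e2 <- estimate_policy_mean(rw$nb, policy("identity"), f2)
  expect_error(estimate_contrast(e1, e2), class = "sdrshift_validation_error")
  expect_error(estimate_policy_mean(prep$coh, pol, f1),
               class = "sdrshift_validation_error")
  cont <- make_continuous_panel()
  expect_error(fit_nuisances(rw$nb, nuisance_spec(), seed = 1) |>
                 (\(f) estimate_policy_mean(rw$nb,
                                            policy("additive_shift", shift_amount = 1), f))(),
               class = "sdrshift_policy_error")
  fc <- fit_nuisances(cont$data, nuisance_spec(), seed = 1)
  expect_error(estimate_policy_mean(cont$data, pol, fc),
               class = "sdrshift_policy_error")
})

test_that("additive shifts on a continuous exposure recover a linear dose effect", {
  cont <- make_continuous_panel(n = 3000, seed = 9, beta = 0.3)
  fits <- fit_nuisances(cont$data, nuisance_spec(), seed = 6)
  pol <- policy("additive_shift", shift_amount = 1, support_cap = 99)
  e1 <- estimate_policy_mean(cont$data, pol, fits)
  eid <- estimate_policy_mean(cont$data, policy("identity"), fits)
  ctr <- estimate_contrast(e1, eid)
  expect_lt(abs(ctr$theta - cont$beta), 4 * ctr$se)
  # a binding support cap attenuates the shift
  pol_cap <- policy("additive_shift", shift_amount = 1, support_cap = 2)
  e_cap <- estimate_policy_mean(cont$data, pol_cap, fits)
  expect_lt(e_cap$point, e1$point)
})

test_that("post-stratification weights enter the final averaging", {
  prep <- prepared_cohort(3000, seed = 26, weight_variation = 0.8)
  rw <- restricted_with_truth(prep)
  fits <- fit_nuisances(rw$nb, nuisance_spec(), seed = 3)
  est <- estimate_policy_mean(rw$nb, policy("identity"), fits, outcomes = "y_o14")
  expect_true(is.finite(est$point) && is.finite(est$se))
  expect_equal(mean(attr(est, "influence")), est$point)
  # weights actually change the answer relative to the unweighted cohort
  nb_unw <- rw$nb
  nb_unw$records$w <- 1
  est_u <- estimate_policy_mean(nb_unw, policy("identity"), fits, outcomes = "y_o14")
  expect_false(isTRUE(all.equal(est$point, est_u$point)))
})
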