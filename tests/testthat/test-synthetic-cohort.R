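test_that("default calibration yields rare initiation and monotone attrition", {
  prep <- prepared_cohort(10000, seed = 6)
  rec <- prep$coh$records
  nb <- rec$a0 == 0
  init1 <- mean(rec$a_t1[nb & rec$c_t1 == 1])
  expect_gt(init1, 0.015)
  expect_lt(init1, 0.04)
  w4 <- nb & rec$c_t4 == 1 & !is.na(rec$a_t1) & rec$a_t1 == 0
  init4 <- mean(rec$a_t4[w4])
  expect_gt(init4, 0.015)
  expect_lt(init4, 0.04)
  # monotone censoring, with exposure persistence high
  expect_true(all(rec$c_t4 <= rec$c_t1 & rec$c_y <= rec$c_t4))
  expect_gt(mean(rec$a_t4[rec$c_t4 == 1 & rec$a_t1 == 1]), 0.7)
  # z-scored outcomes
  expect_equal(mean(rec$y_o01, na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(sd(rec$y_o01, na.rm = TRUE), 1, tolerance = 1e-8)
})

test_that("attrition can be switched off entirely", {
  cfg <- dgp_config(n = 800, attrition_intercept = -Inf,
                    attrition_exposure_coef = 0, seed = 2)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$records$c_t1 == 1 & coh$records$c_t4 == 1 & coh$records$c_y == 1))
  expect_false(anyNA(coh$records$a_t1))
})

test_that("generation is reproducible and config validation rejects bad inputs", {
  c1 <- generate_cohort(dgp_config(n = 500, seed = 33))
  c2 <- generate_cohort(dgp_config(n = 500, seed = 33))
  expect_identical(c1$records, c2$records)
  expect_error(dgp_config(n = 100, init_intercept = NaN),
               class = "sdrshift_config_error")
  expect_error(dgp_config(n = 100, effect_sizes = rep(0.1, 24)),
               class = "sdrshift_config_error")  # violates the selective mask
  expect_error(dgp_config(n = 100, effect_sizes = c(0.1, 0.2)),
               class = "sdrshift_config_error")
})

test_that("confounding does not leak into the oracle under a null DGP", {
  cfg <- dgp_config(n = 6000, selective_mask = rep(FALSE, 24), seed = 12)
  coh <- generate_cohort(cfg)
  rec <- coh$records
  # raw exposed/unexposed difference is confounded away from zero
  obs <- rec$c_y == 1 & !is.na(rec$a_t1)
  dif <- t.test(rec$y_o01[obs & rec$a_t1 == 1], rec$y_o01[obs & rec$a_t1 == 0])
  expect_lt(dif$p.value, 0.01)
  # same-seed oracle contrast is exactly zero (coupled draws, no effect)
  oid <- oracle_policy_mean(cfg, policy("identity"), n_mc = 40000, seed = 5)
  o5 <- oracle_policy_mean(cfg, policy("ips_shift", delta = 5), n_mc = 40000, seed = 5)
  expect_lt(max(abs(o5$mean - oid$mean)), 1e-12)
  # different-seed oracle contrast is zero within Monte-Carlo error
  o5b <- oracle_policy_mean(cfg, policy("ips_shift", delta = 5), n_mc = 40000, seed = 6)
  expect_true(all(abs(o5b$mean - oid$mean) < 4 * sqrt(o5b$mc_se^2 + oid$mc_se^2)))
  # set-to-zero equals identity under the null
  o0 <- oracle_policy_mean(cfg, policy("set_all", value = 0), n_mc = 40000, seed = 5)
  expect_lt(max(abs(o0$mean - oid$mean)), 1e-12)
})

test_that("oracle identity matches the natural course of an uncensored cohort", {
  cfg <- dgp_config(n = 40000, attrition_intercept = -Inf,
                    attrition_exposure_coef = 0, seed = 44)
  coh <- generate_cohort(cfg)
  rec <- coh$records
  nb <- rec$a0 == 0
  oid <- oracle_policy_mean(cfg, policy("identity"), n_mc = 80000, seed = 45)
  # cohort outcomes are z-scored on the full cohort; the baseline non-exposed
  # subgroup mean should agree with the oracle's standardised identity mean
  for (j in c("y_o01", "y_o13")) {
    cohort_mean <- mean(rec[[j]][nb])
    o <- oid$mean[match(j, oid$outcome)]
    expect_lt(abs(cohort_mean - o),
              3 * (oid$mc_se[match(j, oid$outcome)] + 1 / sqrt(sum(nb))))
  }
})

test_that("oracle contrasts are monotone in delta and approach set-to-one", {
  cfg <- dgp_config(n = 1000, seed = 3)
  ms <- vapply(c(1, 2, 5, 10), function(d) {
    o <- oracle_policy_mean(cfg, policy("ips_shift", delta = d), n_mc = 60000, seed = 9)
    o$mean[14]
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  o_inf <- oracle_policy_mean(cfg, policy("ips_shift", delta = 1e4), n_mc = 60000, seed = 9)
  o_set1 <- oracle_policy_mean(cfg, policy("set_all", value = 1), n_mc = 60000, seed = 9)
  expect_lt(max(abs(o_inf$mean - o_set1$mean)),
            4 * max(sqrt(o_inf$mc_se^2 + o_set1$mc_se^2)))
})

test_that("oracle contrast matches a quadrature evaluation of the logistic DGP", {
  # independent closed-form-style oracle: integrate the expected number of
  # exposed waves over the latent-confounder distribution by nested
  # quadrature, exploiting that the delta-shift is affine in the propensity
  cfg <- dgp_config(n = 1000, seed = 3)
  c0 <- cfg$confounding_strength
  shift <- function(p, d) 1 - (1 - p) / d
  var_z <- (1 - c0^2) / 6          # variance of the mean of 6 lagged outcomes
  gtv <- cfg$g4_tv_coef
  e_waves <- function(w, d) {
    g1 <- plogis(cfg$init_intercept + c0 * w)       # a0 = 0 cohort
    p1 <- shift(g1, d)
    out <- numeric(length(w))
    for (a1 in 0:1) {
      pa1 <- if (a1 == 1) p1 else 1 - p1
      mu_l2m <- c0 * w + cfg$tv_exposure_coef * a1
      base <- cfg$init_intercept + c0 * w + cfg$persistence * a1 + gtv * mu_l2m
      g4 <- vapply(base, function(b) {
        stats::integrate(function(z) plogis(b + gtv * z) * dnorm(z, 0, sqrt(var_z)),
                         -8 * sqrt(var_z), 8 * sqrt(var_z))$value
      }, numeric(1))
      out <- out + pa1 * (a1 + shift(g4, d))
    }
    out
  }
  w_weight <- function(w) (1 - plogis(cfg$baseline_exposure_intercept + c0 * w)) * dnorm(w)
  denom <- stats::integrate(w_weight, -8, 8)$value
  ew <- function(d) stats::integrate(function(w) e_waves(w, d) * w_weight(w),
                                     -8, 8, subdivisions = 400L)$value / denom
  delta_waves <- ew(5) - ew(1)
  expected <- 0.04 * delta_waves   # tau per wave, additive across waves

  oid <- oracle_policy_mean(cfg, policy("identity"), n_mc = 150000, seed = 21)
  o5 <- oracle_policy_mean(cfg, policy("ips_shift", delta = 5), n_mc = 150000, seed = 21)
  got <- (o5$mean - oid$mean)[14]
  # tolerance: latent confounder is only approximately Gaussian (CLT over
  # 37 covariates) plus coupled Monte-Carlo error
  expect_lt(abs(got - expected), 0.006)
})
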