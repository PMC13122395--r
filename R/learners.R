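# Nuisance-model learners.  A deliberately small menu standing in for a full
# SuperLearner library: "mean" (marginal rate / grand mean), "glm"
# (linear / logistic regression on the design matrix), "ridge"
# (L2-penalised linear / logistic regression, penalty chosen on a seeded 25%
# holdout — essential for rare-event propensities, where unpenalised MLE
# overfits badly), "stump" (a shallow rpart tree, depth 2) and "xgb"
# (shallow gradient-boosted trees).  When a menu has several learners the
# winner is chosen by risk on a seeded 25% holdout of the training rows
# (discrete selection), then refit on all training rows.

fit_learner <- function(name, x, y, family, weights = NULL, seed = NULL) {
  if (family == "binomial" && length(unique(y)) < 2L) {
    # single exposure/censoring class in this fold: fall back to marginal rate
    return(structure(list(kind = "mean", value = mean(y), fallback = TRUE,
                          family = family),
                     class = "sdr_learner"))
  }
  fit <- switch(name,
    mean = {
      mv <- if (is.null(weights)) mean(y) else stats::weighted.mean(y, weights)
      list(kind = "mean", value = mv)
    },
    glm = {
      if (family == "gaussian") {
        xw <- cbind(`(Intercept)` = 1, x)
        if (!is.null(weights)) {
          sw <- sqrt(weights)
          cf <- qr.coef(qr(xw * sw), y * sw)
        } else {
          cf <- qr.coef(qr(xw), y)
        }
        cf[is.na(cf)] <- 0
        list(kind = "lin", coef = cf)
      } else {
        cf <- tryCatch({
          f <- suppressWarnings(stats::glm.fit(
            cbind(`(Intercept)` = 1, x), y,
            weights = weights %||% rep(1, length(y)),
            family = stats::binomial()))
          cc <- f$coefficients
          cc[is.na(cc)] <- 0
          cc
        }, error = function(e) NULL)
        if (is.null(cf)) list(kind = "mean", value = mean(y), fallback = TRUE)
        else list(kind = "logit", coef = cf)
      }
    },
    ridge = ridge_fit(x, y, family, weights, seed = seed),
    stump = {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      df$.y <- y
      ctl <- rpart::rpart.control(maxdepth = 2L, cp = 0.001, minsplit = 40L, xval = 0L)
      f <- rpart::rpart(.y ~ ., data = df, weights = weights,
                        method = "anova", control = ctl)
      list(kind = "rpart", fit = f, p = ncol(x))
    },
    xgb = {
      obj <- if (family == "binomial") "binary:logistic" else "reg:squarederror"
      f <- xgboost::xgboost(
        data = x, label = y, weight = weights,
        nrounds = 60L, max_depth = 2L, eta = 0.3,
        objective = obj, verbose = 0L, nthread = 1L)
      list(kind = "xgb", fit = f)
    },
    stop_sdr("sdrshift_config_error", "unknown learner '%s'", name)
  )
  fit$family <- family
  structure(fit, class = "sdr_learner")
}

predict_learner <- function(object, x) {
  out <- switch(object$kind,
    mean = rep(object$value, nrow(x)),
    lin = drop(cbind(1, x) %*% object$coef),
    logit = stats::plogis(drop(cbind(1, x) %*% object$coef)),
    lin_coef = {
      eta <- drop(cbind(1, x) %*% object$coef)
      if (object$link == "logit") stats::plogis(eta) else eta
    },
    rpart = {
      df <- as.data.frame(x)
      names(df) <- paste0("V", seq_len(ncol(x)))
      unname(stats::predict(object$fit, newdata = df))
    },
    xgb = stats::predict(object$fit, x)
  )
  if (object$family == "binomial") out <- clip(out, 0, 1)
  out
}

# Fit a (possibly one-element) learner menu with discrete holdout selection.
# Returns the winning fitted learner with the chosen name attached.
fit_menu <- function(learners, x, y, family, weights = NULL, seed = NULL) {
  learners <- unique(learners)
  if (length(learners) == 1L) {
    f <- fit_learner(learners, x, y, family, weights, seed = seed)
    f$name <- learners
    return(f)
  }
  n <- length(y)
  hold <- with_seed(seed, sample.int(n) <= ceiling(n / 4))
  risks <- vapply(learners, function(nm) {
    f <- fit_learner(nm, x[!hold, , drop = FALSE], y[!hold],
                     family, weights[!hold], seed = child_seed(seed, 7L))
    p <- predict_learner(f, x[hold, , drop = FALSE])
    if (family == "binomial") {
      p <- clip(p, 1e-6, 1 - 1e-6)
      -mean(y[hold] * log(p) + (1 - y[hold]) * log(1 - p))
    } else {
      mean((y[hold] - p)^2)
    }
  }, numeric(1))
  win <- learners[which.min(risks)]
  f <- fit_learner(win, x, y, family, weights, seed = seed)
  f$name <- win
  f
}

# L2-penalised linear/logistic regression; the penalty is chosen by risk on
# a seeded 25% holdout over a short glmnet path, then the model is refit on
# all rows at the chosen penalty.
ridge_fit <- function(x, y, family, weights = NULL, seed = NULL) {
  fam <- if (family == "binomial") "binomial" else "gaussian"
  n <- length(y)
  hold <- with_seed(seed, sample.int(n) <= ceiling(n / 4))
  path <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold], family = fam,
                         alpha = 0, nlambda = 30L,
                         weights = if (!is.null(weights)) weights[!hold])
  p <- stats::predict(path, x[hold, , drop = FALSE], type = "response")
  risk <- if (family == "binomial") {
    apply(p, 2, function(pp) {
      pp <- clip(pp, 1e-6, 1 - 1e-6)
      -mean(y[hold] * log(pp) + (1 - y[hold]) * log(1 - pp))
    })
  } else {
    apply(p, 2, function(pp) mean((y[hold] - pp)^2))
  }
  lam <- path$lambda[which.min(risk)]
  full <- glmnet::glmnet(x, y, family = fam, alpha = 0, lambda = path$lambda,
                         weights = weights)
  cf <- as.numeric(stats::coef(full, s = lam))
  list(kind = "lin_coef", coef = cf, link = if (family == "binomial") "logit" else "identity")
}

# Multi-response linear regression via one QR decomposition: used for the
# sequential outcome regressions when the outcome learner menu is just "glm",
# so all outcomes share the factorisation.
fit_linear_multi <- function(x, ymat, weights = NULL) {
  xw <- cbind(`(Intercept)` = 1, x)
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    q <- qr(xw * sw)
    cf <- qr.coef(q, ymat * sw)
  } else {
    q <- qr(xw)
    cf <- qr.coef(q, ymat)
  }
  cf[is.na(cf)] <- 0
  cf
}

predict_linear_multi <- function(coef, x) {
  cbind(1, x) %*% coef
}
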