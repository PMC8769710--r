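ridge_fixture <- function(seed, n = 30, p = 2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    t_true <- rexp(n, exp(0.6 * X[, 1] - 0.3 * X[, p]))
    cens <- rexp(n, 0.25)
    list(X = X, time = pmin(t_true, cens) + 1e-3,
         event = as.numeric(t_true <= cens))
  })
}

test_that("ridge Cox satisfies stationarity and collapses under heavy penalty", {
  fx <- ridge_fixture(1)
  for (lam in c(0.1, 1, 10)) {
    fit <- fit_ridge_cox(fx$X, fx$time, fx$event, lam)
    expect_lt(fit$grad_norm, 1e-6)
    expect_true(all(is.finite(fit$coefficients)))
    expect_true(all(diff(fit$baseline_cumhaz$values) >= -1e-12))
  }
  big <- fit_ridge_cox(fx$X, fx$time, fx$event, 1e6)
  expect_lt(sqrt(sum(big$coefficients^2)), 1e-3)
})

test_that("unpenalized fit matches a generic optimizer and the reference", {
  fx <- ridge_fixture(2)
  fit <- fit_ridge_cox(fx$X, fx$time, fx$event, 0)
  opt <- optim(c(0, 0),
               function(b) -oracle_partial_loglik(b, fx$X, fx$time,
                                                  fx$event),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  cph <- survival::coxph(survival::Surv(fx$time, fx$event) ~ fx$X,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(cph)),
               tolerance = 1e-6)
})

test_that("the coefficient norm is nonincreasing along the penalty path", {
  fx <- ridge_fixture(3)
  path <- 10^seq(2, -3, length.out = 10)
  norms <- vapply(path, function(l) {
    sqrt(sum(fit_ridge_cox(fx$X, fx$time, fx$event, l)$coefficients^2))
  }, 0)
  expect_true(all(diff(norms) >= -1e-8))
})

test_that("penalty selection is seeded, grid-bounded and noise-averse", {
  fx <- ridge_fixture(4, n = 60, p = 4)
  lam1 <- select_lambda_cv(fx$X, fx$time, fx$event, n_folds = 3, seed = 5,
                           path_length = 20)
  lam2 <- select_lambda_cv(fx$X, fx$time, fx$event, n_folds = 3, seed = 5,
                           path_length = 20)
  expect_identical(lam1, lam2)
  grid <- attr(lam1, "grid")
  dev <- attr(lam1, "cv_deviance")
  expect_lte(dev[which(grid == as.numeric(lam1))],
             min(dev[1], dev[length(dev)]) + 1e-12)

  # pure-noise features push the penalty into the upper half of the grid
  upper <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      Xn <- matrix(rnorm(50 * 5), 50, 5)
      tt <- rexp(50) + 0.01
      ee <- rbinom(50, 1, 0.6)
      if (sum(ee) < 3) ee[1:3] <- 1
    })
    lam <- select_lambda_cv(Xn, tt, ee, n_folds = 3, seed = s,
                            path_length = 20)
    g <- attr(lam, "grid")
    which(g == as.numeric(lam)) <= length(g) / 2  # grid is descending
  }, TRUE)
  expect_gte(sum(upper), 3)

  # fewer events than folds: folds are reduced with a warning
  withr::with_seed(9, {
    Xs <- matrix(rnorm(20), 10, 2)
    ts <- rexp(10) + 0.1
    es <- c(1, 1, 1, rep(0, 7))
  })
  expect_warning(select_lambda_cv(Xs, ts, es, n_folds = 5, seed = 1,
                                  path_length = 5), "reducing folds")
})

test_that("survival predictions are valid curves ordered by linear predictor", {
  fx <- ridge_fixture(6)
  fit <- fit_ridge_cox(fx$X, fx$time, fx$event, 0.5)
  pred <- predict_survival(fit, fx$X)
  expect_true(all(pred$surv >= 0 & pred$surv <= 1))
  expect_true(all(apply(pred$surv, 1, function(s) all(diff(s) <= 1e-12))))
  # S(0) = 1 for everyone
  expect_equal(survfilter:::eval_prediction(pred, 0), rep(1, 30))
  # higher linear predictor => pointwise lower curve
  eta <- as.vector(sweep(fx$X, 2, fit$centers) %*% fit$coefficients)
  hi <- which.max(eta); lo <- which.min(eta)
  expect_true(all(pred$surv[hi, ] <= pred$surv[lo, ] + 1e-12))
  # beta = 0 gives everyone the baseline curve
  null_fit <- fit_ridge_cox(fx$X, fx$time, fx$event, 1e9)
  base <- predict_survival(null_fit, fx$X)
  expect_lt(max(apply(base$surv, 2, function(col) diff(range(col)))), 1e-4)
  expect_error(predict_survival(fit, matrix(0, 2, 2)), "feature names")
})

test_that("the Kaplan-Meier predictor returns the training curve for everyone", {
  tt <- c(1, 2, 3, 4)
  ee <- c(1, 0, 1, 0)
  km <- km_predictor(tt, ee)
  pred <- predict_survival(km, matrix(0, 3, 2))
  expect_equal(nrow(pred$surv), 3)
  expect_equal(length(unique(split(pred$surv, row(pred$surv)))), 1)
  ref <- kaplan_meier(tt, ee)
  expect_equal(pred$surv[1, ], eval_step(ref, ref$knots))
  none <- predict_survival(km_predictor(tt, c(0, 0, 0, 0)), matrix(0, 2, 1))
  expect_true(all(none$surv == 1))
})

test_that("Harrell's C matches pair enumeration and its complement identity", {
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 0)
  t5 <- c(2, 4, 4.5, 6, 9)
  e5 <- c(1, 0, 1, 1, 0)
  r5 <- c(0.8, 0.2, 0.5, 0.9, 0.1)
  expect_equal(harrell_c(t5, e5, r5), oracle_harrell_c(t5, e5, r5))
  for (s in 1:5) {
    withr::with_seed(s, {
      tt <- runif(12) + 0.1
      ee <- rbinom(12, 1, 0.7)
      rr <- rnorm(12)
      if (sum(ee) == 0) ee[1] <- 1
    })
    expect_equal(harrell_c(tt, ee, rr), oracle_harrell_c(tt, ee, rr))
    expect_equal(harrell_c(tt, ee, rr) + harrell_c(tt, ee, -rr), 1)
  }
  expect_error(harrell_c(c(3, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("Brier and integrated Brier scores match closed forms and hand sums", {
  # perfect indicator predictions without censoring score zero
  tt <- c(1, 2, 3, 4)
  ee <- rep(1, 4)
  G <- kaplan_meier(tt, 1 - ee)
  perfect <- survival_prediction(sort(tt),
                                 t(vapply(tt, function(ti) {
                                   as.numeric(ti > sort(tt))
                                 }, numeric(4))))
  expect_equal(integrated_brier_score(perfect, tt, ee, G), 0)
  # constant 1/2 prediction scores 1/4 at every horizon
  half <- survival_prediction(0.5, matrix(0.5, 4, 1))
  expect_equal(brier_score(half, tt, ee, 2.5, G), 0.25)
  expect_equal(integrated_brier_score(half, tt, ee, G), 0.25)

  # hand-computed censored 3-observation case at t = 4:
  # G (censoring KM) drops to 1/2 at the censored time 4;
  # terms: 0.5^2 / 1, 0 (censored at 4), (1 - 0.5)^2 / (1/2)
  t3 <- c(2, 4, 6)
  e3 <- c(1, 0, 1)
  G3 <- kaplan_meier(t3, 1 - e3)
  pr3 <- survival_prediction(c(0, 3, 5),
                             matrix(rep(c(0.8, 0.5, 0.2), each = 3), 3))
  expect_equal(brier_score(pr3, t3, e3, 4, G3),
               mean(c(0.25, 0, 0.5)))

  for (s in 1:5) {
    ds <- random_ds(s, n = 25, p = 2)
    fit <- fit_ridge_cox(ds$features, ds$time, ds$event, 1)
    pred <- predict_survival(fit, ds$features)
    Gs <- kaplan_meier(ds$time, 1 - ds$event)
    ibs <- integrated_brier_score(pred, ds$time, ds$event, Gs)
    expect_gte(ibs, 0)
    expect_lte(ibs, 1)
  }
  expect_error(integrated_brier_score(half, tt, ee, G, grid = 1), "grid")
})

test_that("the KM baseline IBS equals the time-averaged Brier of its own curve", {
  ds <- random_ds(8, n = 40, p = 1)
  G <- kaplan_meier(ds$time, 1 - ds$event)
  pred <- predict_survival(km_predictor(ds$time, ds$event), ds$features)
  grid <- sort(unique(ds$time[ds$event == 1]))
  grid <- grid[grid <= max(ds$time[eval_step(G, ds$time) > 0])]
  bs <- vapply(grid, function(t) {
    brier_score(pred, ds$time, ds$event, t, G)
  }, 0)
  manual <- survfilter:::trapezoid(grid, bs) / diff(range(grid))
  expect_equal(integrated_brier_score(pred, ds$time, ds$event, G), manual)
})
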