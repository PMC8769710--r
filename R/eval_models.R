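# Predictive models and metrics: ridge-penalized Cox regression with
# cross-validated penalty selection, the Kaplan-Meier baseline predictor,
# Harrell's C, and the IPCW Brier / integrated Brier score.

# Event-stratified fold indices used internally for penalty selection; falls
# back to a plain shuffled split when one outcome stratum is empty (e.g. a
# fully uncensored training set).
event_balanced_folds <- function(time, event, k, seed) {
  n <- length(time)
  assignment <- integer(n)
  withr::with_seed(seed, {
    for (idx in list(which(event == 1), which(event == 0))) {
      if (length(idx) == 0) next
      shuffled <- idx[sample.int(length(idx))]
      assignment[shuffled] <- rep_len(seq_len(k), length(shuffled))
    }
  })
  split(seq_len(n), factor(assignment, levels = seq_len(k)))
}

# Breslow-ties Cox partial log-likelihood machinery. Everything works on a
# precomputed ordering by descending time so risk-set sums are cumulative
# sums; tied times share a risk set.
cox_order <- function(time, event) {
  ord <- order(time, decreasing = TRUE)
  time_o <- time[ord]
  grp <- match(time_o, unique(time_o))
  last_pos <- cumsum(tabulate(grp))
  list(ord = ord, risk_pos = last_pos[grp], event_o = event[ord])
}

# partial log-likelihood at linear predictor eta (Breslow ties)
cox_partial_loglik <- function(eta, time, event, co = cox_order(time, event)) {
  eta_o <- eta[co$ord]
  cs <- cumsum(exp(eta_o))
  s0 <- cs[co$risk_pos]
  ev <- co$event_o == 1
  sum(eta_o[ev]) - sum(log(s0[ev]))
}

# gradient and Hessian of the partial log-likelihood at beta, plus the
# Breslow cumulative-hazard increments; X already column-centered.
cox_derivatives <- function(X, beta, co, want_hessian = TRUE) {
  eta_o <- as.vector(X %*% beta)[co$ord]
  Xo <- X[co$ord, , drop = FALSE]
  w <- exp(eta_o)
  cs0 <- cumsum(w)
  cs1 <- apply(Xo * w, 2, cumsum)
  ev <- which(co$event_o == 1)
  pos <- co$risk_pos[ev]
  s0 <- cs0[pos]
  s1 <- cs1[pos, , drop = FALSE]
  mu <- s1 / s0
  grad <- colSums(Xo[ev, , drop = FALSE]) - colSums(mu)
  loglik <- sum(eta_o[ev]) - sum(log(s0))
  H <- NULL
  if (want_hessian) {
    # sum_j d_j S2_j / S0_j = X' diag(w_i * H0(T_i)) X with H0 the Breslow
    # cumulative hazard at each observation's own time; the outer-product
    # part is the crossproduct of the per-event risk-set mean rows. H0 must
    # be accumulated per unique time so tied events share their increment.
    grp <- match(co$risk_pos, unique(co$risk_pos))  # unique-time group id
    inc <- numeric(max(grp))
    ev_grp <- grp[ev]
    for (j in seq_along(ev)) inc[ev_grp[j]] <- inc[ev_grp[j]] + 1 / s0[j]
    h0_by_group <- rev(cumsum(rev(inc)))  # groups ordered by descending time
    h0_obs <- h0_by_group[grp]
    H <- crossprod(Xo * sqrt(w * h0_obs)) - crossprod(mu)
  }
  list(grad = grad, hessian = H, loglik = loglik)
}

#' Fit an L2-penalized (ridge) Cox proportional hazards model
#'
#' Maximizes `partial log-likelihood - lambda * ||beta||^2 / 2` by Newton
#' iterations with step halving (Breslow handling of tied event times).
#' Features are centered internally for numerical stability; the Breslow
#' baseline cumulative hazard is computed at the solution on the centered
#' scale, so [predict_survival()] applies the same centering.
#'
#' @param X Numeric feature matrix with column names.
#' @param time,event Observed times and 0/1 event indicators.
#' @param lambda Nonnegative ridge penalty.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the max absolute penalized gradient.
#' @param beta_init Optional warm-start coefficients.
#' @return An object of class `ridge_cox_model` with coefficients, `lambda`,
#'   the baseline cumulative hazard (a [step_function()]), the training
#'   feature names and centers.
#' @export
fit_ridge_cox <- function(X, time, event, lambda, max_iter = 100,
                          tol = 1e-8, beta_init = NULL) {
  X <- as.matrix(X)
  if (lambda < 0) fail_validation("lambda must be nonnegative")
  if (sum(event) < 1) fail_validation("no events in the training data")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  co <- cox_order(time, event)
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)

  pen_loglik <- function(b, ll) ll - lambda * sum(b^2) / 2
  d <- cox_derivatives(Xc, beta, co)
  obj <- pen_loglik(beta, d$loglik)
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    g <- d$grad - lambda * beta
    grad_norm <- max(abs(g))
    if (grad_norm < tol) break
    Hp <- d$hessian + diag(lambda, p)
    step <- tryCatch(solve(Hp, g),
                     error = function(e) g / max(diag(Hp), 1e-8))
    new_beta <- beta
    improved <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      dc <- cox_derivatives(Xc, cand, co)
      if (is.finite(dc$loglik) &&
          pen_loglik(cand, dc$loglik) >= obj - 1e-12) {
        new_beta <- cand
        d <- dc
        obj <- pen_loglik(cand, dc$loglik)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
    beta <- new_beta
  }
  g <- d$grad - lambda * beta
  grad_norm <- max(abs(g))
  if (grad_norm >= max(tol, 1e-6)) {
    fail_validation(
      "ridge Cox did not converge (max |penalized gradient| = %.3g)",
      grad_norm)
  }

  # Breslow baseline at the solution (centered scale)
  eta_o <- as.vector(Xc %*% beta)[co$ord]
  cs0 <- cumsum(exp(eta_o))
  ev <- which(co$event_o == 1)
  s0 <- cs0[co$risk_pos[ev]]
  t_ev <- time[co$ord][ev]
  tab <- rowsum(1 / s0, t_ev)          # d_j / S0_j per unique event time
  knots <- as.numeric(rownames(tab))
  ord_k <- order(knots)
  baseline <- step_function(knots[ord_k], cumsum(tab[ord_k]),
                            value_before = 0)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 lambda = lambda, baseline_cumhaz = baseline,
                 feature_names = colnames(X), centers = centers,
                 loglik = d$loglik, grad_norm = grad_norm),
            class = "ridge_cox_model")
}

#' Select the ridge penalty by cross-validated partial likelihood
#'
#' Builds a grid of `path_length` penalties log-spaced from `lambda_max`
#' (large enough that the fitted coefficients are essentially zero, derived
#' from the score vector at `beta = 0`) down by a factor of
#' `lambda_min_ratio`, and returns the penalty minimizing the mean held-out
#' partial-likelihood deviance over event-stratified folds. Fits along the
#' path are warm-started from the previous penalty.
#'
#' @param X,time,event Training data as in [fit_ridge_cox()].
#' @param n_folds Number of cross-validation folds; reduced with a warning
#'   when there are fewer events than folds.
#' @param seed Integer seed for the fold split.
#' @param path_length Number of grid points.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @return The selected penalty, with the grid and mean deviances attached
#'   as attributes `"grid"` and `"cv_deviance"`.
#' @export
select_lambda_cv <- function(X, time, event, n_folds = 10, seed = 1,
                             path_length = 100, lambda_min_ratio = 1e-4) {
  if (!is_count(n_folds) || n_folds < 2) {
    fail_validation("n_folds must be an integer >= 2")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  n_events <- sum(event)
  if (n_events < n_folds) {
    warning(sprintf("only %d events; reducing folds from %d to %d",
                    n_events, n_folds, max(n_events, 2)))
    n_folds <- max(n_events, 2)
  }
  Xc <- sweep(X, 2, colMeans(X))
  co <- cox_order(time, event)
  g0 <- cox_derivatives(Xc, numeric(ncol(X)), co, want_hessian = FALSE)$grad
  g_max <- max(abs(g0))
  if (g_max <= 0) g_max <- 1
  lambda_max <- 100 * g_max
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = path_length))

  folds <- event_balanced_folds(time, event, n_folds, seed)
  dev <- matrix(NA_real_, n_folds, path_length)
  for (f in seq_len(n_folds)) {
    test_idx <- folds[[f]]
    Xtr <- X[-test_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    t_te <- time[test_idx]
    e_te <- event[test_idx]
    co_te <- cox_order(t_te, e_te)
    beta_warm <- NULL
    for (g in seq_along(grid)) {
      fit <- tryCatch(
        fit_ridge_cox(Xtr, time[-test_idx], event[-test_idx], grid[g],
                      beta_init = beta_warm),
        error = function(e) NULL)
      if (is.null(fit)) next
      beta_warm <- fit$coefficients
      eta_te <- as.vector(Xte %*% fit$coefficients)
      dev[f, g] <- -2 * cox_partial_loglik(eta_te, t_te, e_te, co_te)
    }
  }
  mean_dev <- colMeans(dev)
  if (all(!is.finite(mean_dev))) {
    fail_validation("every penalty failed during cross-validation")
  }
  best <- which.min(mean_dev)  # ties -> first, i.e. the largest penalty
  structure(grid[best], grid = grid, cv_deviance = mean_dev)
}

#' Survival-function predictions
#'
#' Per-observation predicted survival curves on a shared knot grid; a valid
#' survival function for every row (starts at 1, nonincreasing).
#'
#' @param knots Ordered event times.
#' @param surv `n x length(knots)` matrix of survival probabilities.
#' @return An object of class `survival_prediction`.
#' @export
survival_prediction <- function(knots, surv) {
  surv <- as.matrix(surv)
  if (length(knots) != ncol(surv)) {
    fail_validation("one survival column per knot required")
  }
  structure(list(knots = as.numeric(knots), surv = surv),
            class = "survival_prediction")
}

# evaluate predicted survival at time t (vectorized over observations)
eval_prediction <- function(pred, t) {
  idx <- findInterval(t, pred$knots)
  if (idx == 0) rep(1, nrow(pred$surv)) else pred$surv[, idx]
}

#' Predict survival functions from a fitted model
#'
#' @param model A `ridge_cox_model` or `km_model`.
#' @param newdata Feature matrix for prediction (ignored by the
#'   Kaplan-Meier predictor except for its row count).
#' @return A [survival_prediction()].
#' @export
predict_survival <- function(model, newdata) {
  UseMethod("predict_survival")
}

#' @export
predict_survival.ridge_cox_model <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), model$feature_names)) {
    fail_validation("newdata feature names do not match the training features")
  }
  eta <- as.vector(sweep(newdata, 2, model$centers) %*% model$coefficients)
  H0 <- model$baseline_cumhaz
  surv <- exp(-outer(exp(eta), eval_step(H0, H0$knots)))
  survival_prediction(H0$knots, surv)
}

#' Kaplan-Meier baseline predictor
#'
#' Ignores all features: every observation is predicted with the training
#' Kaplan-Meier survival curve.
#'
#' @param time,event Training outcome.
#' @return An object of class `km_model`.
#' @export
km_predictor <- function(time, event) {
  structure(list(curve = kaplan_meier(time, event)), class = "km_model")
}

#' @export
predict_survival.km_model <- function(model, newdata) {
  n <- if (is.matrix(newdata) || is.data.frame(newdata)) nrow(newdata)
       else length(newdata)
  km <- model$curve
  if (length(km$knots) == 0) {
    # no events in training: S is identically 1; use a single dummy knot
    return(survival_prediction(1, matrix(1, n, 1)))
  }
  surv <- matrix(rep(eval_step(km, km$knots), each = n), nrow = n)
  survival_prediction(km$knots, surv)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (`t_i < t_j` with the earlier observation an
#' event) whose risk ordering agrees with the survival ordering; risk ties
#' count 1/2.
#'
#' @param time,event Outcome.
#' @param risk Numeric risk scores (higher risk should mean shorter
#'   survival).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(time, event, risk) {
  n <- length(time)
  concordant <- 0
  comparable <- 0
  for (i in which(event == 1)) {
    later <- time > time[i]
    comparable <- comparable + sum(later)
    concordant <- concordant + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (comparable == 0) fail_validation("no comparable pairs")
  concordant / comparable
}

#' IPCW Brier score at a single time point
#'
#' `BS(t) = mean over i of [ S(t|x_i)^2 * 1(t_i <= t, event) / G(t_i-) +
#' (1 - S(t|x_i))^2 * 1(t_i > t) / G(t) ]`, with `G` the Kaplan-Meier
#' estimate of the censoring survival function (from training data).
#'
#' @param prediction A [survival_prediction()] for the evaluation set.
#' @param time,event Evaluation-set outcome.
#' @param t Evaluation time.
#' @param G_hat Censoring survival function, a [step_function()].
#' @return The Brier score at `t`.
#' @export
brier_score <- function(prediction, time, event, t, G_hat) {
  s_t <- eval_prediction(prediction, t)
  before <- time <= t & event == 1
  after <- time > t
  g_at_t <- eval_step(G_hat, t)
  g_left <- eval_step(G_hat, time, left_limit = TRUE)
  if (any(after) && g_at_t <= 0) {
    fail_validation("censoring survival G(t) is zero at t = %g", t)
  }
  if (any(before & g_left <= 0)) {
    fail_validation("censoring survival G(t-) is zero for an event term")
  }
  terms <- numeric(length(time))
  terms[before] <- s_t[before]^2 / g_left[before]
  terms[after] <- (1 - s_t[after])^2 / g_at_t
  mean(terms)
}

#' Integrated Brier score
#'
#' Time-average of the IPCW Brier score over an evaluation grid: the
#' trapezoidal integral divided by the grid span, which keeps the value in
#' `[0, 1]`. The default grid is the unique event times of the evaluation
#' set, truncated at the largest evaluation time where `G` is still
#' positive.
#'
#' @inheritParams brier_score
#' @param grid Optional evaluation grid (at least two points).
#' @return The integrated Brier score in `[0, 1]`.
#' @export
integrated_brier_score <- function(prediction, time, event, G_hat,
                                   grid = NULL) {
  if (is.null(grid)) {
    tau_candidates <- time[eval_step(G_hat, time) > 0]
    if (length(tau_candidates) == 0) {
      fail_validation("censoring survival vanishes before every test time")
    }
    tau <- max(tau_candidates)
    grid <- sort(unique(time[event == 1]))
    grid <- grid[grid <= tau]
  }
  if (length(grid) < 2 || diff(range(grid)) == 0) {
    fail_validation("degenerate integration grid")
  }
  bs <- vapply(grid, function(t) {
    brier_score(prediction, time, event, t, G_hat)
  }, 0)
  trapezoid(grid, bs) / diff(range(grid))
}
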