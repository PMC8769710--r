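# Univariate filter scores: variance, correlation on martingale residuals,
# Cox score test, and correlation-adjusted regression survival scores (CARSS).

#' Variance filter
#'
#' Scores each feature by its sample variance (denominator `n - 1`). The
#' outcome is ignored entirely; the rationale is that on a common, unscaled
#' measurement scale, features with very little variation carry mostly noise.
#'
#' @param dataset A [survival_dataset()] with `n >= 2`.
#' @return A [filter_scores()] object.
#' @export
variance_filter <- function(dataset) {
  n <- n_obs(dataset)
  if (n < 2) fail_validation("variance filter needs n >= 2")
  x <- dataset$features
  m <- colMeans(x)
  v <- (colSums(x^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # numerical guard for constant columns
  filter_scores("variance", stats::setNames(v, dataset$feature_names))
}

#' Correlation filter on martingale residuals
#'
#' Transforms the censored outcome into the continuous surrogate
#' `Y^(m) =` [martingale_residuals()] and scores each feature by its absolute
#' Pearson correlation with `Y^(m)`. Constant features receive score 0.
#'
#' @param dataset A [survival_dataset()] with `n >= 3`.
#' @return A [filter_scores()] object.
#' @export
correlation_filter <- function(dataset) {
  if (n_obs(dataset) < 3) fail_validation("correlation filter needs n >= 3")
  y <- martingale_residuals(dataset)
  if (stats::sd(y) == 0) {
    fail_validation("martingale residuals are degenerate (all equal)")
  }
  r <- suppressWarnings(as.vector(stats::cor(dataset$features, y)))
  r[!is.finite(r)] <- 0
  filter_scores("correlation",
                stats::setNames(abs(r), dataset$feature_names))
}

# Risk-set moments used by the Cox score test: for each feature, the score
# U_k(0) = sum over events of (x_ik - mean of x_k over the risk set) and the
# information I_k(0) = sum over events of the population variance of x_k over
# the risk set. Risk sets use all observations with time >= t (Breslow-style
# handling of tied event times).
cox_score_components <- function(x, time, event) {
  ord <- order(time, decreasing = TRUE)
  x <- x[ord, , drop = FALSE]
  time <- time[ord]
  event <- event[ord]
  grp <- match(time, unique(time))
  last_pos <- cumsum(tabulate(grp))
  ri <- last_pos[grp]                       # risk-set size for each obs
  cs1 <- apply(x, 2, cumsum)
  cs2 <- apply(x^2, 2, cumsum)
  ev <- which(event == 1)
  r <- ri[ev]
  mu <- cs1[r, , drop = FALSE] / r
  U <- colSums(x[ev, , drop = FALSE]) - colSums(mu)
  V <- cs2[r, , drop = FALSE] / r - mu^2
  list(U = U, I = colSums(pmax(V, 0)))
}

#' Cox score-test filter
#'
#' For each feature, the score-test statistic of the univariate Cox
#' proportional hazards model containing only that feature, evaluated at
#' `beta = 0`: `U_k(0)^2 / I_k(0)`. Larger statistics indicate stronger
#' univariate association with the survival outcome. Constant features (zero
#' information) receive score 0.
#'
#' @param dataset A [survival_dataset()] with at least one event.
#' @return A [filter_scores()] object.
#' @export
cox_score_filter <- function(dataset) {
  if (sum(dataset$event) < 1) {
    fail_validation("cox.score filter needs at least one event")
  }
  comp <- cox_score_components(dataset$features, dataset$time, dataset$event)
  scale <- colMeans(dataset$features^2) + 1
  stat <- ifelse(comp$I > 1e-12 * scale, comp$U^2 / comp$I, 0)
  filter_scores("cox.score",
                stats::setNames(stat, dataset$feature_names))
}

# Inverse-probability-of-censoring weights on the log-time scale:
# G = Kaplan-Meier of the censoring process of log(T); raw weight
# w_i = Delta_i / G(log(t_i)-) (left limit), truncated at max_weight to tame
# the variance explosion from late events (the stabilization used by the
# reference CARSS implementation), then normalized to sum to 1. Censored
# observations get weight 0.
ipc_weights_logtime <- function(time, event, max_weight = 10) {
  logt <- log(time)
  G <- kaplan_meier(logt, 1 - event)
  g_left <- eval_step(G, logt, left_limit = TRUE)
  if (any(event == 1 & g_left <= 0)) {
    fail_validation("censoring survival estimate vanishes at an event time")
  }
  w <- ifelse(event == 1, pmin(1 / g_left, max_weight), 0)
  w / sum(w)
}

# Analytic shrinkage intensity for shrinking the feature correlation matrix
# toward the identity (Ledoit-Wolf / Schaefer-Strimmer family):
# lambda = sum of estimated variances of the off-diagonal correlations
# divided by the sum of their squares, clamped to [0, 1]. Computed entirely
# in the n-dimensional sample space so no p x p matrix is formed.
shrinkage_intensity <- function(z) {
  n <- nrow(z)
  p <- ncol(z)
  if (p < 2 || n < 3) return(1)
  gram <- tcrossprod(z)                       # n x n
  sum_r2_all <- sum(gram^2) / (n - 1)^2
  sum_r2_off <- sum_r2_all - p                # diag of R is exactly 1
  if (sum_r2_off <= 1e-12) return(1)
  rs2 <- rowSums(z^2)
  sum_w2_off <- sum(rs2^2) - sum(z^4)         # sum over k != l of w_ikl^2
  sum_wbar2_off <- ((n - 1) / n)^2 * sum_r2_off
  var_sum <- n / (n - 1)^3 * (sum_w2_off - n * sum_wbar2_off)
  min(max(var_sum / sum_r2_off, 0), 1)
}

#' Correlation-adjusted regression survival scores (CARSS) filter
#'
#' Computes, for every feature, the IPC-weighted marginal correlation with
#' the logarithmic observed time, then decorrelates the vector of marginal
#' correlations with the inverse square root of the shrunken feature
#' correlation matrix `R_shrink = lambda I + (1 - lambda) R`:
#' `score = | R_shrink^(-1/2) R_{X, log T} |`.
#'
#' Weights come from the Kaplan-Meier estimate of the censoring distribution
#' on the log-time scale (censored observations get weight 0). The shrinkage
#' intensity `lambda` is estimated analytically from the data unless
#' supplied. The inverse square root is applied through an eigendecomposition
#' in the n-dimensional sample space, so memory stays `O(np + n^2)` even for
#' `p >> n`.
#'
#' @param dataset A [survival_dataset()] with `n >= 3` and at least two
#'   events.
#' @param lambda Optional shrinkage intensity in `[0, 1]`; `NULL` (default)
#'   estimates it from the data. `lambda = 1` reduces the scores to the
#'   absolute marginal correlations.
#' @param max_ipc_weight Truncation bound for the raw IPC weights
#'   (default 10, the stabilization used by reference implementations of
#'   correlation-adjusted survival scores); untruncated weights at late
#'   event times otherwise dominate the weighted moments.
#' @return A [filter_scores()] object. The IPC weights, marginal
#'   correlations and shrinkage intensity are attached as attribute
#'   `"intermediate"`.
#' @export
carss_filter <- function(dataset, lambda = NULL, max_ipc_weight = 10) {
  n <- n_obs(dataset)
  p <- n_features(dataset)
  if (n < 3) fail_validation("carss filter needs n >= 3")
  if (sum(dataset$event) < 2) {
    fail_validation("carss filter needs at least two events")
  }
  x <- dataset$features
  y <- log(dataset$time)
  w <- ipc_weights_logtime(dataset$time, dataset$event, max_ipc_weight)

  # weighted marginal correlations per the printed definition: weighted
  # covariance and weighted target variance, unweighted (population) feature
  # variance, so that with equal weights the score is the Pearson correlation
  my_w <- sum(w * y)
  s2y_w <- sum(w * (y - my_w)^2)
  mx_w <- as.vector(crossprod(x, w))                    # weighted col means
  cov_w <- as.vector(crossprod(x, w * (y - my_w))) - mx_w * sum(w * (y - my_w))
  mx <- colMeans(x)
  s2x <- colMeans(x^2) - mx^2
  denom <- sqrt(s2x * s2y_w)
  r_xy <- ifelse(denom > 0, cov_w / denom, 0)
  r_xy <- pmin(pmax(r_xy, -1), 1)

  # standardized feature matrix restricted to non-constant columns
  active <- which(s2x > 0)
  z <- sweep(x[, active, drop = FALSE], 2, mx[active])
  z <- sweep(z, 2, sqrt(colSums(z^2) / (n - 1)), "/")
  if (is.null(lambda)) {
    lambda <- shrinkage_intensity(z)
  }
  if (lambda < 0 || lambda > 1) {
    fail_validation("lambda must lie in [0, 1]")
  }
  lam <- max(lambda, 1e-8)  # keep R_shrink invertible when R is singular

  scores <- numeric(p)
  r_act <- r_xy[active]
  if (lam >= 1) {
    scores[active] <- abs(r_act)
  } else {
    zs <- z / sqrt(n - 1)                    # R = t(zs) %*% zs
    eg <- eigen(tcrossprod(zs), symmetric = TRUE)
    keep <- eg$values > 1e-12
    d2 <- eg$values[keep]
    v <- crossprod(zs, eg$vectors[, keep, drop = FALSE]) %*%
      diag(1 / sqrt(d2), nrow = length(d2))  # p_active x m, orthonormal
    coef <- 1 / sqrt(lam + (1 - lam) * d2) - 1 / sqrt(lam)
    s <- r_act / sqrt(lam) +
      as.vector(v %*% (coef * as.vector(crossprod(v, r_act))))
    scores[active] <- abs(s)
  }
  out <- filter_scores("carss",
                       stats::setNames(scores, dataset$feature_names))
  attr(out, "intermediate") <- list(ipc_weights = w,
                                    marginal_correlations = r_xy,
                                    shrinkage_intensity = lambda)
  out
}
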