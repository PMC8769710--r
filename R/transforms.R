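# Survival-target transformations: Nelson-Aalen / martingale residuals,
# Kaplan-Meier, and the equal-width categorization used by the
# mutual-information filters.

# d_j, r_j tabulation shared by the Nelson-Aalen and Kaplan-Meier estimators:
# unique event times t_j, number of events d_j at t_j, and at-risk counts
# r_j = #{i : time_i >= t_j}.
risk_table <- function(time, event) {
  if (length(time) == 0) {
    fail_validation("empty survival input")
  }
  ev_times <- sort(unique(time[event == 1]))
  d <- vapply(ev_times, function(t) sum(time == t & event == 1), 0)
  r <- vapply(ev_times, function(t) sum(time >= t), 0)
  list(times = ev_times, d = d, r = r)
}

#' Nelson-Aalen estimator of the cumulative hazard
#'
#' The baseline cumulative hazard of a Cox model fitted without covariates:
#' `H(t) = sum over event times t_j <= t of d_j / r_j`, with `d_j` events and
#' `r_j` subjects at risk at `t_j` (Breslow-type increments at tied event
#' times). `H` is zero before the first event time.
#'
#' @param time Positive observed times.
#' @param event 0/1 event indicators.
#' @return A nondecreasing [step_function()].
#' @export
nelson_aalen_cumhaz <- function(time, event) {
  rt <- risk_table(time, event)
  step_function(rt$times, cumsum(rt$d / rt$r), value_before = 0)
}

#' Kaplan-Meier estimator of the survival function
#'
#' Product-limit estimator `S(t) = prod over t_j <= t of (1 - d_j / r_j)`;
#' equal to 1 before the first event time. The censoring survival function
#' `G` is obtained by calling this with the flipped indicator `1 - event`.
#'
#' @inheritParams nelson_aalen_cumhaz
#' @return A nonincreasing [step_function()] starting at 1.
#' @export
kaplan_meier <- function(time, event) {
  rt <- risk_table(time, event)
  step_function(rt$times, cumprod(1 - rt$d / rt$r), value_before = 1)
}

#' Martingale residuals of the null Cox model
#'
#' `M_i = Delta_i - H(T_i)` with `H` the Nelson-Aalen cumulative hazard of
#' the dataset's outcome. Martingale residuals are real-valued (at most 1)
#' and serve as an uncensored continuous surrogate outcome for filters that
#' cannot handle censoring directly. They sum to zero.
#'
#' @param dataset A [survival_dataset()].
#' @return Numeric vector of length `n`.
#' @export
martingale_residuals <- function(dataset) {
  H <- nelson_aalen_cumhaz(dataset$time, dataset$event)
  dataset$event - eval_step(H, dataset$time)
}

#' Number of categorization bins as a function of sample size
#'
#' `q = max(min(floor(n / 3), 10), 2)`: roughly `n / 3` bins, capped at 10
#' and never fewer than 2.
#'
#' @param n Number of observations (`>= 1`).
#' @return Integer bin count `q`.
#' @export
n_bins <- function(n) {
  if (!is_count(n) || n < 1) {
    fail_validation("n must be a positive integer")
  }
  max(min(n %/% 3, 10L), 2L)
}

#' Categorize a continuous variable into equal-width bins
#'
#' Cuts the observed range into `q` equally spaced intervals and uses the
#' intervals as categories. Intervals are right-closed, except that the first
#' also includes the minimum, so the minimum always receives code 1 and the
#' maximum code `q`.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param q Number of bins (`>= 2`).
#' @return An object of class `categorized_variable` with integer `codes`
#'   in `1..q`, the bin count `q` and the `q + 1` bin edges.
#' @export
categorize_equal_width <- function(values, q) {
  if (!is_count(q) || q < 2) {
    fail_validation("q must be an integer >= 2")
  }
  rng <- range(values)
  if (!all(is.finite(rng)) || diff(rng) == 0) {
    fail_validation("cannot categorize a constant (or non-finite) variable")
  }
  edges <- seq(rng[1], rng[2], length.out = q + 1)
  codes <- pmax(findInterval(values, edges, left.open = TRUE), 1L)
  codes <- pmin(codes, q)  # guard against floating-point spill at the max
  structure(list(codes = as.integer(codes), q = as.integer(q),
                 bin_edges = edges),
            class = "categorized_variable")
}

#' Categorize a survival dataset for the mutual-information filters
#'
#' Builds the categorical target `Y^(c)` by categorizing the martingale
#' residuals of the outcome, and categorizes every feature with the same
#' number of equal-width bins `q = n_bins(n)`. Constant features cannot be
#' binned by range and are assigned a single category (code 1 throughout),
#' which gives them zero mutual information with everything.
#'
#' @param dataset A [survival_dataset()].
#' @param q Bin count; defaults to `n_bins(n_obs(dataset))`.
#' @return An object of class `categorized_dataset` with integer target
#'   codes `y`, an integer code matrix `x` (one column per feature), `q`
#'   and the feature names.
#' @export
categorize_dataset <- function(dataset, q = NULL) {
  n <- n_obs(dataset)
  if (is.null(q)) q <- n_bins(n)
  y_m <- martingale_residuals(dataset)
  y <- categorize_equal_width(y_m, q)$codes
  x <- matrix(1L, n, n_features(dataset),
              dimnames = list(NULL, dataset$feature_names))
  for (k in seq_len(n_features(dataset))) {
    col <- dataset$features[, k]
    if (diff(range(col)) > 0) {
      x[, k] <- categorize_equal_width(col, q)$codes
    }
  }
  structure(list(y = y, x = x, q = as.integer(q),
                 feature_names = dataset$feature_names),
            class = "categorized_dataset")
}

#' Event-stratified cross-validation folds
#'
#' Splits observations into `k` folds, stratified on the event indicator so
#' that events and censored observations are distributed as evenly as
#' possible (per-fold counts within each stratum differ by at most 1).
#' Each stratum is shuffled with a seeded RNG and dealt round-robin.
#'
#' @param dataset A [survival_dataset()].
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return An object of class `fold_assignment` with elements `k` and
#'   `test_indices` (a list of `k` disjoint index vectors covering all
#'   observations).
#' @export
stratified_folds <- function(dataset, k, seed) {
  if (!is_count(k) || k < 2) {
    fail_validation("k must be an integer >= 2")
  }
  event <- dataset$event
  n <- length(event)
  strata <- list(which(event == 1), which(event == 0))
  if (any(lengths(strata) == 0)) {
    fail_validation("both strata (event = 0 and event = 1) must be nonempty")
  }
  if (any(lengths(strata) < k)) {
    warning("k exceeds the size of a stratum; some folds will lack that stratum")
  }
  assignment <- integer(n)
  withr::with_seed(seed, {
    for (idx in strata) {
      shuffled <- idx[sample.int(length(idx))]
      assignment[shuffled] <- rep_len(seq_len(k), length(shuffled))
    }
  })
  structure(list(k = as.integer(k),
                 test_indices = split(seq_len(n), factor(assignment,
                                                         levels = seq_len(k)))),
            class = "fold_assignment")
}
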