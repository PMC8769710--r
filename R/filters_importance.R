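# Multivariate importance filters: random survival forest permutation and
# impurity importance, and Cox gradient-boosting importance. These are
# self-contained analogues of the classic ensemble implementations: survival
# trees split by exhaustive-midpoint search on the two-sample log-rank
# statistic, and boosting is first-order gradient boosting with
# least-squares regression trees on martingale-type gradients.

#' Two-sample log-rank test statistic
#'
#' Standard chi-square log-rank statistic `(O - E)^2 / V` accumulated over
#' the pooled event times of two groups. Symmetric in the group labels;
#' zero when both groups have identical survival experience.
#'
#' @param time,event Pooled outcome.
#' @param group Two-level grouping (logical or any two-valued vector).
#' @return Nonnegative test statistic.
#' @export
log_rank_statistic <- function(time, event, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2) {
    fail_validation("log-rank test requires exactly two nonempty groups")
  }
  if (sum(event) < 1) fail_validation("log-rank test requires >= 1 event")
  in1 <- g == 1
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at_risk <- time >= t
    r <- sum(at_risk)
    r1 <- sum(at_risk & in1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in1)
    O <- O + d1
    E <- E + d * r1 / r
    if (r > 1) {
      V <- V + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
    }
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# Exhaustive search for the best log-rank split of one feature within a
# node. All candidate thresholds (midpoints of consecutive distinct values)
# are scored at once with cumulative-count matrices over the node's event
# times; memory is O(n * #event times) per feature.
best_split_logrank <- function(time, event, x, min_node_size) {
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0) return(NULL)
  d <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  r <- vapply(ut, function(t) sum(time >= t), 0)

  ord <- order(x)
  xo <- x[ord]
  to <- time[ord]
  eo <- event[ord]
  at_risk <- outer(to, ut, ">=")                       # n x J
  is_event <- outer(to, ut, "==") * (eo == 1)
  R1 <- apply(at_risk, 2, cumsum)                      # left at-risk counts
  D1 <- apply(is_event, 2, cumsum)                     # left event counts
  if (length(ut) == 1) {
    R1 <- matrix(R1, ncol = 1)
    D1 <- matrix(D1, ncol = 1)
  }

  m <- seq_len(n - 1)
  valid <- xo[m] < xo[m + 1] & m >= min_node_size & (n - m) >= min_node_size
  if (!any(valid)) return(NULL)
  P <- sweep(R1[m, , drop = FALSE], 2, r, "/")
  vfac <- ifelse(r > 1, d * (r - d) / (r - 1), 0)
  O <- rowSums(D1[m, , drop = FALSE])
  E <- as.vector(R1[m, , drop = FALSE] %*% (d / r))
  V <- as.vector((P * (1 - P)) %*% vfac)
  stat <- ifelse(V > 1e-12, (O - E)^2 / V, 0)
  stat[!valid] <- -Inf
  best <- which.max(stat)
  if (!is.finite(stat[best]) || stat[best] <= 0) return(NULL)
  list(threshold = (xo[best] + xo[best + 1]) / 2, statistic = stat[best])
}

#' Fit a single survival tree
#'
#' Greedy recursive partitioning: at each node, `mtry` features are sampled
#' without replacement and the (feature, midpoint threshold) pair with the
#' maximal two-sample log-rank statistic is chosen. Recursion stops when a
#' node has fewer than `2 * min_node_size` observations or no admissible
#' split with a positive statistic exists. Each leaf stores the Nelson-Aalen
#' cumulative hazard of its members.
#'
#' @param dataset A [survival_dataset()].
#' @param mtry Number of candidate features per node (`<= p`).
#' @param min_node_size Minimal observations per child node.
#' @param seed Integer seed for the feature draws.
#' @return An object of class `survival_tree` (nested node list). Leaves
#'   carry `members` (training row indices), a `cumhaz` step function and a
#'   precomputed `risk` value (the cumulative hazard summed over the
#'   dataset's unique event times).
#' @export
fit_survival_tree <- function(dataset, mtry = NULL, min_node_size = 3,
                              seed = 1) {
  p <- n_features(dataset)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(p)))
  if (mtry > p) fail_validation("mtry must not exceed p")
  grid <- sort(unique(dataset$time[dataset$event == 1]))
  withr::with_seed(seed, {
    root <- grow_node(dataset, seq_len(n_obs(dataset)), mtry,
                      min_node_size, grid)
  })
  structure(list(root = root, feature_names = dataset$feature_names,
                 risk_grid = grid,
                 config = list(mtry = mtry, min_node_size = min_node_size,
                               seed = seed)),
            class = "survival_tree")
}

grow_node <- function(dataset, rows, mtry, min_node_size, grid) {
  time <- dataset$time[rows]
  event <- dataset$event[rows]
  make_leaf <- function() {
    ch <- nelson_aalen_cumhaz(time, event)
    list(is_leaf = TRUE, members = rows,
         cumhaz = ch,
         risk = if (length(grid)) sum(eval_step(ch, grid)) else 0)
  }
  if (length(rows) < 2 * min_node_size || sum(event) == 0) {
    return(make_leaf())
  }
  candidates <- sort(sample.int(ncol(dataset$features), mtry))
  best <- NULL
  for (k in candidates) {
    sp <- best_split_logrank(time, event, dataset$features[rows, k],
                             min_node_size)
    if (!is.null(sp) &&
        (is.null(best) || sp$statistic > best$statistic)) {
      best <- c(sp, feature = k)
    }
  }
  if (is.null(best)) return(make_leaf())
  go_left <- dataset$features[rows, best$feature] <= best$threshold
  list(is_leaf = FALSE,
       split_feature = best$feature,
       split_value = best$threshold,
       log_rank_statistic = best$statistic,
       left = grow_node(dataset, rows[go_left], mtry, min_node_size, grid),
       right = grow_node(dataset, rows[!go_left], mtry, min_node_size, grid))
}

# mortality-style risk prediction: leaf cumulative hazard summed over the
# training event-time grid
predict_tree_risk <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- tree$root
    while (!node$is_leaf) {
      node <- if (X[i, node$split_feature] <= node$split_value) node$left
              else node$right
    }
    node$risk
  }, 0)
}

tree_split_stats <- function(node) {
  if (node$is_leaf) return(NULL)
  rbind(c(node$split_feature, node$log_rank_statistic),
        tree_split_stats(node$left),
        tree_split_stats(node$right))
}

#' Fit a random survival forest
#'
#' Bagging ensemble of survival trees: each tree is grown on a bootstrap
#' sample (`n` draws with replacement); rows absent from a tree's bootstrap
#' sample form its out-of-bag (oob) set. Defaults mirror the common survival
#' forest settings: 500 trees, `mtry = floor(sqrt(p))`, minimal node size 3.
#'
#' @param dataset A [survival_dataset()].
#' @param num_trees Number of trees.
#' @param mtry Candidate features per split.
#' @param min_node_size Minimal observations per child node.
#' @param seed Integer master seed; per-tree seeds are derived from it.
#' @return An object of class `random_survival_forest`.
#' @export
fit_random_survival_forest <- function(dataset, num_trees = 500,
                                       mtry = NULL, min_node_size = 3,
                                       seed = 1) {
  n <- n_obs(dataset)
  p <- n_features(dataset)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(p)))
  trees <- vector("list", num_trees)
  for (b in seq_len(num_trees)) {
    boot <- withr::with_seed(derive_seed(seed, "bootstrap", b),
                             sample.int(n, n, replace = TRUE))
    tree <- fit_survival_tree(subset_obs(dataset, boot), mtry,
                              min_node_size,
                              seed = derive_seed(seed, "tree", b))
    trees[[b]] <- list(tree = tree, bootstrap = boot,
                       oob = setdiff(seq_len(n), boot))
  }
  structure(list(trees = trees,
                 config = list(num_trees = num_trees, mtry = mtry,
                               min_node_size = min_node_size, seed = seed),
                 feature_names = dataset$feature_names),
            class = "random_survival_forest")
}

#' Impurity importance of a random survival forest
#'
#' For each feature, the sum of the log-rank split statistics over all
#' splits on that feature, across all trees. Features never chosen get 0.
#'
#' @param forest A [fit_random_survival_forest()] result.
#' @return A [filter_scores()] object (all scores nonnegative).
#' @export
rsf_impurity_importance <- function(forest) {
  p <- length(forest$feature_names)
  imp <- numeric(p)
  for (entry in forest$trees) {
    stats <- tree_split_stats(entry$tree$root)
    if (!is.null(stats)) {
      for (i in seq_len(nrow(stats))) {
        imp[stats[i, 1]] <- imp[stats[i, 1]] + stats[i, 2]
      }
    }
  }
  filter_scores("impurity",
                stats::setNames(imp, forest$feature_names))
}

# does any node of the tree split on feature k?
tree_uses_feature <- function(node, k) {
  if (node$is_leaf) return(FALSE)
  node$split_feature == k || tree_uses_feature(node$left, k) ||
    tree_uses_feature(node$right, k)
}

#' Permutation importance of a random survival forest
#'
#' Per tree, the Harrell concordance of the tree's risk predictions
#' (cumulative hazard summed over event times) on its out-of-bag rows is
#' compared with the concordance after permuting one feature within the oob
#' rows; the importance of the feature is the mean decrease over trees.
#' Trees whose oob set has no comparable pair are skipped. One seeded
#' permutation is drawn per (tree, feature).
#'
#' @param forest A [fit_random_survival_forest()] result.
#' @param dataset The training [survival_dataset()].
#' @param seed Integer seed for the permutations.
#' @return A [filter_scores()] object (possibly negative scores).
#' @export
rsf_permutation_importance <- function(forest, dataset, seed = 1) {
  p <- length(forest$feature_names)
  total <- numeric(p)
  used_trees <- 0
  for (b in seq_along(forest$trees)) {
    entry <- forest$trees[[b]]
    oob <- entry$oob
    if (length(oob) < 2) next
    t_o <- dataset$time[oob]
    e_o <- dataset$event[oob]
    comparable <- any(vapply(which(e_o == 1),
                             function(i) any(t_o > t_o[i]), TRUE))
    if (!comparable) next
    X_oob <- dataset$features[oob, , drop = FALSE]
    risk0 <- predict_tree_risk(entry$tree, X_oob)
    c0 <- harrell_c(t_o, e_o, risk0)
    used_trees <- used_trees + 1
    for (k in seq_len(p)) {
      if (!tree_uses_feature(entry$tree$root, k)) next  # exactly 0 decrease
      perm <- withr::with_seed(derive_seed(seed, "perm", b, k),
                               sample.int(length(oob)))
      X_perm <- X_oob
      X_perm[, k] <- X_perm[perm, k]
      ck <- harrell_c(t_o, e_o, predict_tree_risk(entry$tree, X_perm))
      total[k] <- total[k] + (c0 - ck)
    }
  }
  if (used_trees == 0) {
    fail_validation("no tree had out-of-bag observations with comparable pairs")
  }
  filter_scores("permutation",
                stats::setNames(total / used_trees, forest$feature_names))
}

# --- gradient boosting with Cox loss ---------------------------------------

# best squared-error-reduction split for one feature of a regression tree
best_split_sse <- function(x, g, min_node_size) {
  n <- length(x)
  ord <- order(x)
  xo <- x[ord]
  go <- g[ord]
  cs <- cumsum(go)
  tot <- cs[n]
  m <- seq_len(n - 1)
  valid <- xo[m] < xo[m + 1] & m >= min_node_size & (n - m) >= min_node_size
  if (!any(valid)) return(NULL)
  gain <- cs[m]^2 / m + (tot - cs[m])^2 / (n - m) - tot^2 / n
  gain[!valid] <- -Inf
  best <- which.max(gain)
  if (!is.finite(gain[best]) || gain[best] <= 1e-12) return(NULL)
  list(threshold = (xo[best] + xo[best + 1]) / 2, gain = gain[best])
}

grow_regression_node <- function(X, g, rows, depth, max_depth,
                                 min_node_size) {
  make_leaf <- function() list(is_leaf = TRUE, value = mean(g[rows]))
  if (depth >= max_depth || length(rows) < 2 * min_node_size) {
    return(make_leaf())
  }
  best <- NULL
  for (k in seq_len(ncol(X))) {
    sp <- best_split_sse(X[rows, k], g[rows], min_node_size)
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- c(sp, feature = k)
    }
  }
  if (is.null(best)) return(make_leaf())
  go_left <- X[rows, best$feature] <= best$threshold
  list(is_leaf = FALSE, split_feature = best$feature,
       split_value = best$threshold, gain = best$gain,
       left = grow_regression_node(X, g, rows[go_left], depth + 1,
                                   max_depth, min_node_size),
       right = grow_regression_node(X, g, rows[!go_left], depth + 1,
                                    max_depth, min_node_size))
}

predict_regression_tree <- function(node, X) {
  if (node$is_leaf) return(rep(node$value, nrow(X)))
  out <- numeric(nrow(X))
  go_left <- X[, node$split_feature] <= node$split_value
  if (any(go_left)) {
    out[go_left] <- predict_regression_tree(node$left,
                                            X[go_left, , drop = FALSE])
  }
  if (any(!go_left)) {
    out[!go_left] <- predict_regression_tree(node$right,
                                             X[!go_left, , drop = FALSE])
  }
  out
}

regression_tree_gains <- function(node) {
  if (node$is_leaf) return(NULL)
  rbind(c(node$split_feature, node$gain),
        regression_tree_gains(node$left),
        regression_tree_gains(node$right))
}

#' Gradient boosting with Cox partial-likelihood loss
#'
#' First-order gradient boosting with depth-limited least-squares regression
#' trees as weak learners. At each round the negative gradient of the Cox
#' loss at the current linear scores is the martingale-type residual
#' `g_i = Delta_i - H_Breslow(T_i) * exp(score_i)`; a regression tree is fit
#' to `g` and the scores are updated by `learning_rate` times the tree's
#' prediction. Per-split squared-error gains are recorded for the importance
#' filter.
#'
#' @param dataset A [survival_dataset()] with at least one event.
#' @param n_rounds Number of boosting rounds (default 2000).
#' @param learning_rate Shrinkage step size (default 0.05).
#' @param max_depth Maximum tree depth (default 10).
#' @param min_node_size Minimal observations per child node.
#' @param seed Unused by the deterministic fit; kept for config parity.
#' @return An object of class `cox_boosting_model` with the tree sequence,
#'   final scores and the per-round training partial log-likelihood trace.
#' @export
fit_cox_gradient_boosting <- function(dataset, n_rounds = 2000,
                                      learning_rate = 0.05, max_depth = 10,
                                      min_node_size = 1, seed = 1) {
  if (sum(dataset$event) < 1) fail_validation("boosting needs >= 1 event")
  n <- n_obs(dataset)
  X <- dataset$features
  time <- dataset$time
  event <- dataset$event
  co <- cox_order(time, event)
  eta <- numeric(n)
  trees <- vector("list", n_rounds)
  loglik_trace <- numeric(n_rounds)
  for (m in seq_len(n_rounds)) {
    # martingale-type negative gradient at the current scores
    H <- breslow_cumhaz_at_obs(eta, time, event, co)
    g <- event - H * exp(eta)
    root <- grow_regression_node(X, g, seq_len(n), 0, max_depth,
                                 min_node_size)
    trees[[m]] <- root
    eta <- eta + learning_rate * predict_regression_tree(root, X)
    loglik_trace[m] <- cox_partial_loglik(eta, time, event, co)
  }
  structure(list(trees = trees, scores = eta,
                 loglik_trace = loglik_trace,
                 feature_names = dataset$feature_names,
                 config = list(n_rounds = n_rounds,
                               learning_rate = learning_rate,
                               max_depth = max_depth,
                               min_node_size = min_node_size, seed = seed)),
            class = "cox_boosting_model")
}

# Breslow cumulative hazard evaluated at each observation's own time, given
# linear scores eta (shared risk sets for tied times)
breslow_cumhaz_at_obs <- function(eta, time, event, co = cox_order(time, event)) {
  eta_o <- eta[co$ord]
  cs0 <- cumsum(exp(eta_o))
  s0 <- cs0[co$risk_pos]
  grp <- match(co$risk_pos, unique(co$risk_pos))
  inc <- numeric(max(grp))
  ev <- which(co$event_o == 1)
  for (j in ev) inc[grp[j]] <- inc[grp[j]] + 1 / s0[j]
  h_by_group <- rev(cumsum(rev(inc)))
  h_o <- h_by_group[grp]
  h <- numeric(length(eta))
  h[co$ord] <- h_o
  h
}

#' Predict boosting scores
#'
#' Sum of the learning-rate-scaled tree predictions (the model's additive
#' linear score; higher means higher risk).
#'
#' @param model A [fit_cox_gradient_boosting()] result.
#' @param X Feature matrix.
#' @return Numeric score vector.
#' @export
predict_boosting <- function(model, X) {
  eta <- numeric(nrow(X))
  for (root in model$trees) {
    eta <- eta + model$config$learning_rate *
      predict_regression_tree(root, X)
  }
  eta
}

#' Boosting importance
#'
#' For each feature, the sum of the recorded squared-error split gains over
#' all trees and splits on that feature; features never split on get 0.
#'
#' @param model A [fit_cox_gradient_boosting()] result.
#' @return A [filter_scores()] object.
#' @export
boosting_importance <- function(model) {
  p <- length(model$feature_names)
  imp <- numeric(p)
  for (root in model$trees) {
    gains <- regression_tree_gains(root)
    if (!is.null(gains)) {
      for (i in seq_len(nrow(gains))) {
        imp[gains[i, 1]] <- imp[gains[i, 1]] + gains[i, 2]
      }
    }
  }
  filter_scores("boosting", stats::setNames(imp, model$feature_names))
}
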