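# shared strong-signal fixture: feature f1 drives the hazard, the rest are
# noise; regenerated per seed
signal_fixture <- function(seed, n = 120, p = 5, beta = 1.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    t_true <- rexp(n, rate = exp(beta * X[, 1]))
    cens <- rexp(n, rate = 0.3)
    survival_dataset(X, pmin(t_true, cens) + 1e-4,
                     as.numeric(t_true <= cens))
  })
}

test_that("log-rank statistic matches hand tabulation and reference", {
  # identical survival in both groups: duplicated rows split evenly
  time <- rep(c(1, 2, 3, 4), 2)
  event <- rep(c(1, 0, 1, 1), 2)
  group <- rep(c(0, 1), each = 4)
  expect_equal(log_rank_statistic(time, event, group), 0)

  # 6-observation worked instance against the O/E/V tabulation oracle
  t6 <- c(1, 2, 3, 4, 5, 6)
  e6 <- c(1, 1, 0, 1, 1, 0)
  g6 <- c(0, 1, 0, 1, 0, 1)
  expect_equal(log_rank_statistic(t6, e6, g6), oracle_logrank(t6, e6, g6))
  expect_equal(log_rank_statistic(t6, e6, g6),
               log_rank_statistic(t6, e6, 1 - g6))

  for (s in 1:10) {
    withr::with_seed(s, {
      n <- 30
      tt <- rexp(n) + 0.01
      ee <- rbinom(n, 1, 0.7)
      gg <- rbinom(n, 1, 0.5)
      if (sum(ee) == 0) ee[1] <- 1
      if (length(unique(gg)) < 2) gg[1:2] <- c(0, 1)
    })
    expect_equal(log_rank_statistic(tt, ee, gg), oracle_logrank(tt, ee, gg),
                 tolerance = 1e-10)
    # cross-check against the survival package
    expect_equal(log_rank_statistic(tt, ee, gg),
                 survival::survdiff(survival::Surv(tt, ee) ~ gg)$chisq,
                 tolerance = 1e-8)
  }
  expect_error(log_rank_statistic(c(1, 2), c(1, 1), c(1, 1)), "two")
})

test_that("survival trees split perfect separators and respect stopping rules", {
  withr::with_seed(2, {
    x <- c(rnorm(30, -2), rnorm(30, 2))
    tt <- c(rexp(30, 5), rexp(30, 0.2)) + 0.01
  })
  ds <- survival_dataset(cbind(sep = x, noise = withr::with_seed(3, rnorm(60))),
                         tt, rep(1, 60))
  tree <- fit_survival_tree(ds, mtry = 2, min_node_size = 3, seed = 1)
  expect_false(tree$root$is_leaf)
  expect_equal(tree$root$split_feature, 1)
  expect_gt(tree$root$log_rank_statistic, 0)
  expect_identical(fit_survival_tree(ds, mtry = 2, min_node_size = 3,
                                     seed = 1), tree)

  # all censored: no admissible split, single leaf
  flat <- survival_dataset(matrix(rnorm(20), 10, 2), rep(2, 10), rep(0, 10))
  expect_true(fit_survival_tree(flat, mtry = 2, seed = 1)$root$is_leaf)
})

test_that("forests compose bootstrap trees with the expected oob fraction", {
  ds <- signal_fixture(4, n = 60, p = 3)
  f1 <- fit_random_survival_forest(ds, num_trees = 1, mtry = 2, seed = 9)
  boot <- f1$trees[[1]]$bootstrap
  direct <- fit_survival_tree(subset_obs(ds, boot), mtry = 2,
                              min_node_size = 3,
                              seed = derive_seed(9, "tree", 1))
  expect_identical(f1$trees[[1]]$tree, direct)
  expect_identical(fit_random_survival_forest(ds, num_trees = 1, mtry = 2,
                                              seed = 9), f1)

  big <- signal_fixture(5, n = 200, p = 3)
  fo <- fit_random_survival_forest(big, num_trees = 20, mtry = 1, seed = 2)
  oob_frac <- mean(vapply(fo$trees, function(tr) length(tr$oob) / 200, 0))
  expect_lt(abs(oob_frac - exp(-1)), 0.05)
})

test_that("impurity importance sums the recorded split statistics", {
  ds <- signal_fixture(6, n = 80, p = 4)
  fo <- fit_random_survival_forest(ds, num_trees = 10, mtry = 2, seed = 3)
  imp <- rsf_impurity_importance(fo)
  expect_true(all(imp$scores >= 0))
  total_stats <- sum(vapply(fo$trees, function(entry) {
    collect <- function(node) {
      if (node$is_leaf) return(0)
      node$log_rank_statistic + collect(node$left) + collect(node$right)
    }
    collect(entry$tree$root)
  }, 0))
  expect_equal(sum(imp$scores), total_stats)

  # single split on one feature: importance equals that statistic
  one <- fit_survival_tree(ds, mtry = 1, min_node_size = 38, seed = 5)
  if (!one$root$is_leaf) {
    mini <- structure(list(trees = list(list(tree = one)),
                           feature_names = ds$feature_names),
                      class = "random_survival_forest")
    mi <- rsf_impurity_importance(mini)
    expect_equal(unname(mi$scores[one$root$split_feature]),
                 one$root$log_rank_statistic)
    expect_equal(sum(mi$scores > 0), 1)
  }
})

test_that("permutation importance is zero for unused features and finds signal", {
  ds <- signal_fixture(7, n = 200, p = 5)
  fo <- fit_random_survival_forest(ds, num_trees = 25, mtry = 2, seed = 4)
  pim <- rsf_permutation_importance(fo, ds, seed = 4)
  # the informative feature dominates every noise feature
  expect_equal(which.max(pim$scores), 1L, ignore_attr = TRUE)

  # a feature used by no tree scores exactly zero: add an all-but-ignored
  # constant column (never splittable)
  X2 <- cbind(ds$features, dead = rep(1, 200))
  ds2 <- survival_dataset(X2, ds$time, ds$event)
  fo2 <- fit_random_survival_forest(ds2, num_trees = 5, mtry = 3, seed = 5)
  pim2 <- rsf_permutation_importance(fo2, ds2, seed = 5)
  expect_identical(unname(pim2$scores["dead"]), 0)

  # pure-noise scores stay near zero across seeds
  noise_means <- vapply(1:5, function(s) {
    dsn <- signal_fixture(20 + s, n = 200, p = 5)
    fon <- fit_random_survival_forest(dsn, num_trees = 20, mtry = 2,
                                      seed = s)
    mean(rsf_permutation_importance(fon, dsn, seed = s)$scores[2:5])
  }, 0)
  expect_lt(max(abs(noise_means)), 0.05)
})

test_that("boosting obeys the degenerate configurations and records gains", {
  ds <- signal_fixture(8, n = 80, p = 4)
  m0 <- fit_cox_gradient_boosting(ds, n_rounds = 0)
  expect_equal(m0$scores, rep(0, 80))
  expect_equal(sum(boosting_importance(m0)$scores), 0)

  mz <- fit_cox_gradient_boosting(ds, n_rounds = 5, learning_rate = 0)
  expect_equal(mz$scores, rep(0, 80))
  expect_equal(length(unique(round(mz$loglik_trace, 12))), 1)

  mb <- fit_cox_gradient_boosting(ds, n_rounds = 25, learning_rate = 0.1,
                                  max_depth = 3)
  expect_true(all(diff(mb$loglik_trace) >= -1e-9))
  bi <- boosting_importance(mb)
  total_gain <- sum(vapply(mb$trees, function(root) {
    g <- survfilter:::regression_tree_gains(root)
    if (is.null(g)) 0 else sum(g[, 2])
  }, 0))
  expect_equal(sum(bi$scores), total_gain)
  expect_true(all(bi$scores >= 0))
  expect_equal(which.max(bi$scores), 1L, ignore_attr = TRUE)

  # additivity: the stored training scores equal the summed tree predictions
  expect_equal(predict_boosting(mb, ds$features), mb$scores,
               tolerance = 1e-12)
  stumps <- fit_cox_gradient_boosting(ds, n_rounds = 10,
                                      learning_rate = 0.2, max_depth = 1)
  expect_equal(predict_boosting(stumps, ds$features), stumps$scores,
               tolerance = 1e-12)
})

test_that("each importance filter recovers most informative features in its top 5", {
  hits <- matrix(0, 5, 3,
                 dimnames = list(NULL, c("permutation", "impurity",
                                         "boosting")))
  for (s in 1:5) {
    syn <- generate_survival_data(
      synth_config(n = 200, p = 20, n_informative = 3, block_size = 5,
                   rho = 0, beta = 1, variance_sdlog = 0, seed = 100 + s))
    ds <- syn$dataset
    inf_idx <- match(syn$informative, ds$feature_names)
    fo <- fit_random_survival_forest(ds, num_trees = 30, seed = s)
    top5 <- function(scores) order(-scores)[1:5]
    hits[s, "impurity"] <-
      sum(inf_idx %in% top5(rsf_impurity_importance(fo)$scores))
    hits[s, "permutation"] <-
      sum(inf_idx %in% top5(rsf_permutation_importance(fo, ds, s)$scores))
    bm <- fit_cox_gradient_boosting(ds, n_rounds = 40, learning_rate = 0.1,
                                    max_depth = 3)
    hits[s, "boosting"] <-
      sum(inf_idx %in% top5(boosting_importance(bm)$scores))
  }
  for (m in colnames(hits)) {
    expect_gte(sum(hits[, m] >= 2), 4)
  }
})
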