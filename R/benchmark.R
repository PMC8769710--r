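# Nested cross-validation benchmark harness: proportion grid, per-filter
# prop tuning on inner folds, outer evaluation with ridge Cox, the two
# baselines (no filter; Kaplan-Meier), and the aggregations over data sets
# (pairwise wins, relative scores).

#' Proportion grid for the number of selected features
#'
#' The 100 equidistant proportions `0.01, 0.02, ..., 1` transformed by
#' `x -> x^2`, concentrating the grid on small proportions.
#'
#' @return Ascending numeric vector of length 100.
#' @export
prop_grid <- function() {
  (seq_len(100) / 100)^2
}

#' Number of features to select for a proportion
#'
#' `max(1, round(prop * p))` with round-half-up, so at least one feature is
#' always selected.
#'
#' @param prop Proportion in `(0, 1]`.
#' @param p Total number of features.
#' @return Integer selection size.
#' @export
n_select <- function(prop, p) {
  if (prop <= 0 || prop > 1) fail_validation("prop must lie in (0, 1]")
  max(1L, as.integer(floor(prop * p + 0.5)))
}

#' Benchmark configuration
#'
#' @param filters Character vector of filter names; any of `"variance"`,
#'   `"correlation"`, `"cox_score"`, `"carss"`, `"permutation"`,
#'   `"impurity"`, `"boosting"`, `"mim"`, `"mrmr"`, `"jmi"`, `"jmim"`,
#'   `"disr"`, `"njmim"`, `"cmim"`.
#' @param outer_folds,inner_folds Outer / inner cross-validation folds.
#' @param props Proportion grid for tuning (default [prop_grid()]).
#' @param seed Master seed; all child streams are derived from it.
#' @param lambda_nfolds,lambda_path_length Settings of the internal ridge
#'   penalty selection ([select_lambda_cv()]).
#' @param include_baselines Also run the no-filter ridge Cox and the
#'   Kaplan-Meier baseline.
#' @param dataset_id Label recorded with each result.
#' @param importance_config Named list of reduced-scale settings forwarded
#'   to the ensemble filters (`num_trees`, `n_rounds`, `max_depth`, ...).
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(filters = c("variance", "cox_score", "mim"),
                             outer_folds = 10, inner_folds = 10,
                             props = prop_grid(), seed = 1,
                             lambda_nfolds = 10, lambda_path_length = 100,
                             include_baselines = TRUE,
                             dataset_id = "dataset",
                             importance_config = list()) {
  if (outer_folds < 2 || inner_folds < 2) {
    fail_validation("fold counts must be >= 2")
  }
  if (any(props <= 0 | props > 1)) {
    fail_validation("props must lie in (0, 1]")
  }
  structure(list(filters = filters, outer_folds = outer_folds,
                 inner_folds = inner_folds, props = sort(props),
                 seed = seed, lambda_nfolds = lambda_nfolds,
                 lambda_path_length = lambda_path_length,
                 include_baselines = include_baselines,
                 dataset_id = dataset_id,
                 importance_config = importance_config),
            class = "benchmark_config")
}

#' Rank all features of a dataset with a named filter method
#'
#' Dispatcher used by the benchmark harness; returns a full
#' `feature_ranking` for any of the 14 filter methods.
#'
#' @param method Filter name (see [benchmark_config()]).
#' @param dataset A [survival_dataset()].
#' @param seed Seed for the stochastic (ensemble) filters.
#' @param importance_config Reduced-scale settings for the ensemble filters.
#' @return A `feature_ranking`.
#' @export
filter_ranking <- function(method, dataset, seed = 1,
                           importance_config = list()) {
  ic <- function(name, default) importance_config[[name]] %||% default
  switch(method,
    variance = rank_features(variance_filter(dataset)),
    correlation = rank_features(correlation_filter(dataset)),
    cox_score = rank_features(cox_score_filter(dataset)),
    carss = rank_features(carss_filter(dataset)),
    permutation = {
      forest <- fit_random_survival_forest(
        dataset, num_trees = ic("num_trees", 500),
        min_node_size = ic("min_node_size", 3), seed = seed)
      rank_features(rsf_permutation_importance(forest, dataset, seed))
    },
    impurity = {
      forest <- fit_random_survival_forest(
        dataset, num_trees = ic("num_trees", 500),
        min_node_size = ic("min_node_size", 3), seed = seed)
      rank_features(rsf_impurity_importance(forest))
    },
    boosting = {
      model <- fit_cox_gradient_boosting(
        dataset, n_rounds = ic("n_rounds", 2000),
        learning_rate = ic("learning_rate", 0.05),
        max_depth = ic("max_depth", 10), seed = seed)
      rank_features(boosting_importance(model))
    },
    mim = ,
    mrmr = ,
    jmi = ,
    jmim = ,
    disr = ,
    njmim = ,
    cmim = mi_filter(dataset, method),
    fail_validation("unknown filter method '%s'", method)
  )
}

#' Tune the selection proportion of a filter on inner folds
#'
#' For every inner split, the filter ranks the features on the inner
#' training part; for every grid proportion, a ridge Cox model (penalty by
#' [select_lambda_cv()]) is fitted on the top `n_select(prop, p)` features
#' and scored by the integrated Brier score on the held-out part. The
#' proportion minimizing the mean IBS is chosen; ties go to the smallest
#' proportion (the sparser model).
#'
#' @param method Filter name.
#' @param train Training [survival_dataset()].
#' @param inner_folds Number of inner folds.
#' @param grid Proportion grid.
#' @param seed Seed controlling the inner split (shared across filters so
#'   every filter sees identical splits).
#' @param config A [benchmark_config()] supplying penalty-selection
#'   settings.
#' @return A list with the chosen `prop`, the `mean_ibs` per grid value and
#'   `inner_selected_sets` (the per-inner-fold selected feature sets at the
#'   chosen proportion, the input to stability assessment).
#' @export
tune_prop <- function(method, train, inner_folds, grid, seed,
                      config = benchmark_config()) {
  folds <- stratified_folds(train, inner_folds, seed)
  p <- n_features(train)
  ibs_mat <- matrix(NA_real_, inner_folds, length(grid))
  rankings <- vector("list", inner_folds)
  for (f in seq_len(inner_folds)) {
    test_idx <- folds$test_indices[[f]]
    tr <- subset_obs(train, -test_idx)
    te <- subset_obs(train, test_idx)
    ranking <- filter_ranking(method, tr,
                              seed = derive_seed(seed, "filter", method, f),
                              importance_config = config$importance_config)
    rankings[[f]] <- ranking
    G <- kaplan_meier(tr$time, 1 - tr$event)
    for (g in seq_along(grid)) {
      feats <- unclass(ranking)[seq_len(n_select(grid[g], p))]
      ibs_mat[f, g] <- tryCatch({
        lam <- select_lambda_cv(tr$features[, feats, drop = FALSE],
                                tr$time, tr$event,
                                n_folds = config$lambda_nfolds,
                                seed = derive_seed(seed, "lambda", f),
                                path_length = config$lambda_path_length)
        fit <- fit_ridge_cox(tr$features[, feats, drop = FALSE],
                             tr$time, tr$event, as.numeric(lam))
        pred <- predict_survival(fit, te$features[, feats, drop = FALSE])
        integrated_brier_score(pred, te$time, te$event, G)
      }, error = function(e) NA_real_)
    }
  }
  mean_ibs <- suppressWarnings(colMeans(ibs_mat, na.rm = TRUE))
  mean_ibs[!is.finite(mean_ibs)] <- Inf
  if (all(!is.finite(mean_ibs))) {
    fail_validation("every proportion failed during tuning of '%s'", method)
  }
  best <- which.min(mean_ibs)  # grid ascending, ties -> smallest prop
  chosen <- grid[best]
  sets <- lapply(rankings, function(rk) {
    unclass(rk)[seq_len(n_select(chosen, p))]
  })
  list(prop = chosen, mean_ibs = mean_ibs, inner_selected_sets = sets)
}

#' Run the nested cross-validation benchmark on one dataset
#'
#' For every outer fold and filter: tune the proportion on the outer
#' training part, rank and select there, fit ridge Cox with a
#' cross-validated penalty, and record the validation integrated Brier
#' score, the runtime of filtering + fitting + prediction, the selected
#' feature set and the inner-fold selected sets (for stability assessment).
#' The same fold splits are used for every filter. The two baselines are the
#' no-filter ridge Cox (no proportion to tune) and the feature-free
#' Kaplan-Meier predictor. A failing filter is recorded with an error
#' message and never aborts the others.
#'
#' @param dataset A [survival_dataset()].
#' @param config A [benchmark_config()].
#' @return A list of `benchmark_record` lists (class `benchmark_records`).
#' @export
run_nested_cv <- function(dataset, config) {
  outer <- stratified_folds(dataset, config$outer_folds,
                            derive_seed(config$seed, "outer"))
  records <- list()
  methods <- config$filters
  if (config$include_baselines) {
    methods <- c(methods, "no_filter", "kaplan_meier")
  }
  p <- n_features(dataset)
  for (o in seq_len(config$outer_folds)) {
    test_idx <- outer$test_indices[[o]]
    train <- subset_obs(dataset, -test_idx)
    valid <- subset_obs(dataset, test_idx)
    fingerprint <- paste(test_idx, collapse = ",")
    inner_seed <- derive_seed(config$seed, "inner", o)
    G <- kaplan_meier(train$time, 1 - train$event)
    for (method in methods) {
      rec <- tryCatch(
        run_one_cell(method, train, valid, G, o, p, inner_seed, config),
        error = function(e) {
          list(filter = method, fold = o, prop = NA_real_,
               selected = character(0), n_selected = NA_integer_,
               ibs = NA_real_, runtime = NA_real_,
               inner_selected_sets = NULL, error = conditionMessage(e))
        })
      rec$dataset_id <- config$dataset_id
      rec$fold_fingerprint <- fingerprint
      rec$fold <- o
      records[[length(records) + 1]] <- structure(rec,
                                                  class = "benchmark_record")
    }
  }
  structure(records, class = "benchmark_records")
}

run_one_cell <- function(method, train, valid, G, o, p, inner_seed, config) {
  if (method == "kaplan_meier") {
    t0 <- proc.time()["elapsed"]
    model <- km_predictor(train$time, train$event)
    pred <- predict_survival(model, valid$features)
    ibs <- integrated_brier_score(pred, valid$time, valid$event, G)
    runtime <- proc.time()["elapsed"] - t0
    return(list(filter = method, prop = NA_real_, selected = character(0),
                n_selected = 0L, ibs = ibs, runtime = unname(runtime),
                inner_selected_sets = NULL, error = NA_character_))
  }
  if (method == "no_filter") {
    t0 <- proc.time()["elapsed"]
    lam <- select_lambda_cv(train$features, train$time, train$event,
                            n_folds = config$lambda_nfolds,
                            seed = derive_seed(inner_seed, "lambda"),
                            path_length = config$lambda_path_length)
    fit <- fit_ridge_cox(train$features, train$time, train$event,
                         as.numeric(lam))
    pred <- predict_survival(fit, valid$features)
    ibs <- integrated_brier_score(pred, valid$time, valid$event, G)
    runtime <- proc.time()["elapsed"] - t0
    return(list(filter = method, prop = NA_real_,
                selected = train$feature_names, n_selected = p,
                ibs = ibs, runtime = unname(runtime),
                inner_selected_sets = NULL, error = NA_character_))
  }
  tuned <- tune_prop(method, train, config$inner_folds, config$props,
                     inner_seed, config)
  t0 <- proc.time()["elapsed"]
  ranking <- filter_ranking(method, train,
                            seed = derive_seed(config$seed, "outer-filter",
                                               method, o),
                            importance_config = config$importance_config)
  feats <- unclass(ranking)[seq_len(n_select(tuned$prop, p))]
  lam <- select_lambda_cv(train$features[, feats, drop = FALSE],
                          train$time, train$event,
                          n_folds = config$lambda_nfolds,
                          seed = derive_seed(inner_seed, "lambda"),
                          path_length = config$lambda_path_length)
  fit <- fit_ridge_cox(train$features[, feats, drop = FALSE],
                       train$time, train$event, as.numeric(lam))
  pred <- predict_survival(fit, valid$features[, feats, drop = FALSE])
  ibs <- integrated_brier_score(pred, valid$time, valid$event, G)
  runtime <- proc.time()["elapsed"] - t0
  list(filter = method, prop = tuned$prop, selected = feats,
       n_selected = length(feats), ibs = ibs, runtime = unname(runtime),
       inner_selected_sets = tuned$inner_selected_sets,
       error = NA_character_)
}

#' Flatten benchmark records into a data frame
#'
#' @param x A `benchmark_records` list.
#' @param ... Unused.
#' @return One row per record with the scalar fields.
#' @export
as.data.frame.benchmark_records <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    data.frame(dataset_id = r$dataset_id, filter = r$filter, fold = r$fold,
               prop = r$prop, n_selected = r$n_selected, ibs = r$ibs,
               runtime = r$runtime, fold_fingerprint = r$fold_fingerprint,
               error = r$error, stringsAsFactors = FALSE)
  }))
}

#' Aggregate benchmark records per filter and dataset
#'
#' Mean integrated Brier score, median runtime and mean selection
#' proportion of the outer folds — the per-(filter, data set) quantities
#' entering the cross-data-set aggregations.
#'
#' @param records A `benchmark_records` list (or a data frame from
#'   [as.data.frame.benchmark_records()]).
#' @return Data frame with one row per (filter, dataset).
#' @export
aggregate_records <- function(records) {
  df <- if (is.data.frame(records)) records else as.data.frame(records)
  agg <- lapply(split(df, list(df$filter, df$dataset_id), drop = TRUE),
                function(d) {
                  data.frame(filter = d$filter[1],
                             dataset = d$dataset_id[1],
                             mean_ibs = mean(d$ibs, na.rm = TRUE),
                             median_runtime = stats::median(d$runtime,
                                                            na.rm = TRUE),
                             mean_prop = mean(d$prop, na.rm = TRUE),
                             stringsAsFactors = FALSE)
                })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Pairwise win counts between filter methods
#'
#' Entry (A, B) counts the data sets on which filter A achieves a lower
#' mean integrated Brier score than filter B. Rows and columns are ordered
#' by decreasing row sums (total wins).
#'
#' @param mean_scores Data frame with columns `filter`, `dataset`,
#'   `mean_ibs` covering every (filter, dataset) pair.
#' @return Integer matrix with zero diagonal.
#' @export
pairwise_wins <- function(mean_scores) {
  filters <- unique(mean_scores$filter)
  datasets <- unique(mean_scores$dataset)
  tab <- matrix(NA_real_, length(filters), length(datasets),
                dimnames = list(filters, datasets))
  for (i in seq_len(nrow(mean_scores))) {
    tab[mean_scores$filter[i], mean_scores$dataset[i]] <-
      mean_scores$mean_ibs[i]
  }
  if (anyNA(tab)) fail_validation("incomplete (filter, dataset) score table")
  f <- length(filters)
  wins <- matrix(0L, f, f, dimnames = list(filters, filters))
  for (a in seq_len(f)) {
    for (b in seq_len(f)) {
      if (a != b) wins[a, b] <- sum(tab[a, ] < tab[b, ])
    }
  }
  ord <- order(-rowSums(wins))
  wins[ord, ord]
}

#' Relative mean IBS and relative log median runtime per filter
#'
#' Per data set, the best (smallest) mean integrated Brier score is
#' subtracted from every filter's mean IBS, so the best filter scores 0;
#' runtimes are compared as `log10(median runtime)` minus the fastest
#' filter's value on the same data set. Per filter, the median, minimum and
#' maximum across data sets are reported for both criteria.
#'
#' @param mean_scores Data frame with columns `filter`, `dataset`,
#'   `mean_ibs`, `median_runtime` (e.g. from [aggregate_records()]).
#' @return Data frame with one row per filter.
#' @export
relative_scores <- function(mean_scores) {
  df <- mean_scores
  df$rel_ibs <- NA_real_
  df$rel_log_runtime <- NA_real_
  for (d in unique(df$dataset)) {
    rows <- df$dataset == d
    df$rel_ibs[rows] <- df$mean_ibs[rows] - min(df$mean_ibs[rows])
    lrt <- log10(df$median_runtime[rows])
    df$rel_log_runtime[rows] <- lrt - min(lrt)
  }
  agg <- lapply(split(df, df$filter), function(x) {
    data.frame(filter = x$filter[1],
               rel_ibs_median = stats::median(x$rel_ibs),
               rel_ibs_min = min(x$rel_ibs), rel_ibs_max = max(x$rel_ibs),
               rel_log_runtime_median = stats::median(x$rel_log_runtime),
               rel_log_runtime_min = min(x$rel_log_runtime),
               rel_log_runtime_max = max(x$rel_log_runtime),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
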