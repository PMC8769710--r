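test_that("delimited files load into validated datasets, CSV and TSV alike", {
  df <- data.frame(t = c(2, 5, 7), e = c(1, 1, 0),
                   g1 = c(0.1, 0.2, 0.3), g2 = c(5, 4, 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.csv(df, csv, row.names = FALSE)
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- load_dataset(csv, time_col = "t", event_col = "e")
  expect_equal(n_obs(ds), 3)
  expect_equal(n_features(ds), 2)
  expect_identical(ds$feature_names, c("g1", "g2"))
  ds_tsv <- load_dataset(tsv, time_col = "t", event_col = "e",
                         delimiter = "\t")
  expect_identical(ds, ds_tsv)
})

test_that("validation errors name the offending column or row", {
  df <- data.frame(t = c(2, 5), e = c(1, 2), g1 = c(1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_dataset(path, "t", "e"), "event.*row 2")
  df2 <- data.frame(t = c(-1, 5), e = c(1, 0), g1 = c(1, 2))
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_dataset(path, "t", "e"), "positive.*row 1")
  expect_error(load_dataset(path, "missing", "e"), "not found")
  df3 <- data.frame(t = c(1, 5), e = c(1, 0), g1 = c("a", "b"))
  write.csv(df3, path, row.names = FALSE)
  expect_error(load_dataset(path, "t", "e"), "not numeric")
  expect_error(survival_dataset(matrix(1, 2, 2), c(1, 2), c(0, 1),
                                feature_names = c("g", "g")),
               "unique")
})

test_that("Nelson-Aalen and Kaplan-Meier match hand computations", {
  H <- nelson_aalen_cumhaz(c(2, 5, 7), c(1, 1, 0))
  expect_equal(eval_step(H, c(2, 5, 7)), c(1 / 3, 5 / 6, 5 / 6))
  expect_equal(eval_step(H, 1.9), 0)

  expect_equal(eval_step(nelson_aalen_cumhaz(c(1, 2, 3), c(0, 0, 0)),
                         c(1, 2, 3)), c(0, 0, 0))
  expect_equal(eval_step(nelson_aalen_cumhaz(1, 1), 1), 1)

  S <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(eval_step(S, c(1, 2, 3)), c(2 / 3, 2 / 3, 0))
  expect_equal(eval_step(kaplan_meier(c(1, 2), c(0, 0)), c(1, 2)), c(1, 1))
  expect_error(nelson_aalen_cumhaz(numeric(0), numeric(0)), "empty")
})

test_that("estimators are permutation invariant, monotone, and satisfy exp(-H) >= S", {
  for (s in 1:10) {
    ds <- random_ds(s, n = 30)
    H <- nelson_aalen_cumhaz(ds$time, ds$event)
    S <- kaplan_meier(ds$time, ds$event)
    expect_true(all(diff(H$values) >= -1e-12))
    expect_true(all(diff(S$values) <= 1e-12))
    expect_true(all(exp(-H$values) >= S$values - 1e-12))
    perm <- withr::with_seed(s, sample(n_obs(ds)))
    expect_equal(nelson_aalen_cumhaz(ds$time[perm], ds$event[perm]), H)
    expect_equal(kaplan_meier(ds$time[perm], ds$event[perm]), S)
    # jumps only at event times
    expect_true(all(H$knots %in% ds$time[ds$event == 1]))
  }
})

test_that("martingale residuals match the worked example and sum to zero", {
  ds <- make_ds(c(1, 2, 3), c(2, 5, 7), c(1, 1, 0))
  expect_equal(martingale_residuals(ds), c(2 / 3, 1 / 6, -5 / 6))
  ds0 <- make_ds(c(1, 2, 3), c(2, 5, 7), c(0, 0, 0))
  expect_equal(martingale_residuals(ds0), c(0, 0, 0))
  for (s in 1:25) {
    ds <- random_ds(s, n = 20 + s)
    expect_lt(abs(sum(martingale_residuals(ds))), 1e-10)
    expect_true(all(martingale_residuals(ds) <= 1))
  }
})

test_that("the bin-count rule and equal-width categorization behave as printed", {
  expect_equal(n_bins(30), 10)
  expect_equal(n_bins(9), 3)
  expect_equal(n_bins(4), 2)
  expect_error(n_bins(0), "positive")

  cv <- categorize_equal_width(c(0, 1, 2, 3), 2)
  expect_equal(cv$codes, c(1L, 1L, 2L, 2L))
  expect_equal(cv$bin_edges, c(0, 1.5, 3))

  # min and max always land in the first and last bin
  for (s in 1:5) {
    v <- withr::with_seed(s, rnorm(50))
    codes <- categorize_equal_width(v, 7)$codes
    expect_equal(codes[which.min(v)], 1L)
    expect_equal(codes[which.max(v)], 7L)
    expect_true(all(codes >= 1 & codes <= 7))
  }
  expect_error(categorize_equal_width(rep(1, 10), 3), "constant")

  # uniform draw occupies every bin at roughly its share
  u <- withr::with_seed(99, runif(1000))
  occupancy <- tabulate(categorize_equal_width(u, 10)$codes, 10) / 1000
  expect_true(all(occupancy > 0.05 & occupancy < 0.15))
})

test_that("stratified folds balance events and are reproducible", {
  ds <- make_ds(rnorm(10), time = 1:10, event = rep(c(1, 0), 5))
  f <- stratified_folds(ds, 5, seed = 1)
  for (idx in f$test_indices) {
    expect_equal(sum(ds$event[idx]), 1)
    expect_equal(length(idx), 2)
  }
  expect_identical(stratified_folds(ds, 5, seed = 1), f)
  expect_error(stratified_folds(ds, 1, seed = 1), "k must")

  big <- make_ds(rnorm(100), time = runif(100) + 0.1,
                 event = rep(c(1, 0, 0, 1, 0, 0, 0, 1, 0, 0), 10))
  expect_equal(sum(big$event), 30)
  folds <- stratified_folds(big, 10, seed = 42)
  event_counts <- vapply(folds$test_indices,
                         function(idx) sum(big$event[idx]), 0)
  expect_true(all(event_counts == 3))
  expect_setequal(unlist(folds$test_indices), 1:100)
})

test_that("the categorization pipeline composes with martingale residuals", {
  for (s in 1:5) {
    ds <- random_ds(s, n = 35, p = 4)
    cd <- categorize_dataset(ds)
    expect_equal(cd$q, n_bins(35))
    expect_true(all(cd$y >= 1 & cd$y <= cd$q))
    expect_equal(dim(cd$x), c(35, 4))
  }
  # a constant feature collapses to one category instead of failing
  X <- cbind(f1 = rnorm(20), f2 = rep(2, 20))
  ds <- survival_dataset(X, time = runif(20) + 0.1,
                         event = rep(c(0, 1), 10))
  cd <- categorize_dataset(ds)
  expect_true(all(cd$x[, "f2"] == 1L))
})

test_that("step functions serialize to delimited text and back", {
  sf <- step_function(c(1, 2.5, 4), c(0.2, 0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_step_function(sf, path)
  expect_equal(read_step_function(path), sf)
})
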