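#' Construct a right-censored survival dataset
#'
#' The universal input container of the package: an `n x p` matrix of
#' continuous features together with the observed outcome time `T` and the
#' event indicator `Delta` (1 = event observed, 0 = right-censored). The
#' observed time is `min(T_true, C)` for latent true survival and censoring
#' times; neither latent variable is stored here (only the synthetic-data
#' generator knows them).
#'
#' @param features Numeric matrix (or data frame) with one row per
#'   observation and one column per feature. Features are assumed continuous
#'   and measured on a common, unscaled scale.
#' @param time Numeric vector of strictly positive observed outcome times.
#' @param event Vector of event indicators, each 0 or 1.
#' @param feature_names Optional character vector of unique feature names;
#'   defaults to the column names of `features` (or `X1 ... Xp`).
#' @return An object of class `survival_dataset` with elements `features`,
#'   `feature_names`, `time` and `event`.
#' @export
survival_dataset <- function(features, time, event,
                             feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) {
    feature_names <- paste0("X", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  ds <- structure(
    list(features = features,
         feature_names = as.character(feature_names),
         time = as.numeric(time),
         event = as.numeric(event)),
    class = "survival_dataset"
  )
  validate_survival_dataset(ds)
}

validate_survival_dataset <- function(ds) {
  n <- nrow(ds$features)
  p <- ncol(ds$features)
  if (length(ds$time) != n || length(ds$event) != n) {
    fail_validation("time/event length (%d/%d) does not match %d feature rows",
                    length(ds$time), length(ds$event), n)
  }
  if (anyNA(ds$features)) {
    bad <- which(apply(is.na(ds$features), 2, any))[1]
    fail_validation("missing values in feature column '%s'",
                    ds$feature_names[bad])
  }
  if (anyNA(ds$time) || any(ds$time <= 0)) {
    bad <- which(is.na(ds$time) | ds$time <= 0)[1]
    fail_validation("time must be strictly positive; offending row %d", bad)
  }
  if (anyNA(ds$event) || any(!ds$event %in% c(0, 1))) {
    bad <- which(is.na(ds$event) | !ds$event %in% c(0, 1))[1]
    fail_validation("event values must be 0 or 1; offending row %d", bad)
  }
  if (anyDuplicated(ds$feature_names)) {
    fail_validation("feature names must be unique (duplicate: '%s')",
                    ds$feature_names[anyDuplicated(ds$feature_names)])
  }
  if (length(ds$feature_names) != p) {
    fail_validation("feature_names length %d does not match p = %d",
                    length(ds$feature_names), p)
  }
  ds
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d observations, %d features, %d events (%.2f)\n",
              n_obs(x), n_features(x), sum(x$event),
              mean(x$event)))
  invisible(x)
}

#' Number of observations in a survival dataset
#' @param ds A `survival_dataset`.
#' @export
n_obs <- function(ds) length(ds$time)

#' Number of features in a survival dataset
#' @param ds A `survival_dataset`.
#' @export
n_features <- function(ds) ncol(ds$features)

#' Subset the observations of a survival dataset
#'
#' @param ds A `survival_dataset`.
#' @param rows Integer or logical row index.
#' @return A `survival_dataset` restricted to `rows`.
#' @export
subset_obs <- function(ds, rows) {
  survival_dataset(ds$features[rows, , drop = FALSE],
                   ds$time[rows], ds$event[rows],
                   feature_names = ds$feature_names)
}

#' Read a survival dataset from delimited text
#'
#' Expects a header row, one row per observation, designated time and event
#' columns, and all remaining columns numeric features. Feature column order
#' is preserved.
#'
#' @param path Path to the file.
#' @param time_col,event_col Names of the outcome columns.
#' @param delimiter Field delimiter, `","` for CSV or `"\t"` for TSV.
#' @return A validated `survival_dataset`.
#' @export
load_dataset <- function(path, time_col = "time", event_col = "event",
                         delimiter = ",") {
  if (!file.exists(path)) {
    fail_validation("file not found: %s", path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(raw)) {
      fail_validation("column '%s' not found in %s", col, path)
    }
  }
  feat_cols <- setdiff(names(raw), c(time_col, event_col))
  for (col in feat_cols) {
    if (!is.numeric(raw[[col]])) {
      fail_validation("feature column '%s' is not numeric", col)
    }
  }
  survival_dataset(as.matrix(raw[feat_cols]),
                   time = raw[[time_col]], event = raw[[event_col]],
                   feature_names = feat_cols)
}
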