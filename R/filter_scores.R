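#' Per-feature filter scores
#'
#' Container returned by every score-based filter: one finite score per
#' feature, higher is better. Degenerate features (e.g. constants) are mapped
#' to 0 by the individual filters so that the score vector is always total.
#'
#' @param method Filter name.
#' @param scores Named numeric vector, one entry per feature, in the original
#'   column order of the dataset.
#' @return An object of class `filter_scores`.
#' @export
filter_scores <- function(method, scores) {
  if (anyNA(scores) || any(!is.finite(scores))) {
    fail_validation("filter '%s' produced non-finite scores", method)
  }
  if (is.null(names(scores))) {
    fail_validation("scores must be named by feature")
  }
  structure(list(method = method, scores = scores,
                 higher_is_better = TRUE),
            class = "filter_scores")
}

#' @export
print.filter_scores <- function(x, ...) {
  cat(sprintf("filter_scores (%s): %d features\n", x$method,
              length(x$scores)))
  print(utils::head(sort(x$scores, decreasing = TRUE), 5))
  invisible(x)
}

#' Rank features by filter score
#'
#' Orders features by descending score; ties are broken by ascending original
#' column index so rankings are deterministic.
#'
#' @param scores A [filter_scores()] object.
#' @return An object of class `feature_ranking`: the feature names, best
#'   first, with the scores attached as an attribute.
#' @export
rank_features <- function(scores) {
  s <- scores$scores
  ord <- order(-s, seq_along(s))
  structure(names(s)[ord], scores = s[ord], method = scores$method,
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking (%s): %d features; top: %s\n",
              attr(x, "method") %||% "?", length(x),
              paste(utils::head(unclass(x), 5), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
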