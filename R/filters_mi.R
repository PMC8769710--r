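# Entropy / mutual-information machinery on categorized variables and the
# seven MI filters: mim plus the six greedy forward selectors
# (mrmr, jmi, jmim, disr, njmim, cmim). All quantities are plug-in estimates
# from empirical contingency tables, in bits (log base 2).

# collapse one or more categorical vectors into a single composite code
joint_code <- function(...) {
  args <- list(...)
  if (length(args) == 1) return(as.integer(factor(args[[1]])))
  key <- do.call(paste, c(args, sep = "\r"))
  match(key, unique(key))
}

#' Empirical entropy (bits)
#'
#' Plug-in entropy `H(Y) = -sum p(y) log2 p(y)` of a categorical vector,
#' with the convention `0 * log(0) = 0`.
#'
#' @param codes Categorical vector (integer codes or factor).
#' @return Nonnegative entropy in bits.
#' @export
entropy <- function(codes) {
  if (length(codes) == 0) fail_validation("entropy of an empty vector")
  p <- tabulate(joint_code(codes)) / length(codes)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Empirical conditional entropy (bits)
#'
#' `H(Y | X) = sum_x p(x) H(Y | X = x)`, computed via the identity
#' `H(Y | X) = H(X, Y) - H(X)`. Satisfies `0 <= H(Y|X) <= H(Y)`.
#'
#' @param y,x Categorical vectors of equal length.
#' @return Nonnegative conditional entropy in bits.
#' @export
conditional_entropy <- function(y, x) {
  if (length(y) != length(x)) fail_validation("y and x differ in length")
  entropy(joint_code(y, x)) - entropy(x)
}

#' Empirical mutual information (bits)
#'
#' `I(Y; X) = H(Y) - H(Y | X)`; symmetric and nonnegative. When `x2` is
#' supplied, the joint mutual information `I(Y; X, X2)` is computed by
#' treating `(X, X2)` as one composite variable.
#'
#' @param y,x Categorical vectors of equal length.
#' @param x2 Optional second conditioning variable for joint MI.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(y, x, x2 = NULL) {
  if (!is.null(x2)) {
    if (length(x2) != length(x)) fail_validation("x and x2 differ in length")
    x <- joint_code(x, x2)
  }
  if (length(y) != length(x)) fail_validation("y and x differ in length")
  entropy(y) - conditional_entropy(y, x)
}

#' Empirical conditional mutual information (bits)
#'
#' `I(Y; X_k | X_j) = H(Y | X_j) - H(Y | X_k, X_j)`; nonnegative for plug-in
#' estimates (up to floating point).
#'
#' @param y,xk,xj Categorical vectors of equal length.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(y, xk, xj) {
  if (length(y) != length(xk) || length(y) != length(xj)) {
    fail_validation("inputs differ in length")
  }
  conditional_entropy(y, xj) - conditional_entropy(y, joint_code(xk, xj))
}

#' Mutual-information-maximization (mim) filter
#'
#' Scores each categorized feature by the information it shares with the
#' categorized target: `I(Y^(c); X_k^(c))`.
#'
#' @param cdata A [categorize_dataset()] result.
#' @return A [filter_scores()] object.
#' @export
mim_filter <- function(cdata) {
  scores <- vapply(seq_len(ncol(cdata$x)),
                   function(k) mutual_information(cdata$y, cdata$x[, k]), 0)
  filter_scores("mim", stats::setNames(scores, cdata$feature_names))
}

# per-iteration score of each greedy method given the aggregate statistics
# carried along; the aggregates are updated incrementally as features enter G
greedy_score <- function(method, state) {
  switch(method,
    mrmr  = state$rel - state$red_sum / state$g_size,
    jmi   = state$jmi_sum,
    jmim  = state$jmi_min,
    disr  = state$ratio_sum,
    njmim = state$ratio_min,
    cmim  = state$cmi_min
  )
}

#' Greedy forward selection with a mutual-information criterion
#'
#' All six greedy MI filters start from the feature with maximal mutual
#' information with the categorized target and then iteratively add the
#' unselected feature maximizing the method's score given the already
#' selected set `G`:
#'
#' * `mrmr`: relevance minus mean pairwise MI with `G`;
#' * `jmi`: sum over `G` of joint MI `I(Y; X_k, X_j)`;
#' * `jmim`: minimum over `G` of the joint MI;
#' * `disr`: sum over `G` of joint MI divided by the joint entropy
#'   `H(Y, X_k, X_j)`;
#' * `njmim`: minimum over `G` of that ratio;
#' * `cmim`: minimum over `G` of the conditional MI `I(Y; X_k | X_j)`.
#'
#' Ties are broken by the lowest original column index. Per-iteration winning
#' scores are recorded but are not comparable across iterations.
#'
#' @param cdata A [categorize_dataset()] result.
#' @param method One of `"mrmr"`, `"jmi"`, `"jmim"`, `"disr"`, `"njmim"`,
#'   `"cmim"`.
#' @param k Number of features to select (`1 <= k <= p`).
#' @return An object of class `greedy_selection_trace` with the selected
#'   feature names in selection order, the per-iteration winning scores and
#'   the method name.
#' @export
greedy_mi_filter <- function(cdata, method = c("mrmr", "jmi", "jmim", "disr",
                                               "njmim", "cmim"),
                             k) {
  method <- match.arg(method)
  p <- ncol(cdata$x)
  if (!is_count(k) || k < 1 || k > p) {
    fail_validation("k must be an integer in 1..p")
  }
  y <- cdata$y
  rel <- vapply(seq_len(p), function(j) mutual_information(y, cdata$x[, j]), 0)

  selected <- integer(0)
  winning <- numeric(0)
  remaining <- seq_len(p)

  pick <- remaining[which.max(rel[remaining])]
  selected <- pick
  winning <- rel[pick]
  remaining <- setdiff(remaining, pick)

  # incremental aggregates over the selected set, one slot per feature
  red_sum <- numeric(p)     # sum of I(Xk; Xj), j in G          (mrmr)
  jmi_sum <- numeric(p)     # sum of I(Y; Xk, Xj)               (jmi)
  jmi_min <- rep(Inf, p)    # min of I(Y; Xk, Xj)               (jmim)
  ratio_sum <- numeric(p)   # sum of I(Y;Xk,Xj)/H(Y,Xk,Xj)      (disr)
  ratio_min <- rep(Inf, p)  # min of that ratio                 (njmim)
  cmi_min <- rep(Inf, p)    # min of I(Y; Xk | Xj)              (cmim)

  while (length(selected) < k) {
    j_new <- selected[length(selected)]
    xj <- cdata$x[, j_new]
    for (f in remaining) {
      xf <- cdata$x[, f]
      if (method == "mrmr") {
        red_sum[f] <- red_sum[f] + mutual_information(xf, xj)
      } else if (method == "cmim") {
        cmi_min[f] <- min(cmi_min[f],
                          conditional_mutual_information(y, xf, xj))
      } else {
        jnt <- mutual_information(y, xf, xj)
        if (method == "jmi") jmi_sum[f] <- jmi_sum[f] + jnt
        if (method == "jmim") jmi_min[f] <- min(jmi_min[f], jnt)
        if (method %in% c("disr", "njmim")) {
          h3 <- entropy(joint_code(y, xf, xj))
          ratio <- if (h3 > 0) jnt / h3 else 0
          if (method == "disr") ratio_sum[f] <- ratio_sum[f] + ratio
          if (method == "njmim") ratio_min[f] <- min(ratio_min[f], ratio)
        }
      }
    }
    state <- list(rel = rel[remaining], red_sum = red_sum[remaining],
                  g_size = length(selected), jmi_sum = jmi_sum[remaining],
                  jmi_min = jmi_min[remaining],
                  ratio_sum = ratio_sum[remaining],
                  ratio_min = ratio_min[remaining],
                  cmi_min = cmi_min[remaining])
    sc <- greedy_score(method, state)
    best <- which.max(sc)  # remaining is ascending, so ties -> lowest index
    winning <- c(winning, sc[best])
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  structure(list(selected = cdata$feature_names[selected],
                 scores = winning, method = method),
            class = "greedy_selection_trace")
}

#' @export
print.greedy_selection_trace <- function(x, ...) {
  cat(sprintf("greedy_selection_trace (%s): %s\n", x$method,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Mutual-information filter on a survival dataset
#'
#' End-to-end composite used by the benchmark harness: categorize the
#' martingale residuals and the features with `q = n_bins(n)` equal-width
#' bins, then score with `mim` or run the greedy selector. For greedy
#' methods a full ranking over all `p` features is produced by running the
#' selection to depth `k` and ranking the unselected remainder by their
#' first-iteration relevance.
#'
#' @param dataset A [survival_dataset()].
#' @param method One of `"mim"`, `"mrmr"`, `"jmi"`, `"jmim"`, `"disr"`,
#'   `"njmim"`, `"cmim"`.
#' @param k Greedy selection depth (ignored for `mim`); defaults to `p`.
#' @return A [rank_features()] style `feature_ranking` over all features.
#'   For greedy methods, attribute `"selected"` holds the greedily selected
#'   prefix.
#' @export
mi_filter <- function(dataset, method = "mim", k = NULL) {
  cdata <- categorize_dataset(dataset)
  if (method == "mim") {
    return(rank_features(mim_filter(cdata)))
  }
  p <- ncol(cdata$x)
  if (is.null(k)) k <- p
  trace <- greedy_mi_filter(cdata, method, k)
  rel <- mim_filter(cdata)$scores
  rest <- setdiff(cdata$feature_names, trace$selected)
  rest_ord <- rest[order(-rel[rest], match(rest, cdata$feature_names))]
  structure(c(trace$selected, rest_ord), method = method,
            selected = trace$selected, class = "feature_ranking")
}
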