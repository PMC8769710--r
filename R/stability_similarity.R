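# Feature-selection stability (SMA-Count) and top-list ranking similarity
# (OL score with linear weights), plus single-linkage ordering of methods.

#' Absolute-correlation feature similarity matrix
#'
#' Convenience builder of the feature-similarity source used by SMA-Count:
#' `|Pearson correlation|` between all feature pairs of a data matrix.
#' Constant features get similarity 0 to everything (diagonal stays 1).
#'
#' @param X Numeric matrix with named columns.
#' @return Symmetric matrix with unit diagonal and entries in `[0, 1]`.
#' @export
feature_similarity <- function(X) {
  S <- abs(suppressWarnings(stats::cor(X)))
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  S
}

#' Correlation-adjustment count between two feature sets
#'
#' `A(Vi, Vj)` counts the features selected only in `Vi` that have a highly
#' similar partner (similarity `>= theta`) among the features selected only
#' in `Vj`; the adjustment is the minimum of both directions. This credits
#' selections that swap a feature for a near-duplicate.
#'
#' @param Vi,Vj Character vectors of selected feature names.
#' @param sim Feature-similarity matrix with dimnames covering the universe.
#' @param theta Similarity threshold in `[0, 1]`.
#' @return Integer adjustment count.
#' @export
adjustment_count <- function(Vi, Vj, sim, theta) {
  a_dir <- function(A, B) {
    da <- setdiff(A, B)
    db <- setdiff(B, A)
    if (length(da) == 0 || length(db) == 0) return(0L)
    sub <- sim[da, db, drop = FALSE]
    sum(apply(sub, 1, max) >= theta)
  }
  min(a_dir(Vi, Vj), a_dir(Vj, Vi))
}

#' Expected chance overlap of two random feature sets
#'
#' Estimates `E[|Vi inter Vj| + Adj(Vi, Vj)]` under uniformly random
#' selection of two sets with the given cardinalities from a universe of `p`
#' features. The intersection part has the closed form `ni * nj / p`, used
#' by default as an exact (variance-free) replacement; the adjustment part
#' is estimated by seeded Monte-Carlo draws. When no off-diagonal similarity
#' reaches `theta`, the adjustment is identically zero and no sampling is
#' needed.
#'
#' @param ni,nj Set cardinalities.
#' @param sim Feature-similarity matrix over the universe (dimnames =
#'   feature names).
#' @param theta Similarity threshold.
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param exact_intersection Use the closed form for the intersection part
#'   (default); `FALSE` estimates it from the same draws (useful for
#'   checking the Monte-Carlo machinery itself).
#' @return The estimated expectation.
#' @export
expected_pair_overlap <- function(ni, nj, sim, theta, n_mc = 1000, seed = 1,
                                  exact_intersection = TRUE) {
  universe <- rownames(sim)
  p <- length(universe)
  off <- sim
  diag(off) <- 0
  any_adjacent <- any(off >= theta)
  if (!any_adjacent && exact_intersection) {
    return(ni * nj / p)
  }
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_mc), function(s) {
      A <- universe[sample.int(p, ni)]
      B <- universe[sample.int(p, nj)]
      inter <- length(intersect(A, B))
      adj <- if (any_adjacent) adjustment_count(A, B, sim, theta) else 0L
      c(inter, adj)
    }, c(0, 0))
  })
  if (exact_intersection) {
    ni * nj / p + mean(draws[2, ])
  } else {
    mean(draws[1, ]) + mean(draws[2, ])
  }
}

#' SMA-Count feature-selection stability
#'
#' Similarity-adjusted stability of `m` selected feature sets: the mean over
#' all unordered pairs of
#' `S(Vi, Vj) = (|Vi inter Vj| + Adj - E) / (sqrt(|Vi| |Vj|) - E)` with
#' `E = E[|Vi inter Vj| + Adj]` under random selection of equally sized
#' sets. The maximum value 1 indicates a perfectly stable selection;
#' identical sets attain it exactly, independent of the Monte-Carlo estimate
#' of `E` (the ratio cancels algebraically).
#'
#' @param sets List of `m >= 2` character vectors of selected features.
#' @param similarity Feature-similarity matrix over the universe (e.g.
#'   [feature_similarity()]) or a data matrix with named columns from which
#'   it is computed.
#' @param theta Similarity threshold (default 0.9, a strong association).
#' @param n_mc Monte-Carlo draws for the adjustment expectation.
#' @param seed Integer seed.
#' @return SMA-Count stability value (`<= 1`).
#' @export
sma_count <- function(sets, similarity, theta = 0.9, n_mc = 1000, seed = 1) {
  if (length(sets) < 2) fail_validation("need at least two feature sets")
  if (any(lengths(sets) == 0)) fail_validation("empty feature set")
  if (is.null(rownames(similarity))) {
    fail_validation("similarity source must carry feature names")
  }
  if (nrow(similarity) != ncol(similarity)) {
    similarity <- feature_similarity(similarity)
  }
  universe <- rownames(similarity)
  if (!all(unlist(sets) %in% universe)) {
    fail_validation("selected features outside the similarity universe")
  }
  m <- length(sets)
  total <- 0
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      Vi <- sets[[i]]
      Vj <- sets[[j]]
      obs <- length(intersect(Vi, Vj)) +
        adjustment_count(Vi, Vj, similarity, theta)
      E <- expected_pair_overlap(length(Vi), length(Vj), similarity, theta,
                                 n_mc = n_mc,
                                 seed = derive_seed(seed, "pair", i, j))
      denom <- sqrt(length(Vi) * length(Vj)) - E
      if (denom <= 0) {
        fail_validation("degenerate denominator for pair (%d, %d)", i, j)
      }
      total <- total + (obs - E) / denom
    }
  }
  2 * total / (m * (m - 1))
}

#' Ordered-list (OL) similarity of two feature rankings
#'
#' Weighted sum over the top-list depths `k = 1..r` of the overlap
#' `|Li[1..k] inter Lj[1..k]|`, with linearly decreasing positional weights
#' `w_k = (r + 1 - k) / sum_i i (r + 1 - i)`. The scaling makes the score of
#' a ranking with itself exactly 1; disjoint top-`r` lists score 0.
#'
#' @param Li,Lj Duplicate-free ranked feature lists (best first), each of
#'   length `>= r`.
#' @param r Top-list depth (default 100).
#' @return OL score in `[0, 1]`.
#' @export
ol_score <- function(Li, Lj, r = 100) {
  Li <- as.character(Li)
  Lj <- as.character(Lj)
  if (anyDuplicated(Li) || anyDuplicated(Lj)) {
    fail_validation("ranked lists must be duplicate-free")
  }
  if (r > min(length(Li), length(Lj))) {
    fail_validation("r exceeds a list length")
  }
  top_i <- Li[seq_len(r)]
  pos_j <- match(top_i, Lj[seq_len(r)])
  common <- which(!is.na(pos_j))
  # the element enters the overlap count at depth max(rank_i, rank_j)
  enter <- pmax(common, pos_j[common])
  overlap <- cumsum(tabulate(enter, nbins = r))
  k <- seq_len(r)
  w <- (r + 1 - k) / sum(k * (r + 1 - k))
  sum(w * overlap)
}

#' Pairwise OL similarity matrix of filter methods
#'
#' Computes the symmetric matrix of pairwise OL scores between the rankings
#' of several methods on one data set; given rankings from several data sets
#' (a list of per-data-set ranking lists), the per-data-set matrices are
#' aggregated with the arithmetic mean.
#'
#' @param rankings Either a named list of rankings (one per method) or a
#'   list of such lists (one per data set, identical method names).
#' @param r Top-list depth.
#' @return Symmetric `similarity_matrix` with unit diagonal.
#' @export
ol_similarity_matrix <- function(rankings, r = 100) {
  if (is.list(rankings[[1]]) && !inherits(rankings[[1]], "feature_ranking")) {
    mats <- lapply(rankings, ol_similarity_matrix, r = r)
    ref <- dimnames(mats[[1]])
    for (m in mats) {
      if (!identical(dimnames(m), ref)) {
        fail_validation("method labels differ across data sets")
      }
    }
    return(structure(Reduce(`+`, mats) / length(mats),
                     class = c("similarity_matrix", "matrix")))
  }
  labels <- names(rankings)
  if (is.null(labels)) labels <- paste0("method", seq_along(rankings))
  universe <- sort(as.character(unclass(rankings[[1]])))
  for (rk in rankings) {
    if (!identical(sort(as.character(unclass(rk))), universe)) {
      fail_validation("rankings must cover the same feature universe")
    }
  }
  f <- length(rankings)
  S <- diag(1, f)
  dimnames(S) <- list(labels, labels)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      if (j > i) {
        S[i, j] <- S[j, i] <- ol_score(rankings[[i]], rankings[[j]], r)
      }
    }
  }
  structure(S, class = c("similarity_matrix", "matrix"))
}

#' Order methods by single-linkage clustering of their similarity
#'
#' Agglomerative single-linkage clustering on the distance `1 - similarity`;
#' returns the dendrogram leaf order, which places similar methods next to
#' each other.
#'
#' @param similarity A symmetric similarity matrix with unit diagonal.
#' @return Character vector of method labels in leaf order.
#' @export
single_linkage_order <- function(similarity) {
  labels <- rownames(similarity)
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "single")
  labels[hc$order]
}
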