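# Shared fixtures and independent oracles. Every oracle here recomputes the
# target quantity along a different path than the implementation (explicit
# table sums, numerical differentiation, generic optimization) so the two
# routes stay independent.

make_ds <- function(X, time, event) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  survival_dataset(X, time, event)
}

random_ds <- function(seed, n = 25, p = 3, event_prob = 0.7) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    time <- rexp(n) + 0.05
    event <- rbinom(n, 1, event_prob)
    if (sum(event) == 0) event[1] <- 1
    if (sum(event) == n) event[1] <- 0
    survival_dataset(X, time, event)
  })
}

# Independent Cox partial log-likelihood (Breslow ties), O(n^2) double loop.
oracle_partial_loglik <- function(beta, X, time, event) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# score-test statistic via central-difference derivatives of the oracle
# partial log-likelihood of the univariate model at beta = 0
oracle_score_statistic <- function(x, time, event, h = 1e-4) {
  f <- function(b) oracle_partial_loglik(b, matrix(x, ncol = 1), time, event)
  U <- (f(h) - f(-h)) / (2 * h)
  I <- -(f(h) - 2 * f(0) + f(-h)) / h^2
  U^2 / I
}

# two-sample log-rank statistic by explicit per-event-time O/E/V tabulation
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= t & g == 1)
    n2 <- sum(time >= t & g == 2)
    d1 <- sum(time == t & event == 1 & g == 1)
    d2 <- sum(time == t & event == 1 & g == 2)
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# entropy / MI oracles by explicit sums over empirical tables
oracle_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log2(p))
}
oracle_joint_entropy <- function(...) {
  oracle_entropy(do.call(paste, list(...)))
}
oracle_mi <- function(y, x) {
  tab <- table(y, x) / length(y)
  py <- rowSums(tab); px <- colSums(tab)
  s <- 0
  for (i in seq_along(py)) {
    for (j in seq_along(px)) {
      if (tab[i, j] > 0) {
        s <- s + tab[i, j] * log2(tab[i, j] / (py[i] * px[j]))
      }
    }
  }
  as.numeric(s)
}
oracle_cond_entropy <- function(y, x) {
  s <- 0
  n <- length(y)
  for (xv in unique(x)) {
    idx <- x == xv
    s <- s + sum(idx) / n * oracle_entropy(y[idx])
  }
  s
}

# brute-force greedy MI selection recomputing every term from raw tables
oracle_greedy_mi <- function(y, X, method, k) {
  I2 <- function(a, b) {
    oracle_entropy(a) + oracle_entropy(b) - oracle_joint_entropy(a, b)
  }
  I3 <- function(y, a, b) {
    oracle_entropy(y) + oracle_joint_entropy(a, b) -
      oracle_joint_entropy(y, a, b)
  }
  p <- ncol(X)
  rel <- sapply(seq_len(p), function(j) I2(y, X[, j]))
  sel <- which.max(rel)
  rem <- setdiff(seq_len(p), sel)
  while (length(sel) < k) {
    sc <- sapply(rem, function(f) {
      switch(method,
        mrmr = rel[f] - mean(sapply(sel, function(j) I2(X[, f], X[, j]))),
        jmi = sum(sapply(sel, function(j) I3(y, X[, f], X[, j]))),
        jmim = min(sapply(sel, function(j) I3(y, X[, f], X[, j]))),
        disr = sum(sapply(sel, function(j) {
          I3(y, X[, f], X[, j]) / oracle_joint_entropy(y, X[, f], X[, j])
        })),
        njmim = min(sapply(sel, function(j) {
          I3(y, X[, f], X[, j]) / oracle_joint_entropy(y, X[, f], X[, j])
        })),
        cmim = min(sapply(sel, function(j) {
          (oracle_joint_entropy(y, X[, j]) - oracle_entropy(X[, j])) -
            (oracle_joint_entropy(y, X[, f], X[, j]) -
               oracle_joint_entropy(X[, f], X[, j]))
        }))
      )
    })
    pick <- rem[which.max(sc)]
    sel <- c(sel, pick)
    rem <- setdiff(rem, pick)
  }
  sel
}

# Harrell concordance by exhaustive pair enumeration
oracle_harrell_c <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (event[i] == 1 && time[i] < time[j]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# block index of a synthetic feature name for a given block size
synth_block_of <- function(names, all_names, block_size) {
  ((match(names, all_names) - 1) %/% block_size) + 1
}
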