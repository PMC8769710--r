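---
title: "Filter methods for censored, high-dimensional survival data: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter methods for censored, high-dimensional survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survfilter)
```

## The problem

A survival dataset records, for each of $n$ subjects, $p$ continuous
features $X_1,\dots,X_p$, an observed time $T = \min(T_{\text{true}}, C)$
and an event indicator $\Delta = \mathbb 1(T_{\text{true}} \le C)$. In
gene-expression cohorts $p$ is in the tens of thousands while $n$ is a few
hundred, and a large majority of features are irrelevant for the outcome.
Filter methods score every feature cheaply — independently of any
downstream model — and keep only the top-scoring fraction before a survival
model is fitted. This vignette documents what each component of the package
computes, the assumptions behind it, the parameters that matter, and the
choices we made where a design was genuinely open.

## Target transformations

Censoring prevents most regression-style scores from being applied
directly, so several filters first transform the outcome.

**Martingale residuals.** A Cox model fitted without covariates has
cumulative hazard equal to the Nelson–Aalen estimator
$\hat H(t) = \sum_{t_j \le t} d_j / r_j$ ($d_j$ events, $r_j$ at risk at
the $j$-th event time). The martingale residual
$M_i = \Delta_i - \hat H(T_i)$ is real-valued, at most 1, sums to zero,
and serves as an uncensored continuous surrogate outcome $Y^{(m)}$ for the
correlation filter and, after categorization, for the mutual-information
filters. At tied event times we use the Breslow-type increment $d_j/r_j$.
The classic alternative (Efron tie handling) differs only in the presence
of ties; we chose Breslow because it is closed-form, matches the
Nelson–Aalen estimator exactly, and is identical when event times are
unique. All Cox-type computations in the package (score test, ridge fit,
baseline hazard) use the same convention, so internal comparisons are
consistent.

**Categorization.** The mutual-information filters require categorical
variables. Each variable's observed range is cut into
$q = \max\{\min\{\lfloor n/3\rfloor, 10\}, 2\}$ equally spaced intervals
(right-closed, minimum included in the first bin, so the extremes always
receive codes $1$ and $q$). The $n/3$ term is floored since bin counts must
be integers. Constant features cannot be binned by range; they are assigned
a single category, which gives them zero mutual information with everything
and therefore the bottom of every MI ranking — the same "no evidence"
convention (score 0) that the univariate filters apply to constants.

## The filter scores

**Variance** ignores the outcome entirely: it assumes features are on a
common, unscaled measurement scale, so variation itself is evidence of
signal. On standardized data it is meaningless — hence the synthetic
generator never standardizes columns.

**Correlation** is $|\mathrm{cor}(X_k, Y^{(m)})|$, a linear-association
screen on the surrogate outcome.

**Cox score** is the score-test statistic of the univariate Cox model:
$U_k(0)^2 / I_k(0)$, with $U_k(0) = \sum_{\text{events}} (x_{ik} - \bar
x_k^{R})$ and $I_k(0)$ the summed risk-set (population) variances. It is
invariant to affine rescaling of the feature and is computed for all $p$
features in one vectorized pass over the risk sets. We deliberately report
the statistic itself, not a p-value: the filter only needs a ranking.

**CARSS** (correlation-adjusted regression survival scores) addresses the
blind spot of marginal screens — correlated features share credit — by
decorrelating the vector of marginal correlations with
$R_{\text{shrink}}^{-1/2}$, where
$R_{\text{shrink}} = \lambda I + (1-\lambda) R$ shrinks the empirical
feature correlation matrix toward the identity:

* *IPC weights.* The marginal correlations with $\log T$ are
  inverse-probability-of-censoring weighted: $w_i = \Delta_i / \hat
  G(\log t_i^-)$ with $\hat G$ the Kaplan–Meier estimate of the censoring
  survival function on the log-time scale, censored observations receiving
  weight 0, and weights normalized to sum to one. Raw weights are
  truncated at 10 before normalization — the stabilization used by
  reference implementations of correlation-adjusted survival scores —
  because $1/\hat G$ explodes at late event times and would otherwise let
  one or two observations dominate the weighted moments.
* *Moment placement.* As printed in the defining formula, the covariance
  and the target variance are weighted while the feature variance is not;
  we use population-style normalizations throughout so that with equal
  weights the marginal score reduces exactly to the Pearson correlation
  with $\log T$.
* *Shrinkage intensity.* $\lambda$ is the analytic
  Ledoit–Wolf/Schäfer–Strimmer estimate for correlation shrinkage toward
  the identity (ratio of summed estimated variances of the off-diagonal
  correlations to their summed squares), clamped to $[0,1]$, computed
  entirely in the $n$-dimensional sample space. A floor of $10^{-8}$
  keeps $R_{\text{shrink}}$ invertible in the degenerate case
  $\lambda = 0$ with rank-deficient $R$.
* *Inverse square root.* With $p \approx 25{,}000$ a dense $p \times p$
  route is infeasible. Because $R_{\text{shrink}}$ is the identity plus a
  low-rank term, $R_{\text{shrink}}^{-1/2}$ is applied through the
  eigendecomposition of the $n \times n$ Gram matrix of the standardized
  features; memory stays $O(np + n^2)$. A dense oracle (explicit $R$,
  full eigendecomposition) is kept in the test suite and agrees to
  $10^{-8}$ for small $p$.

**Importance filters.** Random survival forests are bagged survival trees:
at each node, `mtry` features are drawn and the split (feature, midpoint
threshold) with the maximal two-sample log-rank statistic is taken;
leaves carry the Nelson–Aalen hazard of their members. *Impurity*
importance sums each feature's split statistics; *permutation* importance
measures the out-of-bag drop in Harrell's C (risk = cumulative hazard
summed over event times) after permuting the feature, one seeded
permutation per (tree, feature). Gradient *boosting* fits depth-limited
least-squares trees to the martingale-type negative gradient
$\Delta_i - \hat H(T_i)e^{\eta_i}$ of the Cox partial likelihood and sums
squared-error split gains per feature. These are deliberately simplified,
fully deterministic analogues of the classic ensemble implementations:
first-order gradients rather than second-order Newton gains, and
exhaustive midpoint split search rather than randomized speedups. Exact
numeric parity with those toolboxes is a non-goal; the importances are
defined conceptually and our tests check the conceptual contracts
(conservation, null behavior, signal recovery). Forest defaults (500
trees, $\sqrt p$ candidates, minimal node size 3) mirror common survival
forest defaults; boosting defaults (2000 rounds, step 0.05, depth 10)
mirror the usual boosted-Cox configuration. Neither is tuned by the
benchmark harness, and tests use far smaller ensembles.

**Mutual-information filters.** All MI quantities are plug-in estimates
from empirical contingency tables in bits; joint quantities treat
$(X_k, X_j)$ or $(Y, X_k, X_j)$ as composite variables; no smoothing or
pseudo-counts are applied. The greedy selectors share the initialization
$\arg\max_k I(Y^{(c)}; X_k^{(c)})$ and add, per iteration, the feature
maximizing their criterion given the selected set $G$ (mean-redundancy
penalty for `mrmr`; sum/min of joint MI for `jmi`/`jmim`; sum/min of the
joint-MI-to-joint-entropy ratio for `disr`/`njmim`; min conditional MI
for `cmim`). Argmax ties are broken by the lowest original column index,
which makes traces deterministic and prefix-consistent. When a full
ranking of all $p$ features is needed (the similarity analysis ranks every
feature), the greedy run is extended to depth $p$ and any remaining
features are ordered by first-iteration relevance.

## Evaluation machinery

**Ridge Cox.** The $L_2$-penalized partial log-likelihood (Breslow ties)
is maximized by Newton iterations with step halving; convergence requires
the penalized gradient below $10^{-8}$ (fits failing $10^{-6}$ raise an
error rather than returning silently). The penalty grid has 100 points
log-spaced over four decades below $\lambda_{\max}$ (derived from the
score vector at $\beta = 0$), fits are warm-started along the path, and
the selected penalty minimizes the mean held-out partial-likelihood
deviance over event-stratified folds — conceptually the usual
cross-validated ridge path, implemented self-contained. $L_2$ (not $L_1$)
is used precisely because it performs no embedded selection: the filter
alone decides which features enter.

**Integrated Brier score.** The IPCW Brier score at horizon $t$ weights
observed-event terms by $1/\hat G(T_i^-)$ and still-at-risk terms by
$1/\hat G(t)$, with $\hat G$ estimated from the *training* outcome. The
integration grid — not fixed by the usual definitions — is the unique
event times of the evaluation set truncated at the last evaluation time
with $\hat G > 0$; the trapezoidal integral is divided by the grid span,
making the score a time-average guaranteed to lie in $[0,1]$. One
convention is used everywhere (inner tuning, outer evaluation, baselines)
so comparisons are internally consistent.

## Stability and similarity

SMA-Count compares $m$ selected sets pairwise:
$S(V_i,V_j) = (|V_i \cap V_j| + \mathrm{Adj} - E)/(\sqrt{|V_i||V_j|} - E)$,
where the adjustment counts features selected in only one set that have a
highly similar partner (|Pearson correlation| $\ge \theta$, default
$\theta = 0.9$) selected in only the other. The chance expectation $E$ of
the intersection term has the closed form $|V_i||V_j|/p$, which we use
exactly; the adjustment term has no simple closed form under arbitrary
correlation structure and is estimated by seeded Monte-Carlo draws
(default 1000), skipped entirely when no feature pair reaches $\theta$.
Identical sets score exactly 1 by algebraic cancellation, independent of
the Monte-Carlo noise.

The OL similarity of two rankings sums top-$k$ overlaps for
$k = 1,\dots,r$ with linearly decreasing weights
$w_k = (r+1-k)/\sum_i i(r+1-i)$ (so a ranking against itself scores
exactly 1); $r = 100$ concentrates the comparison on the head of the
rankings without letting the first handful of positions dominate, as
exponential weights would. Method-similarity matrices are averaged
arithmetically across datasets and displayed in single-linkage leaf order.

## Benchmark design

Each filter has a single hyperparameter, the proportion of features kept
(`prop`), tuned by grid search over $\{0.01,\dots,1\}$ squared (100
values concentrated near zero). Nested cross-validation separates tuning
from evaluation: inner folds choose `prop` by mean validation IBS (ties
to the smallest proportion, favoring sparsity); outer folds measure the
tuned pipeline. All splits are stratified on the event indicator, and the
same splits are reused for every filter so differences are attributable to
the filters alone (records carry a fold fingerprint that tests assert on).
Runtime is recorded as filtering + fitting + prediction wall-clock time;
being hardware-bound, it is reported but never asserted against. Per-cell
failures are caught and recorded without aborting other filters, and
per-purpose child seeds are derived from one master seed so removing a
filter from the configuration leaves every other filter's records
bit-identical. The rounding rule for the selection size is
$\max(1, \text{round-half-up}(\text{prop}\cdot p))$.

## The synthetic generator

`generate_survival_data()` emulates the structure the benchmark assumes:
block-correlated Gaussian features (blocks of 5, within-block correlation
$\rho = 0.7$ — the scale of a tight co-expression module), log-normal
column scales (features on heterogeneous, *unscaled* scales, which is the
regime where the variance filter is meaningful), and a Weibull-baseline
Cox outcome drawn by inversion, $T = (-\log U / (\text{scale}\cdot
e^{\eta}))^{1/\text{shape}}$, with the linear predictor built from the
latent unit-variance informative features so effect sizes are per latent
standard deviation. Censoring is exponential and independent of the
covariates (the IPCW estimators in scope assume random censoring); the
default rate 0.49 was calibrated once, by bisection under common random
numbers (`calibrate_censoring()`), to an event fraction of 0.30 — the
middle of the 0.10–0.50 range typical of TCGA-style cohorts. Defaults
$n = 300$, $p = 1000$, three informative features with effect size 1 in
distinct blocks constitute the strong-signal reference condition used by
the recovery tests.

What the generator does *not* emulate: real expression marginals
(heavy tails, bimodality), batch effects, covariate-dependent censoring,
and RNA/miRNA composition. Passing recovery tests on this generator
therefore demonstrates correctness of the machinery under a known
Cox-generating mechanism, not performance claims about any real cohort.

### A note on CARSS under heavy censoring

The recovery experiments show a real statistical limit worth documenting:
with 30% events at $n = 300$, the IPC-weighted marginal correlation —
effectively estimated from the ~90 events with highly unequal weights —
is noisy enough that the weakest of three informative blocks often fails
to reach the top 10 of $p = 1000$ features, even though the estimator is
consistent (at large $n$ it orders the features correctly, and without
censoring CARSS ranks the informative features first in every seed).
The Cox score filter, which uses all $n$ observations through the risk
sets rather than reweighting events, recovers the same signal reliably.
This gap between the two filters under heavy censoring is a property of
the estimators, not of the implementation, and is asserted as such in the
test suite.

## Problem sizes used by the test suite

Tests and the acceptance script run at desk scale by explicit
configuration, never by silent defaults: oracle comparisons use $n \le
60$, $p \le 50$; ensemble tests use 20–30 trees and $\le 40$ boosting
rounds; the end-to-end benchmark test runs $n = 120$, $p = 300$ with
three filters, both baselines, 3 outer/3 inner folds, a 10-point
proportion grid, and the ridge path reduced to 25 penalties over 3 folds.
These sizes exercise every code path; the package itself imposes no upper
limits beyond memory.
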