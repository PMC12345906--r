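---
title: "Exhaustive model selection for radiomic feature tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive model selection for radiomic feature tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgrid)
```

## The problem

Radiomic feature tables pair hundreds-to-thousands of strongly correlated
continuous features with tens-to-hundreds of samples. On such tables the
apparent performance of a pipeline depends heavily on three ad hoc choices —
the feature-selection method, the classifier, and the particular train–test
split — and a model picked from a single split routinely fails to replicate.
radgrid addresses this by brute force and protocol discipline: it evaluates
*every* combination of a predefined axis set over *repeated* stratified
train–test splits with inner stratified K-fold cross-validation, and
summarises each combination by its full performance distribution rather than
a single number.

## The search grid

The default grid is the Cartesian product of four axes, 4704 combinations in
total:

* **Scalers (4):** none, min–max, standard (z-score), robust
  (median/IQR). Parameters are always estimated on training rows only.
* **Oversampling (12):** random duplication and SMOTE, each at gap
  fractions 0, 0.25, 0.5, 0.75, 0.9 and 1. The level is the fraction of the
  minority–majority count gap that resampling closes: the target minority
  count is `n_min + round(level * (n_maj - n_min))` (half-up). Level 0 is a
  no-op for both methods; the two level-0 specs are deliberately kept as
  distinct grid points so the axis has its nominal size of 12.
* **Selector chains (14):** the four primitives — correlation filter,
  mRMR, LASSO, random-forest importance — and every ordered combination of
  correlation, mRMR and LASSO, applied left to right with each step seeing
  only the survivors of the previous one. The shipped set comprises the
  eight canonical chains (`corr`; `mrmr k=10`; `lasso`; `rf k=10`;
  `corr,mrmr`; `corr,lasso`; `mrmr,lasso`; `corr,mrmr,lasso`), the mRMR
  single at k ∈ {1, 2, 5, 15, 25}, and the RF selector at k = 25. Published
  descriptions of this family of grids give the axis size (14) and the
  available method set but not the exact fourteen-member list, which cannot
  be reconstructed uniquely from the method set and the k-sweep
  {1, 2, 5, 10, 15, 25}; the shipped list is therefore this package's
  documented choice, covering every named method while keeping the axis at
  its nominal size. The axis is fully manifest-driven, so any other
  composition (including the full k-sweep on both ranked selectors) is one
  YAML file away.
* **Classifiers (7):** L2 logistic regression, RBF-kernel SVM, random
  forest (100 trees), 5-nearest-neighbours, Gaussian naive Bayes, AdaBoost
  (50 depth-1 CART stumps, discrete/SAMME weighting), and gradient-boosted
  trees (100 rounds, depth 3, learning rate 0.3). Hyperparameters are fixed
  defaults — tuning classifier internals is explicitly out of scope — and
  every stochastic learner is seeded.

## The evaluation protocol

For each configuration and each of `n_splits` (default 10) stratified
train–test splits at `test_fraction` (default 0.1, i.e. a 90:10 split):

1. the training subset is partitioned into K stratified folds — K = 5 when
   the dataset has fewer than 100 samples, K = 10 otherwise (the rule keys
   on the full dataset size);
2. each fold is held out once: the pipeline is fitted on the other K − 1
   folds and scored on the fold (K *fold-validation* values per metric);
3. the pipeline is refitted on the full training subset and scored on the
   held-out test subset (one *split-test* value per metric).

That yields `n_splits * (K + 1)` values per metric per configuration. Every
per-evaluation fit runs the same leakage-safe order: fit scaler on the
training rows → transform both sets → run the selector chain on transformed
training rows only → restrict both sets to the selected columns → oversample
the training rows only → fit the classifier → score the evaluation rows.
Held-out rows are never visible to scaling, selection, resampling or
fitting; the test suite verifies that permuting or replacing held-out rows
leaves the fitted pipeline unchanged.

**Aggregation.** A configuration's summary per metric is the arithmetic
mean and the 95% percentile interval (2.5th/97.5th percentiles, linear
interpolation between order statistics) of its value distribution. The
default `pooled` mode pools fold-validation and split-test values — the
distribution "across all splits and folds"; `test_only` (used by the
replication workflow) and `folds_only` restrict it. Both readings of what
the distribution should contain are defensible, which is exactly why the
mode is an explicit protocol parameter rather than a constant.

**Seeds.** Every source of randomness derives from one base seed:
`seed(split s, fold f) = base_seed + 1000*s + f` (the split-test evaluation
uses f = 0). The complete record set is a pure function of (configuration,
table, protocol).

## Selection and reporting

* **Well-performing filter:** mean AUC ≥ 0.7 *and* mean accuracy ≥ 0.7
  (inclusive).
* **Best model:** the configuration maximising the unweighted mean of the
  two metric means (the weight is exposed); ties break to the higher mean
  AUC, then to the lexicographically smaller configuration id, so selection
  is invariant to input order. Per-metric argmaxes are reported alongside
  because the best-AUC and best-accuracy models need not coincide.
* **Heatmaps:** a selector-chain × classifier matrix per metric; each cell
  is the best (optionally the mean — the published heatmaps do not state
  which reduction they use, so both are available) metric mean over that
  pair's well-performing configurations across all scalers and resampling
  specs, and pairs with none are left blank.
* **Comparison:** two performance distributions are compared with the
  Mann–Whitney U test: U from rank sums with midranks, exact two-sided p
  (from the tie-free null distribution of U, which is symmetric) when the
  combined sample size is ≤ 12 with no ties, otherwise the normal
  approximation with tie and continuity corrections. The switch point is a
  convention: the distributions this package compares typically hold 10–110
  values, squarely in normal-approximation territory.

## Numerical and degenerate-case decisions

* **Constant features** get a unit divisor in every scaler, so they map to
  a constant instead of NaN and the column index space stays intact.
* **Out-of-range test values** are *not* clipped by the min–max scaler:
  clipping would destroy score orderings that rank-based AUC relies on.
* **mRMR estimators:** relevance = one-way F statistic of feature against
  class; redundancy = mean absolute Pearson correlation with the selected
  set; criterion = their difference (MID-style). Correlation-based
  redundancy is natural and binning-free for continuous radiomic features.
  Ties break to the lowest column index, making selection order-stable.
* **Correlation filter** is the standard greedy keep-first pass: a feature
  is dropped iff |r| with any already-kept feature exceeds the cutoff
  (default 0.9).
* **LASSO penalty** is expressed on the per-sample loss scale
  (glmnet `lambda = penalty / n`), so the default strength 1.0 behaves like
  a conventionally regularised L1 logistic fit; a raw `lambda` of 1.0 would
  annihilate every coefficient on typical standardized tables and reduce
  the selector to its fallback.
* **Empty selections** never kill a grid run: a step that would empty the
  feature set falls back to the single feature with the largest absolute
  univariate association under that step's own score.
* **Degenerate resampling:** a singleton minority class falls back from
  SMOTE interpolation to duplication; the SMOTE neighbourhood shrinks to
  `n_min - 1` when the minority class is small. K folds reduce (with a
  warning) to the minority class size when necessary.
* **Undefined AUC** (single-class evaluation fold) is recorded as NA and
  excluded from summaries rather than propagated as an error.

## The synthetic generator

`generate_table()` emulates the structure of radiomic tables — not their
provenance: features are unit-variance Gaussian; a chosen handful of
*informative* features are mutually independent with a between-class mean
shift (in sd units); the remaining *nuisance* features come in equicorrelated
blocks (default size 5, ρ = 0.5), mimicking the strong redundancy of
features extracted from a shared image region; labels match the requested
class fraction to within one sample. The Gaussian equal-covariance design is
chosen because it admits a closed-form optimum: the Bayes-optimal linear
score separates the class means by the Mahalanobis distance
`shift * sqrt(n_informative)`, giving optimum AUC
`pnorm(shift * sqrt(n_informative) / sqrt(2))` — e.g. ≈ 0.921 for four
informative features with unit shift. That closed form is what lets the test
suite check parameter recovery against a known truth.

What passing these tests does *not* show: real radiomic features are
non-Gaussian (skewed, bounded, heavy-tailed), their correlation is not block
structured, and informative features are usually themselves correlated.
Results on the generator validate the machinery — leakage-freedom,
calibration under the null, recovery of planted signal — not any clinical
claim.

## Problem sizes used by the shipped checks

The test suite exercises the framework at deliberately modest scales chosen
to make the properties sharp, not to mimic any particular cohort: oracle
equivalence on thousands of micro-instances (n ≤ 12 for AUC, p ≤ 8 for
mRMR, n ≤ 5 per sample for the exact U test); null calibration and signal
recovery on 200-sample, 50-feature tables with the full 10-split protocol
(null calibration pools all 110 values per configuration; signal recovery
ranks a 48-configuration reduced grid by its split-test records, the same
aggregation the replication workflow reports). The full 4704-configuration
grid is enumerated and validated structurally; evaluating it end to end on
a real table is the `run_search()` / CLI use case, sized for a workstation
rather than a test suite.

## Known limitations

* Binary classification only; no multiclass grading tasks.
* No hyperparameter optimisation inside the grid (by design), no Boruta or
  information-theoretic filters, no undersampling or ADASYN/borderline
  SMOTE variants.
* No multiple-testing correction across the grid's thousands of
  configurations — the well-performing filter and heatmaps are descriptive,
  and the selection-induced optimism of the best model's summary is not
  corrected; the replication workflow (`run_replicate()` on fresh splits)
  is the honest way to quote its performance.
* Feature extraction from images is out of scope; the package starts at the
  feature table.
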