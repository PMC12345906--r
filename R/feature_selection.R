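# Selector primitives and chain composition. All selectors see training rows
# only and return indices in the ORIGINAL column space.

# |Pearson r| matrix with NA (constant columns) mapped to 0.
abs_cor <- function(x, y = NULL) {
  r <- suppressWarnings(stats::cor(x, y))
  r[is.na(r)] <- 0
  abs(r)
}

# One-way F statistic of each column against a binary grouping; constant
# columns (and zero within-group variance with zero between) score 0.
f_statistic <- function(x, y) {
  y <- as.integer(y)
  n <- nrow(x)
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- colSums((t(t(x[g1, , drop = FALSE]) - m1))^2) +
         colSums((t(t(x[!g1, , drop = FALSE]) - m0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- 0
  f
}

check_binary <- function(y) {
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the labels")
}

#' Correlation redundancy filter
#'
#' Greedy keep-first pass over features in column order: a feature is dropped
#' iff its absolute Pearson correlation with any already-kept feature exceeds
#' `threshold`. Every kept pair therefore satisfies |r| <= threshold. The
#' pass is deterministic and order-stable, the standard redundancy filter in
#' radiomics pipelines.
#'
#' @param x Training matrix (samples in rows).
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return Integer vector of kept column indices (ascending, nonempty).
#' @export
correlation_filter <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("correlation_filter needs at least one feature")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  kept <- 1L
  if (ncol(x) > 1L) {
    for (j in 2:ncol(x)) {
      r <- abs_cor(x[, kept, drop = FALSE], x[, j])
      if (all(r <= threshold)) kept <- c(kept, j)
    }
  }
  kept
}

#' Minimum-redundancy maximum-relevance greedy selection
#'
#' Relevance of a feature is its one-way F statistic against the class label;
#' redundancy is its mean absolute Pearson correlation with the features
#' already selected. The first pick maximizes relevance; every subsequent
#' pick maximizes relevance minus redundancy (the difference, MID-style,
#' natural for continuous radiomic features). Ties break to the lowest
#' column index.
#'
#' @param x Training matrix.
#' @param y Binary labels (0/1), both classes present.
#' @param k Number of features to select.
#' @return Integer vector of `min(k, ncol(x))` indices in selection order.
#' @export
mrmr_select <- function(x, y, k) {
  x <- as.matrix(x)
  check_binary(y)
  if (k < 1) stop("k must be at least 1")
  p <- ncol(x)
  k <- min(as.integer(k), p)
  relevance <- f_statistic(x, y)
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)  # running sum of |r| with selected features
  for (step in seq_len(k)) {
    score <- if (step == 1L) relevance[remaining]
             else relevance[remaining] - red_sum[remaining] / (step - 1L)
    pick <- remaining[which.max(score)]  # which.max -> lowest index on ties
    selected <- c(selected, pick)
    remaining <- remaining[remaining != pick]
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        as.vector(abs_cor(x[, remaining, drop = FALSE], x[, pick]))
  }
  selected
}

#' LASSO feature selection
#'
#' Fits an L1-penalized logistic model and keeps the features with nonzero
#' coefficients. `penalty` is the regularization strength on the per-sample
#' loss scale (glmnet lambda = penalty / n). If shrinkage empties the set,
#' the single feature with the largest absolute point-biserial association
#' with the label is returned instead, so an exhaustive grid never dies on a
#' degenerate step.
#'
#' @param x Training matrix.
#' @param y Binary labels (0/1), both classes present.
#' @param penalty Positive regularization strength.
#' @return Integer vector of kept indices (ascending, nonempty).
#' @export
lasso_select <- function(x, y, penalty = 1.0) {
  x <- as.matrix(x)
  check_binary(y)
  if (penalty <= 0) stop("penalty must be positive")
  if (ncol(x) == 1L) return(1L)
  lambda <- penalty / nrow(x)
  fit <- glmnet::glmnet(x, as.factor(y), family = "binomial", alpha = 1,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  idx <- which(beta != 0)
  if (length(idx) == 0L) idx <- which.max(abs_cor(x, as.numeric(y)))
  sort(idx)
}

#' Random-forest importance selection
#'
#' Fits a seeded 100-tree random forest and keeps the top `k` features by
#' mean decrease in Gini impurity; ties break to the lowest column index.
#'
#' @param x Training matrix.
#' @param y Binary labels (0/1), both classes present.
#' @param k Number of features to keep.
#' @param seed Integer seed for the forest.
#' @param ntree Number of trees.
#' @return Integer vector of `min(k, ncol(x))` indices, importance order.
#' @export
rf_importance_select <- function(x, y, k, seed = 0L, ntree = 100L) {
  x <- as.matrix(x)
  check_binary(y)
  if (k < 1) stop("k must be at least 1")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(seed)
  fit <- randomForest::randomForest(x, as.factor(y), ntree = ntree)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, seq_along(imp))
  ord[seq_len(min(as.integer(k), ncol(x)))]
}

#' Apply an ordered selector chain
#'
#' Each step receives only the columns surviving the previous step; the
#' returned indices always refer to the original column space, so nesting
#' holds: survivors after step i+1 are a subset of survivors after step i.
#'
#' @param chain A `selector_chain`.
#' @param x Training matrix.
#' @param y Binary labels (0/1).
#' @param seed Seed passed to stochastic steps (random forest).
#' @return A `selection_result`: `selected` (original-space indices),
#'   `per_step` (list of kind + surviving indices after each step).
#' @export
apply_chain <- function(chain, x, y, seed = 0L) {
  stopifnot(inherits(chain, "selector_chain"))
  x <- as.matrix(x)
  cur <- seq_len(ncol(x))
  per_step <- vector("list", length(chain$steps))
  for (i in seq_along(chain$steps)) {
    step <- chain$steps[[i]]
    xs <- x[, cur, drop = FALSE]
    local_idx <- switch(step$kind,
      correlation   = correlation_filter(xs, step$threshold),
      mrmr          = mrmr_select(xs, y, step$k),
      lasso         = lasso_select(xs, y, step$penalty),
      random_forest = rf_importance_select(xs, y, step$k, seed = seed))
    cur <- cur[local_idx]
    per_step[[i]] <- list(kind = step$kind, survivors = cur)
  }
  structure(list(selected = cur, per_step = per_step),
            class = "selection_result")
}
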