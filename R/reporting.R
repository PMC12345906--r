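# Well-performing filtering, best-model selection, heatmap matrices and
# Mann-Whitney comparison of performance distributions.

# long summary (config_id, metric, mean, ...) -> one row per config with
# mean_auc / mean_accuracy columns
summary_wide <- function(summaries) {
  a <- summaries[summaries$metric == "auc", c("config_id", "mean", "ci_low", "ci_high")]
  b <- summaries[summaries$metric == "accuracy", c("config_id", "mean", "ci_low", "ci_high")]
  names(a)[2:4] <- c("mean_auc", "auc_ci_low", "auc_ci_high")
  names(b)[2:4] <- c("mean_accuracy", "accuracy_ci_low", "accuracy_ci_high")
  merge(a, b, by = "config_id", sort = TRUE)
}

#' Filter well-performing configurations
#'
#' A configuration is well-performing when its mean AUC and mean accuracy
#' both reach the threshold (inclusive).
#'
#' @param summaries Long summary data.frame from [summarize_records()],
#'   containing both metrics.
#' @param wp_threshold Cutoff applied to both metric means (default 0.7).
#' @return The wide per-config summary restricted to well-performing rows
#'   (possibly empty), with a `well_performing` flag column.
#' @export
filter_well_performing <- function(summaries, wp_threshold = 0.7) {
  w <- summary_wide(summaries)
  w$well_performing <- w$mean_auc >= wp_threshold &
    w$mean_accuracy >= wp_threshold
  w[w$well_performing, , drop = FALSE]
}

#' Select the best configuration
#'
#' The overall best maximizes the (by default unweighted) mean of the two
#' metric means; ties break to the higher mean AUC, then to the
#' lexicographically smaller config id, so the choice is invariant to input
#' order. Per-metric argmaxes are returned alongside, since the best AUC and
#' best accuracy models need not coincide.
#'
#' @param summaries Long summary data.frame with both metrics.
#' @param auc_weight Weight of AUC in the combined score (accuracy gets
#'   `1 - auc_weight`).
#' @return List with `best_overall`, `best_by_auc`, `best_by_accuracy`
#'   (config ids) and the wide `table` ordered by combined score.
#' @export
select_best <- function(summaries, auc_weight = 0.5) {
  w <- summary_wide(summaries)
  if (nrow(w) == 0L) stop("no summaries to select from")
  w$combined <- auc_weight * w$mean_auc + (1 - auc_weight) * w$mean_accuracy
  ord <- order(-w$combined, -w$mean_auc, w$config_id)
  w <- w[ord, , drop = FALSE]
  rownames(w) <- NULL
  by_auc <- w$config_id[order(-w$mean_auc, w$config_id)][1]
  by_acc <- w$config_id[order(-w$mean_accuracy, w$config_id)][1]
  list(best_overall = w$config_id[1], best_by_auc = by_auc,
       best_by_accuracy = by_acc, table = w)
}

#' Selector-chain by classifier heatmap matrix
#'
#' One row per selector chain, one column per classifier. A cell holds the
#' best (or mean) metric mean over the pair's well-performing configurations
#' across all scalers and resamplings; pairs with no well-performing config
#' are NA — rendered as blank cells.
#'
#' @param summaries Long summary data.frame with both metrics.
#' @param components Per-config component breakdown from
#'   [grid_components()].
#' @param metric `"auc"` or `"accuracy"`.
#' @param wp_threshold Well-performing cutoff applied to both metrics.
#' @param aggregate `"max"` (default) or `"mean"` over the pair's
#'   well-performing configs.
#' @return Numeric matrix (chains x classifiers) with NA for blank cells.
#' @export
heatmap_matrix <- function(summaries, components, metric = c("auc", "accuracy"),
                           wp_threshold = 0.7, aggregate = c("max", "mean")) {
  metric <- match.arg(metric)
  aggregate <- match.arg(aggregate)
  wp <- filter_well_performing(summaries, wp_threshold)
  chains <- unique(components$chain)
  classifiers <- unique(components$classifier)
  m <- matrix(NA_real_, length(chains), length(classifiers),
              dimnames = list(chains, classifiers))
  if (nrow(wp) > 0L) {
    col <- if (metric == "auc") "mean_auc" else "mean_accuracy"
    dat <- merge(wp, components, by = "config_id")
    agg <- stats::aggregate(dat[[col]],
                            by = list(chain = dat$chain,
                                      classifier = dat$classifier),
                            FUN = if (aggregate == "max") max else mean)
    for (i in seq_len(nrow(agg)))
      m[agg$chain[i], agg$classifier[i]] <- agg$x[i]
  }
  m
}

#' Mann-Whitney U test for two performance distributions
#'
#' U is computed from rank sums with midranks for ties, reported for the
#' first sample. The two-sided p-value is exact (by the symmetry of the
#' tie-free null distribution of U) when `n_a + n_b <= exact_limit` and no
#' ties are present, and a normal approximation with tie and continuity
#' corrections otherwise.
#'
#' @param a,b Numeric samples, both nonempty.
#' @param exact_limit Combined size at or below which the exact tie-free
#'   null distribution is used.
#' @return List with `u` (first sample), `p`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12L) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  mu <- n_a * n_b / 2
  if (!ties && n_a + n_b <= exact_limit) {
    # two-sided: null mass at least as far from mu = n_a*n_b/2 as observed;
    # U is integer and 2*mu is integer, so the extreme tails start at the
    # integers lo = min(u, 2mu - u) and hi = max(u, 2mu - u)
    lo <- min(u, n_a * n_b - u)
    hi <- max(u, n_a * n_b - u)
    p <- min(1, stats::pwilcox(lo, n_a, n_b) +
               1 - stats::pwilcox(hi - 1, n_a, n_b))
    method <- "exact"
  } else {
    n <- n_a + n_b
    tie_counts <- table(pooled)
    sigma2 <- n_a * n_b / 12 * ((n + 1) -
                                  sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(u = u, p = max(p, .Machine$double.xmin), n_a = n_a, n_b = n_b,
       method = method)
}
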