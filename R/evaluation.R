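# The leakage-safe evaluation harness: repeated stratified train-test splits
# with inner stratified K-fold cross-validation, rank-based AUC and accuracy,
# and distribution-based aggregation.

#' Evaluation protocol parameters
#'
#' @param n_splits Number of repeated stratified train-test splits.
#' @param test_fraction Held-out fraction per split (in (0, 0.5)).
#' @param fold_cutoff Sample-size cutoff of the fold rule: 5 folds below it,
#'   10 folds at or above it.
#' @param wp_threshold Well-performing cutoff applied to both metric means.
#' @param base_seed Integer master seed; all split/fold/model seeds derive
#'   from it.
#' @param aggregation_mode `"pooled"` (fold-validation and split-test values
#'   together), `"test_only"`, or `"folds_only"`.
#' @return An `evaluation_protocol` object.
#' @export
evaluation_protocol <- function(n_splits = 10L, test_fraction = 0.1,
                                fold_cutoff = 100L, wp_threshold = 0.7,
                                base_seed = 0L,
                                aggregation_mode = c("pooled", "test_only",
                                                     "folds_only")) {
  aggregation_mode <- match.arg(aggregation_mode)
  if (n_splits < 1) stop("n_splits must be at least 1")
  if (test_fraction <= 0 || test_fraction >= 0.5)
    stop("test_fraction must lie in (0, 0.5)")
  if (wp_threshold < 0 || wp_threshold > 1)
    stop("wp_threshold must lie in [0, 1]")
  structure(list(n_splits = as.integer(n_splits),
                 test_fraction = test_fraction,
                 fold_cutoff = as.integer(fold_cutoff),
                 wp_threshold = wp_threshold,
                 base_seed = as.integer(base_seed),
                 aggregation_mode = aggregation_mode),
            class = "evaluation_protocol")
}

#' Fold count from the dataset-size rule
#'
#' 5-fold cross-validation for datasets smaller than the cutoff, 10-fold at
#' or above it. The rule keys on the full dataset size.
#'
#' @param n_samples Dataset size.
#' @param cutoff Size cutoff (default 100).
#' @return 5 or 10.
#' @export
choose_fold_count <- function(n_samples, cutoff = 100L) {
  if (n_samples < 2) stop("need at least two samples")
  if (n_samples < cutoff) 5L else 10L
}

# largest-remainder allocation of the test size across classes
allocate_test_counts <- function(class_sizes, test_fraction) {
  total <- as.integer(floor(sum(class_sizes) * test_fraction + 0.5))
  exact <- class_sizes * test_fraction
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    order_rem <- order(-(exact - base), seq_along(class_sizes))
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Repeated seeded stratified train-test splits
#'
#' Per-class test counts follow largest-remainder rounding so the overall
#' test size equals `round(n * test_fraction)` while class proportions are
#' preserved as closely as integers allow.
#'
#' @param y Binary labels (0/1).
#' @param n_splits Number of splits.
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed; split s uses seed + s.
#' @return A `split_plan`: list of `list(train =, test =)` index pairs.
#' @export
stratified_splits <- function(y, n_splits = 10L, test_fraction = 0.1,
                              seed = 0L) {
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(c) sum(y == c), integer(1))
  if (any(sizes < 2)) stop("each class needs at least two samples")
  n_test <- allocate_test_counts(sizes, test_fraction)
  if (any(n_test == 0))
    stop("a class is too small to appear in the test set at this fraction")
  if (any(n_test >= sizes))
    stop("test_fraction leaves no training samples for a class")
  plan <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(seed + s)
    test <- integer(0)
    for (ci in seq_along(classes)) {
      idx <- which(y == classes[ci])
      test <- c(test, sample(idx, n_test[ci]))
    }
    test <- sort(test)
    plan[[s]] <- list(train = setdiff(seq_along(y), test), test = test)
  }
  structure(plan, class = "split_plan")
}

#' Seeded stratified K-fold partition
#'
#' Shuffles each class and deals it round-robin so fold sizes differ by at
#' most one and class balance is preserved. If K exceeds the minority class
#' size it is reduced to that size, with a warning.
#'
#' @param y_train Binary labels of the training rows.
#' @param k Requested fold count.
#' @param seed Integer seed.
#' @return List of K disjoint index vectors covering `seq_along(y_train)`.
#' @export
stratified_folds <- function(y_train, k, seed = 0L) {
  min_size <- min(table(y_train))
  if (k > min_size) {
    warning("reducing fold count from ", k, " to minority class size ",
            min_size)
    k <- min_size
  }
  k <- as.integer(k)
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in sort(unique(y_train))) {
    idx <- sample(which(y_train == cls))
    assignment <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assignment == f])
  }
  lapply(folds, sort)
}

#' Rank-based ROC AUC
#'
#' The probability that a random positive outranks a random negative, ties
#' counted one half — the Mann-Whitney form of the area under the ROC curve.
#'
#' @param scores Continuous scores, larger = more positive.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC is undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification accuracy
#'
#' @param pred Predicted binary labels.
#' @param labels True binary labels, same length.
#' @return Fraction of matches.
#' @export
accuracy <- function(pred, labels) {
  if (length(pred) != length(labels)) stop("length mismatch")
  mean(as.integer(pred) == as.integer(labels))
}

#' Fit one configuration on a training set and score an evaluation set
#'
#' The leakage-safe order: fit the scaler on the training rows; transform
#' both sets; run the selector chain on the transformed training rows;
#' restrict both sets to the selected columns; oversample the training rows
#' only; fit the classifier; score the evaluation rows. AUC comes from the
#' continuous scores, accuracy from the model's native label decision.
#'
#' @param config A `model_config`.
#' @param x_train,y_train Training matrix and labels.
#' @param x_eval,y_eval Evaluation matrix and labels.
#' @param seed Integer seed for selection, resampling and fitting.
#' @return List with `auc` (NA if `y_eval` is single-class), `accuracy`,
#'   and `selected` (original-space feature indices).
#' @export
fit_and_score <- function(config, x_train, y_train, x_eval, y_eval,
                          seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  check_binary(y_train)
  params <- fit_scaler(config$scaler, x_train)
  xt <- apply_scaler(params, x_train)
  xe <- apply_scaler(params, x_eval)
  sel <- apply_chain(config$chain, xt, y_train, seed = seed)
  xt <- xt[, sel$selected, drop = FALSE]
  xe <- xe[, sel$selected, drop = FALSE]
  rs <- oversample(config$resampling, xt, y_train, seed = seed)
  model <- fit_classifier(config$classifier, rs$x, rs$y, seed = seed)
  scores <- predict_scores(model, xe)
  pred <- predict_labels(model, xe)
  auc <- if (length(unique(y_eval)) < 2L) NA_real_ else roc_auc(scores, y_eval)
  list(auc = auc, accuracy = accuracy(pred, y_eval), selected = sel$selected)
}

eval_seed <- function(base_seed, split, fold = 0L) {
  base_seed + 1000L * split + fold
}

#' Evaluate one configuration under the full protocol
#'
#' For every split: K fold-validation evaluations (train on K-1 folds, score
#' the held-out fold) plus one test evaluation after refitting on the full
#' training subset — `n_splits * (K + 1)` values per metric. Seeds derive
#' deterministically from `base_seed`, the split and the fold, so the output
#' is a pure function of (config, table, protocol). Splits where the AUC is
#' undefined (single-class evaluation set) are recorded as NA and dropped at
#' summary time.
#'
#' @param config A `model_config`.
#' @param table A `feature_table`.
#' @param protocol An `evaluation_protocol`.
#' @return A data.frame of metric records (`config_id`, `split`, `stage`,
#'   `metric`, `value`) with attribute `selected`: the per-split
#'   test-stage feature selections.
#' @export
evaluate_config <- function(config, table, protocol = evaluation_protocol()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(protocol, "evaluation_protocol"))
  x <- table$x; y <- table$y
  k <- choose_fold_count(nrow(x), protocol$fold_cutoff)
  plan <- stratified_splits(y, protocol$n_splits, protocol$test_fraction,
                            seed = protocol$base_seed)
  rows <- list()
  selected <- vector("list", protocol$n_splits)
  for (s in seq_along(plan)) {
    tr <- plan[[s]]$train; te <- plan[[s]]$test
    folds <- stratified_folds(y[tr], k, seed = eval_seed(protocol$base_seed, s))
    for (f in seq_along(folds)) {
      hold <- tr[folds[[f]]]
      fit_on <- setdiff(tr, hold)
      res <- fit_and_score(config, x[fit_on, , drop = FALSE], y[fit_on],
                           x[hold, , drop = FALSE], y[hold],
                           seed = eval_seed(protocol$base_seed, s, f))
      rows[[length(rows) + 1L]] <-
        data.frame(config_id = config$id, split = s,
                   stage = sprintf("fold%d", f),
                   metric = c("auc", "accuracy"),
                   value = c(res$auc, res$accuracy))
    }
    res <- fit_and_score(config, x[tr, , drop = FALSE], y[tr],
                         x[te, , drop = FALSE], y[te],
                         seed = eval_seed(protocol$base_seed, s))
    selected[[s]] <- res$selected
    rows[[length(rows) + 1L]] <-
      data.frame(config_id = config$id, split = s, stage = "test",
                 metric = c("auc", "accuracy"),
                 value = c(res$auc, res$accuracy))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selected") <- selected
  out
}

percentile_ci <- function(values, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(values, c(a, 1 - a), names = FALSE, type = 7)
}

#' Summarize metric records into per-config performance distributions
#'
#' Mean and 95% percentile interval (2.5th/97.5th percentiles, linear
#' interpolation between order statistics) of the metric values, per config
#' and metric. `pooled` uses fold-validation and split-test values together;
#' `test_only` and `folds_only` restrict the distribution. NA values (AUC on
#' a degenerate evaluation set) are dropped.
#'
#' @param records Record data.frame from [evaluate_config()] (several
#'   configs may be row-bound).
#' @param mode Aggregation mode.
#' @return A data.frame: `config_id`, `metric`, `mean`, `ci_low`, `ci_high`,
#'   `n_values`, `mode`.
#' @export
summarize_records <- function(records, mode = c("pooled", "test_only",
                                                "folds_only")) {
  mode <- match.arg(mode)
  keep <- switch(mode,
                 pooled = rep(TRUE, nrow(records)),
                 test_only = records$stage == "test",
                 folds_only = records$stage != "test")
  records <- records[keep & !is.na(records$value), , drop = FALSE]
  if (nrow(records) == 0L) stop("no metric values to summarize")
  groups <- split(records,
                  list(records$config_id, records$metric), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    ci <- percentile_ci(g$value)
    data.frame(config_id = g$config_id[1], metric = g$metric[1],
               mean = mean(g$value), ci_low = ci[1], ci_high = ci[2],
               n_values = nrow(g), mode = mode)
  }))
  rownames(out) <- NULL
  out[order(out$config_id, out$metric), , drop = FALSE]
}
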