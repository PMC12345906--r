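# Grid definition: scalers x selector chains x oversampling x classifiers.

#' Grid axis vocabularies
#'
#' The fixed vocabularies of the search grid: four scaler kinds (including
#' no scaling), four selector primitives, two oversampling methods with six
#' default gap-fraction levels, and seven classifier kinds.
#'
#' @name grid-vocabulary
#' @aliases SCALER_KINDS SELECTOR_KINDS RESAMPLING_METHODS CLASSIFIER_KINDS
#'   DEFAULT_LEVELS
NULL

#' @rdname grid-vocabulary
#' @export
SCALER_KINDS <- c("none", "minmax", "standard", "robust")
#' @rdname grid-vocabulary
#' @export
SELECTOR_KINDS <- c("correlation", "mrmr", "lasso", "random_forest")
#' @rdname grid-vocabulary
#' @export
RESAMPLING_METHODS <- c("random", "smote")
#' @rdname grid-vocabulary
#' @export
CLASSIFIER_KINDS <- c("logistic_regression", "svm", "random_forest", "knn",
                      "naive_bayes", "adaboost", "xgboost")
#' @rdname grid-vocabulary
#' @export
DEFAULT_LEVELS <- c(0, 0.25, 0.5, 0.75, 0.9, 1.0)

#' One feature-selection step
#'
#' A step is one of the four selector primitives. `k` (number of features to
#' keep) is required for mRMR and random-forest importance ranking, the
#' absolute-correlation cutoff `threshold` for the correlation filter, and the
#' regularization strength `penalty` for the LASSO.
#'
#' @param kind One of `"correlation"`, `"mrmr"`, `"lasso"`, `"random_forest"`.
#' @param k Positive integer; features to keep (mrmr / random_forest only).
#' @param threshold Absolute Pearson correlation cutoff in (0, 1]
#'   (correlation only).
#' @param penalty Positive regularization strength (lasso only).
#' @return A `selector_step` object.
#' @export
selector_step <- function(kind, k = NULL, threshold = NULL, penalty = NULL) {
  kind <- match.arg(kind, SELECTOR_KINDS)
  needs_k <- kind %in% c("mrmr", "random_forest")
  if (needs_k) {
    if (is.null(k) || length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
      stop("selector step '", kind, "' requires a positive integer k")
  } else if (!is.null(k)) {
    stop("k is only meaningful for mrmr and random_forest steps")
  }
  if (kind == "correlation") {
    if (is.null(threshold)) threshold <- 0.9
    if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
      stop("correlation threshold must lie in (0, 1]")
  } else if (!is.null(threshold)) {
    stop("threshold is only meaningful for correlation steps")
  }
  if (kind == "lasso") {
    if (is.null(penalty)) penalty <- 1.0
    if (!is.numeric(penalty) || penalty <= 0)
      stop("lasso penalty must be positive")
  } else if (!is.null(penalty)) {
    stop("penalty is only meaningful for lasso steps")
  }
  structure(
    list(kind = kind,
         k = if (needs_k) as.integer(k) else NULL,
         threshold = if (kind == "correlation") as.numeric(threshold) else NULL,
         penalty = if (kind == "lasso") as.numeric(penalty) else NULL),
    class = "selector_step")
}

step_label <- function(step) {
  switch(step$kind,
         correlation   = sprintf("corr%g", step$threshold),
         mrmr          = sprintf("mrmr%d", step$k),
         lasso         = sprintf("lasso%g", step$penalty),
         random_forest = sprintf("rf%d", step$k))
}

#' An ordered feature-selection chain
#'
#' Steps are applied in list order, each seeing only the survivors of the
#' previous step. No two steps may share a kind, and the random-forest
#' selector is only allowed as a single-step chain.
#'
#' @param ... `selector_step` objects (or a single list of them).
#' @return A `selector_chain` object.
#' @export
selector_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1L]], "selector_step"))
    steps <- steps[[1L]]
  if (length(steps) == 0L) stop("a selector chain needs at least one step")
  ok <- vapply(steps, inherits, logical(1), "selector_step")
  if (!all(ok)) stop("all chain elements must be selector_step objects")
  kinds <- vapply(steps, `[[`, character(1), "kind")
  if (anyDuplicated(kinds)) stop("a chain may not repeat a selector kind")
  if ("random_forest" %in% kinds && length(steps) > 1L)
    stop("random_forest is only allowed as a single-step chain")
  structure(list(steps = steps), class = "selector_chain")
}

chain_label <- function(chain) {
  paste(vapply(chain$steps, step_label, character(1)), collapse = ",")
}

#' A minority-oversampling specification
#'
#' `level` is the fraction of the minority-majority count gap that resampling
#' closes: 0 is a no-op, 1 balances the classes exactly.
#'
#' @param method `"random"` (duplication) or `"smote"` (interpolation).
#' @param level Fraction in \[0, 1\] of the class-count gap to close.
#' @param k_neighbors Neighbourhood size for SMOTE interpolation.
#' @return A `resampling_spec` object.
#' @export
resampling_spec <- function(method = c("random", "smote"), level = 0,
                            k_neighbors = 5L) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > 1)
    stop("resampling level must lie in [0, 1]")
  if (!is.numeric(k_neighbors) || k_neighbors < 1)
    stop("k_neighbors must be a positive integer")
  structure(list(method = method, level = as.numeric(level),
                 k_neighbors = as.integer(k_neighbors)),
            class = "resampling_spec")
}

resampling_label <- function(rs) {
  if (rs$method == "smote") sprintf("smote%g(k%d)", rs$level, rs$k_neighbors)
  else sprintf("random%g", rs$level)
}

#' One grid point: a full model configuration
#'
#' @param scaler One of `"none"`, `"minmax"`, `"standard"`, `"robust"`.
#' @param chain A `selector_chain`.
#' @param resampling A `resampling_spec`.
#' @param classifier One of the seven classifier kinds
#'   (see [CLASSIFIER_KINDS]).
#' @return A `model_config` with a canonical `id`.
#' @export
model_config <- function(scaler, chain, resampling, classifier) {
  scaler <- match.arg(scaler, SCALER_KINDS)
  classifier <- match.arg(classifier, CLASSIFIER_KINDS)
  stopifnot(inherits(chain, "selector_chain"),
            inherits(resampling, "resampling_spec"))
  cfg <- structure(list(scaler = scaler, chain = chain,
                        resampling = resampling, classifier = classifier),
                   class = "model_config")
  cfg$id <- config_id(cfg)
  cfg
}

#' Canonical identifier of a model configuration
#'
#' Deterministic, human-readable and injective: the string encodes the scaler,
#' every chain step with its parameter (in application order, comma-separated),
#' the resampling method with its level, and the classifier.
#'
#' @param config A `model_config`.
#' @return A single string.
#' @export
config_id <- function(config) {
  paste(config$scaler, chain_label(config$chain),
        resampling_label(config$resampling), config$classifier, sep = "|")
}

#' @exportS3Method base::print
print.model_config <- function(x, ...) {
  cat("<model_config> ", x$id, "\n", sep = "")
  invisible(x)
}

#' A search space: the axes whose Cartesian product is the grid
#'
#' @param scalers Character vector of scaler kinds.
#' @param chains List of `selector_chain` objects.
#' @param resamplings List of `resampling_spec` objects.
#' @param classifiers Character vector of classifier kinds.
#' @return A `search_space` object.
#' @export
search_space <- function(scalers, chains, resamplings, classifiers) {
  scalers <- vapply(scalers, match.arg, character(1), SCALER_KINDS)
  classifiers <- vapply(classifiers, match.arg, character(1), CLASSIFIER_KINDS)
  if (length(scalers) == 0L || length(chains) == 0L ||
      length(resamplings) == 0L || length(classifiers) == 0L)
    stop("every search-space axis must be nonempty")
  if (anyDuplicated(scalers) || anyDuplicated(classifiers))
    stop("duplicate entries on a search-space axis")
  chain_ids <- vapply(chains, chain_label, character(1))
  rs_ids <- vapply(resamplings, resampling_label, character(1))
  if (anyDuplicated(chain_ids) || anyDuplicated(rs_ids))
    stop("duplicate entries on a search-space axis")
  structure(list(scalers = unname(scalers), chains = chains,
                 resamplings = resamplings, classifiers = unname(classifiers)),
            class = "search_space")
}

#' @exportS3Method base::print
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d scalers x %d chains x %d resamplings x %d classifiers = %d configs\n",
              length(x$scalers), length(x$chains), length(x$resamplings),
              length(x$classifiers),
              length(x$scalers) * length(x$chains) * length(x$resamplings) *
                length(x$classifiers)))
  invisible(x)
}

#' The shipped default search space
#'
#' Four scalers (including no scaling), twelve oversampling specifications
#' (random duplication and SMOTE, each at gap fractions 0, 0.25, 0.5, 0.75,
#' 0.9 and 1), fourteen selector chains, and seven classifiers: 4704
#' configurations in total. The fourteen chains are the eight canonical ones
#' (each single method plus every ordered combination of correlation, mRMR
#' and LASSO) together with the mRMR single-step chain at k in
#' {1, 2, 5, 15, 25} and the random-forest selector at k = 25.
#'
#' @param corr_threshold Correlation-filter cutoff used throughout.
#' @param lasso_penalty LASSO regularization strength used throughout.
#' @param smote_k SMOTE neighbourhood size.
#' @return A `search_space` of 4704 configurations.
#' @export
build_default_space <- function(corr_threshold = 0.9, lasso_penalty = 1.0,
                                smote_k = 5L) {
  co <- function() selector_step("correlation", threshold = corr_threshold)
  mr <- function(k) selector_step("mrmr", k = k)
  la <- function() selector_step("lasso", penalty = lasso_penalty)
  rf <- function(k) selector_step("random_forest", k = k)
  chains <- c(
    list(selector_chain(co()),
         selector_chain(mr(10)),
         selector_chain(la()),
         selector_chain(rf(10)),
         selector_chain(co(), mr(10)),
         selector_chain(co(), la()),
         selector_chain(mr(10), la()),
         selector_chain(co(), mr(10), la())),
    lapply(c(1L, 2L, 5L, 15L, 25L), function(k) selector_chain(mr(k))),
    list(selector_chain(rf(25))))
  resamplings <- unlist(lapply(RESAMPLING_METHODS, function(m)
    lapply(DEFAULT_LEVELS, function(l)
      resampling_spec(m, level = l, k_neighbors = smote_k))),
    recursive = FALSE)
  search_space(SCALER_KINDS, chains, resamplings, CLASSIFIER_KINDS)
}

#' Enumerate the full grid of a search space
#'
#' Deterministic scaler-major order: scaler, then chain, resampling,
#' classifier.
#'
#' @param space A `search_space`.
#' @return A list of `model_config`, of length equal to the product of the
#'   axis sizes, with pairwise-distinct ids.
#' @export
enumerate_grid <- function(space) {
  stopifnot(inherits(space, "search_space"))
  out <- vector("list",
                length(space$scalers) * length(space$chains) *
                  length(space$resamplings) * length(space$classifiers))
  i <- 0L
  for (sc in space$scalers)
    for (ch in space$chains)
      for (rs in space$resamplings)
        for (cl in space$classifiers) {
          i <- i + 1L
          out[[i]] <- model_config(sc, ch, rs, cl)
        }
  out
}

#' Component breakdown of an enumerated grid
#'
#' @param configs List of `model_config` (e.g. from [enumerate_grid()]).
#' @return A data.frame with one row per config: id, scaler, chain,
#'   resampling and classifier labels.
#' @export
grid_components <- function(configs) {
  data.frame(
    config_id = vapply(configs, `[[`, character(1), "id"),
    scaler = vapply(configs, `[[`, character(1), "scaler"),
    chain = vapply(configs, function(c) chain_label(c$chain), character(1)),
    resampling = vapply(configs, function(c) resampling_label(c$resampling),
                        character(1)),
    classifier = vapply(configs, `[[`, character(1), "classifier"),
    stringsAsFactors = FALSE)
}
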