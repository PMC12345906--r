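# Feature-table container, CSV/manifest readers and result writers.

#' A samples-by-features table with a binary label
#'
#' The in-memory container every workflow operates on: a numeric matrix with
#' unique, ordered feature names, a 0/1 label vector (1 = declared positive
#' class) and sample ids. Missing values are rejected outright — radiomics
#' extractors emit complete tables, and silent imputation hides bugs.
#'
#' @param x Numeric matrix (samples in rows) with unique column names.
#' @param y Binary labels, one per row, both classes present.
#' @param sample_ids Optional character ids, one per row.
#' @param positive_label Display value of the positive class.
#' @return A `feature_table` object.
#' @export
feature_table <- function(x, y, sample_ids = NULL, positive_label = "1") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  if (ncol(x) < 1L) stop("need at least one feature")
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (is.null(colnames(x))) colnames(x) <- sprintf("feat_%03d", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("one label per sample required")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("both label classes must be present")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(x)))
  structure(list(x = x, y = y, sample_ids = as.character(sample_ids),
                 positive_label = as.character(positive_label)),
            class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; positives: %d, negatives: %d\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' Read a feature table from CSV
#'
#' Every non-label column is parsed as a numeric feature; the label column is
#' mapped to 0/1 by `positive_label`. Fails fast on a missing label column,
#' non-numeric feature cells, missing values, more than two label values, or
#' a single-class label.
#'
#' @param path CSV file with a header row.
#' @param label_column Name of the label column.
#' @param positive_label Label value mapped to 1; defaults to the
#'   lexicographically larger of the two values.
#' @param id_column Optional name of a sample-id column.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label",
                               positive_label = NULL, id_column = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  labels_raw <- as.character(df[[label_column]])
  ids <- if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("id column '", id_column, "' not found")
    as.character(df[[id_column]])
  } else NULL
  feat_cols <- setdiff(names(df), c(label_column, id_column))
  if (length(feat_cols) == 0L) stop("no feature columns in ", path)
  xm <- matrix(NA_real_, nrow(df), length(feat_cols),
               dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    col <- df[[feat_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "")
    if (length(bad) > 0L)
      stop("non-numeric value in column '", feat_cols[j], "', row ", bad[1])
    miss <- which(is.na(num))
    if (length(miss) > 0L)
      stop("missing value in column '", feat_cols[j], "', row ", miss[1])
    xm[, j] <- num
  }
  values <- unique(labels_raw)
  if (length(values) != 2L)
    stop("label column '", label_column, "' has ", length(values),
         " distinct values; exactly 2 required")
  if (is.null(positive_label)) positive_label <- sort(values)[2]
  if (!positive_label %in% values)
    stop("positive label '", positive_label, "' absent from label column")
  y <- as.integer(labels_raw == positive_label)
  feature_table(xm, y, sample_ids = ids, positive_label = positive_label)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: features, then a `label` column
#' holding the original label values.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @param label_column Name for the label column.
#' @export
write_feature_table <- function(table, path, label_column = "label") {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$x, check.names = FALSE)
  neg <- if (table$positive_label == "0") "1" else "0"
  df[[label_column]] <- ifelse(table$y == 1L, table$positive_label, neg)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# ---- grid manifest ---------------------------------------------------------

parse_chain_spec <- function(steps) {
  selector_chain(lapply(steps, function(s)
    selector_step(s[["kind"]], k = s[["k"]], threshold = s[["threshold"]],
                  penalty = s[["penalty"]])))
}

#' Read a search-space / protocol manifest
#'
#' YAML or JSON with top-level keys `scalers`, `selectors` (a list of
#' chains, each a list of step objects `{kind, k?, threshold?, penalty?}`),
#' `resampling` (`{methods, levels, k_neighbors}`), `classifiers` and
#' `protocol` (`{n_splits, test_fraction, fold_cutoff, wp_threshold, seed,
#' aggregation_mode}`). Missing keys fall back to the shipped defaults.
#'
#' @param path Manifest file (`.yaml`/`.yml`/`.json`).
#' @return List with `space` (a [search_space()]) and `protocol`
#'   (an [evaluation_protocol()]).
#' @export
read_manifest <- function(path) {
  m <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  default <- build_default_space()
  scalers <- if (!is.null(m$scalers)) unlist(m$scalers) else default$scalers
  chains <- if (!is.null(m$selectors))
    lapply(m$selectors, parse_chain_spec) else default$chains
  resamplings <- if (!is.null(m$resampling)) {
    methods <- unlist(m$resampling$methods %||% RESAMPLING_METHODS)
    levels <- unlist(m$resampling$levels %||% DEFAULT_LEVELS)
    kn <- m$resampling$k_neighbors %||% 5L
    unlist(lapply(methods, function(me)
      lapply(levels, function(l) resampling_spec(me, l, kn))),
      recursive = FALSE)
  } else default$resamplings
  classifiers <- if (!is.null(m$classifiers)) unlist(m$classifiers)
  else default$classifiers
  p <- m$protocol %||% list()
  protocol <- evaluation_protocol(
    n_splits = p$n_splits %||% 10L,
    test_fraction = p$test_fraction %||% 0.1,
    fold_cutoff = p$fold_cutoff %||% 100L,
    wp_threshold = p$wp_threshold %||% 0.7,
    base_seed = p$seed %||% 0L,
    aggregation_mode = p$aggregation_mode %||% "pooled")
  list(space = search_space(scalers, chains, resamplings, classifiers),
       protocol = protocol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- result writers --------------------------------------------------------

write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
}

read_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

write_summary_csv <- function(summaries, components, wp_threshold, path) {
  w <- summary_wide(summaries)
  w$well_performing <- w$mean_auc >= wp_threshold &
    w$mean_accuracy >= wp_threshold
  out <- merge(components, w, by = "config_id", sort = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

write_heatmap_csv <- function(m, path) {
  df <- data.frame(chain = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
}
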