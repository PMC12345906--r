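# The four workflows: full grid search, single-config replication,
# distribution comparison, synthetic-table simulation.

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the exhaustive grid search
#'
#' Enumerates the space, evaluates every configuration under the protocol,
#' and writes: the long-format metric records (`records.csv`), the per-config
#' summary with component breakdown and well-performing flag
#' (`summary.csv`), one heatmap matrix per metric (`heatmap_auc.csv`,
#' `heatmap_accuracy.csv`), the best-model report (`best_model.json`) and an
#' append-only log with seeds and grid size (`run.log`).
#'
#' @param table A [feature_table()].
#' @param space A [search_space()] (default: the shipped 4704-config space).
#' @param protocol An [evaluation_protocol()].
#' @param outdir Output directory (created if absent).
#' @param progress Print per-config progress lines.
#' @return Invisibly, a list with `records`, `summaries`, `best`, and the
#'   artifact paths.
#' @export
run_search <- function(table, space = build_default_space(),
                       protocol = evaluation_protocol(), outdir = ".",
                       progress = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  configs <- enumerate_grid(space)
  components <- grid_components(configs)
  log_line(log_path, "grid size ", length(configs),
           "; n=", nrow(table$x), " p=", ncol(table$x),
           "; base_seed=", protocol$base_seed,
           "; n_splits=", protocol$n_splits,
           "; folds=", choose_fold_count(nrow(table$x), protocol$fold_cutoff))
  records <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    records[[i]] <- evaluate_config(configs[[i]], table, protocol)
    if (progress) message(sprintf("[%d/%d] %s", i, length(configs),
                                  configs[[i]]$id))
    log_line(log_path, "evaluated ", configs[[i]]$id)
  }
  records <- do.call(rbind, records)
  summaries <- summarize_records(records, protocol$aggregation_mode)
  best <- select_best(summaries)
  paths <- list(records = file.path(outdir, "records.csv"),
                summary = file.path(outdir, "summary.csv"),
                heatmap_auc = file.path(outdir, "heatmap_auc.csv"),
                heatmap_accuracy = file.path(outdir, "heatmap_accuracy.csv"),
                best = file.path(outdir, "best_model.json"))
  write_records_csv(records, paths$records)
  write_summary_csv(summaries, components, protocol$wp_threshold,
                    paths$summary)
  write_heatmap_csv(heatmap_matrix(summaries, components, "auc",
                                   protocol$wp_threshold), paths$heatmap_auc)
  write_heatmap_csv(heatmap_matrix(summaries, components, "accuracy",
                                   protocol$wp_threshold),
                    paths$heatmap_accuracy)
  best_tbl <- best$table[best$table$config_id == best$best_overall, ]
  jsonlite::write_json(list(
    best_overall = best$best_overall,
    best_by_auc = best$best_by_auc,
    best_by_accuracy = best$best_by_accuracy,
    metrics = list(mean_auc = best_tbl$mean_auc,
                   auc_ci = c(best_tbl$auc_ci_low, best_tbl$auc_ci_high),
                   mean_accuracy = best_tbl$mean_accuracy,
                   accuracy_ci = c(best_tbl$accuracy_ci_low,
                                   best_tbl$accuracy_ci_high)),
    aggregation_mode = protocol$aggregation_mode,
    base_seed = protocol$base_seed),
    paths$best, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_path, "best overall: ", best$best_overall)
  invisible(list(records = records, summaries = summaries, best = best,
                 paths = paths))
}

#' Re-evaluate a single configuration under the protocol
#'
#' The replication workflow: one configuration (e.g. an originally published
#' pipeline) evaluated over the protocol's repeated splits, summarized by
#' default from the split-test values only, emitting the same artifact
#' shapes as [run_search()].
#'
#' @param config A `model_config`.
#' @param table A `feature_table`.
#' @param protocol An `evaluation_protocol`; its `aggregation_mode` is
#'   honoured, defaulting here to `"test_only"`.
#' @param outdir Optional output directory; when given, records and summary
#'   CSVs are written.
#' @return List with `records` and `summaries`.
#' @export
run_replicate <- function(config, table,
                          protocol = evaluation_protocol(
                            aggregation_mode = "test_only"),
                          outdir = NULL) {
  records <- evaluate_config(config, table, protocol)
  summaries <- summarize_records(records, protocol$aggregation_mode)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_records_csv(records, file.path(outdir, "records.csv"))
    utils::write.csv(summaries, file.path(outdir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(records = records, summaries = summaries)
}

#' Compare two performance distributions
#'
#' Extracts one metric's values from two record sets (as produced by
#' [evaluate_config()] / [run_replicate()], or read back from a records
#' CSV) and runs the Mann-Whitney U test.
#'
#' @param records_a,records_b Record data.frames.
#' @param metric `"auc"` or `"accuracy"`.
#' @param stage Restrict to `"test"` records (default) or use `"all"`.
#' @param out_path Optional JSON report path.
#' @return The [mann_whitney_u()] result.
#' @export
run_compare <- function(records_a, records_b, metric = c("auc", "accuracy"),
                        stage = c("test", "all"), out_path = NULL) {
  metric <- match.arg(metric)
  stage <- match.arg(stage)
  pull <- function(r) {
    if (!metric %in% r$metric) stop("metric '", metric, "' absent from records")
    keep <- r$metric == metric & !is.na(r$value)
    if (stage == "test") keep <- keep & r$stage == "test"
    r$value[keep]
  }
  res <- mann_whitney_u(pull(records_a), pull(records_b))
  if (!is.null(out_path))
    jsonlite::write_json(c(res, list(metric = metric, stage = stage)),
                         out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  res
}
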