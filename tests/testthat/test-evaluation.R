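test_that("fold-count rule switches at the cutoff", {
  expect_identical(choose_fold_count(96), 5L)
  expect_identical(choose_fold_count(124), 10L)
  expect_identical(choose_fold_count(100), 10L)  # "smaller than" excludes 100
  expect_error(choose_fold_count(1), "two samples")
})

test_that("stratified splits are proportional, disjoint and seeded", {
  y <- c(rep(0L, 90), rep(1L, 10))
  plan <- stratified_splits(y, n_splits = 5, test_fraction = 0.1, seed = 3)
  for (s in plan) {
    expect_length(s$test, 10)
    expect_equal(sum(y[s$test] == 0L), 9)
    expect_equal(sum(y[s$test] == 1L), 1)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(y))
  }
  plan2 <- stratified_splits(y, n_splits = 5, test_fraction = 0.1, seed = 3)
  expect_identical(plan, plan2)
  expect_false(identical(plan[[1]]$test, plan[[2]]$test))
  expect_error(stratified_splits(c(rep(0L, 97), rep(1L, 3)), 5, 0.1, 1),
               "too small")
})

test_that("stratified folds partition the training set near-evenly", {
  y <- rep(c(0L, 1L), 50)
  folds <- stratified_folds(y, 10, seed = 4)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 10))
  expect_setequal(unlist(folds), seq_along(y))
  expect_equal(anyDuplicated(unlist(folds)), 0)
  for (f in folds) expect_equal(sum(y[f] == 1L), 5)
  # K above the minority size is reduced with a warning
  y_small <- c(rep(0L, 20), rep(1L, 3))
  expect_warning(folds2 <- stratified_folds(y_small, 5, seed = 1), "reducing")
  expect_length(folds2, 3)
})

test_that("roc_auc matches hand values and handles ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "single class")
  # independent cross-check against pROC's trapezoid AUC
  set.seed(99)
  sc <- rnorm(40); lb <- sample(0:1, 40, replace = TRUE)
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("roc_auc equals the pair-counting oracle on 1000 seeded cases", {
  for (case in 1:1000) {
    set.seed(case)
    n <- sample(4:12, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    # half the cases use coarse scores so ties are frequent
    scores <- if (case %% 2) round(runif(n), 1) else rnorm(n)
    expect_equal(roc_auc(scores, labels), pair_counting_auc(scores, labels))
  }
})

test_that("accuracy is the match fraction", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(accuracy(c(1, 0), c(0, 1)), 0)
  expect_equal(accuracy(c(1, 1, 0, 0), c(1, 1, 0, 1)), 0.75)
  expect_error(accuracy(1, c(1, 0)), "length")
})

test_that("fit_and_score nails a separable toy and honours contracts", {
  tbl <- separable_table(n = 60, margin = 8)
  cfg <- tiny_config()
  idx <- seq_len(60)
  tr <- idx[idx %% 3 != 0]; te <- idx[idx %% 3 == 0]
  res <- fit_and_score(cfg, tbl$x[tr, ], tbl$y[tr], tbl$x[te, ], tbl$y[te],
                       seed = 1)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$auc, 1.0)
  # permuting evaluation labels cannot change the selected features
  res2 <- fit_and_score(cfg, tbl$x[tr, ], tbl$y[tr], tbl$x[te, ],
                        rev(tbl$y[te]), seed = 1)
  expect_identical(res$selected, res2$selected)
})

test_that("level-1 oversampling balances the classifier's training classes", {
  set.seed(30)
  x <- matrix(rnorm(200), 50, 4)
  y <- c(rep(1L, 10), rep(0L, 40))
  rs <- oversample(resampling_spec("random", 1.0), x, y, seed = 2)
  expect_equal(sum(rs$y == 1L), sum(rs$y == 0L))
})

test_that("evaluate_config yields n_splits*(K+1) records per metric, all in [0,1], deterministically", {
  gen <- generate_table(synthetic_spec(n_samples = 110, n_features = 10,
                                       n_informative = 2, seed = 8))
  cfg <- tiny_config(chain = selector_chain(selector_step("mrmr", k = 3)),
                     classifier = "naive_bayes")
  prot <- evaluation_protocol(n_splits = 2, base_seed = 5)
  rec <- evaluate_config(cfg, gen$table, prot)   # n=110 -> K=10
  expect_equal(nrow(rec), 2 * (10 + 1) * 2)
  expect_equal(sum(rec$metric == "auc"), 22)
  expect_true(all(rec$value >= 0 & rec$value <= 1, na.rm = TRUE))
  expect_identical(rec, evaluate_config(cfg, gen$table, prot),
                   ignore_attr = FALSE)
  expect_length(attr(rec, "selected"), 2)
})

test_that("summaries use the pooled distribution with a percentile CI", {
  rec <- data.frame(config_id = "c", split = 1, stage = "test",
                    metric = "auc", value = rep(0.8, 10))
  s <- summarize_records(rec, "pooled")
  expect_equal(s$mean, 0.8)
  expect_equal(s$ci_low, 0.8)
  expect_equal(s$ci_high, 0.8)
  rec2 <- data.frame(config_id = "c", split = 1:2,
                     stage = c("fold1", "test"), metric = "auc",
                     value = c(0.6, 0.8))
  expect_equal(summarize_records(rec2, "pooled")$mean, 0.7)
  expect_equal(summarize_records(rec2, "test_only")$mean, 0.8)
  expect_equal(summarize_records(rec2, "folds_only")$mean, 0.6)

  set.seed(40)
  vals <- runif(20)
  rec3 <- data.frame(config_id = "c", split = 1, stage = "test",
                     metric = "accuracy", value = vals)
  s3 <- summarize_records(rec3, "pooled")
  ci <- sort_interpolate_ci(vals)
  expect_equal(s3$ci_low, ci[1])
  expect_equal(s3$ci_high, ci[2])
  expect_error(summarize_records(rec3[0, ], "pooled"), "no metric values")
})
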