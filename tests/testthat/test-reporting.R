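make_summaries <- function(df) {
  # df: config_id, auc, acc
  rbind(
    data.frame(config_id = df$config_id, metric = "auc", mean = df$auc,
               ci_low = df$auc - 0.05, ci_high = df$auc + 0.05,
               n_values = 10, mode = "pooled"),
    data.frame(config_id = df$config_id, metric = "accuracy", mean = df$acc,
               ci_low = df$acc - 0.05, ci_high = df$acc + 0.05,
               n_values = 10, mode = "pooled"))
}

test_that("well-performing filter is inclusive at the boundary, on both metrics", {
  s <- make_summaries(data.frame(
    config_id = c("a", "b", "c"),
    auc = c(0.71, 0.71, 0.69),
    acc = c(0.70, 0.69, 0.95)))
  kept <- filter_well_performing(s, 0.7)
  expect_identical(kept$config_id, "a")
  expect_equal(nrow(filter_well_performing(s, 0)), 3)
  expect_equal(nrow(filter_well_performing(s, 0.99)), 0)
})

test_that("best-model selection maximizes the metric average with canonical ties", {
  s <- make_summaries(data.frame(config_id = c("a", "b"),
                                 auc = c(0.9, 0.85), acc = c(0.8, 0.88)))
  expect_identical(select_best(s)$best_overall, "b")  # 0.865 > 0.85
  # exact tie on average and AUC -> lexicographically smaller id
  s2 <- make_summaries(data.frame(config_id = c("zed", "abc"),
                                  auc = c(0.8, 0.8), acc = c(0.8, 0.8)))
  expect_identical(select_best(s2)$best_overall, "abc")
  expect_identical(select_best(s2[sample(nrow(s2)), ])$best_overall, "abc")
  s3 <- make_summaries(data.frame(config_id = "only", auc = 0.6, acc = 0.9))
  b3 <- select_best(s3)
  expect_identical(b3$best_overall, "only")
  expect_identical(b3$best_by_auc, "only")
  # metric-specific bests can differ
  s4 <- make_summaries(data.frame(config_id = c("a", "b"),
                                  auc = c(0.9, 0.7), acc = c(0.7, 0.9)))
  b4 <- select_best(s4)
  expect_identical(b4$best_by_auc, "a")
  expect_identical(b4$best_by_accuracy, "b")
  expect_error(select_best(make_summaries(data.frame(config_id = character(0),
                                                     auc = numeric(0),
                                                     acc = numeric(0)))))
})

test_that("heatmap cells hold the pair's best well-performing mean, else NA", {
  s <- make_summaries(data.frame(
    config_id = c("s1|corr0.9|random0|knn", "s2|corr0.9|random0.5|knn",
                  "s1|lasso1|random0|svm"),
    auc = c(0.8, 0.75, 0.65), acc = c(0.8, 0.78, 0.66)))
  comp <- data.frame(
    config_id = c("s1|corr0.9|random0|knn", "s2|corr0.9|random0.5|knn",
                  "s1|lasso1|random0|svm"),
    scaler = c("standard", "minmax", "standard"),
    chain = c("corr0.9", "corr0.9", "lasso1"),
    resampling = c("random0", "random0.5", "random0"),
    classifier = c("knn", "knn", "svm"))
  m <- heatmap_matrix(s, comp, "auc", 0.7)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["corr0.9", "knn"], 0.8)      # max over the pair's configs
  expect_true(is.na(m["lasso1", "svm"]))      # below threshold -> blank
  expect_true(is.na(m["lasso1", "knn"]))
  expect_true(all(m[!is.na(m)] >= 0.7))
  m_mean <- heatmap_matrix(s, comp, "auc", 0.7, aggregate = "mean")
  expect_equal(m_mean["corr0.9", "knn"], 0.775)
})

test_that("Mann-Whitney U matches hand-computed exact cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p, 1 / 3)
  expect_identical(r$method, "exact")
  r2 <- mann_whitney_u(c(1, 2), c(1, 2))        # full ties: U = n_a*n_b/2
  expect_equal(r2$u, 2)
  expect_equal(r2$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("U is antisymmetric and the exact p matches full enumeration", {
  for (case in 1:200) {
    set.seed(case)
    n_a <- sample(1:5, 1); n_b <- sample(1:5, 1)
    vals <- sample(1:50, n_a + n_b)             # distinct integers: no ties
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    got <- mann_whitney_u(a, b)
    want <- enumeration_mw(a, b)
    expect_equal(got$u, want$u)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$u + mann_whitney_u(b, a)$u, n_a * n_b)
  }
})

test_that("large or tied samples use the tie-corrected normal approximation", {
  set.seed(60)
  a <- rnorm(30); b <- rnorm(30, 1)
  r <- mann_whitney_u(a, b)
  expect_identical(r$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$u, unname(ref$statistic))
  expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  # ties route to the approximation even for small n
  rt <- mann_whitney_u(c(1, 2, 2), c(2, 3))
  expect_identical(rt$method, "normal_approx")
  expect_true(r$p > 0 && r$p <= 1)
})
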