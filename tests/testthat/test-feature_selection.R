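test_that("correlation filter drops redundant columns, keep-first", {
  set.seed(5)
  a <- rnorm(200)
  x <- cbind(a, b = a, c = rnorm(200))
  expect_identical(correlation_filter(x, 0.9), c(1L, 3L))
  x_ind <- matrix(rnorm(600), 200, 3)
  expect_identical(correlation_filter(x_ind, 0.9), 1:3)
  x_same <- cbind(a, a, a)
  expect_identical(correlation_filter(x_same, 0.9), 1L)
  # kept pairs all satisfy |r| <= threshold
  set.seed(6)
  z <- matrix(rnorm(100 * 12), 100, 12)
  z[, 5] <- z[, 1] + rnorm(100, sd = 0.05)
  kept <- correlation_filter(z, 0.8)
  r <- abs(cor(z[, kept]))
  diag(r) <- 0
  expect_true(all(r <= 0.8))
})

test_that("mrmr base case and exhaustion follow the greedy contract", {
  set.seed(7)
  n <- 80
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[, 3] <- x[, 3] + 2 * y  # dominant relevance
  first <- mrmr_select(x, y, 1)
  expect_identical(first, 3L)
  all_of_them <- mrmr_select(x, y, 99)
  expect_setequal(all_of_them, 1:5)
  expect_identical(all_of_them[1], 3L)
  expect_error(mrmr_select(x, rep(0, n), 2), "both classes")
})

test_that("mrmr matches the exhaustive greedy oracle on random instances", {
  mismatches <- 0
  for (case in 1:150) {
    set.seed(case)
    n <- sample(20:40, 1)
    p <- sample(2:8, 1)
    k <- sample(1:4, 1)
    y <- c(rep(0L, n %/% 2), rep(1L, n - n %/% 2))
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + runif(1, 0, 1.5) * y
    got <- mrmr_select(x, y, k)
    want <- greedy_mrmr_oracle(x, y, k)
    if (!identical(got, want)) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("lasso keeps planted signal and falls back under heavy shrinkage", {
  set.seed(9)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[, 4] <- x[, 4] + 2.5 * y
  sel <- lasso_select(x, y, penalty = 1.0)
  expect_true(4L %in% sel)
  # extreme penalty: everything shrunk away -> single-feature fallback
  sel_hi <- lasso_select(x, y, penalty = 1e6)
  expect_length(sel_hi, 1)
  expect_identical(sel_hi, 4L)  # strongest univariate association
  # weak penalty keeps (nearly) all features
  sel_lo <- lasso_select(x, y, penalty = 1e-4)
  expect_gte(length(sel_lo), 8)
})

test_that("rf importance selection is seeded and finds planted signal", {
  set.seed(10)
  n <- 100
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8)
  x[, 6] <- x[, 6] + 3 * y
  expect_identical(rf_importance_select(x, y, 1, seed = 3), 6L)
  expect_identical(rf_importance_select(x, y, 4, seed = 3),
                   rf_importance_select(x, y, 4, seed = 3))
  expect_setequal(rf_importance_select(x, y, 99, seed = 3), 1:8)
})

test_that("chains compose with original-index bookkeeping and nesting", {
  set.seed(12)
  n <- 150
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[, 2] <- x[, 1]            # duplicate dropped by correlation
  x[, 5] <- x[, 5] + 2 * y    # planted signal

  single <- apply_chain(selector_chain(selector_step("correlation")), x, y)
  expect_identical(single$selected, correlation_filter(x, 0.9))

  ch <- selector_chain(selector_step("correlation"),
                       selector_step("mrmr", k = 2))
  res <- apply_chain(ch, x, y)
  expect_length(res$per_step[[1]]$survivors, 5)    # duplicate gone
  expect_length(res$selected, 2)
  expect_true(all(res$selected %in% res$per_step[[1]]$survivors))
  expect_true(5L %in% res$selected)                # original-space index
  expect_false(2L %in% res$per_step[[1]]$survivors)

  full <- apply_chain(selector_chain(selector_step("correlation"),
                                     selector_step("mrmr", k = 3),
                                     selector_step("lasso")), x, y)
  expect_true(5L %in% full$selected)
  # nesting of survivors across steps
  for (i in 2:length(full$per_step))
    expect_true(all(full$per_step[[i]]$survivors %in%
                      full$per_step[[i - 1]]$survivors))
})

test_that("selection never reads evaluation rows", {
  set.seed(13)
  n <- 100
  y <- rep(0:1, n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  ch <- selector_chain(selector_step("correlation"),
                       selector_step("mrmr", k = 3))
  sel1 <- apply_chain(ch, x[1:80, ], y[1:80])$selected
  # changing rows outside the training window must not matter
  x2 <- x; x2[81:100, ] <- matrix(rnorm(200, 50), 20, 10)
  sel2 <- apply_chain(ch, x2[1:80, ], y[1:80])$selected
  expect_identical(sel1, sel2)
})
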