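# Independent brute-force oracles used to pin expected values. Each oracle
# recomputes its quantity from first principles, sharing no code with the
# implementation it checks.

# AUC by exhaustive enumeration of positive-negative pairs, ties = 1/2.
pair_counting_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n, n_a)
# equally likely assignments of the pooled tie-free values to sample a.
enumeration_mw <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">"))
  u_obs <- u_of(a, b)
  mu <- n_a * length(b) / 2
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu)))
}

# Greedy mRMR by brute force: recompute the full criterion for every
# remaining candidate at every step (F-statistic relevance via stats::aov,
# redundancy via stats::cor), ties to the lowest index.
greedy_mrmr_oracle <- function(x, y, k) {
  p <- ncol(x)
  relevance <- vapply(seq_len(p), function(j) {
    fit <- summary(stats::aov(x[, j] ~ factor(y)))[[1]]
    f <- fit[["F value"]][1]
    if (is.na(f)) 0 else f
  }, numeric(1))
  selected <- integer(0)
  for (step in seq_len(min(k, p))) {
    best <- NA_integer_; best_score <- -Inf
    for (j in setdiff(seq_len(p), selected)) {
      red <- if (length(selected) == 0) 0
      else mean(vapply(selected, function(s) {
        r <- suppressWarnings(stats::cor(x[, j], x[, s]))
        if (is.na(r)) 0 else abs(r)
      }, numeric(1)))
      score <- relevance[j] - red
      if (score > best_score + 1e-12) { best <- j; best_score <- score }
    }
    selected <- c(selected, best)
  }
  selected
}

# 2.5th/97.5th percentiles by explicit sort-and-interpolate between order
# statistics: h = (n - 1) p + 1, linear between floor(h) and ceiling(h).
sort_interpolate_ci <- function(values) {
  s <- sort(values)
  n <- length(s)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(one(0.025), one(0.975))
}

# A tiny linearly separable table: two Gaussian clusters far apart on the
# first two features, pure noise elsewhere.
separable_table <- function(n = 60, p = 5, margin = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + margin * y
  x[, 2] <- x[, 2] - margin * y
  colnames(x) <- paste0("feat_", seq_len(p))
  feature_table(x, y)
}

tiny_config <- function(scaler = "none",
                        chain = selector_chain(selector_step("correlation")),
                        resampling = resampling_spec("random", 0),
                        classifier = "logistic_regression") {
  model_config(scaler, chain, resampling, classifier)
}
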