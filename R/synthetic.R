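# Seeded generator of radiomics-like feature tables with known ground truth:
# unit-variance Gaussian features, a handful of independent informative
# features with a between-class mean shift, and nuisance features in
# equicorrelated blocks (radiomic features from a shared image region are
# strongly mutually correlated).

#' Specification of a synthetic radiomics-like table
#'
#' @param n_samples Number of samples.
#' @param n_features Total number of features.
#' @param n_informative Number of informative features (mutually independent,
#'   class-shifted).
#' @param shift Between-class mean difference of each informative feature, in
#'   standard-deviation units.
#' @param class_fraction Positive-class proportion.
#' @param block_size Size of the equicorrelated nuisance blocks.
#' @param block_rho Within-block correlation of nuisance features, in
#'   \[0, 1).
#' @param seed Integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_samples = 200L, n_features = 50L,
                           n_informative = 4L, shift = 1.0,
                           class_fraction = 0.5, block_size = 5L,
                           block_rho = 0.5, seed = 1L) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must lie in [0, 1)")
  if (class_fraction <= 0 || class_fraction >= 1)
    stop("class_fraction must lie in (0, 1)")
  if (shift < 0) stop("shift must be nonnegative")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 shift = shift, class_fraction = class_fraction,
                 block_size = as.integer(block_size), block_rho = block_rho,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature table with ground truth
#'
#' Labels are assigned to match `class_fraction` to within one sample and
#' shuffled. Informative features are independent unit-variance Gaussians
#' whose class means differ by `shift`; nuisance features are unit-variance
#' Gaussians in equicorrelated blocks of `block_size` with correlation
#' `block_rho`, independent of the label. Fully deterministic given the spec.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `table` (a [feature_table()]) and `truth`
#'   (informative indices, class-conditional means, theoretical optimum AUC).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_features; pi_ <- spec$n_informative
  n_pos <- as.integer(floor(spec$class_fraction * n + 0.5))
  if (n_pos < 2L || n - n_pos < 2L) stop("a class has fewer than two samples")
  y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  x <- matrix(0, n, p)
  info_idx <- sort(sample.int(p, pi_))
  if (pi_ > 0)
    x[, info_idx] <- matrix(stats::rnorm(n * pi_), n, pi_) +
      spec$shift * y  # class 0 at mean 0, class 1 shifted
  noise_idx <- setdiff(seq_len(p), info_idx)
  if (length(noise_idx) > 0) {
    blocks <- split(noise_idx,
                    ceiling(seq_along(noise_idx) / spec$block_size))
    for (b in blocks) {
      shared <- stats::rnorm(n)
      for (j in b)
        x[, j] <- sqrt(spec$block_rho) * shared +
          sqrt(1 - spec$block_rho) * stats::rnorm(n)
    }
  }
  colnames(x) <- sprintf("feat_%03d", seq_len(p))
  tbl <- feature_table(x, y, sample_ids = sprintf("s%03d", seq_len(n)))
  truth <- list(informative = info_idx,
                mean_class0 = rep(0, pi_),
                mean_class1 = rep(spec$shift, pi_),
                optimum_auc = theoretical_auc(spec))
  list(table = tbl, truth = truth)
}

#' Theoretical optimum AUC of a synthetic specification
#'
#' With independent unit-variance informative features and equal class
#' covariance, the Bayes-optimal linear score separates the class means by
#' the Mahalanobis distance `shift * sqrt(n_informative)`, giving an optimum
#' AUC of `pnorm(shift * sqrt(n_informative) / sqrt(2))`.
#'
#' @param spec A `synthetic_spec`.
#' @return AUC in \[0.5, 1).
#' @export
theoretical_auc <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stats::pnorm(spec$shift * sqrt(spec$n_informative) / sqrt(2))
}
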