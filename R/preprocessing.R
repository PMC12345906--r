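# Leakage-safe scaling: parameters come from the training matrix only.

#' Fit per-feature scaling parameters on a training matrix
#'
#' Statistics are computed column-wise from `train_matrix` alone. Degenerate
#' features (zero range, zero standard deviation or zero IQR) get a unit
#' divisor so the transform maps them to a constant instead of dividing by
#' zero, keeping the column index space intact for downstream selection.
#'
#' @param kind Scaler kind: `"none"`, `"minmax"`, `"standard"` or `"robust"`.
#' @param train_matrix Numeric matrix, samples in rows.
#' @return A `scaler_params` object.
#' @export
fit_scaler <- function(kind, train_matrix) {
  kind <- match.arg(kind, SCALER_KINDS)
  x <- as.matrix(train_matrix)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("cannot fit a scaler on an empty matrix")
  if (!is.numeric(x)) stop("train_matrix must be numeric")
  p <- ncol(x)
  params <- switch(kind,
    none = list(),
    minmax = {
      mn <- apply(x, 2, min); mx <- apply(x, 2, max)
      rg <- mx - mn
      rg[rg == 0] <- 1
      list(center = mn, scale = rg)
    },
    standard = {
      mu <- colMeans(x)
      sd_ <- apply(x, 2, stats::sd)
      sd_[sd_ == 0 | is.na(sd_)] <- 1
      list(center = mu, scale = sd_)
    },
    robust = {
      med <- apply(x, 2, stats::median)
      iqr <- apply(x, 2, function(col)
        diff(stats::quantile(col, c(0.25, 0.75), names = FALSE)))
      iqr[iqr == 0] <- 1
      list(center = med, scale = iqr)
    })
  structure(c(list(kind = kind, n_features = p), params),
            class = "scaler_params")
}

#' Apply fitted scaling parameters to a matrix
#'
#' minmax: (x - min) / (max - min); standard: (x - mean) / sd; robust:
#' (x - median) / IQR; none: identity. Values outside the training range are
#' not clipped, so e.g. minmax can produce values outside \[0, 1\] on test
#' rows — deliberate: clipping would destroy the ordering that rank-based
#' AUC relies on.
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param matrix_ Numeric matrix with the same feature count and order as the
#'   fitting matrix.
#' @return The transformed matrix.
#' @export
apply_scaler <- function(params, matrix_) {
  stopifnot(inherits(params, "scaler_params"))
  x <- as.matrix(matrix_)
  if (ncol(x) != params$n_features)
    stop("feature count mismatch: scaler fitted on ", params$n_features,
         " features, matrix has ", ncol(x))
  if (params$kind == "none") return(x)
  sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
}
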