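# Minority oversampling: duplication or SMOTE interpolation, training rows
# only (the evaluation harness applies it after feature selection).

#' Target minority count for a fractional oversampling level
#'
#' The level is the fraction of the minority-majority count gap to close:
#' the target is `n_min + round(level * (n_maj - n_min))` with half-up
#' rounding.
#'
#' @param n_min Minority class count.
#' @param n_maj Majority class count (`n_min <= n_maj`).
#' @param level Fraction in \[0, 1\].
#' @return Integer target minority count.
#' @export
minority_target_count <- function(n_min, n_maj, level) {
  if (n_min > n_maj) stop("n_min exceeds n_maj; swap which class is minority")
  if (level < 0 || level > 1) stop("level must lie in [0, 1]")
  as.integer(n_min + floor(level * (n_maj - n_min) + 0.5))
}

minority_class <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present for oversampling")
  # ties (balanced classes): call class 1 the minority; level then adds 0 rows
  if (tab[["1"]] <= tab[["0"]]) 1L else 0L
}

new_resampled_set <- function(x, y, x_new, origin, minority) {
  structure(list(
    x = rbind(x, x_new),
    y = c(y, rep(minority, nrow(x_new))),
    n_added = nrow(x_new),
    origin = origin), class = "resampled_set")
}

#' Random minority oversampling by duplication
#'
#' Appends uniformly drawn (with replacement, seeded) copies of minority rows
#' until the minority count reaches [minority_target_count()]. Original rows
#' are untouched and come first.
#'
#' @param x Training matrix.
#' @param y Binary labels (0/1).
#' @param level Fraction of the class-count gap to close.
#' @param seed Integer seed.
#' @return A `resampled_set` with fields `x`, `y`, `n_added`, `origin`.
#' @export
random_oversample <- function(x, y, level, seed = 0L) {
  x <- as.matrix(x)
  minority <- minority_class(y)
  min_idx <- which(y == minority)
  target <- minority_target_count(length(min_idx), length(y) - length(min_idx),
                                  level)
  n_new <- target - length(min_idx)
  if (n_new == 0L)
    return(new_resampled_set(x, y, x[0, , drop = FALSE], list(), minority))
  set.seed(seed)
  src <- sample(min_idx, n_new, replace = TRUE)
  new_resampled_set(x, y, x[src, , drop = FALSE],
                    lapply(src, function(i) list(copied = i)), minority)
}

#' SMOTE minority oversampling
#'
#' Each appended row is `x + u * (x' - x)` where `x` is a seeded-random
#' minority row, `x'` one of its `k_neighbors` nearest minority neighbours
#' (Euclidean distance) and `u` uniform on \[0, 1\]. The neighbourhood shrinks
#' to `n_min - 1` when the minority class is smaller than `k_neighbors + 1`,
#' and a singleton minority falls back to duplication.
#'
#' @inheritParams random_oversample
#' @param k_neighbors Neighbourhood size.
#' @return A `resampled_set`; `origin` records parent pair and weight.
#' @export
smote_oversample <- function(x, y, level, k_neighbors = 5L, seed = 0L) {
  x <- as.matrix(x)
  minority <- minority_class(y)
  min_idx <- which(y == minority)
  n_min <- length(min_idx)
  target <- minority_target_count(n_min, length(y) - n_min, level)
  n_new <- target - n_min
  if (n_new == 0L)
    return(new_resampled_set(x, y, x[0, , drop = FALSE], list(), minority))
  if (n_min == 1L) {  # nothing to interpolate with: duplicate
    set.seed(seed)
    src <- rep(min_idx, n_new)
    return(new_resampled_set(x, y, x[src, , drop = FALSE],
                             lapply(src, function(i) list(copied = i)),
                             minority))
  }
  k <- min(as.integer(k_neighbors), n_min - 1L)
  xm <- x[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  # k nearest minority neighbours of each minority row (ties by index)
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- matrix(nn, nrow = k)
  set.seed(seed)
  base <- sample.int(n_min, n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  x_new <- matrix(0, n_new, ncol(x))
  origin <- vector("list", n_new)
  for (i in seq_len(n_new)) {
    b <- base[i]
    nb <- nn[pick[i], b]
    x_new[i, ] <- xm[b, ] + u[i] * (xm[nb, ] - xm[b, ])
    origin[[i]] <- list(parents = c(min_idx[b], min_idx[nb]), weight = u[i])
  }
  new_resampled_set(x, y, x_new, origin, minority)
}

#' Oversample according to a resampling specification
#'
#' @param spec A `resampling_spec`.
#' @inheritParams random_oversample
#' @return A `resampled_set`.
#' @export
oversample <- function(spec, x, y, seed = 0L) {
  stopifnot(inherits(spec, "resampling_spec"))
  if (spec$method == "smote")
    smote_oversample(x, y, spec$level, spec$k_neighbors, seed)
  else random_oversample(x, y, spec$level, seed)
}
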