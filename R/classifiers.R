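# The seven binary classifiers behind a uniform fit/score/label surface.
# Hyperparameters are fixed defaults (no tuning inside the grid); every
# stochastic learner is seeded. Scores are continuous and oriented so that
# larger means more likely positive; labels use each model's native decision
# rule (probability 0.5 / sign of the margin).

drop_constant_cols <- function(x) {
  keep <- which(apply(x, 2, function(col) any(col != col[1])))
  if (length(keep) == 0L) keep <- integer(0)
  keep
}

#' Fit one of the seven grid classifiers
#'
#' Defaults: L2 (ridge) logistic regression; RBF-kernel SVM scored by its
#' continuous margin; 100-tree random forest; 5-nearest-neighbour vote;
#' Gaussian naive Bayes; adaptive boosting of 50 depth-1 CART stumps;
#' gradient boosting with 100 rounds of depth-3 trees.
#'
#' @param kind One of [CLASSIFIER_KINDS].
#' @param x Numeric training matrix.
#' @param y Binary labels (0/1), both classes present.
#' @param seed Integer seed for stochastic learners.
#' @return A `grid_classifier` object for [predict_scores()] /
#'   [predict_labels()].
#' @export
fit_classifier <- function(kind, x, y, seed = 0L) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  x <- as.matrix(x)
  check_binary(y)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  set.seed(seed)
  fit <- switch(kind,
    logistic_regression = fit_ridge_logistic(x, y),
    svm = e1071::svm(x, as.factor(y), kernel = "radial", scale = FALSE,
                     probability = FALSE),
    random_forest = randomForest::randomForest(x, as.factor(y), ntree = 100L),
    knn = list(x = x, y = y, k = min(5L, nrow(x))),
    naive_bayes = fit_gaussian_nb(x, y),
    adaboost = fit_adaboost_stumps(x, y, n_rounds = 50L),
    xgboost = fit_xgb(x, y, seed))
  structure(list(kind = kind, fit = fit, p = ncol(x), seed = seed),
            class = "grid_classifier")
}

fit_ridge_logistic <- function(x, y) {
  if (ncol(x) >= 2L) {
    m <- glmnet::glmnet(x, as.factor(y), family = "binomial", alpha = 0,
                        lambda = 1 / nrow(x), standardize = FALSE)
    list(type = "glmnet", model = m)
  } else {
    d <- data.frame(y = y, f1 = x[, 1])
    m <- suppressWarnings(stats::glm(y ~ f1, data = d, family = stats::binomial()))
    list(type = "glm", model = m)
  }
}

# Gaussian naive Bayes with sklearn-style variance smoothing; immune to
# constant features (which e1071's Gaussian tables turn into NaN densities).
fit_gaussian_nb <- function(x, y) {
  pos <- y == 1L
  v <- rbind(apply(x[!pos, , drop = FALSE], 2, stats::var),
             apply(x[pos, , drop = FALSE], 2, stats::var))
  v[is.na(v)] <- 0
  eps <- 1e-9 * max(apply(x, 2, stats::var), 1e-12)
  list(prior = c(mean(!pos), mean(pos)),
       mu = rbind(colMeans(x[!pos, , drop = FALSE]),
                  colMeans(x[pos, , drop = FALSE])),
       var = v + eps)
}

nb_log_posterior <- function(fit, x) {
  ll <- sapply(1:2, function(g) {
    rowSums(-0.5 * (log(2 * pi * rep(1, nrow(x)) %o% fit$var[g, ]) +
                      sweep(x, 2, fit$mu[g, ])^2 /
                        (rep(1, nrow(x)) %o% fit$var[g, ]))) +
      log(fit$prior[g])
  })
  matrix(ll, nrow = nrow(x))
}

# Discrete AdaBoost (SAMME) over depth-1 CART stumps.
fit_adaboost_stumps <- function(x, y, n_rounds = 50L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y == 1L, 1, -1)
  d <- data.frame(y = factor(y, levels = c(0, 1)), x)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = d, weights = w, method = "class",
                        control = ctrl)
    pred <- ifelse(stats::predict(fit, d, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err <= 1e-10) {  # perfect stump: it alone decides
      stumps <- c(stumps, list(fit)); alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break  # no better than chance under current weights
    a <- 0.5 * log((1 - err) / err)
    stumps <- c(stumps, list(fit)); alphas <- c(alphas, a)
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {  # fall back to the class prior
    stumps <- list(NULL); alphas <- c(if (mean(y) >= 0.5) 1e-3 else -1e-3)
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_margin <- function(fit, x) {
  d <- data.frame(x)
  f <- numeric(nrow(x))
  for (m in seq_along(fit$stumps)) {
    if (is.null(fit$stumps[[m]])) { f <- f + fit$alphas[m]; next }
    pred <- ifelse(stats::predict(fit$stumps[[m]], d, type = "class") == "1",
                   1, -1)
    f <- f + fit$alphas[m] * pred
  }
  f
}

fit_xgb <- function(x, y, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                 nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = 100L,
                     verbose = 0)
}

#' Continuous scores of a fitted classifier
#'
#' Larger score = more likely positive. Probabilities where the model is
#' probabilistic, the decision margin for the SVM and AdaBoost.
#'
#' @param model A `grid_classifier`.
#' @param x Matrix with the same feature count as the training matrix.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "grid_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != model$p) stop("feature count mismatch in predict_scores")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  switch(model$kind,
    logistic_regression = {
      if (model$fit$type == "glmnet")
        as.numeric(stats::predict(model$fit$model, x, type = "response"))
      else
        as.numeric(stats::predict(model$fit$model,
                                  data.frame(f1 = x[, 1]), type = "response"))
    },
    svm = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the margin toward the class named first in the column
      # label "a/b": flip when that class is "0"
      pos_first <- startsWith(colnames(dv)[1], "1")
      if (pos_first) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
    },
    random_forest = as.numeric(stats::predict(model$fit, x,
                                              type = "prob")[, "1"]),
    knn = {
      set.seed(model$seed)
      pred <- class::knn(model$fit$x, x, factor(model$fit$y), k = model$fit$k,
                         prob = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    naive_bayes = {
      lp <- nb_log_posterior(model$fit, x)
      1 / (1 + exp(lp[, 1] - lp[, 2]))
    },
    adaboost = adaboost_margin(model$fit, x),
    xgboost = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x))))
}

#' Hard label predictions of a fitted classifier
#'
#' Each model's native decision rule: probability threshold 0.5 for the
#' probabilistic models, sign of the margin for SVM and AdaBoost.
#'
#' @inheritParams predict_scores
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, x) {
  s <- predict_scores(model, x)
  cut <- if (model$kind %in% c("svm", "adaboost")) 0 else 0.5
  as.integer(s > cut)
}
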