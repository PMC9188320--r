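# The seven classical classifiers behind one train/predict surface, plus
# report-level 5-fold cross-validated hyperparameter selection.

bow_classifiers <- function() {
  c("lr", "lasso", "ridge", "svm", "knn", "nb", "rf")
}

# Classifiers that see standardized features (train-set mean/sd on the six
# structured columns; tf-idf is already unit-normalized). Trees and the
# multinomial NB take raw features (NB requires non-negative counts).
scaled_classifiers <- function() c("lr", "lasso", "ridge", "svm", "knn")

scale_structured <- function(x, scaling = NULL) {
  k <- min(n_structured_features(), ncol(x))
  if (is.null(scaling)) {
    mu <- colMeans(x[, 1:k, drop = FALSE])
    sg <- apply(x[, 1:k, drop = FALSE], 2, sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    scaling <- list(mu = mu, sd = sg)
  }
  x[, 1:k] <- sweep(sweep(x[, 1:k, drop = FALSE], 2, scaling$mu), 2,
                    scaling$sd, `/`)
  list(x = x, scaling = scaling)
}

#' Train a bag-of-words classifier
#'
#' Fits one of the seven classical classifiers as a 3-class model exposing
#' per-class probability scores. Defaults follow the canonical
#' configuration: unpenalized logistic regression; L1/L2-penalized
#' multinomial logistic models with lambda = 0.01; a polynomial-kernel SVM
#' with probability calibration; kNN with k = 3; multinomial Naive Bayes
#' with additive smoothing alpha = 0.5; a 500-tree random forest with
#' sqrt(d) features per split.
#'
#' @param x Feature matrix from [featurize()].
#' @param y Labels (character or factor with levels from
#'   [class_labels()]).
#' @param clf One of `"lr"`, `"lasso"`, `"ridge"`, `"svm"`, `"knn"`,
#'   `"nb"`, `"rf"`.
#' @param params Named list of hyperparameter overrides (`lambda`, `k`,
#'   `alpha`, `num_trees`, `cost`, `degree`).
#' @param seed Seed for the stochastic learners.
#' @return Object of class `bow_model`.
#' @export
train_bow <- function(x, y, clf = "rf", params = list(), seed = 1L) {
  clf <- match.arg(clf, bow_classifiers())
  y <- factor(as.character(y), levels = class_labels())
  assert_that(nlevels(droplevels(y)) >= 2,
              "training data must contain at least 2 classes")
  scaling <- NULL
  if (clf %in% scaled_classifiers()) {
    sc <- scale_structured(x)
    x <- sc$x
    scaling <- sc$scaling
  }
  fit <- with_seed(seed, switch(
    clf,
    lr = nnet::multinom(y ~ ., data = data.frame(y = y, x = I(x)),
                        MaxNWts = 100000, maxit = 200, trace = FALSE),
    # fit along a decreasing lambda path (required for stable convergence)
    # and predict at the target penalty
    lasso = glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                           lambda = glmnet_path(params$lambda %||% 0.01)),
    ridge = glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                           lambda = glmnet_path(params$lambda %||% 0.01)),
    svm = e1071::svm(x, y, kernel = "polynomial",
                     degree = params$degree %||% 3,
                     cost = params$cost %||% 1,
                     probability = TRUE, scale = FALSE),
    knn = caret::knn3(x, y, k = params$k %||% 3),
    nb = fit_multinomial_nb(x, y, alpha = params$alpha %||% 0.5),
    rf = ranger::ranger(x = x, y = y,
                        num.trees = params$num_trees %||% 500,
                        probability = TRUE, seed = seed,
                        num.threads = 1, verbose = FALSE)))
  structure(list(clf = clf, fit = fit, scaling = scaling,
                 params = params, seed = seed,
                 lambda = if (clf %in% c("lasso", "ridge")) params$lambda %||% 0.01,
                 classes = class_labels()),
            class = "bow_model")
}

glmnet_path <- function(lambda, length.out = 20) {
  exp(seq(log(max(1, lambda * 100)), log(lambda), length.out = length.out))
}

# Multinomial Naive Bayes with additive (Laplace-alpha) smoothing; features
# must be non-negative (term counts / weights and layout magnitudes).
fit_multinomial_nb <- function(x, y, alpha = 0.5) {
  assert_that(all(x >= 0), "multinomial NB requires non-negative features")
  classes <- levels(y)
  logprior <- log(prop.table(table(y) + 0))
  loglik <- matrix(0, length(classes), ncol(x),
                   dimnames = list(classes, colnames(x)))
  for (c in classes) {
    fs <- colSums(x[y == c, , drop = FALSE]) + alpha
    loglik[c, ] <- log(fs / sum(fs))
  }
  structure(list(logprior = as.numeric(logprior), loglik = loglik,
                 classes = classes, alpha = alpha),
            class = "multinomial_nb")
}

predict_multinomial_nb <- function(fit, x) {
  lp <- x %*% t(fit$loglik)
  lp <- sweep(lp, 2, fit$logprior, `+`)
  lp <- lp - apply(lp, 1, max)
  p <- exp(lp)
  p / rowSums(p)
}

#' Per-class probability scores from a fitted model
#'
#' @param object A `bow_model` or `seq_model`.
#' @param x Feature matrix (bag-of-words) or candidate tibble (sequence
#'   models).
#' @param ... Unused.
#' @return Numeric matrix, one column per class in [class_labels()].
#' @export
predict_scores <- function(object, x, ...) UseMethod("predict_scores")

#' @export
predict_scores.bow_model <- function(object, x, ...) {
  if (!is.null(object$scaling)) {
    x <- scale_structured(x, object$scaling)$x
  }
  p <- switch(
    object$clf,
    lr = predict(object$fit, newdata = data.frame(x = I(x)), type = "probs"),
    lasso = ,
    ridge = predict(object$fit, newx = x, type = "response",
                    s = object$lambda)[, , 1],
    svm = attr(predict(object$fit, x, probability = TRUE), "probabilities"),
    knn = predict(object$fit, x, type = "prob"),
    nb = predict_multinomial_nb(object$fit, x),
    rf = predict(object$fit, data = x, num.threads = 1)$predictions)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  # align columns to the canonical order; classes absent from training get 0
  out <- matrix(0, nrow(p), length(object$classes),
                dimnames = list(NULL, object$classes))
  common <- intersect(colnames(p), object$classes)
  out[, common] <- p[, common]
  out
}

#' Report-level k-fold cross-validation over a hyperparameter grid
#'
#' Reports (never individual segments) are partitioned into `k` seeded
#' folds; each grid point is scored by mean fold segment-level accuracy;
#' the best point (ties resolved by grid order) is refit on the full
#' development set.
#'
#' @param x Development feature matrix.
#' @param y Development labels.
#' @param report_ids Report id per row of `x`.
#' @param clf Classifier name.
#' @param grid List of hyperparameter lists (non-empty).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List with `best_params`, `model` (refit on all of `x`),
#'   `cv` (tibble of grid point vs mean fold accuracy), `folds`.
#' @export
cross_validate <- function(x, y, report_ids, clf, grid = list(list()),
                           k = 5, seed = 1L) {
  assert_that(length(grid) >= 1, "hyperparameter grid must be non-empty")
  ids <- unique(report_ids)
  assert_that(length(ids) >= k, "fewer reports than folds")
  fold_of <- with_seed(seed, {
    setNames(rep_len(seq_len(k), length(ids))[sample.int(length(ids))], ids)
  })
  fold <- fold_of[report_ids]
  acc <- numeric(length(grid))
  for (g in seq_along(grid)) {
    fa <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- train_bow(x[tr, , drop = FALSE], y[tr], clf, grid[[g]], seed = seed)
      p <- predict_scores(m, x[!tr, , drop = FALSE])
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      fa[f] <- mean(pred == as.character(y[!tr]))
    }
    acc[g] <- mean(fa)
  }
  best <- which.max(acc)  # first maximum = first in grid order on ties
  list(best_params = grid[[best]],
       model = train_bow(x, y, clf, grid[[best]], seed = seed),
       cv = tibble(grid_point = seq_along(grid), mean_accuracy = acc),
       folds = fold_of)
}

#' @export
print.bow_model <- function(x, ...) {
  cat("<bow_model> classifier '", x$clf, "', classes ",
      paste(x$classes, collapse = "/"), "\n", sep = "")
  invisible(x)
}
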