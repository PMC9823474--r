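#' Classifier configuration
#'
#' Bundles the classifier family and its hyperparameters. Defaults follow
#' the benchmark settings: RBF-kernel SVM with `C = 1`, `gamma = 1e-3`; MLP
#' with one hidden layer of 100 units; random forest of 100 trees with Gini
#' splitting (also used by the single decision tree); Gaussian naive Bayes
#' with variance smoothing `1e-9`; 3-nearest-neighbors with uniform weights.
#' AdaBoost (SAMME over depth-1 trees) and quadratic discriminant analysis
#' are available but were the weakest performers and are excluded from
#' headline comparisons.
#'
#' @param kind One of `"svm"`, `"mlp"`, `"random_forest"`,
#'   `"decision_tree"`, `"gaussian_nb"`, `"knn"`, `"adaboost"`, `"qda"`.
#' @param seed Integer seed fixed for training reproducibility.
#' @param svm_cost,svm_gamma SVM hyperparameters.
#' @param mlp_hidden,mlp_maxit MLP hidden-layer width and iteration cap.
#' @param rf_trees Number of random-forest trees.
#' @param nb_smoothing Gaussian naive Bayes variance smoothing, as a
#'   fraction of the largest feature variance.
#' @param knn_k Number of neighbors.
#' @param ada_rounds AdaBoost boosting rounds.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("svm", "mlp", "random_forest",
                                       "decision_tree", "gaussian_nb",
                                       "knn", "adaboost", "qda"),
                              seed = 1L,
                              svm_cost = 1.0, svm_gamma = 1e-3,
                              mlp_hidden = 100L, mlp_maxit = 100L,
                              rf_trees = 100L,
                              nb_smoothing = 1e-9,
                              knn_k = 3L,
                              ada_rounds = 50L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed),
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 mlp_hidden = mlp_hidden, mlp_maxit = mlp_maxit,
                 rf_trees = rf_trees, nb_smoothing = nb_smoothing,
                 knn_k = knn_k, ada_rounds = ada_rounds),
            class = "classifier_config")
}

#' Train a frame classifier on a feature matrix
#'
#' Dispatches to the requested classifier family with the configured
#' hyperparameters. Training is deterministic given the configuration seed.
#' The returned handle predicts with [predict.eye_classifier()] and is
#' serializable with `saveRDS()` (k-NN stores its training set, as the
#' method requires).
#'
#' @param features Numeric matrix, one row per frame.
#' @param labels Factor or character vector of frame labels (>= 2 classes).
#' @param config A [classifier_config()].
#' @return An object of class `eye_classifier`.
#' @export
train_classifier <- function(features, labels,
                             config = classifier_config()) {
  stopifnot(is.matrix(features))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("training set must contain at least two classes")
  if (length(labels) != nrow(features))
    stop("features and labels disagree in length")
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- with_seed(config$seed, switch(
    config$kind,
    svm = e1071::svm(features, labels, kernel = "radial",
                     cost = config$svm_cost, gamma = config$svm_gamma,
                     scale = FALSE, cachesize = 512),
    mlp = nnet::nnet(features, nnet::class.ind(labels),
                     size = config$mlp_hidden, softmax = TRUE,
                     maxit = config$mlp_maxit,
                     MaxNWts = 1e7, trace = FALSE),
    random_forest = randomForest::randomForest(features, labels,
                                               ntree = config$rf_trees),
    decision_tree = rpart::rpart(
      label ~ ., data = data.frame(label = labels, features),
      method = "class", parms = list(split = "gini")),
    gaussian_nb = nb_fit(features, labels, config$nb_smoothing),
    knn = list(x = features, y = labels, k = config$knn_k),
    adaboost = ada_fit(features, labels, config$ada_rounds),
    qda = MASS::qda(features, labels)
  ))
  structure(list(kind = config$kind, fit = fit, levels = levels(labels),
                 n_features = ncol(features), config = config),
            class = "eye_classifier")
}

# Gaussian naive Bayes with scikit-style variance smoothing: every
# per-class variance is raised by `smoothing` times the largest feature
# variance, which also guards constant-within-class features.
nb_fit <- function(features, labels, smoothing) {
  eps <- smoothing * max(apply(features, 2, stats::var))
  classes <- levels(labels)
  stats_by_class <- lapply(classes, function(cl) {
    x <- features[labels == cl, , drop = FALSE]
    list(mean = colMeans(x),
         var = apply(x, 2, stats::var) + eps,
         logprior = log(nrow(x) / nrow(features)))
  })
  names(stats_by_class) <- classes
  stats_by_class
}

nb_predict <- function(fit, features) {
  scores <- vapply(fit, function(s) {
    -0.5 * colSums((t(features) - s$mean)^2 / s$var) -
      0.5 * sum(log(2 * pi * s$var)) + s$logprior
  }, numeric(nrow(features)))
  if (nrow(features) == 1) scores <- matrix(scores, 1)
  names(fit)[max.col(scores, ties.method = "first")]
}

# multiclass AdaBoost (SAMME) over depth-1 rpart stumps
ada_fit <- function(features, labels, rounds) {
  n <- length(labels)
  K <- nlevels(labels)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  dat <- data.frame(label = labels, features)
  for (m in seq_len(rounds)) {
    stump <- rpart::rpart(label ~ ., data = dat, weights = w,
                          method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = -1,
                                                         minsplit = 2,
                                                         xval = 0))
    pred <- predict(stump, dat, type = "class")
    err <- sum(w * (pred != labels)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != labels))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    if (err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(labels))
}

ada_predict <- function(fit, newdata) {
  votes <- matrix(0, nrow(newdata), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  df <- data.frame(newdata)
  for (m in seq_along(fit$stumps)) {
    pred <- as.character(predict(fit$stumps[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(votes)), match(pred, fit$levels))] <-
      votes[cbind(seq_len(nrow(votes)), match(pred, fit$levels))] +
      fit$alphas[m]
  }
  fit$levels[max.col(votes, ties.method = "first")]
}

#' Predict frame labels from a trained classifier
#'
#' @param object An `eye_classifier` from [train_classifier()].
#' @param newdata Numeric feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.eye_classifier <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features)
    stop("feature dimensionality (", ncol(newdata),
         ") does not match the trained model (", object$n_features, ")")
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  out <- switch(
    object$kind,
    svm = as.character(predict(object$fit, newdata)),
    mlp = {
      p <- predict(object$fit, newdata)
      colnames(p)[max.col(p, ties.method = "first")]
    },
    random_forest = as.character(predict(object$fit, newdata)),
    decision_tree = as.character(
      predict(object$fit, data.frame(newdata), type = "class")),
    gaussian_nb = nb_predict(object$fit, newdata),
    knn = with_seed(object$config$seed,
                    as.character(class::knn(object$fit$x, newdata,
                                            object$fit$y,
                                            k = object$fit$k))),
    adaboost = ada_predict(object$fit, newdata),
    qda = as.character(predict(object$fit, newdata)$class)
  )
  factor(out, levels = object$levels)
}

#' Evaluate a classifier on a labeled feature matrix
#'
#' @param model An `eye_classifier`.
#' @param features Numeric feature matrix.
#' @param labels True labels.
#' @param time_per_frame If `TRUE`, additionally times single-frame
#'   predictions one at a time (see [measure_sfpt()]) and reports timing
#'   statistics.
#' @return A list with `accuracy`, `confusion` (true labels in rows),
#'   `n`, and optionally `timing`.
#' @export
evaluate_classifier <- function(model, features, labels,
                                time_per_frame = FALSE) {
  labels <- factor(labels, levels = union(model$levels, unique(labels)))
  pred <- predict(model, features)
  pred <- factor(as.character(pred), levels = levels(labels))
  confusion <- table(truth = labels, prediction = pred)
  out <- list(accuracy = mean(as.character(pred) == as.character(labels)),
              confusion = confusion, n = length(labels))
  if (time_per_frame) {
    rows <- lapply(seq_len(nrow(features)),
                   function(i) features[i, , drop = FALSE])
    out$timing <- measure_sfpt(function(x) predict(model, x), rows)
  }
  out
}
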