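# Feature-based baseline classifiers: k-nearest neighbours (Euclidean, k = 3)
# and Gaussian naive Bayes, operating on the four hand-crafted features.

#' Standardize feature matrices with training statistics
#'
#' Per-feature z-scores using the training set's means and standard
#' deviations (test data uses the same statistics; zero-variance features are
#' left centred only).
#'
#' @param train,test numeric feature matrices (columns = features).
#' @return list with standardized `train` and `test` matrices.
#' @export
standardize_features <- function(train, test) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  mu <- colMeans(train)
  sigma <- apply(train, 2, sd)
  sigma[sigma == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sigma, "/"),
       test = sweep(sweep(test, 2, mu), 2, sigma, "/"))
}

#' k-nearest-neighbour baseline
#'
#' Majority vote among the `k` nearest training points by Euclidean distance
#' on standardized features; distance ties are broken toward the lower
#' training index.
#'
#' @param train_features,test_features numeric feature matrices.
#' @param train_labels binary labels for the training rows.
#' @param k neighbourhood size (the baseline uses 3).
#' @param standardize z-score the features with training statistics first?
#' @return integer vector of predicted labels for the test rows.
#' @export
knn_baseline <- function(train_features, test_features, train_labels, k = 3,
                         standardize = TRUE) {
  if (k > nrow(as.matrix(train_features)))
    stop("knn_baseline: k exceeds the training-set size")
  if (standardize) {
    st <- standardize_features(train_features, test_features)
    train_features <- st$train
    test_features <- st$test
  } else {
    train_features <- as.matrix(train_features)
    test_features <- as.matrix(test_features)
  }
  tr2 <- rowSums(train_features^2)
  labs <- as.integer(train_labels)
  apply_one <- function(i) {
    d2 <- tr2 - 2 * as.vector(train_features %*% test_features[i, ])
    ord <- order(d2, seq_along(d2))  # stable: ties to lower training index
    as.integer(mean(labs[ord[seq_len(k)]]) >= 0.5)
  }
  vapply(seq_len(nrow(test_features)), apply_one, integer(1))
}

#' Gaussian naive Bayes baseline
#'
#' Class-conditional independent Gaussians per feature with class priors from
#' the training frequencies; per-class per-feature variances are floored at
#' `1e-9`. A posterior tie is resolved toward the positive class.
#'
#' @inheritParams knn_baseline
#' @return list with `label` (integer predictions) and `posterior` (matrix
#'   of class probabilities, columns `0` and `1`, rows summing to 1).
#' @export
gnb_baseline <- function(train_features, test_features, train_labels) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  y <- as.integer(train_labels)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("gnb_baseline: training set must contain both classes")
  loglik <- vapply(classes, function(cl) {
    Xc <- train_features[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- pmax(apply(Xc, 2, var), 1e-9)
    prior <- mean(y == cl)
    ll <- -0.5 * sweep(sweep(test_features, 2, mu)^2, 2, v, "/")
    rowSums(sweep(ll, 2, 0.5 * log(2 * pi * v))) + log(prior)
  }, numeric(nrow(test_features)))
  loglik <- matrix(loglik, ncol = length(classes))
  post <- exp(loglik - apply(loglik, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- as.character(classes)
  # argmax with ties toward the positive (higher) class
  pick <- max.col(post, ties.method = "last")
  list(label = as.integer(classes[pick]), posterior = post)
}
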