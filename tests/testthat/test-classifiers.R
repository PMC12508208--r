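# The conv-biLSTM, its uni-directional baseline, and the feature-based ML
# baselines.

toy_tone_windows <- function(f, n, seed) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    ph <- runif(1, 0, 2 * pi)
    runif(1, 0.5, 2) * sin(2 * pi * f * (0:49) / 100 + ph)
  }, numeric(50)))
}

test_that("shape propagation matches the published architecture", {
  tr <- tremorsep:::shape_trace(classifier_spec())
  expect_equal(unname(tr), c(50, 50, 25, 25, 12))
  trv <- tremorsep:::shape_trace(classifier_spec(padding_mode = "valid"))
  expect_equal(unname(trv), c(50, 31, 15, 6, 3))
  # a window too short for valid padding fails with a shape trace
  expect_error(build_conv_bilstm(classifier_spec(padding_mode = "valid",
                                                 input_len = 30)),
               "shape trace")
})

test_that("builds are seed-deterministic and outputs live strictly in (0,1)", {
  m1 <- build_conv_bilstm(seed = 42)
  m2 <- build_conv_bilstm(seed = 42)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, build_conv_bilstm(seed = 43)$params))

  x <- matrix(rnorm(20 * 50), 20, 50)
  p <- predict(m1, x)
  expect_true(all(p$score > 0 & p$score < 1))
  expect_identical(p$label, as.integer(p$score >= 0.5))
  expect_identical(predict(m1, x)$score, p$score)  # repeated calls agree
  # batch prediction equals sample-by-sample prediction
  one_by_one <- vapply(seq_len(nrow(x)),
                       function(i) predict(m1, x[i, ])$score, numeric(1))
  expect_equal(one_by_one, p$score, tolerance = 1e-12)
  expect_error(predict(m1, matrix(0, 2, 49)), "length")
})

test_that("the uni-directional baseline has strictly fewer parameters", {
  expect_lt(n_params(build_conv_lstm(seed = 1)),
            n_params(build_conv_bilstm(seed = 1)))
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("tremorsep")
  spec <- classifier_spec(conv1_filters = 4, conv1_kernel = 5,
                          conv2_filters = 3, conv2_kernel = 3,
                          lstm_units = 6, input_len = 20,
                          input_scaling = "none")
  set.seed(11)
  x <- matrix(rnorm(8 * 20), 8, 20)
  y <- rep(c(0, 1), 4)
  eps <- 1e-6
  for (builder in list(build_conv_bilstm, build_conv_lstm)) {
    m <- builder(spec, seed = 2)
    fw <- ns$model_forward(m, x, cache = TRUE)
    g <- ns$model_backward(m, fw, y)
    loss_at <- function(mm) ns$bce_loss(ns$model_forward(mm, x), y)
    for (nm in names(g)) {
      ga <- if (is.list(g[[nm]])) g[[nm]]$W else g[[nm]]
      v <- if (is.list(m$params[[nm]])) m$params[[nm]]$W else m$params[[nm]]
      idx <- which(abs(ga) == max(abs(ga)))[1]  # check the dominant gradient
      bump <- function(delta) {
        mm <- m
        if (is.list(mm$params[[nm]])) mm$params[[nm]]$W[idx] <- v[idx] + delta
        else mm$params[[nm]][idx] <- v[idx] + delta
        loss_at(mm)
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      expect_equal(ga[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  x <- rbind(toy_tone_windows(6, 40, 1), toy_tone_windows(1, 40, 2))
  y <- rep(c(1, 0), each = 40)
  cfg <- train_config(epochs = 3, seed = 9)
  m <- train_model(build_conv_bilstm(seed = 5), x, y, cfg)
  m2 <- train_model(build_conv_bilstm(seed = 5), x, y, cfg)
  expect_identical(m$params, m2$params)
  expect_true(all(is.finite(m$history)))
  expect_error(train_model(build_conv_bilstm(seed = 1), x, rep(1, 80)),
               "both classes")
})

test_that("the network overfits a separable toy problem within 100 epochs", {
  # 400 windows give plain SGD at the fixed published learning rate enough
  # updates per epoch; smaller sets can stall inside the epoch budget
  x <- rbind(toy_tone_windows(6, 200, 1), toy_tone_windows(1, 200, 2))
  y <- rep(c(1, 0), each = 200)
  m <- train_model(build_conv_bilstm(seed = 5), x, y,
                   train_config(epochs = 100, seed = 9))
  expect_lt(m$history[length(m$history)], m$history[1])
  expect_gte(mean(predict(m, x)$label == y), 0.99)
})

test_that("KNN matches the exhaustive-distance oracle and its contracts", {
  set.seed(23)
  train <- matrix(rnorm(60 * 4), 60, 4)
  labels <- rbinom(60, 1, 0.5)
  test <- matrix(rnorm(50 * 4), 50, 4)
  # oracle on unstandardized features; disable scaling for exact comparison
  expect_identical(knn_baseline(train, test, labels, standardize = FALSE),
                   knn_oracle(train, test, labels))

  # a test point duplicating a training point present three times
  tri <- rbind(matrix(0, 3, 2), matrix(10, 30, 2))
  lab <- c(1, 1, 1, rep(0, 30))
  expect_identical(knn_baseline(tri, matrix(0, 1, 2), lab), 1L)

  # two well-separated clusters classify perfectly
  cl <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 10), 20, 2))
  cly <- rep(c(0, 1), each = 20)
  expect_identical(knn_baseline(cl, cl, cly), as.integer(cly))
  expect_error(knn_baseline(cl[1:2, ], cl, cly[1:2]), "exceeds")
})

test_that("Gaussian naive Bayes recovers the closed-form decision boundary", {
  set.seed(24)
  train <- matrix(c(rnorm(400, 0), rnorm(400, 4)), ncol = 1)
  y <- rep(c(0, 1), each = 400)
  grid <- matrix(seq(0, 4, by = 0.01), ncol = 1)
  g <- gnb_baseline(train, grid, y)
  boundary <- grid[which(diff(g$label) == 1) + 1]
  expect_equal(boundary, 2, tolerance = 0.2)
  expect_equal(unname(rowSums(g$posterior)), rep(1, nrow(grid)),
               tolerance = 1e-12)

  # symmetric classes, equidistant point: tie resolved to the positive class
  sym <- matrix(c(-2, -1, 1, 2), ncol = 1)
  gs <- gnb_baseline(sym, matrix(0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(gs$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(gs$label, 1L)
  expect_error(gnb_baseline(sym, sym, rep(1, 4)), "both classes")
})
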