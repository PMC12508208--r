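# The convolutional bi-directional LSTM window classifier and the
# uni-directional convolutional LSTM baseline, trained by plain SGD on binary
# cross-entropy.

#' Architecture specification of the window classifiers
#'
#' The published architecture: conv(30 filters, kernel 20, stride 1, ReLU) ->
#' maxpool(2) -> conv(30 filters, kernel 10, stride 1, ReLU) -> maxpool(2) ->
#' per-time-step single-unit dense (ReLU) -> bi-directional LSTM (64 cells
#' per direction) -> tanh on the LSTM outputs -> single sigmoid output unit.
#'
#' @param conv1_filters,conv1_kernel,conv2_filters,conv2_kernel convolution
#'   sizes (stride is 1).
#' @param pool_size max-pooling size.
#' @param lstm_units LSTM cells per direction.
#' @param padding_mode `"same"` keeps sequence length through the
#'   convolutions (50 -> 25 -> 12 steps into the LSTM); `"valid"` shrinks it
#'   (50 -> 15 -> 3), starving the recurrent layer — provided because the
#'   source description is silent on padding.
#' @param post_lstm_tanh apply the extra tanh to the LSTM outputs before the
#'   output unit (as described), or use them directly.
#' @param input_scaling `"maxabs"` scales each window by its peak magnitude
#'   (bounded inputs keep plain SGD at the stated learning rate stable);
#'   `"none"` feeds raw degrees.
#' @param input_len window length.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(conv1_filters = 30, conv1_kernel = 20,
                            conv2_filters = 30, conv2_kernel = 10,
                            pool_size = 2, lstm_units = 64,
                            padding_mode = c("same", "valid"),
                            post_lstm_tanh = TRUE,
                            input_scaling = c("maxabs", "none"),
                            input_len = 50) {
  sizes <- c(conv1_filters, conv1_kernel, conv2_filters, conv2_kernel,
             pool_size, lstm_units, input_len)
  if (any(sizes <= 0)) stop("classifier_spec: all sizes must be positive")
  structure(list(conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
                 conv2_filters = conv2_filters, conv2_kernel = conv2_kernel,
                 pool_size = pool_size, lstm_units = lstm_units,
                 padding_mode = match.arg(padding_mode),
                 post_lstm_tanh = isTRUE(post_lstm_tanh),
                 input_scaling = match.arg(input_scaling),
                 input_len = input_len),
            class = "classifier_spec")
}

#' Training configuration
#'
#' Plain stochastic gradient descent (no momentum) at learning rate 0.01,
#' binary cross-entropy loss, batch size 64, 100 epochs — the published
#' optimization settings.
#'
#' @param learning_rate SGD step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed RNG seed controlling shuffling.
#' @param decision_threshold sigmoid score at or above which a window is
#'   called tremulous.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 100, batch_size = 64,
                         seed = 0, decision_threshold = 0.5) {
  if (learning_rate <= 0) stop("train_config: learning_rate must be positive")
  if (epochs < 1) stop("train_config: epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 decision_threshold = decision_threshold),
            class = "train_config")
}

# sequence lengths through the network, with a shape trace for errors
shape_trace <- function(spec) {
  L0 <- spec$input_len
  L1 <- conv_out_len(L0, spec$conv1_kernel, spec$padding_mode)
  L2 <- L1 %/% spec$pool_size
  L3 <- conv_out_len(L2, spec$conv2_kernel, spec$padding_mode)
  L4 <- L3 %/% spec$pool_size
  c(input = L0, conv1 = L1, pool1 = L2, conv2 = L3, pool2 = L4)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

lstm_init <- function(units) {
  W <- glorot(1 + units, 4 * units)
  b <- numeric(4 * units)
  b[units + seq_len(units)] <- 1  # forget-gate bias at 1 aids gradient flow
  list(W = W, b = b)
}

build_seq_model <- function(spec, seed, bidirectional) {
  stopifnot(inherits(spec, "classifier_spec"))
  tr <- shape_trace(spec)
  if (any(tr <= 0))
    stop(sprintf(
      "model construction: sequence collapsed to length 0 [shape trace: %s]",
      paste(names(tr), tr, sep = "=", collapse = " -> ")))
  u <- spec$lstm_units
  params <- with_local_seed(seed, {
    p <- list(
      W1 = glorot(spec$conv1_kernel, spec$conv1_filters),
      b1 = numeric(spec$conv1_filters),
      W2 = glorot(spec$conv2_kernel * spec$conv1_filters, spec$conv2_filters),
      b2 = numeric(spec$conv2_filters),
      Wd = glorot(spec$conv2_filters, 1),
      bd = numeric(1),
      lstm_f = lstm_init(u))
    if (bidirectional) p$lstm_b <- lstm_init(u)
    p$Wo <- glorot(if (bidirectional) 2 * u else u, 1)
    p$bo <- numeric(1)
    p
  })
  structure(list(type = if (bidirectional) "conv_bilstm" else "conv_lstm",
                 spec = spec, params = params, seed = seed, trained = FALSE),
            class = "tremor_classifier")
}

#' Build the convolutional bi-directional LSTM
#'
#' Maps a length-50 window to a tremulous-probability in (0, 1). Weights are
#' Glorot-uniform initialized from the seed (forget-gate biases start at 1);
#' two builds with the same seed are identical.
#'
#' @param spec a [classifier_spec()].
#' @param seed integer seed for weight initialization.
#' @return A `tremor_classifier` (untrained).
#' @export
build_conv_bilstm <- function(spec = classifier_spec(), seed = 0)
  build_seq_model(spec, seed, bidirectional = TRUE)

#' Build the uni-directional convolutional LSTM baseline
#'
#' Same convolutional front-end as [build_conv_bilstm()] with a single
#' forward LSTM; strictly fewer parameters.
#'
#' @inheritParams build_conv_bilstm
#' @return A `tremor_classifier` (untrained).
#' @export
build_conv_lstm <- function(spec = classifier_spec(), seed = 0)
  build_seq_model(spec, seed, bidirectional = FALSE)

#' Number of trainable parameters
#' @param model a `tremor_classifier`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, numeric(1)))
                       else length(p)
  as.integer(count(model$params))
}

#' @export
print.tremor_classifier <- function(x, ...) {
  tr <- shape_trace(x$spec)
  cat(sprintf("<%s: %d params, steps %s, %s>\n", x$type, n_params(x),
              paste(tr, collapse = "->"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

scale_windows <- function(X, mode) {
  if (mode == "none") return(X)
  peak <- apply(abs(X), 1, max)
  peak[peak == 0] <- 1
  X / peak
}

model_forward <- function(model, X, cache = FALSE) {
  spec <- model$spec
  p <- model$params
  B <- nrow(X)
  X <- scale_windows(X, spec$input_scaling)
  mode <- spec$padding_mode
  A0 <- matrix(as.vector(X), ncol = 1)  # (B*L) x 1, batch-fastest layout
  L0 <- ncol(X)
  cv1 <- conv1d_forward(A0, B, L0, p$W1, p$b1, mode)
  pl1 <- maxpool2_forward(cv1$A, B, cv1$L_out)
  cv2 <- conv1d_forward(pl1$P, B, pl1$L_out, p$W2, p$b2, mode)
  pl2 <- maxpool2_forward(cv2$A, B, cv2$L_out)
  Zd <- sweep(pl2$P %*% p$Wd, 2, p$bd, "+")
  s <- matrix(pmax(Zd, 0), B, pl2$L_out)  # B x L sequence into the LSTM
  fwd_f <- lstm_forward(s, p$lstm_f$W, p$lstm_f$b, reverse = FALSE)
  hf <- fwd_f$h_final
  if (model$type == "conv_bilstm") {
    fwd_b <- lstm_forward(s, p$lstm_b$W, p$lstm_b$b, reverse = TRUE)
    hcat <- cbind(hf, fwd_b$h_final)
  } else {
    fwd_b <- NULL
    hcat <- hf
  }
  ho <- if (spec$post_lstm_tanh) tanh(hcat) else hcat
  score <- as.vector(sigmoid(ho %*% p$Wo + p$bo[1]))
  if (!cache) return(score)
  list(score = score, X = X, B = B, L0 = L0, cv1 = cv1, pl1 = pl1, cv2 = cv2,
       pl2 = pl2, Zd = Zd, s = s, fwd_f = fwd_f, fwd_b = fwd_b, hcat = hcat,
       ho = ho)
}

model_backward <- function(model, fw, y) {
  spec <- model$spec
  p <- model$params
  B <- fw$B
  mode <- spec$padding_mode
  u <- spec$lstm_units
  dlogit <- matrix((fw$score - y) / B, ncol = 1)   # BCE + sigmoid
  g <- list(Wo = crossprod(fw$ho, dlogit), bo = sum(dlogit))
  dho <- dlogit %*% t(p$Wo)
  dhcat <- if (spec$post_lstm_tanh) dho * (1 - tanh(fw$hcat)^2) else dho
  bk_f <- lstm_backward(dhcat[, seq_len(u), drop = FALSE], fw$fwd_f,
                        p$lstm_f$W)
  g$lstm_f <- list(W = bk_f$dW, b = bk_f$db)
  ds <- bk_f$ds
  if (model$type == "conv_bilstm") {
    bk_b <- lstm_backward(dhcat[, u + seq_len(u), drop = FALSE], fw$fwd_b,
                          p$lstm_b$W)
    g$lstm_b <- list(W = bk_b$dW, b = bk_b$db)
    ds <- ds + bk_b$ds
  }
  dZd <- matrix(as.vector(ds), ncol = 1) * (fw$Zd > 0)
  g$Wd <- crossprod(fw$pl2$P, dZd)
  g$bd <- sum(dZd)
  dP2 <- dZd %*% t(p$Wd)
  dA2 <- maxpool2_backward(dP2, fw$pl2, B, fw$cv2$L_out, spec$conv2_filters)
  bk2 <- conv1d_backward(dA2, fw$cv2, p$W2, B, fw$pl1$L_out,
                         spec$conv1_filters, mode)
  g$W2 <- bk2$dW
  g$b2 <- bk2$db
  dA1 <- maxpool2_backward(bk2$dX, fw$pl1, B, fw$cv1$L_out, spec$conv1_filters)
  bk1 <- conv1d_backward(dA1, fw$cv1, p$W1, B, fw$L0, 1L, mode)
  g$W1 <- bk1$dW
  g$b1 <- bk1$db
  g
}

bce_loss <- function(score, y) {
  eps <- 1e-12
  -mean(y * log(score + eps) + (1 - y) * log(1 - score + eps))
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    if (is.list(params[[nm]])) {
      params[[nm]]$W <- params[[nm]]$W - lr * grads[[nm]]$W
      params[[nm]]$b <- params[[nm]]$b - lr * grads[[nm]]$b
    } else {
      params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    }
  }
  params
}

#' Train a window classifier by mini-batch SGD
#'
#' Shuffled mini-batches, plain SGD, binary cross-entropy. Training aborts
#' with diagnostics if the loss turns non-finite. Deterministic given
#' `(model seed, data, cfg seed)`.
#'
#' @param model an untrained (or trained) `tremor_classifier`.
#' @param x matrix of windows (rows) of length `spec$input_len`.
#' @param y binary labels (1 = tremulous).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss?
#' @return The trained model; element `history` holds the per-epoch mean
#'   training loss.
#' @export
train_model <- function(model, x, y, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "tremor_classifier"))
  if (ncol(x) != model$spec$input_len)
    stop(sprintf("train_model: window length %d != spec input_len %d",
                 ncol(x), model$spec$input_len))
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("train_model: training set must contain both classes")
  n <- nrow(x)
  history <- numeric(cfg$epochs)
  params <- model$params
  with_local_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1, n)]
        model$params <- params
        fw <- model_forward(model, x[idx, , drop = FALSE], cache = TRUE)
        loss <- bce_loss(fw$score, y[idx])
        if (!is.finite(loss))
          stop(sprintf(
            "train_model: non-finite loss at epoch %d (batch at %d); %s",
            ep, start, "reduce the learning rate or check the inputs"))
        losses <- c(losses, loss)
        grads <- model_backward(model, fw, y[idx])
        params <- sgd_step(params, grads, cfg$learning_rate)
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %3d/%d  loss %.5f", ep, cfg$epochs, history[ep]))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$history <- history
  model$train_config <- cfg
  model
}

#' Predict tremulous probability for windows
#'
#' Deterministic forward pass; a window is labeled tremulous when its score
#' is at or above the threshold (ties at the threshold go to the positive
#' class).
#'
#' @param object a `tremor_classifier`.
#' @param x matrix of windows (rows).
#' @param threshold decision threshold on the sigmoid score.
#' @param ... unused.
#' @return list with `score` (in (0, 1)) and `label` (0/1 integer).
#' @export
predict.tremor_classifier <- function(object, x, threshold = 0.5, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$spec$input_len)
    stop(sprintf("predict: window length %d != spec input_len %d",
                 ncol(x), object$spec$input_len))
  score <- model_forward(object, x)
  list(score = score, label = as.integer(score >= threshold))
}
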