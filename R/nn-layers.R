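# Primitive layers for the sequence classifiers, batch-vectorized in base R.
#
# Activation layout convention: a sequence activation with C channels over L
# time steps for a batch of B windows is a (B*L) x C matrix whose row index is
# b + (t-1)*B ("batch fastest"). array(x, c(B, L, C)) round-trips this layout.

sigmoid <- function(x) 1 / (1 + exp(-x))

# rows of the layout corresponding to the given time steps
rows_at <- function(B, times) as.vector(outer(seq_len(B), (times - 1L) * B, "+"))

conv_pad_sizes <- function(k, mode) {
  if (mode == "same") {
    pl <- (k - 1L) %/% 2L
    c(pl, k - 1L - pl)
  } else c(0L, 0L)
}

conv_out_len <- function(L, k, mode) {
  if (mode == "same") L else L - k + 1L
}

# im2col: unfold a (B*L) x C sequence into (B*L_out) x (k*C) patches.
# Column block j (j = 1..k) holds the input advanced by j-1 steps.
im2col <- function(A, B, L, k, mode) {
  C <- ncol(A)
  pad <- conv_pad_sizes(k, mode)
  Lp <- L + pad[1] + pad[2]
  Lo <- conv_out_len(L, k, mode)
  Ap <- matrix(0, B * Lp, C)
  Ap[rows_at(B, pad[1] + seq_len(L)), ] <- A
  Xc <- matrix(0, B * Lo, k * C)
  for (j in seq_len(k))
    Xc[, (seq_len(C) - 1L) * k + j] <- Ap[rows_at(B, j - 1L + seq_len(Lo)), ]
  Xc
}

# col2im: scatter-add patch gradients back onto the input sequence.
col2im <- function(dXc, B, L, k, C, mode) {
  pad <- conv_pad_sizes(k, mode)
  Lp <- L + pad[1] + pad[2]
  Lo <- conv_out_len(L, k, mode)
  dAp <- matrix(0, B * Lp, C)
  for (j in seq_len(k)) {
    r <- rows_at(B, j - 1L + seq_len(Lo))
    dAp[r, ] <- dAp[r, ] + dXc[, (seq_len(C) - 1L) * k + j]
  }
  dAp[rows_at(B, pad[1] + seq_len(L)), , drop = FALSE]
}

conv1d_forward <- function(A, B, L, W, b, mode) {
  k <- nrow(W) / ncol(A)
  Xc <- im2col(A, B, L, k, mode)
  Z <- sweep(Xc %*% W, 2, b, "+")
  list(A = pmax(Z, 0), Z = Z, Xc = Xc, L_out = conv_out_len(L, k, mode))
}

conv1d_backward <- function(dA, cache, W, B, L_in, C_in, mode) {
  dZ <- dA * (cache$Z > 0)
  k <- nrow(W) / C_in
  list(dW = crossprod(cache$Xc, dZ), db = colSums(dZ),
       dX = col2im(dZ %*% t(W), B, L_in, k, C_in, mode))
}

maxpool2_forward <- function(A, B, L) {
  Lo <- L %/% 2L
  A1 <- A[rows_at(B, 2L * seq_len(Lo) - 1L), , drop = FALSE]
  A2 <- A[rows_at(B, 2L * seq_len(Lo)), , drop = FALSE]
  mask <- A1 >= A2
  list(P = pmax(A1, A2), mask = mask, L_out = Lo)
}

maxpool2_backward <- function(dP, cache, B, L_in, C) {
  Lo <- cache$L_out
  dA <- matrix(0, B * L_in, C)
  dA[rows_at(B, 2L * seq_len(Lo) - 1L), ] <- dP * cache$mask
  dA[rows_at(B, 2L * seq_len(Lo)), ] <- dP * !cache$mask
  dA
}

# One LSTM direction over a (B x L) single-feature sequence `s`.
# Gate order in the fused weight matrix: input, forget, cell, output.
# W: (1 + units) x (4*units), rows = [x; h_prev].
lstm_forward <- function(s, W, b, reverse = FALSE) {
  B <- nrow(s)
  L <- ncol(s)
  units <- ncol(W) / 4L
  h <- matrix(0, B, units)
  cc <- matrix(0, B, units)
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  cache <- vector("list", L)
  for (si in seq_along(steps)) {
    t <- steps[si]
    xt <- s[, t]
    Z <- sweep(cbind(xt, h) %*% W, 2, b, "+")
    i <- sigmoid(Z[, seq_len(units), drop = FALSE])
    f <- sigmoid(Z[, units + seq_len(units), drop = FALSE])
    g <- tanh(Z[, 2L * units + seq_len(units), drop = FALSE])
    o <- sigmoid(Z[, 3L * units + seq_len(units), drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    cache[[si]] <- list(t = t, xt = xt, h_prev = h_prev, c_prev = c_prev,
                        i = i, f = f, g = g, o = o, c = cc)
  }
  list(h_final = h, cache = cache, steps = steps)
}

# Backprop the gradient at the final hidden state through time; returns
# weight gradients and the gradient on the input sequence.
lstm_backward <- function(dh_final, fwd, W) {
  units <- ncol(W) / 4L
  B <- nrow(dh_final)
  L <- length(fwd$cache)
  dW <- matrix(0, nrow(W), ncol(W))
  db <- numeric(ncol(W))
  ds <- matrix(0, B, L)
  dh <- dh_final
  dc <- matrix(0, B, units)
  for (si in rev(seq_len(L))) {
    cc <- fwd$cache[[si]]
    tc <- tanh(cc$c)
    do_ <- dh * tc
    dc <- dc + dh * cc$o * (1 - tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cbind(cc$xt, cc$h_prev), dZ)
    db <- db + colSums(dZ)
    dxh <- dZ %*% t(W)
    ds[, cc$t] <- dxh[, 1]
    dh <- dxh[, -1, drop = FALSE]
    dc <- dc * cc$f
  }
  list(dW = dW, db = db, ds = ds)
}
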