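# Independent brute-force oracles, deliberately written as plain double loops
# so they share no code path with the package implementations they check.

# Sample entropy by direct template counting.
sampen_oracle <- function(x, m = 2, r_ratio = 0.2) {
  n <- length(x)
  r <- r_ratio * sd(x)
  count <- function(mm) {
    nt <- n - m
    tot <- 0L
    for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
      ok <- TRUE
      for (k in 0:(mm - 1)) if (abs(x[i + k] - x[j + k]) > r) { ok <- FALSE; break }
      if (ok) tot <- tot + 1L
    }
    tot
  }
  B <- count(m)
  A <- count(m + 1)
  if (B == 0) return(0)
  if (A == 0) return(log(B * max(B - 1, 1)))  # the documented cap convention
  -log(A / B)
}

# AUC by exhaustive pairwise comparison (ties count one half).
auc_oracle <- function(y, s) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# KNN by exhaustive distances, majority of k (ties by training index).
knn_oracle <- function(train, test, labels, k = 3) {
  out <- integer(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- numeric(nrow(train))
    for (j in seq_len(nrow(train))) d[j] <- sqrt(sum((test[i, ] - train[j, ])^2))
    nb <- order(d, seq_along(d))[1:k]
    out[i] <- as.integer(mean(labels[nb]) >= 0.5)
  }
  out
}
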