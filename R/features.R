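# The four hand-crafted window features used by the ML baselines:
# instantaneous frequency (Hilbert), kurtosis, crest factor (peak/RMS), and
# sample entropy. Zero-padded window tails are trimmed before computing
# features (padding is a sequence-model convenience, not signal).

hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Mean instantaneous frequency of a window
#'
#' Phase slope of the analytic signal: Hilbert transform, unwrapped phase,
#' mean phase derivative over the window interior (the first and last two
#' samples are trimmed, where the discrete analytic signal is least
#' reliable), divided by 2*pi.
#'
#' @param window numeric vector, length >= 8.
#' @param fs sampling rate, Hz.
#' @return frequency in Hz; a constant window returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
#' @examples
#' t <- seq(0, 0.49, by = 0.01)
#' instantaneous_frequency(sin(2 * pi * 5 * t), fs = 100)  # ~5
instantaneous_frequency <- function(window, fs = 100) {
  x <- as.numeric(window)
  if (length(x) < 8) stop("instantaneous_frequency: window shorter than 8")
  if (max(x) == min(x)) return(structure(0, degenerate = TRUE))
  ph <- Arg(hilbert_analytic(x))
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))  # unwrap increments into (-pi, pi]
  interior <- d[3:(length(d) - 2)]
  structure(mean(interior) * fs / (2 * pi), degenerate = FALSE)
}

#' Pearson (non-excess) kurtosis
#'
#' `m4 / m2^2` with population moments; 3 for a Gaussian, 1.5 for a
#' sinusoid sampled over whole periods.
#'
#' @param window numeric vector with positive variance.
#' @return dimensionless kurtosis; zero-variance windows return `NA` with
#'   attribute `degenerate = TRUE`.
#' @export
kurtosis <- function(window) {
  x <- as.numeric(window)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(structure(NA_real_, degenerate = TRUE))
  structure(mean((x - mean(x))^4) / m2^2, degenerate = FALSE)
}

#' Crest factor: peak magnitude over RMS
#'
#' @param window numeric vector, not all zero.
#' @return `max(|x|) / sqrt(mean(x^2))` (>= 1 for any non-zero window);
#'   all-zero windows return `NA` with attribute `degenerate = TRUE`.
#' @export
peak_to_rms <- function(window) {
  x <- as.numeric(window)
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(structure(NA_real_, degenerate = TRUE))
  structure(max(abs(x)) / rms, degenerate = FALSE)
}

#' Sample entropy
#'
#' `-ln(A / B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` of each other (self-matches excluded) and `A`
#' counts the same for length `m + 1`. The tolerance is `r_ratio` times the
#' sample standard deviation of the window; the standard regularity-analysis
#' defaults `m = 2`, `r_ratio = 0.2` are used. When no length-`(m+1)` match
#' exists (`A = 0`) the value is capped at `ln(B * (B - 1))` (attribute
#' `capped = TRUE`) instead of returning infinity.
#'
#' @param window numeric vector, length >= 10.
#' @param m template length.
#' @param r_ratio tolerance as a fraction of the window's standard deviation.
#' @return entropy in nats (>= 0); zero-variance windows return 0 with
#'   attribute `degenerate = TRUE`.
#' @export
sample_entropy <- function(window, m = 2, r_ratio = 0.2) {
  x <- as.numeric(window)
  n <- length(x)
  if (n < 10) stop("sample_entropy: window shorter than 10")
  s <- sd(x)
  if (s == 0) return(structure(0, degenerate = TRUE))
  r <- r_ratio * s
  count_matches <- function(mm) {
    nt <- n - m  # the standard estimator forms n - m templates of both lengths
    total <- 0L
    for (i in seq_len(nt - 1)) {
      js <- (i + 1):nt
      dmax <- rep(0, length(js))
      for (k in 0:(mm - 1))
        dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
      total <- total + sum(dmax <= r)
    }
    total
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (B == 0) return(structure(0, degenerate = TRUE))
  if (A == 0)
    return(structure(log(B * max(B - 1, 1)), capped = TRUE, degenerate = FALSE))
  structure(-log(A / B), capped = FALSE, degenerate = FALSE)
}

#' Feature vector of one window
#'
#' Computes the four baseline features on the unpadded prefix of a window.
#'
#' @param window numeric vector.
#' @param fs sampling rate, Hz.
#' @param pad_len number of trailing padding zeros to trim before computing.
#' @return named numeric vector `inst_freq`, `kurt`, `peak_rms`, `sampen`.
#' @export
feature_vector <- function(window, fs = 100, pad_len = 0) {
  x <- as.numeric(window)
  if (pad_len > 0) x <- x[seq_len(length(x) - pad_len)]
  c(inst_freq = as.numeric(instantaneous_frequency(x, fs)),
    kurt = as.numeric(kurtosis(x)),
    peak_rms = as.numeric(peak_to_rms(x)),
    sampen = as.numeric(sample_entropy(x)))
}

#' Feature table of a window set
#'
#' One row per window: provenance and label columns from the window set plus
#' the four features. Degenerate windows (zero variance) yield `NA` kurtosis
#' and crest factor.
#'
#' @param ws a `window_set` (see [windows_from_decomposition()]).
#' @param fs sampling rate, Hz.
#' @return data frame: `recording, imf, widx, label, inst_freq, kurt,
#'   peak_rms, sampen` (plus `activity` when present).
#' @export
feature_table <- function(ws, fs = 100) {
  feats <- t(vapply(seq_len(nrow(ws$x)),
                    function(i) feature_vector(ws$x[i, ], fs = fs,
                                               pad_len = ws$meta$pad_len[i]),
                    numeric(4)))
  cbind(ws$meta[c("recording", "imf", "widx", "label",
                  intersect("activity", names(ws$meta)))],
        as.data.frame(feats))
}
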