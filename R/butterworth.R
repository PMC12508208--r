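# Butterworth reference filters. No DSP package ships with the supported R
# stack, so the 4th-order designs (band-pass 3-10 Hz for tremulous motion,
# low-pass 3 Hz for voluntary motion) are derived here from the analog
# prototype via the bilinear transform, and zero-phase filtering follows the
# usual odd-extension forward-backward scheme with steady-state initial
# conditions. The IIR inner loop is compiled (src/emd.cpp).

poly_from_roots <- function(roots) {
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0) - c(0, p) * r  # multiply by (z - r)
  p
}

#' Butterworth filter specification
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param cutoffs_hz two band edges (bandpass) or one cutoff (lowpass), Hz.
#' @param order analog prototype order (the study's benchmark uses 4).
#' @param zero_phase apply forward-backward (zero phase distortion, squared
#'   magnitude response)? `FALSE` gives the causal single-pass filter.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), cutoffs_hz,
                        order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  need <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs_hz) != need)
    stop(sprintf("filter_spec: %s needs %d cutoff(s)", kind, need))
  if (any(cutoffs_hz <= 0) || is.unsorted(cutoffs_hz, strictly = TRUE) &&
      need == 2L)
    stop("filter_spec: cutoffs must be positive and increasing")
  structure(list(kind = kind, cutoffs_hz = cutoffs_hz, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Tremulous / voluntary benchmark filter specs
#'
#' The reference extraction filters: a 4th-order Butterworth band-pass with
#' 3-10 Hz cutoffs for tremulous motion and a 4th-order low-pass at 3 Hz for
#' voluntary motion.
#'
#' @param zero_phase see [filter_spec()].
#' @return a `filter_spec`.
#' @export
tremor_benchmark_spec <- function(zero_phase = TRUE)
  filter_spec("bandpass", c(3, 10), order = 4, zero_phase = zero_phase)

#' @rdname tremor_benchmark_spec
#' @export
voluntary_benchmark_spec <- function(zero_phase = TRUE)
  filter_spec("lowpass", 3, order = 4, zero_phase = zero_phase)

#' Digital Butterworth coefficients
#'
#' Analog Butterworth prototype (poles on the unit semicircle), low-pass or
#' band-pass transformed with pre-warped edge frequencies, then mapped to the
#' z-domain by the bilinear transform.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz. Cutoffs must lie below `fs / 2`.
#' @return list with numerator `b` and denominator `a` (with `a[1] = 1`).
#' @export
butter_coefficients <- function(spec, fs) {
  if (any(spec$cutoffs_hz >= fs / 2))
    stop("butter_coefficients: cutoff at or above the Nyquist frequency")
  n <- spec$order
  fs2 <- 2 * fs
  # analog prototype: n poles, no zeros, gain 1
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warped <- fs2 * tan(pi * spec$cutoffs_hz / fs)
  if (spec$kind == "lowpass") {
    wc <- warped[1]
    pa <- wc * p
    za <- complex(0)
    ka <- wc^n
  } else {
    w0 <- sqrt(prod(warped))
    bw <- diff(warped)
    pb <- bw * p / 2
    disc <- sqrt(pb^2 - w0^2)
    pa <- c(pb + disc, pb - disc)
    za <- rep(0 + 0i, n)
    ka <- bw^n
  }
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pa) / (fs2 - pa)
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  zd <- c(zd, rep(-1 + 0i, length(pa) - length(za)))
  list(b = Re(kd * poly_from_roots(zd)), a = Re(poly_from_roots(pd)))
}

#' Filter magnitude response
#'
#' @param coef list with `b`, `a` as from [butter_coefficients()].
#' @param f_hz frequencies to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector `|H(f)|`.
#' @export
filter_magnitude <- function(coef, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  ztf <- function(c, w) vapply(w, function(wi)
    sum(c * exp(-1i * wi * (seq_along(c) - 1))), complex(1))
  Mod(ztf(coef$b, w) / ztf(coef$a, w))
}

# steady-state initial filter state for a unit-step input (so filtfilt edges
# settle inside the padding)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  bb <- c(b, numeric(n - length(b)))
  aa <- c(a, numeric(n - length(a)))
  if (n == 1) return(numeric(0))
  comp_t <- rbind(-aa[-1] / aa[1],
                  cbind(diag(1, n - 2), numeric(n - 2)))  # companion(a)^T? no:
  # companion matrix C has first row -a[2:n]/a[1] and ones on the subdiagonal;
  # comp_t above is C itself; the state recursion uses t(C).
  IminusA <- diag(1, n - 1) - t(comp_t)
  B <- bb[-1] - aa[-1] * bb[1]
  solve(IminusA, B)
}

apply_iir <- function(coef, x, zero_phase = TRUE) {
  b <- coef$b
  a <- coef$a
  if (!zero_phase)
    return(iir_filter_cpp(b, a, x, numeric(max(length(a), length(b)) - 1)))
  edge <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= edge)
    stop("apply_iir: signal too short for zero-phase edge padding")
  ext <- c(2 * x[1] - x[(edge + 1):2], x, 2 * x[n] - x[(n - 1):(n - edge)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(edge + 1):(edge + n)]
}

#' Extract a benchmark component with a Butterworth filter
#'
#' Applies the designed filter to a preprocessed signal. Zero-phase
#' (forward-backward) application is the default so benchmark components have
#' no phase shift relative to the input; set `zero_phase = FALSE` in the spec
#' for the causal variant.
#'
#' @param signal an [orientation_signal()] or numeric vector (no `NA`).
#' @param spec a [filter_spec()]; see [tremor_benchmark_spec()].
#' @param fs sampling rate when `signal` is a bare vector.
#' @return Filtered signal of the same type and length.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 1 * t)
#' trem <- butterworth_extract(x, tremor_benchmark_spec(), fs = 100)
butterworth_extract <- function(signal, spec, fs = NULL) {
  fs <- signal_fs(signal, fs)
  x <- as_signal_values(signal)
  if (anyNA(x)) stop("butterworth_extract: missing values; preprocess first")
  coef <- butter_coefficients(spec, fs)
  y <- apply_iir(coef, x, zero_phase = spec$zero_phase)
  if (inherits(signal, "orientation_signal")) {
    signal$values <- y
    signal
  } else y
}
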