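# Preprocessing: shape-preserving cubic Hermite interpolation of missing
# samples, then whole-record linear detrending — the two steps applied to the
# raw orientation data before decomposition.

#' Fill missing samples by piecewise cubic Hermite interpolation
#'
#' Missing (`NA`) interior samples are replaced by values of the
#' shape-preserving piecewise cubic Hermite interpolant through the present
#' samples (Fritsch-Carlson monotone Hermite, `stats::splinefun(method =
#' "monoH.FC")`). Present samples are returned unchanged. Endpoints must be
#' present: interpolation is never extrapolation.
#'
#' @param signal an [orientation_signal()] (or numeric vector).
#' @return An object of the same type with no missing values.
#' @export
interpolate_missing <- function(signal) {
  x <- as_signal_values(signal)
  miss <- is.na(x)
  if (!any(miss)) return(signal)
  if (miss[1] || miss[length(x)])
    stop("interpolate_missing: endpoint sample is missing; cannot extrapolate")
  if (sum(!miss) < 2)
    stop("interpolate_missing: fewer than 2 present samples")
  idx <- seq_along(x)
  f <- splinefun(idx[!miss], x[!miss], method = "monoH.FC")
  x[miss] <- f(idx[miss])
  if (inherits(signal, "orientation_signal")) {
    signal$values <- x
    signal
  } else x
}

#' Remove the least-squares linear trend
#'
#' Subtracts the ordinary least-squares straight line fitted over the whole
#' record, leaving a signal with zero mean and zero least-squares slope.
#'
#' @param signal an [orientation_signal()] (or numeric vector) with no
#'   missing values.
#' @return An object of the same type, detrended.
#' @export
detrend_linear <- function(signal) {
  x <- as_signal_values(signal)
  n <- length(x)
  if (n < 2) stop("detrend_linear: need at least 2 samples")
  if (anyNA(x))
    stop("detrend_linear: missing values present; interpolate first")
  t <- seq_len(n) - (n + 1) / 2           # centred time axis
  slope <- sum(t * x) / sum(t * t)        # OLS on centred predictor
  out <- x - mean(x) - slope * t
  if (inherits(signal, "orientation_signal")) {
    signal$values <- out
    signal
  } else out
}

#' Standard preprocessing chain
#'
#' [interpolate_missing()] followed by [detrend_linear()], the order fixed
#' because detrending requires complete data.
#'
#' @inheritParams interpolate_missing
#' @return Preprocessed signal of the same type and length.
#' @export
preprocess_signal <- function(signal) {
  detrend_linear(interpolate_missing(signal))
}
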