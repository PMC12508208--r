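#' Orientation signal container
#'
#' One channel of sampled angular data (degrees) with its sampling rate and
#' provenance tags. Values may contain `NA` markers for missing samples before
#' preprocessing.
#'
#' @param values numeric vector of angles in degrees (may contain `NA`).
#' @param fs sampling frequency in Hz (the study hardware samples at 100 Hz).
#' @param meta named list of provenance tags (`subject`, `activity`,
#'   `body_part`, `axis`); free-form, may be empty.
#'
#' @return An object of class `orientation_signal`: a list with elements
#'   `values`, `fs`, `meta`.
#' @export
#' @examples
#' s <- orientation_signal(sin(2 * pi * 5 * seq(0, 1, by = 0.01)), fs = 100)
#' length(s$values)
orientation_signal <- function(values, fs = 100, meta = list()) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("orientation_signal: `values` must be numeric of length >= 2")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("orientation_signal: `fs` must be a positive scalar")
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 meta = as.list(meta)),
            class = "orientation_signal")
}

#' @export
print.orientation_signal <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<orientation_signal: %d samples @ %g Hz (%.2f s), %d missing>\n",
              n, x$fs, n / x$fs, sum(is.na(x$values))))
  tags <- x$meta[lengths(x$meta) > 0]
  if (length(tags))
    cat("  ", paste(names(tags), unlist(tags), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.orientation_signal <- function(x) length(x$values)

as_signal_values <- function(x) {
  if (inherits(x, "orientation_signal")) x$values else as.numeric(x)
}

signal_fs <- function(x, fs = NULL) {
  if (inherits(x, "orientation_signal")) x$fs else if (is.null(fs)) 100 else fs
}

#' Time axis of a signal
#'
#' @param signal an [orientation_signal()].
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
signal_time <- function(signal) {
  (seq_along(signal$values) - 1) / signal$fs
}

#' Fraction of periodogram power inside a frequency band
#'
#' Used to check the spectral contracts of the simulator: voluntary motion
#' lives below 3 Hz, tremulous motion between 3 and 10 Hz.
#'
#' @param signal an [orientation_signal()] or numeric vector (no `NA`).
#' @param band length-2 numeric, band edges in Hz (inclusive).
#' @param fs sampling rate, used when `signal` is a bare vector.
#' @return scalar in \[0, 1\]: band power over total power (raw periodogram,
#'   no taper or smoothing).
#' @export
band_power_fraction <- function(signal, band, fs = NULL) {
  x <- as_signal_values(signal)
  fs <- signal_fs(signal, fs)
  if (anyNA(x)) stop("band_power_fraction: signal contains missing values")
  if (all(x == 0)) return(NA_real_)
  pg <- spec.pgram(stats::ts(x, frequency = fs), taper = 0, detrend = FALSE,
                   plot = FALSE)
  inb <- pg$freq >= band[1] & pg$freq <= band[2]
  sum(pg$spec[inb]) / sum(pg$spec)
}

#' Write / read a recording channel as CSV
#'
#' Two columns `t` (seconds) and `value` (degrees); missing samples are empty
#' cells. An optional JSON sidecar (`<path>.json`) stores the provenance tags.
#'
#' @param signal an [orientation_signal()].
#' @param path CSV file path.
#' @param sidecar write `<path>.json` with `fs` and meta tags?
#' @return `path`, invisibly (`write_signal_csv`); an [orientation_signal()]
#'   (`read_signal_csv`).
#' @export
write_signal_csv <- function(signal, path, sidecar = TRUE) {
  df <- data.frame(t = signal_time(signal), value = signal$values)
  write.csv(df, path, row.names = FALSE, na = "")
  if (sidecar) {
    jsonlite::write_json(c(list(fs = signal$fs), signal$meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("t", "value") %in% names(df)))
    stop(sprintf("read_signal_csv: '%s' must have columns `t` and `value`; found: %s",
                 path, paste(names(df), collapse = ", ")))
  meta <- list()
  fs <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    fs <- meta$fs
    meta$fs <- NULL
  }
  if (is.null(fs)) {
    dt <- stats::median(diff(df$t))
    fs <- if (is.finite(dt) && dt > 0) 1 / dt else 100
  }
  orientation_signal(df$value, fs = fs, meta = meta)
}
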