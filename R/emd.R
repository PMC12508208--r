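# Empirical mode decomposition (sifting with a Cauchy-type stoppage
# criterion) and its noise-assisted ensemble variant (EEMD). The sifting core
# lives in src/emd.cpp; this file owns configuration, validation, the
# ensemble loop, and the decomposition container.

#' EMD configuration
#'
#' @param stoppage_threshold threshold on the Cauchy-type sifting criterion
#'   `D_j = sum|h_{j-1} - h_j|^2 / sum|h_{j-1}|^2`; sifting stops when
#'   `D_j` falls below it. The source method leaves the value unspecified;
#'   0.2 is the conventional choice.
#' @param max_siftings cap on sifting iterations per IMF (guards
#'   non-convergence).
#' @param max_imfs cap on the number of extracted IMFs.
#' @param min_extrema minimum number of maxima (and minima) required to sift;
#'   below it the residual is declared monotone.
#' @return list of class `emd_config`.
#' @export
emd_config <- function(stoppage_threshold = 0.2, max_siftings = 50,
                       max_imfs = 12, min_extrema = 2) {
  if (stoppage_threshold <= 0 || max_siftings <= 0 || max_imfs <= 0 ||
      min_extrema <= 0)
    stop("emd_config: all parameters must be positive")
  structure(list(stoppage_threshold = stoppage_threshold,
                 max_siftings = as.integer(max_siftings),
                 max_imfs = as.integer(max_imfs),
                 min_extrema = as.integer(min_extrema)),
            class = "emd_config")
}

#' EEMD configuration
#'
#' @param emd an [emd_config()] used for each ensemble member.
#' @param n_ensembles number of white-noise realizations N.
#' @param noise_std_ratio standard deviation of the added white noise as a
#'   fraction of the input signal's standard deviation. The conventional
#'   0.2 / N = 100 pairing is the default.
#' @param seed integer; ensemble member n draws its noise from `seed + n`.
#' @return list of class `eemd_config`.
#' @export
eemd_config <- function(emd = emd_config(), n_ensembles = 100,
                        noise_std_ratio = 0.2, seed = 0) {
  if (n_ensembles < 1) stop("eemd_config: n_ensembles must be >= 1")
  if (noise_std_ratio < 0) stop("eemd_config: noise_std_ratio must be >= 0")
  structure(list(emd = emd, n_ensembles = as.integer(n_ensembles),
                 noise_std_ratio = noise_std_ratio, seed = as.integer(seed)),
            class = "eemd_config")
}

#' Locate strict local extrema
#'
#' Three-point comparison; runs of equal values (plateaus) are compressed and
#' contribute their midpoint index once. Endpoints never qualify.
#'
#' @param x numeric vector (length >= 3 for any extremum to exist).
#' @return list with integer vectors `maxima` and `minima` (1-based indices).
#' @export
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0))  # maximum at 2, minimum at 4
find_extrema <- function(x) {
  x <- as_signal_values(x)
  if (anyNA(x)) stop("find_extrema: missing values present")
  if (length(x) < 3) return(list(maxima = integer(0), minima = integer(0)))
  find_extrema_cpp(x)
}

#' Mean of the upper and lower spline envelopes
#'
#' Natural cubic splines through the maxima (upper) and minima (lower), each
#' extended by mirroring the two nearest extrema about the signal endpoints to
#' suppress edge swing, evaluated on the full support and averaged pointwise.
#'
#' @param x numeric vector.
#' @param maxima,minima 1-based extrema indices, e.g. from [find_extrema()];
#'   computed when omitted. At least 2 of each are required.
#' @return numeric vector `m(t)` of `length(x)`.
#' @export
envelope_mean <- function(x, maxima = NULL, minima = NULL) {
  x <- as_signal_values(x)
  if (is.null(maxima) || is.null(minima)) {
    ex <- find_extrema(x)
    maxima <- ex$maxima
    minima <- ex$minima
  }
  envelope_mean_cpp(x, as.integer(maxima), as.integer(minima))
}

#' Cauchy-type sifting stoppage criterion
#'
#' `D = sum_t |h_prev(t) - h_curr(t)|^2 / sum_t |h_prev(t)|^2`.
#'
#' @param h_prev,h_curr consecutive temporary IMFs (equal length; `h_prev`
#'   must not be identically zero).
#' @return scalar `D`.
#' @export
stoppage_criterion <- function(h_prev, h_curr) {
  if (length(h_prev) != length(h_curr))
    stop("stoppage_criterion: length mismatch")
  den <- sum(h_prev^2)
  if (den == 0) stop("stoppage_criterion: h_prev has zero energy")
  sum((h_prev - h_curr)^2) / den
}

#' Sift one intrinsic mode function
#'
#' Iterates `h <- h - envelope_mean(h)` until the stoppage criterion drops
#' below `cfg$stoppage_threshold` or `cfg$max_siftings` is reached.
#'
#' @param x numeric vector with at least 2 maxima and 2 minima.
#' @param cfg an [emd_config()].
#' @return list with `imf` (numeric vector) and `n_sifts` (integer).
#' @export
sift_one_imf <- function(x, cfg = emd_config()) {
  x <- as_signal_values(x)
  sift_one_cpp(x, cfg$stoppage_threshold, cfg$max_siftings)
}

new_imf_decomposition <- function(input, imfs, residual, config, method,
                                  fs = 100, extra = list()) {
  colnames(imfs) <- if (ncol(imfs) > 0) paste0("imf", seq_len(ncol(imfs)))
  structure(c(list(input = input, imfs = imfs, residual = residual,
                   config = config, method = method, fs = fs), extra),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition: %s, %d IMFs + residual, %d samples>\n",
              x$method, ncol(x$imfs), nrow(x$imfs)))
  invisible(x)
}

#' Number of IMFs in a decomposition
#' @param decomp an `imf_decomposition`.
#' @return integer count (residual not included).
#' @export
n_imfs <- function(decomp) ncol(decomp$imfs)

#' Empirical mode decomposition
#'
#' Repeatedly sifts IMFs out of the running residual (`r <- r - IMF_i`) until
#' the residual is monotone (fewer than `cfg$min_extrema` maxima or minima) or
#' `cfg$max_imfs` is reached. The decomposition telescopes: the IMFs plus the
#' residual reproduce the input to floating-point accuracy.
#'
#' @param x an [orientation_signal()] or numeric vector, preprocessed (no
#'   missing values), length >= 10.
#' @param cfg an [emd_config()].
#' @return An `imf_decomposition`: list with `input`, `imfs` (matrix, one
#'   column per IMF), `residual`, `config`, `method = "EMD"`, `n_sifts`.
#' @export
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' d <- emd(sin(2 * pi * 6 * t) + sin(2 * pi * 1 * t))
#' n_imfs(d)
emd <- function(x, cfg = emd_config()) {
  fs <- signal_fs(x)
  x <- as_signal_values(x)
  if (length(x) < 10) stop("emd: signal shorter than 10 samples")
  if (anyNA(x)) stop("emd: missing values present; preprocess first")
  res <- emd_cpp(x, cfg$stoppage_threshold, cfg$max_siftings, cfg$max_imfs)
  new_imf_decomposition(x, res$imfs, res$residual, cfg, "EMD", fs = fs,
                        extra = list(n_sifts = res$n_sifts))
}

#' Ensemble empirical mode decomposition
#'
#' For each ensemble member n = 1..N, adds white Gaussian noise `w^n(t)` with
#' standard deviation `noise_std_ratio * sd(x)` (drawn from `seed + n`) to the
#' input, decomposes the noisy copy by [emd()], and averages IMFs across
#' members index-wise. Members yielding fewer IMFs than the ensemble-wide
#' maximum are zero-padded before averaging; residuals are averaged likewise.
#' The added noise masks intermittency, mitigating the mode-mixing failure of
#' plain EMD; the noise itself cancels in the ensemble mean at rate 1/sqrt(N).
#'
#' @inheritParams emd
#' @param cfg an [eemd_config()].
#' @return An `imf_decomposition` with `method = "EEMD"` and
#'   `n_imfs_per_member` recording each member's IMF count. With
#'   `noise_std_ratio = 0` and `n_ensembles = 1` the result equals [emd()].
#' @export
eemd <- function(x, cfg = eemd_config()) {
  fs <- signal_fs(x)
  x <- as_signal_values(x)
  if (length(x) < 10) stop("eemd: signal shorter than 10 samples")
  if (anyNA(x)) stop("eemd: missing values present; preprocess first")
  n <- length(x)
  noise_sd <- cfg$noise_std_ratio * sd(x)
  members <- vector("list", cfg$n_ensembles)
  for (m in seq_len(cfg$n_ensembles)) {
    w <- with_local_seed(cfg$seed + m, rnorm(n, 0, noise_sd))
    members[[m]] <- emd_cpp(x + w, cfg$emd$stoppage_threshold,
                            cfg$emd$max_siftings, cfg$emd$max_imfs)
  }
  counts <- vapply(members, function(d) ncol(d$imfs), integer(1))
  kmax <- max(counts)
  imfs <- matrix(0, n, kmax)
  residual <- numeric(n)
  for (m in seq_len(cfg$n_ensembles)) {
    k <- counts[m]
    if (k > 0) imfs[, seq_len(k)] <- imfs[, seq_len(k)] + members[[m]]$imfs
    residual <- residual + members[[m]]$residual
  }
  imfs <- imfs / cfg$n_ensembles
  residual <- residual / cfg$n_ensembles
  new_imf_decomposition(x, imfs, residual, cfg, "EEMD", fs = fs,
                        extra = list(n_imfs_per_member = counts))
}

#' Does a component satisfy the IMF criteria?
#'
#' Checks (a) the zero-crossing and extrema counts differ by at most one and
#' (b) the envelope mean is small relative to the component's amplitude.
#'
#' @param x numeric vector.
#' @param mean_tol tolerance for criterion (b): interior mean-envelope
#'   magnitude as a fraction of the component's maximum amplitude.
#' @return logical; attributes `n_zero_crossings`, `n_extrema`.
#' @export
is_imf <- function(x, mean_tol = 0.1) {
  x <- as_signal_values(x)
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- sum(diff(s) != 0)
  crit_a <- abs(n_zc - n_ext) <= 1
  crit_b <- TRUE
  if (length(ex$maxima) >= 2 && length(ex$minima) >= 2) {
    m <- envelope_mean(x, ex$maxima, ex$minima)
    interior <- seq(max(2, round(0.1 * length(x))),
                    min(length(x) - 1, round(0.9 * length(x))))
    crit_b <- max(abs(m[interior])) <= mean_tol * max(abs(x))
  }
  structure(crit_a && crit_b, n_zero_crossings = n_zc, n_extrema = n_ext)
}

#' Write / read an IMF decomposition as CSV
#'
#' Columns `imf1..imfK, residual`, one row per sample; a JSON sidecar
#' (`<path>.json`) stores the method, sampling rate, and configuration.
#'
#' @param decomp an `imf_decomposition`.
#' @param path CSV file path.
#' @return `path` invisibly (write); an `imf_decomposition` (read; its
#'   `input` is reconstructed as the row sums).
#' @export
write_decomposition_csv <- function(decomp, path) {
  df <- as.data.frame(decomp$imfs)
  df$residual <- decomp$residual
  write.csv(df, path, row.names = FALSE)
  cfg <- decomp$config
  if (inherits(cfg, "eemd_config")) cfg$emd <- unclass(cfg$emd)
  jsonlite::write_json(list(method = decomp$method, fs = decomp$fs,
                            config = unclass(cfg)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decomposition_csv
#' @export
read_decomposition_csv <- function(path) {
  df <- read.csv(path)
  if (!"residual" %in% names(df))
    stop(sprintf("read_decomposition_csv: '%s' lacks a `residual` column", path))
  imf_cols <- grep("^imf[0-9]+$", names(df), value = TRUE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(method = "EMD", fs = 100, config = NULL)
  imfs <- as.matrix(df[imf_cols])
  residual <- df$residual
  new_imf_decomposition(rowSums(imfs) + residual, imfs, residual,
                        meta$config, meta$method, fs = meta$fs)
}
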