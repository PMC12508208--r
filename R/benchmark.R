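# Scoring IMF combinations against Butterworth-filtered references: which
# combination of modes best reproduces the band-pass (tremulous) and low-pass
# (voluntary) benchmark components of a recording.

#' Logged root-mean-square error
#'
#' `log10(sqrt(mean((x - xhat)^2)))`. An RMSE below `1e-15` (an exact match to
#' floating-point accuracy) is floored at -15 and flagged via the
#' `exact_match` attribute so the logarithm cannot diverge.
#'
#' @param x benchmark signal.
#' @param xhat extracted signal, same length.
#' @return scalar score (dimensionless); attribute `exact_match` logical.
#' @export
#' @examples
#' log_rmse(1:5, 1:5 + 0.1)  # -1
log_rmse <- function(x, xhat) {
  x <- as_signal_values(x)
  xhat <- as_signal_values(xhat)
  if (length(x) != length(xhat)) stop("log_rmse: length mismatch")
  if (length(x) < 1) stop("log_rmse: empty input")
  rmse <- sqrt(mean((x - xhat)^2))
  if (rmse < 1e-15)
    structure(-15, exact_match = TRUE)
  else
    structure(log10(rmse), exact_match = FALSE)
}

#' Sum selected IMFs of a decomposition
#'
#' @param decomp an `imf_decomposition`.
#' @param indices integer set of IMF indices (1 = highest-frequency mode).
#' @param include_residual add the residual to the sum?
#' @return numeric vector, the pointwise sum.
#' @export
combine_imfs <- function(decomp, indices, include_residual = FALSE) {
  indices <- unique(as.integer(indices))
  k <- n_imfs(decomp)
  if (length(indices) > 0 && (min(indices) < 1 || max(indices) > k))
    stop(sprintf("combine_imfs: indices out of range 1..%d", k))
  out <- if (length(indices) == 0) numeric(nrow(decomp$imfs))
         else rowSums(decomp$imfs[, indices, drop = FALSE])
  if (include_residual) out <- out + decomp$residual
  out
}

combo_label <- function(indices) paste0("IMF", paste(sort(indices), collapse = ""))

#' Score IMF combinations against benchmark components
#'
#' For every candidate combination, computes the [log_rmse()] of (i) the
#' combination's sum against the tremulous benchmark and (ii) the
#' complementary sum (all remaining IMFs plus the residual) against the
#' voluntary benchmark. The combination minimizing the tremulous score is
#' identified: on well-decomposed recordings this is the mode pair carrying
#' the 3-10 Hz motion.
#'
#' @param decomp an `imf_decomposition`.
#' @param tremor_benchmark,voluntary_benchmark benchmark signals (same length
#'   as the decomposition input), e.g. from [butterworth_extract()].
#' @param combos list of integer vectors, e.g. `list(1, 2, 1:2, 2:3)`.
#' @return A data frame of class `benchmark_scores` with columns `combo`,
#'   `target` (`"tremulous"` / `"voluntary"`), `score`, `n`; attribute
#'   `best_tremulous` holds the minimizing combination (integer vector).
#' @export
score_combinations <- function(decomp, tremor_benchmark, voluntary_benchmark,
                               combos = list(1, 2, 1:2, 2:3)) {
  if (length(combos) == 0) stop("score_combinations: empty combo list")
  trem <- as_signal_values(tremor_benchmark)
  vol <- as_signal_values(voluntary_benchmark)
  n <- nrow(decomp$imfs)
  if (length(trem) != n || length(vol) != n)
    stop("score_combinations: benchmark length differs from decomposition")
  rows <- lapply(combos, function(idx) {
    idx <- sort(unique(as.integer(idx)))
    if (length(idx) == 0) stop("score_combinations: empty combination")
    ts <- log_rmse(trem, combine_imfs(decomp, idx))
    comp <- setdiff(seq_len(n_imfs(decomp)), idx)
    vs <- log_rmse(vol, combine_imfs(decomp, comp, include_residual = TRUE))
    data.frame(combo = combo_label(idx), target = c("tremulous", "voluntary"),
               score = c(as.numeric(ts), as.numeric(vs)), n = n)
  })
  out <- do.call(rbind, rows)
  trem_scores <- out$score[out$target == "tremulous"]
  best <- combos[[which.min(trem_scores)]]
  structure(out, best_tremulous = sort(unique(as.integer(best))),
            class = c("benchmark_scores", "data.frame"))
}

#' Benchmark a recording end to end
#'
#' Convenience wrapper: filters the preprocessed input with the two benchmark
#' filters and scores the given IMF combinations.
#'
#' @param decomp an `imf_decomposition` of a preprocessed signal.
#' @param combos candidate combinations (see [score_combinations()]).
#' @param zero_phase use zero-phase benchmark filters?
#' @return see [score_combinations()].
#' @export
benchmark_decomposition <- function(decomp, combos = list(1, 2, 1:2, 2:3),
                                    zero_phase = TRUE) {
  x <- decomp$input
  fs <- decomp$fs
  trem <- butterworth_extract(x, tremor_benchmark_spec(zero_phase), fs = fs)
  vol <- butterworth_extract(x, voluntary_benchmark_spec(zero_phase), fs = fs)
  score_combinations(decomp, trem, vol, combos)
}

#' Select the tremulous IMF combination across recordings
#'
#' The combination-selection procedure of the decomposition comparison:
#' scores every candidate combination on each recording's decomposition,
#' averages the tremulous scores over recordings (as the published comparison
#' averages over patients within an activity), and returns the minimizer.
#'
#' @param decomps list of `imf_decomposition`s (same activity/context).
#' @param combos candidate combinations (list of integer vectors).
#' @param zero_phase use zero-phase benchmark filters?
#' @return list with `best` (integer vector), `mean_scores` (named numeric,
#'   mean tremulous log-RMSE per combination) and `scores` (matrix,
#'   recordings x combinations).
#' @export
select_tremor_combination <- function(decomps, combos = list(1, 2, 1:2, 2:3),
                                      zero_phase = TRUE) {
  scores <- t(vapply(decomps, function(d) {
    sc <- benchmark_decomposition(d, combos, zero_phase = zero_phase)
    sc$score[sc$target == "tremulous"]
  }, numeric(length(combos))))
  colnames(scores) <- vapply(combos, combo_label, character(1))
  means <- colMeans(scores)
  list(best = sort(unique(as.integer(combos[[which.min(means)]]))),
       mean_scores = means, scores = scores)
}
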