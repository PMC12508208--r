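# Windowing IMFs into fixed-length labeled samples and building the shuffled
# 80:20 re-training splits.

#' Cut an IMF into non-overlapping fixed-length windows
#'
#' `ceiling(length / window)` windows; all are full except possibly the last,
#' which is zero-padded at its end to the window length. Concatenating the
#' windows and trimming the recorded padding reproduces the IMF exactly.
#'
#' @param imf numeric vector (length >= 1).
#' @param window window length in samples (the classification pipeline uses
#'   50, i.e. 0.5 s at 100 Hz).
#' @return list with `values` (matrix, one row per window) and `pad_len`
#'   (integer vector; zeros appended to each window — positive only for the
#'   final one).
#' @export
#' @examples
#' w <- window_imf(rnorm(120))
#' nrow(w$values)  # 3 windows; w$pad_len is c(0, 0, 30)
window_imf <- function(imf, window = 50) {
  imf <- as.numeric(imf)
  n <- length(imf)
  if (n < 1) stop("window_imf: empty IMF")
  n_win <- ceiling(n / window)
  pad <- n_win * window - n
  vals <- matrix(c(imf, numeric(pad)), nrow = n_win, ncol = window,
                 byrow = TRUE)
  list(values = vals, pad_len = c(rep.int(0L, n_win - 1L), as.integer(pad)))
}

#' Window every IMF of a decomposition into a labeled sample set
#'
#' Windows each IMF (the residual is excluded — only proper modes enter
#' classification), labels windows positive when their source IMF index lies
#' in `tremor_imf_indices`, and tracks provenance.
#'
#' @param decomp an `imf_decomposition`.
#' @param recording_id identifier stored with each window.
#' @param tremor_imf_indices IMF indices whose windows are tremulous
#'   (positive class). The default `c(1, 2)` is the mode pair selected by the
#'   benchmark comparison; pass the data-driven `best_tremulous` combination
#'   from [score_combinations()] to re-derive it.
#' @param window window length in samples.
#' @param activity optional activity tag replicated over the windows.
#' @return A `window_set`: list with `x` (n_windows x window matrix), and
#'   data frame `meta` (columns `recording`, `imf`, `widx`, `pad_len`,
#'   `label`, `activity`).
#' @export
windows_from_decomposition <- function(decomp, recording_id = 1L,
                                       tremor_imf_indices = c(1, 2),
                                       window = 50, activity = NA_character_) {
  k <- n_imfs(decomp)
  xs <- vector("list", k)
  metas <- vector("list", k)
  for (i in seq_len(k)) {
    w <- window_imf(decomp$imfs[, i], window = window)
    xs[[i]] <- w$values
    metas[[i]] <- data.frame(
      recording = recording_id, imf = i, widx = seq_len(nrow(w$values)),
      pad_len = w$pad_len,
      label = as.integer(i %in% tremor_imf_indices),
      activity = activity)
  }
  structure(list(x = do.call(rbind, xs), meta = do.call(rbind, metas),
                 window = window),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d windows of length %d, %.1f%% positive>\n",
              nrow(x$x), x$window, 100 * mean(x$meta$label)))
  invisible(x)
}

#' Merge window sets from several recordings
#' @param ... `window_set` objects (or a single list of them).
#' @return one combined `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  structure(list(x = do.call(rbind, lapply(sets, `[[`, "x")),
                 meta = do.call(rbind, lapply(sets, `[[`, "meta")),
                 window = sets[[1]]$window),
            class = "window_set")
}

#' Split configuration for the re-training protocol
#'
#' @param ratio train fraction (the protocol uses 0.8).
#' @param n_repeats number of independent re-shuffles (the protocol uses 10).
#' @param seed integer seed.
#' @param mode `"window_shuffle"` shuffles all windows before each split (the
#'   re-training protocol); `"subject_holdout"` partitions whole subjects
#'   (emulating the 48-train / 12-test patient layout), preventing leakage of
#'   a subject's windows across the split.
#' @return list of class `split_config`.
#' @export
split_config <- function(ratio = 0.8, n_repeats = 10, seed = 0,
                         mode = c("window_shuffle", "subject_holdout")) {
  if (ratio <= 0 || ratio >= 1) stop("split_config: ratio must be in (0, 1)")
  if (n_repeats < 1) stop("split_config: n_repeats must be >= 1")
  structure(list(ratio = ratio, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), mode = match.arg(mode)),
            class = "split_config")
}

#' Build shuffled train/test splits
#'
#' @param ws a `window_set` (both classes must be present).
#' @param cfg a [split_config()].
#' @param subjects integer vector of subject ids per window, required for
#'   `subject_holdout` mode (defaults to `ws$meta$recording`).
#' @return list of `cfg$n_repeats` lists, each with integer index vectors
#'   `train` and `test` (disjoint, covering all windows).
#' @export
make_splits <- function(ws, cfg = split_config(), subjects = NULL) {
  n <- nrow(ws$x)
  if (n < 10) stop("make_splits: need at least 10 samples")
  if (length(unique(ws$meta$label)) < 2)
    stop("make_splits: both classes must be present")
  with_local_seed(cfg$seed, lapply(seq_len(cfg$n_repeats), function(r) {
    if (cfg$mode == "window_shuffle") {
      perm <- sample.int(n)
      n_train <- round(cfg$ratio * n)
      list(train = perm[seq_len(n_train)], test = perm[-seq_len(n_train)])
    } else {
      subj <- if (is.null(subjects)) ws$meta$recording else subjects
      ids <- unique(subj)
      perm <- sample(ids)
      n_train <- round(cfg$ratio * length(ids))
      tr_ids <- perm[seq_len(n_train)]
      list(train = which(subj %in% tr_ids), test = which(!subj %in% tr_ids))
    }
  }))
}

#' Export a window set for inspection
#'
#' CSV with provenance/label columns followed by `v1..v<window>` sample
#' columns.
#'
#' @param ws a `window_set`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_window_set_csv <- function(ws, path) {
  vals <- as.data.frame(ws$x)
  names(vals) <- paste0("v", seq_len(ncol(vals)))
  write.csv(cbind(ws$meta, vals), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_set_csv
#' @export
read_window_set_csv <- function(path) {
  df <- read.csv(path)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  need <- c("recording", "imf", "widx", "pad_len", "label")
  if (length(vcols) == 0 || !all(need %in% names(df)))
    stop(sprintf("read_window_set_csv: '%s' must have columns %s and v1..vK",
                 path, paste(need, collapse = ", ")))
  structure(list(x = as.matrix(df[vcols]),
                 meta = df[setdiff(names(df), vcols)],
                 window = length(vcols)),
            class = "window_set")
}
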