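# Pipeline orchestration: a single JSON-configurable end-to-end run
# (simulate -> preprocess -> decompose -> benchmark -> window/label -> split
# -> train -> evaluate) plus the per-stage functions behind the command-line
# wrapper (inst/cli/tremorsep).

#' Default pipeline configuration
#'
#' A nested list with one section per stage. The decomposition, windowing and
#' optimization settings default to the published pipeline values (EEMD with
#' 100 ensembles, window 50, 80:20 shuffled splits, SGD at 0.01, batch 64);
#' cohort size, epochs and repeat count default to a compact run that
#' finishes on a laptop in about a minute — raise them towards study scale
#' (60 subjects, 9 channels, 100 epochs, 10 repeats) for full experiments.
#'
#' @param seed global seed; every stage derives its randomness from it.
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_subjects = 4L, activities = c("resting", "outstretching",
                                                  "wing", "drinking"),
                  body_parts = "lower_arm", axes = "roll"),
    decompose = list(method = "EEMD", n_ensembles = 100L,
                     noise_std_ratio = 0.2, stoppage_threshold = 0.2,
                     max_siftings = 50L, max_imfs = 12L),
    benchmark = list(combos = list(1L, 2L, c(1L, 2L), c(2L, 3L)),
                     zero_phase = TRUE),
    dataset = list(window = 50L, tremor_imf_indices = c(1L, 2L), ratio = 0.8,
                   n_repeats = 2L, mode = "window_shuffle"),
    classifier = list(model = "conv_bilstm", padding_mode = "same",
                      lstm_units = 64L, post_lstm_tanh = TRUE,
                      input_scaling = "maxabs"),
    train = list(learning_rate = 0.01, epochs = 10L, batch_size = 64L,
                 decision_threshold = 0.5)), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON file with the same nesting as [default_pipeline_config()];
#' supplied values override the defaults, unknown keys are rejected with
#' their section named.
#'
#' @param path JSON file path (or `NULL` for pure defaults).
#' @param seed optional override of the global seed.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path = NULL, seed = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(user), c(names(cfg)))
    if (length(bad))
      stop(sprintf("load_pipeline_config: unknown section(s): %s",
                   paste(bad, collapse = ", ")))
    for (sec in names(user)) {
      if (sec == "seed") {
        cfg$seed <- as.integer(user$seed)
        next
      }
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(bad))
        stop(sprintf("load_pipeline_config: unknown key(s) in `%s`: %s",
                     sec, paste(bad, collapse = ", ")))
      if (sec == "benchmark" && !is.null(user$benchmark$combos))
        user$benchmark$combos <- lapply(user$benchmark$combos, as.integer)
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

pipe_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

decompose_config_from <- function(cfg, seed) {
  emdc <- emd_config(stoppage_threshold = cfg$decompose$stoppage_threshold,
                     max_siftings = cfg$decompose$max_siftings,
                     max_imfs = cfg$decompose$max_imfs)
  if (toupper(cfg$decompose$method) == "EMD") emdc
  else eemd_config(emd = emdc, n_ensembles = cfg$decompose$n_ensembles,
                   noise_std_ratio = cfg$decompose$noise_std_ratio,
                   seed = seed)
}

decompose_with <- function(x, dcfg) {
  if (inherits(dcfg, "eemd_config")) eemd(x, dcfg) else emd(x, dcfg)
}

#' Run the full pipeline
#'
#' Simulates a cohort, preprocesses and decomposes every recording,
#' benchmarks the IMF combinations on the first recording of each activity,
#' builds the labeled window dataset, trains the configured classifier over
#' the re-training splits, and evaluates each repeat. All artifacts are
#' written under `out_dir`; the run is deterministic given the config.
#'
#' @param config a `pipeline_config` (see [load_pipeline_config()]).
#' @param out_dir output directory (created if absent); `NULL` skips all file
#'   output.
#' @param verbose log stage progress?
#' @return list with `manifest`, `decompositions`, `benchmark` (score table),
#'   `windows` (a `window_set`), `repeats` (per-repeat `metrics_report`s),
#'   `aggregate` (mean +/- SD data frame), and `per_action` (breakdown for
#'   the first repeat).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  log_ <- if (verbose) pipe_log else function(...) invisible(NULL)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- simulate -------------------------------------------------------------
  profiles <- lapply(config$cohort$activities, activity_profile)
  cohort <- generate_cohort(config$cohort$n_subjects, profiles,
                            seed = config$seed,
                            body_parts = config$cohort$body_parts,
                            axes = config$cohort$axes)
  log_("simulate", "%d recordings (%d subjects x %d activities x %d channels)",
       nrow(cohort$manifest), config$cohort$n_subjects,
       length(config$cohort$activities),
       length(config$cohort$body_parts) * length(config$cohort$axes))
  if (!is.null(out_dir))
    write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)

  # --- preprocess + decompose ----------------------------------------------
  dcfg <- decompose_config_from(config, config$seed)
  decomps <- vector("list", length(cohort$recordings))
  for (i in seq_along(cohort$recordings)) {
    pre <- preprocess_signal(cohort$recordings[[i]]$mixed)
    if (inherits(dcfg, "eemd_config")) dcfg$seed <- config$seed + i * 1000L
    decomps[[i]] <- decompose_with(pre, dcfg)
  }
  log_("decompose", "%s: %s IMFs per recording (median %d)",
       config$decompose$method,
       paste(range(vapply(decomps, n_imfs, integer(1))), collapse = "-"),
       as.integer(stats::median(vapply(decomps, n_imfs, integer(1)))))

  # --- benchmark ------------------------------------------------------------
  first_per_act <- match(unique(cohort$manifest$activity),
                         cohort$manifest$activity)
  bench <- do.call(rbind, lapply(first_per_act, function(i) {
    sc <- benchmark_decomposition(decomps[[i]], config$benchmark$combos,
                                  zero_phase = config$benchmark$zero_phase)
    cbind(activity = cohort$manifest$activity[i], as.data.frame(sc))
  }))
  log_("benchmark", "scored %d combinations per activity",
       length(config$benchmark$combos))
  if (!is.null(out_dir))
    write.csv(bench, file.path(out_dir, "benchmark_scores.csv"),
              row.names = FALSE)

  # --- dataset --------------------------------------------------------------
  ws <- bind_window_sets(lapply(seq_along(decomps), function(i)
    windows_from_decomposition(
      decomps[[i]], recording_id = i,
      tremor_imf_indices = config$dataset$tremor_imf_indices,
      window = config$dataset$window,
      activity = cohort$manifest$activity[i])))
  log_("dataset", "%d windows, %.1f%% positive", nrow(ws$x),
       100 * mean(ws$meta$label))
  if (!is.null(out_dir))
    write_window_set_csv(ws, file.path(out_dir, "windows.csv"))
  subjects <- cohort$manifest$subject[ws$meta$recording]
  splits <- make_splits(ws, split_config(ratio = config$dataset$ratio,
                                         n_repeats = config$dataset$n_repeats,
                                         seed = config$seed,
                                         mode = config$dataset$mode),
                        subjects = subjects)

  # --- train + evaluate -----------------------------------------------------
  model_name <- config$classifier$model
  spec <- classifier_spec(lstm_units = config$classifier$lstm_units,
                          padding_mode = config$classifier$padding_mode,
                          post_lstm_tanh = config$classifier$post_lstm_tanh,
                          input_scaling = config$classifier$input_scaling,
                          input_len = config$dataset$window)
  tcfg <- train_config(learning_rate = config$train$learning_rate,
                       epochs = config$train$epochs,
                       batch_size = config$train$batch_size,
                       seed = config$seed,
                       decision_threshold = config$train$decision_threshold)
  feats <- if (model_name %in% c("knn", "gnb")) feature_table(ws) else NULL
  repeats <- vector("list", length(splits))
  per_action <- NULL
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    y_tr <- ws$meta$label[sp$train]
    y_te <- ws$meta$label[sp$test]
    if (model_name %in% c("conv_bilstm", "conv_lstm")) {
      builder <- if (model_name == "conv_bilstm") build_conv_bilstm
                 else build_conv_lstm
      tcfg_r <- tcfg
      tcfg_r$seed <- tcfg$seed + r
      model <- builder(spec, seed = config$seed + r)
      model <- train_model(model, ws$x[sp$train, , drop = FALSE], y_tr, tcfg_r)
      pred <- predict(model, ws$x[sp$test, , drop = FALSE],
                      threshold = tcfg$decision_threshold)
      rep_r <- evaluate_predictions(y_te, pred$label, pred$score)
    } else if (model_name == "knn") {
      fm <- as.matrix(feats[c("inst_freq", "kurt", "peak_rms", "sampen")])
      lab <- knn_baseline(fm[sp$train, ], fm[sp$test, ], y_tr, k = 3)
      rep_r <- evaluate_predictions(y_te, lab)
      pred <- list(label = lab, score = NULL)
    } else if (model_name == "gnb") {
      fm <- as.matrix(feats[c("inst_freq", "kurt", "peak_rms", "sampen")])
      g <- gnb_baseline(fm[sp$train, ], fm[sp$test, ], y_tr)
      rep_r <- evaluate_predictions(y_te, g$label, g$posterior[, "1"])
      pred <- list(label = g$label, score = g$posterior[, "1"])
    } else stop(sprintf("run_pipeline: unknown model `%s`", model_name))
    repeats[[r]] <- rep_r
    if (r == 1)
      per_action <- per_action_report(y_te, pred$label,
                                      ws$meta$activity[sp$test], pred$score)
    log_("evaluate", "repeat %d/%d: accuracy %.3f", r, length(splits),
         rep_r$accuracy)
  }
  agg <- if (length(repeats) > 1) aggregate_repeats(repeats) else NULL

  result <- list(manifest = cohort$manifest, decompositions = decomps,
                 benchmark = bench, windows = ws, repeats = repeats,
                 aggregate = agg, per_action = per_action,
                 model = model_name, config = config)
  if (!is.null(out_dir)) {
    metrics <- list(
      model = model_name,
      repeats = lapply(repeats, function(r)
        r[c("counts", "accuracy", "precision", "sensitivity", "specificity",
            "f1", "auc_roc", "n")]),
      aggregate = agg,
      per_action = lapply(per_action, function(r)
        r[c("accuracy", "precision", "sensitivity", "specificity", "f1",
            "auc_roc", "n")]))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    log_("evaluate", "metrics written to %s",
         file.path(out_dir, "metrics.json"))
  }
  invisible(result)
}

#' Decompose a CSV recording from disk
#'
#' Stage function behind the CLI: reads a `t,value` CSV, preprocesses
#' (interpolation + detrend) and decomposes it, writing the IMF matrix CSV
#' with a JSON sidecar next to `out_csv`.
#'
#' @param in_csv input recording CSV (columns `t`, `value`).
#' @param out_csv output IMF CSV path.
#' @param config a `pipeline_config`.
#' @return the `imf_decomposition`, invisibly.
#' @export
decompose_file <- function(in_csv, out_csv,
                           config = default_pipeline_config()) {
  sig <- read_signal_csv(in_csv)
  pre <- preprocess_signal(sig)
  d <- decompose_with(pre, decompose_config_from(config, config$seed))
  write_decomposition_csv(d, out_csv)
  invisible(d)
}

#' Benchmark an IMF CSV against its raw recording
#'
#' @param imf_csv decomposition CSV (from [decompose_file()]).
#' @param raw_csv the recording CSV it came from.
#' @param config a `pipeline_config`.
#' @return `benchmark_scores` data frame.
#' @export
benchmark_file <- function(imf_csv, raw_csv,
                           config = default_pipeline_config()) {
  d <- read_decomposition_csv(imf_csv)
  sig <- preprocess_signal(read_signal_csv(raw_csv))
  d$input <- as_signal_values(sig)
  d$fs <- sig$fs
  benchmark_decomposition(d, config$benchmark$combos,
                          zero_phase = config$benchmark$zero_phase)
}
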