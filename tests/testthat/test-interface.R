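# Configuration handling, end-to-end pipeline determinism, and the CLI
# wrapper.

tiny_config <- function(dir, seed = 5) {
  cfg <- list(seed = seed,
              cohort = list(n_subjects = 2, activities = c("resting", "wing")),
              decompose = list(method = "EEMD", n_ensembles = 20),
              dataset = list(n_repeats = 1),
              classifier = list(model = "gnb"),
              train = list(epochs = 2))
  path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  path
}

test_that("config loading merges overrides and rejects unknown keys", {
  dir <- withr::local_tempdir()
  cfg <- load_pipeline_config(tiny_config(dir), seed = 99)
  expect_identical(cfg$seed, 99L)
  expect_identical(cfg$cohort$n_subjects, 2L)
  expect_identical(cfg$decompose$n_ensembles, 20L)
  expect_identical(cfg$train$batch_size, 64L)  # untouched default

  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(list(cohort = list(n_patients = 3)), bad,
                       auto_unbox = TRUE)
  expect_error(load_pipeline_config(bad), "unknown key.*cohort")
  jsonlite::write_json(list(mystery = 1), bad, auto_unbox = TRUE)
  expect_error(load_pipeline_config(bad), "unknown section")
})

test_that("the full pipeline is deterministic: re-runs are byte-identical", {
  dir <- withr::local_tempdir()
  cfg <- load_pipeline_config(tiny_config(dir))
  out1 <- file.path(dir, "run1")
  out2 <- file.path(dir, "run2")
  run_pipeline(cfg, out_dir = out1, verbose = FALSE)
  run_pipeline(cfg, out_dir = out2, verbose = FALSE)
  for (f in c("metrics.json", "manifest.csv", "benchmark_scores.csv"))
    expect_identical(readBin(file.path(out1, f), "raw", 1e7),
                     readBin(file.path(out2, f), "raw", 1e7))
})

test_that("the default pipeline produces every stage artifact", {
  dir <- withr::local_tempdir()
  res <- run_pipeline(default_pipeline_config(seed = 2), out_dir = dir,
                      verbose = FALSE)
  for (f in c("manifest.csv", "benchmark_scores.csv", "windows.csv",
              "metrics.json"))
    expect_true(file.exists(file.path(dir, f)))
  expect_identical(nrow(res$manifest), 16L)  # 4 subjects x 4 activities
  expect_length(res$repeats, 2)
  expect_s3_class(res$repeats[[1]], "metrics_report")
  expect_true(all(c("accuracy", "sensitivity") %in% res$aggregate$metric))
  metrics <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_identical(metrics$model, "conv_bilstm")
})

test_that("file stages validate schemas with named columns", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(time = 1:10, angle = rnorm(10)), bad,
            row.names = FALSE)
  expect_error(decompose_file(bad, file.path(dir, "out.csv")),
               "`t` and `value`")

  rec <- generate_recording(activity_profile("resting"), seed = 4)
  raw <- file.path(dir, "rec.csv")
  write_signal_csv(rec$mixed, raw)
  imf_csv <- file.path(dir, "imfs.csv")
  cfg <- load_pipeline_config(tiny_config(dir))
  d <- decompose_file(raw, imf_csv, cfg)
  expect_true(file.exists(imf_csv))
  expect_true(file.exists(paste0(imf_csv, ".json")))
  sc <- benchmark_file(imf_csv, raw, cfg)
  expect_s3_class(sc, "benchmark_scores")
})

test_that("the CLI wrapper runs stages end to end from a shell", {
  dir <- withr::local_tempdir()
  cli <- system.file("cli", "tremorsep", package = "tremorsep")
  rscript <- file.path(R.home("bin"), "Rscript")
  cfgp <- tiny_config(dir)

  out <- system2(rscript, c(cli, "simulate", "--out", file.path(dir, "sim"),
                            "--config", cfgp, "--subjects", "1"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "sim", "manifest.csv")))
  expect_true(file.exists(file.path(dir, "sim", "rec0001.csv")))

  system2(rscript, c(cli, "decompose", "--in", file.path(dir, "sim", "rec0001.csv"),
                     "--out", file.path(dir, "imfs.csv"), "--config", cfgp),
          stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "imfs.csv")))

  # schema violation exits non-zero
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(a = 1:5), bad, row.names = FALSE)
  st <- system2(rscript, c(cli, "decompose", "--in", bad, "--out",
                           file.path(dir, "x.csv")),
                stdout = FALSE, stderr = FALSE)
  expect_gt(st, 0)

  st2 <- system2(rscript, c(cli, "nonsense"), stdout = FALSE, stderr = FALSE)
  expect_gt(st2, 0)
})

test_that("window-set CSV round-trips through the dataset exchange format", {
  ws <- windows_from_decomposition(emd(sin((1:500) / 8) + sin((1:500) / 40)))
  path <- file.path(withr::local_tempdir(), "ws.csv")
  write_window_set_csv(ws, path)
  back <- read_window_set_csv(path)
  expect_equal(unname(back$x), unname(ws$x), tolerance = 1e-12)
  expect_identical(back$meta$label, ws$meta$label)
  expect_error(read_window_set_csv({
    p <- file.path(withr::local_tempdir(), "nope.csv")
    write.csv(data.frame(a = 1), p, row.names = FALSE); p
  }), "columns")
})
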