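# Synthetic recording simulator: spectral contracts, determinism, corruption
# bookkeeping, cohort layout.

test_that("component generators honour amplitude, seed and band contracts", {
  prof <- activity_profile("resting")

  zero <- activity_profile("resting", voluntary_amplitude_deg = 0,
                           tremor_amplitude_deg = 0)
  expect_true(all(generate_voluntary(zero, 1)$values == 0))
  expect_true(all(generate_tremor(zero, 1)$values == 0))

  v1 <- generate_voluntary(prof, 42)
  v2 <- generate_voluntary(prof, 42)
  expect_identical(v1$values, v2$values)
  expect_false(identical(v1$values, generate_voluntary(prof, 43)$values))
  t1 <- generate_tremor(prof, 42)
  expect_identical(t1$values, generate_tremor(prof, 42)$values)

  # band separation, all four default activities
  for (p in default_profiles()) {
    expect_gte(band_power_fraction(generate_voluntary(p, 7), c(0, 3)), 0.95)
    expect_gte(band_power_fraction(generate_tremor(p, 7), c(3, 10)), 0.95)
  }
})

test_that("an unmodulated fixed-carrier tremor peaks at the carrier", {
  prof <- activity_profile("resting")
  x <- generate_tremor(prof, 5, carrier_hz = 5, am_depth = 0, fm_dev_hz = 0)
  pg <- stats::spec.pgram(stats::ts(x$values, frequency = 100), taper = 0,
                          detrend = FALSE, plot = FALSE)
  expect_equal(pg$freq[which.max(pg$spec)], 5, tolerance = 0.02)
  expect_identical(x$meta$carrier_hz, 5)
})

test_that("recordings have the documented length, additivity and corruption", {
  rec <- generate_recording(activity_profile("resting"), seed = 3)
  expect_length(rec$mixed$values, 1000)  # 10 s at 100 Hz

  clean <- activity_profile("resting", noise_std_deg = 0,
                            drift_slope_deg_per_s = 0, missing_fraction = 0)
  rc <- generate_recording(clean, seed = 3)
  expect_identical(rc$mixed$values,
                   rc$voluntary_truth$values + rc$tremor_truth$values)

  miss <- activity_profile("resting", missing_fraction = 0.02)
  rm2 <- generate_recording(miss, seed = 9)
  expect_identical(sum(is.na(rm2$mixed$values)), 20L)
  expect_false(is.na(rm2$mixed$values[1]))
  expect_false(is.na(rm2$mixed$values[1000]))
  # ground truths never corrupted
  expect_false(anyNA(rm2$voluntary_truth$values))
  expect_false(anyNA(rm2$tremor_truth$values))
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(activity_profile("resting", duration_s = 0), "positive")
  expect_error(activity_profile("drinking", duration_s = 5), ">= 10")
  expect_error(activity_profile("wing", missing_fraction = 0.25), "missing_fraction")
  expect_error(activity_profile("wing", tremor_amplitude_deg = -1), ">= 0")
})

test_that("cohorts have the full subject x activity x channel layout", {
  ch <- generate_cohort(2, default_profiles(), seed = 11)
  expect_length(ch$recordings, 2 * 4 * 9)
  expect_identical(nrow(ch$manifest), 72L)
  expect_true(all(c("subject", "activity", "body_part", "axis", "seed",
                    "carrier_hz") %in% names(ch$manifest)))
  # same master seed: identical manifest; distinct subjects: distinct carriers
  ch2 <- generate_cohort(2, default_profiles(), seed = 11)
  expect_identical(ch$manifest, ch2$manifest)
  carriers <- unique(ch$manifest[c("subject", "carrier_hz")])
  expect_identical(anyDuplicated(carriers$carrier_hz), 0L)
  expect_error(generate_cohort(0), "n_subjects")
  expect_error(generate_cohort(1, list()), "empty")
})

test_that("recording CSV round-trips including missing markers and tags", {
  rec <- generate_recording(activity_profile("outstretching",
                                             missing_fraction = 0.02),
                            seed = 5, meta = list(subject = 9, body_part = "palm",
                                                  axis = "yaw"))
  stem <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, stem)
  back <- read_signal_csv(paste0(stem, ".csv"))
  expect_equal(back$values, rec$mixed$values)
  expect_identical(back$fs, rec$mixed$fs)
  expect_identical(back$meta$subject, 9L)
  expect_identical(back$meta$name, "outstretching")
})
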