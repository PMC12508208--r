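# Butterworth benchmark filters and IMF-combination scoring.

test_that("designed coefficients match the reference DSP implementation", {
  # frozen from scipy.signal.butter(4, [3,10], 'bandpass', fs=100) and
  # butter(4, 3, 'low', fs=100)
  bp <- butter_coefficients(tremor_benchmark_spec(), fs = 100)
  expect_equal(bp$b,
               c(0.001397475359, 0, -0.005589901437, 0, 0.008384852156,
                 0, -0.005589901437, 0, 0.001397475359), tolerance = 1e-9)
  expect_equal(bp$a,
               c(1, -6.4463338198, 18.5440305303, -31.1010718967,
                 33.2682468987, -23.2446521479, 10.3615191260,
                 -2.6949969436, 0.3133712478), tolerance = 1e-9)
  lp <- butter_coefficients(voluntary_benchmark_spec(), fs = 100)
  expect_equal(lp$b, c(6.238698355e-05, 2.495479342e-04, 3.743219013e-04,
                       2.495479342e-04, 6.238698355e-05), tolerance = 1e-6)
  expect_equal(lp$a, c(1, -3.5077862074, 4.6409024127, -2.7426528211,
                       0.6105348076), tolerance = 1e-9)
  # Butterworth magnitude is 1/sqrt(2) at the band edges
  expect_equal(filter_magnitude(bp, c(3, 10), 100), rep(1 / sqrt(2), 2),
               tolerance = 1e-6)
  expect_error(butter_coefficients(filter_spec("lowpass", 60), fs = 100),
               "Nyquist")
})

test_that("zero-phase extraction passes the band and rejects DC without lag", {
  t <- (0:999) / 100
  trim <- 51:950  # transient trim for amplitude checks only

  x5 <- sin(2 * pi * 5 * t)
  y5 <- butterworth_extract(x5, tremor_benchmark_spec(), fs = 100)
  expect_gte(max(abs(y5[trim])), 0.9)
  cc <- stats::ccf(y5[trim], x5[trim], lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)][1], 0)

  ydc <- butterworth_extract(rep(1, 1000), tremor_benchmark_spec(), fs = 100)
  expect_lt(max(abs(ydc)), 1e-3)

  y1 <- butterworth_extract(sin(2 * pi * 1 * t), voluntary_benchmark_spec(),
                            fs = 100)
  expect_gte(max(abs(y1[trim])), 0.95)

  # causal option exists and differs by a phase shift
  yc <- butterworth_extract(x5, tremor_benchmark_spec(zero_phase = FALSE),
                            fs = 100)
  ccc <- stats::ccf(yc[trim], x5[trim], lag.max = 20, plot = FALSE)
  expect_false(ccc$lag[which.max(ccc$acf)][1] == 0)
})

test_that("log RMSE has its closed-form values and exact-match floor", {
  x <- rnorm(100)
  expect_equal(as.numeric(log_rmse(x, x + 0.1)), -1, tolerance = 1e-12)
  expect_equal(as.numeric(log_rmse(x, x + 1)), 0, tolerance = 1e-12)
  exact <- log_rmse(x, x)
  expect_identical(as.numeric(exact), -15)
  expect_true(attr(exact, "exact_match"))
  expect_error(log_rmse(1:3, 1:4), "length")
})

test_that("combining IMFs is order-invariant and completes with the residual", {
  t <- (0:999) / 100
  d <- emd(sin(2 * pi * 6 * t) + sin(2 * pi * 1 * t))
  expect_identical(combine_imfs(d, 1), d$imfs[, 1])
  expect_identical(combine_imfs(d, c(1, 2)), combine_imfs(d, c(2, 1)))
  all_idx <- seq_len(n_imfs(d))
  expect_lt(max(abs(combine_imfs(d, all_idx, include_residual = TRUE) -
                    d$input)), 1e-8)
  expect_error(combine_imfs(d, n_imfs(d) + 1), "out of range")
})

test_that("combination scoring finds the tremulous pair and is order-invariant", {
  rec <- generate_recording(activity_profile("resting"), seed = 2)
  d <- eemd(preprocess_signal(rec$mixed), eemd_config(seed = 77))
  sc <- benchmark_decomposition(d, combos = list(1:2, 2:3))
  trem <- sc[sc$target == "tremulous", ]
  expect_lt(trem$score[trem$combo == "IMF12"],
            trem$score[trem$combo == "IMF23"])

  sc_rev <- benchmark_decomposition(d, combos = list(2:3, 1:2))
  expect_identical(sort(sc$score), sort(sc_rev$score))
  expect_error(benchmark_decomposition(d, combos = list()), "empty")
  expect_error(score_combinations(d, d$input, d$input, list(integer(0))),
               "empty combination")
})

test_that("multi-recording selection averages scores as in the published table", {
  decomps <- lapply(1:3, function(p) {
    rec <- generate_recording(activity_profile("resting"), seed = 600 + p)
    eemd(preprocess_signal(rec$mixed), eemd_config(seed = 700 + p))
  })
  sel <- select_tremor_combination(decomps)
  expect_identical(dim(sel$scores), c(3L, 4L))
  expect_equal(unname(sel$mean_scores), unname(colMeans(sel$scores)))
  expect_identical(sel$best, c(1L, 2L))
})
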