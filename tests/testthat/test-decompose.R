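# EMD/EEMD: extrema detection, envelopes, sifting, completeness, ensemble
# behaviour.

test_that("extrema detection handles monotone, periodic and plateau cases", {
  expect_identical(find_extrema(1:50),
                   list(maxima = integer(0), minima = integer(0)))
  expect_identical(find_extrema(rep(1, 50)),
                   list(maxima = integer(0), minima = integer(0)))

  t <- (0:199) / 100
  ex <- find_extrema(sin(2 * pi * t))  # 1 Hz over 2 s at 100 Hz
  expect_length(ex$maxima, 2)
  expect_length(ex$minima, 2)
  expect_true(all(abs(ex$maxima - c(26, 126)) <= 1))  # peaks at t=0.25, 1.25
  expect_true(all(abs(ex$minima - c(76, 176)) <= 1))

  # plateaus contribute their midpoint exactly once
  expect_identical(find_extrema(c(0, 1, 1, 1, 0))$maxima, 3L)
  expect_identical(find_extrema(c(0, -2, -2, 0, 0, 1))$minima, 2L)
})

test_that("envelope mean is odd-symmetric, translation-equivariant and small on tones", {
  t <- (0:999) / 100
  x <- sin(2 * pi * 1 * t)  # 10 periods
  m <- envelope_mean(x)
  expect_equal(envelope_mean(-x), -m, tolerance = 1e-12)
  expect_equal(envelope_mean(x + 5), m + 5, tolerance = 1e-9)
  interior <- 100:900
  expect_lt(max(abs(m[interior])), 0.05)
  expect_error(envelope_mean(1:50), "monotone")
})

test_that("the stoppage criterion matches its closed form", {
  expect_identical(stoppage_criterion(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(stoppage_criterion(c(1, 2), c(0, 0)), 1)
  expect_identical(stoppage_criterion(c(1, 1), c(1, 0)), 0.5)
  expect_error(stoppage_criterion(c(0, 0), c(1, 1)), "zero energy")
  expect_error(stoppage_criterion(1:3, 1:4), "length")
})

test_that("sifting extracts tones and converges fast on existing IMFs", {
  t <- (0:999) / 100
  tone <- sin(2 * pi * 5 * t)
  s <- sift_one_imf(tone)
  expect_gt(cor(s$imf, tone), 0.99)
  # a previously extracted IMF needs at most 2 further sifting passes
  s2 <- sift_one_imf(s$imf)
  expect_lte(s2$n_sifts, 2)
  expect_error(sift_one_imf(seq(0, 1, length.out = 100)), "monotone")
})

test_that("EMD telescopes exactly and separates a two-tone mixture", {
  t <- (0:999) / 100
  ramp <- seq(0, 1, length.out = 100)
  dr <- emd(ramp)
  expect_identical(n_imfs(dr), 0L)
  expect_identical(dr$residual, ramp)

  lo <- sin(2 * pi * 1 * t)
  hi <- sin(2 * pi * 6 * t)
  d <- emd(hi + lo)
  expect_lt(max(abs(rowSums(d$imfs) + d$residual - (hi + lo))), 1e-8)
  expect_gt(cor(d$imfs[, 1], hi), 0.9)
  expect_gt(max(vapply(seq_len(n_imfs(d)), function(i) cor(d$imfs[, i], lo),
                       numeric(1))), 0.9)
  expect_error(emd(1:5), "10 samples")
  expect_error(emd(c(1:20, NA)), "missing")
})

test_that("EMD is amplitude-equivariant and its IMFs near-satisfy criterion (a)", {
  # The operative stop rule is the Cauchy criterion, so the ideal-IMF
  # zero-crossing/extrema parity holds exactly for clean modes and within a
  # few percent of the extrema count for the noise-dominated leading mode.
  set.seed(31)
  for (case in 1:5) {
    x <- as.vector(arima.sim(list(ar = 0.8), 400)) + sin((1:400) / 5)
    d <- emd(x)
    d3 <- emd(3 * x)
    expect_identical(n_imfs(d3), n_imfs(d))
    expect_equal(d3$imfs, 3 * d$imfs, tolerance = 1e-9)
    for (i in seq_len(n_imfs(d))) {
      chk <- is_imf(d$imfs[, i])
      gap <- abs(attr(chk, "n_zero_crossings") - attr(chk, "n_extrema"))
      expect_lte(gap, max(1, 0.05 * attr(chk, "n_extrema")))
    }
  }
  # clean tones sift to exact parity
  t <- (0:999) / 100
  d5 <- emd(sin(2 * pi * 5 * t) + sin(2 * pi * 0.7 * t))
  chk <- is_imf(d5$imfs[, 1])
  expect_lte(abs(attr(chk, "n_zero_crossings") - attr(chk, "n_extrema")), 1)
})

test_that("EEMD degenerates to EMD, is seed-deterministic, and nearly telescopes", {
  t <- (0:999) / 100
  x <- sin(2 * pi * 6 * t) + sin(2 * pi * 1 * t)
  d_emd <- emd(x)
  d0 <- eemd(x, eemd_config(n_ensembles = 1, noise_std_ratio = 0, seed = 4))
  expect_identical(unname(d0$imfs), unname(d_emd$imfs))
  expect_identical(d0$residual, d_emd$residual)

  cfg <- eemd_config(n_ensembles = 50, seed = 12)
  da <- eemd(x, cfg)
  db <- eemd(x, cfg)
  expect_identical(da$imfs, db$imfs)

  # each member telescopes to x + w^n exactly, so the gap equals the maximum
  # of the ensemble-mean noise: sd ratio*sd(x)/sqrt(N), and its max over 1000
  # samples concentrates near sqrt(2*log(1000)) ~ 3.7 sd (4.5 sd is a safe cap)
  gap <- max(abs(rowSums(da$imfs) + da$residual - x))
  expect_lte(gap, 4.5 * 0.2 * sd(x) / sqrt(50))
})

test_that("decomposition CSV round-trips", {
  t <- (0:499) / 100
  d <- emd(sin(2 * pi * 6 * t) + sin(2 * pi * 1 * t))
  path <- file.path(withr::local_tempdir(), "imfs.csv")
  write_decomposition_csv(d, path)
  back <- read_decomposition_csv(path)
  expect_equal(unname(back$imfs), unname(d$imfs), tolerance = 1e-12)
  expect_equal(back$residual, d$residual, tolerance = 1e-12)
  expect_identical(back$method, "EMD")
  expect_error(read_decomposition_csv(
    {p <- file.path(withr::local_tempdir(), "bad.csv")
     write.csv(data.frame(a = 1:3), p, row.names = FALSE); p}),
    "residual")
})
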