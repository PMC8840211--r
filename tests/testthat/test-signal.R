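# Waveform conditioning: band-pass behavior, normalization, spline
# resampling against analytic signals, peak detection, and NNI arithmetic.

tone <- function(freq, rate, dur, phase = 0) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  pulse_trace(sin(2 * pi * freq * t + phase), rate)
}

interior <- function(n, rate, trim = 2) (trim * rate):(n - trim * rate)

test_that("band-pass keeps the pass band and rejects drift", {
  x <- tone(1.2, 30, 30)
  y <- bandpass(x, 0.5, 4)
  idx <- interior(length(x$samples), 30)
  ratio <- stats::sd(y$samples[idx]) / stats::sd(x$samples[idx])
  expect_lt(abs(ratio - 1), 0.05) # in-band amplitude preserved within 5%

  drift <- tone(0.1, 30, 60)
  yd <- bandpass(drift, 0.5, 4)
  idxd <- interior(length(drift$samples), 30)
  atten <- stats::sd(yd$samples[idxd]) / stats::sd(drift$samples[idxd])
  expect_lt(20 * log10(atten), -20) # stop-band attenuation >= 20 dB

  mix <- pulse_trace(tone(1.2, 30, 30)$samples + tone(6, 30, 30)$samples, 30)
  ym <- bandpass(mix, 0.5, 4)
  expect_gt(stats::cor(ym$samples[idx], tone(1.2, 30, 30)$samples[idx]), 0.99)

  expect_error(bandpass(x, 0, 4), "cutoffs")
  expect_error(bandpass(x, 1, 16), "cutoffs")
})

test_that("band-pass is idempotent and preserves peak times", {
  x <- tone(1.1, 30, 30)
  y1 <- bandpass(x, 0.5, 4)
  y2 <- bandpass(y1, 0.5, 4)
  idx <- interior(length(x$samples), 30)
  expect_gt(stats::cor(y1$samples[idx], y2$samples[idx]), 0.999)
  p_raw <- detect_peaks(znormalize(x), edge_trim = 2)
  p_flt <- detect_peaks(znormalize(y1), edge_trim = 2)
  common <- min(length(p_raw$indices), length(p_flt$indices))
  expect_true(all(abs(p_raw$indices[1:common] - p_flt$indices[1:common]) <= 1))
})

test_that("z-normalization centers, scales, and is idempotent", {
  y <- znormalize(pulse_trace(c(1, 3), 10))
  expect_equal(y$samples, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(31)
  z <- znormalize(pulse_trace(rnorm(100, 5, 3), 10))
  expect_equal(mean(z$samples), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$samples), 1, tolerance = 1e-12)
  expect_equal(znormalize(z)$samples, z$samples, tolerance = 1e-12)
  expect_error(znormalize(pulse_trace(rep(2, 10), 10)), "degenerate")
})

test_that("cubic-spline resampling is exact on polynomials and accurate on tones", {
  const <- pulse_trace(rep(4.2, 40), 20)
  expect_true(all(abs(resample_uniform(const, 77)$samples - 4.2) < 1e-12))
  ramp <- pulse_trace(seq(0, 5, length.out = 50), 10)
  rs <- resample_uniform(ramp, 33)
  t_out <- (seq_along(rs$samples) - 1) / 33
  expect_equal(rs$samples, t_out * (5 / 4.9), tolerance = 1e-9)
  x <- tone(1, 30, 10)
  up <- resample_uniform(x, 256)
  t_up <- (seq_along(up$samples) - 1) / 256
  expect_lt(max(abs(up$samples - sin(2 * pi * t_up))), 1e-3)
  expect_error(resample_uniform(pulse_trace(c(1, 2), 10), 20), "4 samples")
})

test_that("peak detection finds every cycle of a clean tone", {
  x <- tone(1.2, 256, 10)
  pk <- detect_peaks(znormalize(x))
  expect_equal(length(pk$indices), 12)
  gaps <- diff(pk$indices)
  expect_true(all(gaps %in% c(213, 214))) # 256/1.2 = 213.3 samples per beat
  expect_length(detect_peaks(pulse_trace(rep(1, 100), 256))$indices, 0)
  two <- tone(1, 256, 2)
  expect_equal(length(detect_peaks(znormalize(two))$indices), 2)
})

test_that("NNI extraction is exact interval arithmetic", {
  pk <- structure(list(indices = c(1L, 257L, 513L), rate = 256), class = "peak_set")
  expect_equal(as.numeric(peaks_to_nni(pk)), c(1000, 1000))
  pk2 <- structure(list(indices = c(1L, 201L), rate = 256), class = "peak_set")
  expect_equal(as.numeric(peaks_to_nni(pk2)), 781.25)
  pk1 <- structure(list(indices = 5L, rate = 256), class = "peak_set")
  expect_error(peaks_to_nni(pk1), "insufficient beats")
  # total time identity: sum of intervals spans first to last peak exactly
  set.seed(32)
  idx <- sort(sample(10000, 20))
  pkr <- structure(list(indices = idx, rate = 256), class = "peak_set")
  expect_equal(sum(peaks_to_nni(pkr)),
               (idx[20] - idx[1]) / 256 * 1000)
})

test_that("trace text round-trip preserves samples and rate", {
  set.seed(33)
  tr <- pulse_trace(rnorm(64), 30)
  f <- tempfile(fileext = ".csv")
  write_pulse_trace(tr, f)
  back <- read_pulse_trace(f)
  expect_equal(back$rate, 30, tolerance = 1e-6)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
})
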