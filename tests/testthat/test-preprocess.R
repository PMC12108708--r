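test_that("bandpass filter attenuates the stop band and passes the band", {
  # 0.05 Hz drift: one decade below the 0.5 Hz edge
  drift <- sine_record(0.05)
  expect_lt(rms(bandpass_filter(drift)$samples), 0.1 * rms(drift$samples))

  # 10 Hz is mid-band; compare away from the edges (1 s trimmed)
  tone <- sine_record(10)
  out <- bandpass_filter(tone)
  core <- 101:5900
  expect_lt(abs(rms(out$samples[core]) / rms(tone$samples[core]) - 1), 0.05)

  # linearity: zero in, zero out
  z <- bandpass_filter(ecg_record("z", 100, rep(0, 6000)))
  expect_equal(max(abs(z$samples)), 0)
})

test_that("filtering is idempotent in the pass band within 5%", {
  tone <- sine_record(10)
  once <- bandpass_filter(tone)
  twice <- bandpass_filter(once)
  core <- 101:5900
  expect_lt(abs(rms(twice$samples[core]) / rms(once$samples[core]) - 1),
            0.05)
})

test_that("zero-phase filtering preserves timing of an in-band sine", {
  tone <- sine_record(10)
  out <- bandpass_filter(tone)
  core <- 101:5900
  cc <- stats::ccf(out$samples[core], tone$samples[core], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter parameter and degenerate-input errors are raised", {
  r <- sine_record(10)
  expect_error(bandpass_filter(r, filter_spec(high_hz = 50)),
               class = "osadetect_param_error")
  short <- ecg_record("s", 100, rnorm(5))
  expect_error(bandpass_filter(short), class = "osadetect_degenerate_error")
  expect_error(filter_spec(low_hz = 2, high_hz = 1),
               class = "osadetect_param_error")
})

test_that("moving-average smoothing matches a direct convolution oracle", {
  const <- ecg_record("c", 100, rep(3.5, 200))
  expect_equal(smooth_signal(const, 7)$samples, rep(3.5, 200))

  r <- sine_record(5, dur = 2)
  expect_equal(smooth_signal(r, 1)$samples, r$samples)

  imp <- ecg_record("i", 100, c(rep(0, 50), 1, rep(0, 50)))
  sm <- smooth_signal(imp, 5)
  expect_equal(sm$samples[49:53], rep(0.2, 5))
  expect_equal(sm$samples[c(48, 54)], c(0, 0))
  expect_length(sm$samples, 101)

  # truncated-window edges: brute-force oracle on a random signal
  set.seed(3)
  x <- rnorm(30)
  got <- smooth_signal(ecg_record("e", 10, x), 7)$samples
  want <- vapply(seq_along(x), function(i)
    mean(x[max(1, i - 3):min(30, i + 3)]), 0)
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(smooth_signal(imp, 4), class = "osadetect_param_error")
  expect_error(smooth_signal(imp, -3), class = "osadetect_param_error")
})

test_that("outlier detection agrees with a brute-force median/MAD oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(50:300, 1)
    x <- rnorm(n, sd = runif(1, 0.05, 2))
    k <- runif(1, 2, 6)
    got <- detect_outliers(ecg_record("o", 100, x), k)
    med <- median(x)
    madv <- 1.4826 * median(abs(x - med))
    want <- which(abs(x - med) > k * madv) - 1L
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("outlier detection flags an injected spike and honors k", {
  set.seed(3)
  x <- rnorm(6000, sd = 0.1)
  x[1235] <- 5.0                       # 0-based index 1234
  got <- detect_outliers(ecg_record("s", 100, x), 5)
  expect_true(1234 %in% got)
  x2 <- rnorm(6000, sd = 0.1)
  expect_length(detect_outliers(ecg_record("s", 100, x2), 10), 0)
})

test_that("constant signals set the degenerate MAD flag", {
  out <- detect_outliers(ecg_record("c", 100, rep(1, 50)))
  expect_length(out, 0)
  expect_true(attr(out, "degenerate"))
})

test_that("segmentation arithmetic drops the trailing partial window", {
  r <- ecg_record("r", 100, rnorm(60000))       # 600 s
  s <- segment_and_normalize(r)
  expect_equal(dim(s$segments), c(10, 6000))

  r2 <- ecg_record("r", 100, rnorm(65000))      # 650 s
  s2 <- segment_and_normalize(r2)
  expect_equal(nrow(s2$segments), 10)           # final 50 s discarded

  short <- ecg_record("r", 100, rnorm(5999))
  expect_error(segment_and_normalize(short),
               class = "osadetect_degenerate_error")
})

test_that("normalized rows have mean 0 and sd 1; constant rows map to zero", {
  set.seed(4)
  r <- ecg_record("r", 100, rnorm(30000))
  s <- segment_and_normalize(r)
  expect_true(s$normalized)
  expect_lt(max(abs(rowMeans(s$segments))), 1e-6)
  expect_lt(max(abs(apply(s$segments, 1, sd) - 1)), 1e-4)

  flat <- ecg_record("f", 100, rep(2, 12000))
  sf <- segment_and_normalize(flat)
  expect_equal(max(abs(sf$segments)), 0)
})

test_that("unnormalized segments reassemble the input bit-for-bit", {
  set.seed(5)
  x <- rnorm(24500)
  r <- ecg_record("r", 100, x)
  s <- segment_and_normalize(r, normalize = FALSE)
  expect_equal(s$provenance$start_sample, (0:3) * 6000)
  expect_identical(as.vector(t(s$segments)), x[1:24000])
})
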