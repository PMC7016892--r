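fs <- 1000

test_that("comb notch removes the line tone and spares nearby bands", {
  x50 <- tone(50, 10, fs)
  y <- remove_line_noise(x50, rate = fs)
  expect_lt(sqrt(mean(y^2)), 0.01 * sqrt(mean(x50^2)))

  x <- tone(5, 20, fs) + tone(50, 20, fs)
  y <- remove_line_noise(x, rate = fs)
  psd <- compute_psd(y, seg_s = 5, rate = fs)
  p5_in <- trapz_band_test(psd, 4, 6)
  p5_ref <- trapz_band_test(compute_psd(tone(5, 20, fs), seg_s = 5, rate = fs), 4, 6)
  expect_lt(abs(p5_in - p5_ref) / p5_ref, 0.05)
  p50 <- trapz_band_test(psd, 49, 51)
  p50_ref <- trapz_band_test(compute_psd(tone(50, 20, fs), seg_s = 5, rate = fs), 49, 51)
  expect_lt(10 * log10(p50 / p50_ref), -40)

  expect_equal(remove_line_noise(numeric(2000), rate = fs), numeric(2000))
})

test_that("zero-phase filter has zero lag, squared-magnitude attenuation and symmetric impulse response", {
  # passband tone: peak cross-correlation at lag 0
  x <- tone(10, 10, fs) * (1 + 0.3 * tone(0.5, 10, fs))
  y <- zero_phase_filter(x, "low-pass", 25, rate = fs)
  cc <- ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # tone at twice the cutoff: attenuation of the double pass >= 60 dB
  fc <- 25
  x2 <- tone(2 * fc, 10, fs)
  y2 <- zero_phase_filter(x2, "low-pass", fc, order = 5, rate = fs)
  att_db <- 20 * log10(sd(y2[2000:8000]) / sd(x2))
  expect_lt(att_db, -60)
  # and matches the squared analytic Butterworth magnitude at 2 fc
  expected_db <- 10 * log10((1 / (1 + 2^10))^2)
  expect_lt(abs(att_db - expected_db), 1)

  # impulse response symmetric about the impulse time
  imp <- numeric(2001); imp[1001] <- 1
  h <- zero_phase_filter(imp, "band-pass", c(5, 40), rate = fs)
  expect_lt(max(abs(h[1001 + 1:300] - h[1001 - 1:300])), 1e-8)
})

test_that("frequency-domain response agrees with forward-backward filtfilt on a stable design", {
  bf <- signal::butter(5, 25 / (fs / 2), type = "low")
  set.seed(3)
  x <- rnorm(8000)
  y_fd <- zero_phase_filter(x, "low-pass", 25, rate = fs)
  y_tt <- signal::filtfilt(bf, x)
  mid <- 2000:6000
  err <- sqrt(mean((y_fd[mid] - y_tt[mid])^2)) / sd(y_tt[mid])
  expect_lt(err, 0.05)
})

test_that("running-median baseline removal kills drift and spares rhythms", {
  x <- rep(3.7, 5000)
  expect_lt(max(abs(remove_baseline(x, 2, rate = fs))), 1e-12)

  drift <- tone(0.01, 60, fs, amp = 5)
  rhythm <- tone(1, 60, fs)
  y <- remove_baseline(drift + rhythm, 10, rate = fs)
  psd_b <- compute_psd(drift + rhythm, seg_s = 30, rate = fs)
  psd_a <- compute_psd(y, seg_s = 30, rate = fs)
  drift_red <- trapz_band_test(psd_a, 0, 0.05) / trapz_band_test(psd_b, 0, 0.05)
  expect_lt(drift_red, 0.1)
  p1 <- trapz_band_test(psd_a, 0.9, 1.1) / trapz_band_test(psd_b, 0.9, 1.1)
  expect_gt(p1, 0.9)
  expect_lt(p1, 1.1)

  expect_error(remove_baseline(rnorm(100), 10, rate = fs), "exceeds")
})

test_that("decimation keeps every q-th sample and preserves content below the cutoff", {
  x <- seq_len(60 * 10000)
  y <- downsample(x, 500, rate = 10000)
  expect_length(y, 30000)
  expect_equal(y[1:3], c(1, 21, 41))

  expect_equal(downsample(rep(2.5, 1000), 100, rate = 1000), rep(2.5, 100))
  expect_error(downsample(rnorm(100), 300, rate = 1000), "integer multiple")

  x100 <- tone(100, 30, 10000)
  lp <- zero_phase_filter(x100 + 0.1 * rnorm(length(x100)), "low-pass", 190,
                          rate = 10000)
  d <- downsample(lp, 500, rate = 10000)
  psd <- compute_psd(d, seg_s = 5, rate = 500)
  expect_equal(psd$freq[which.max(psd$density[1, ])], 100, tolerance = 1e-6)
})

test_that("preprocessing chain preserves channel count and is deterministic", {
  cfg <- synth_config(n_channels = 2, duration = 20, rate = 1000, seed = 42)
  rec <- generate_lfp(cfg)$rec
  p1 <- preprocess_lfp(rec, median_window_s = 5)
  p2 <- preprocess_lfp(rec, median_window_s = 5)
  expect_identical(p1$samples, p2$samples)
  expect_equal(dim(p1$samples), c(2L, 10000L))
  expect_equal(p1$rate, 500)
})
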