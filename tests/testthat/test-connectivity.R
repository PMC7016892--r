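test_that("Hilbert envelope recovers a known slow modulator", {
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  A <- 1 + 0.5 * sin(2 * pi * 0.2 * t)
  x <- A * sin(2 * pi * 20 * t)
  env <- instantaneous_amplitude(vec_rec(x, fs), c(15, 25))$samples[1, ]
  mid <- (5 * fs):(55 * fs)
  expect_lt(max(abs(env[mid] - A[mid]) / A[mid]), 0.02)

  env_c <- instantaneous_amplitude(vec_rec(tone(20, 20, fs), fs),
                                   c(15, 25))$samples[1, ]
  expect_lt(diff(range(env_c[(2 * fs):(18 * fs)])), 0.02)

  env_z <- instantaneous_amplitude(vec_rec(numeric(10 * fs), fs),
                                   c(15, 25))$samples[1, ]
  expect_true(all(env_z < 1e-10))
  expect_true(all(env >= 0))
})

test_that("xcorr_max matches the direct-evaluation oracle and its contracts", {
  set.seed(44)
  fs <- 100
  a <- as.numeric(stats::filter(rnorm(3000), rep(1 / 20, 20), sides = 2))
  a[is.na(a)] <- 0
  self <- xcorr_max(a, a, fs, 200)
  expect_equal(self[["r_max"]], 1, tolerance = 1e-10)
  expect_equal(self[["latency_ms"]], 0)

  # B delayed by 40 ms: latency(A, B) = -40 (A leads)
  d <- 4  # samples at 100 Hz
  b <- c(rep(0, d), a[1:(length(a) - d)])
  res <- xcorr_max(a, b, fs, 200, interp = FALSE)
  expect_equal(res[["latency_ms"]], -40)
  orc <- xcorr_oracle(a, b, 20)
  expect_equal(res[["latency_ms"]], 1000 * orc[["lag"]] / fs)
  expect_equal(res[["r_max"]], orc[["r"]], tolerance = 1e-6)

  expect_error(xcorr_max(a, a[-1], fs, 100), "equal length")
  expect_error(xcorr_max(a[1:100], a[1:100], fs, 30000), "half the window")
})

test_that("envelope correlation of independent noise stays below the circular-shift null", {
  set.seed(45)
  fs <- 500
  cfg <- synth_config(n_channels = 2, duration = 120, rate = fs,
                      band_fractions = c(so = 0), seed = 46)
  rec <- generate_lfp(cfg)$rec
  env <- instantaneous_amplitude(rec, "so")
  a <- env$samples[1, ]; b <- env$samples[2, ]
  obs <- xcorr_max(a, b, fs, 500)[["r_max"]]
  null_r <- replicate(39, {
    sh <- sample(5000:55000, 1)
    xcorr_max(a, c(b[-(1:sh)], b[1:sh]), fs, 500)[["r_max"]]
  })
  expect_lt(abs(obs), max(abs(null_r)))
})

test_that("connectivity matrices recover an injected lag ladder with correct signs", {
  lags <- c(0, 20, 40, 60)
  cfg <- synth_config(n_channels = 4, duration = 120, rate = 500,
                      band_fractions = c(so = 0.9, delta = 0.08),
                      noise_exponent = 0, so_lag_ms = lags, seed = 50)
  g <- generate_lfp(cfg)
  res <- connectivity_matrices(g$rec, "so")
  expect_equal(res$coeff, t(res$coeff))
  expect_true(all(diag(res$coeff) == 1))
  expect_equal(res$latency_ms, -t(res$latency_ms))
  expect_lt(max(abs(res$latency_ms - g$truth$lag_ms)), 2)
  # channel 1 leads everything: its row is negative off-diagonal
  expect_true(all(res$latency_ms[1, -1] < 0))
})

test_that("a common zero-lag source yields near-unit coefficients at zero latency", {
  cfg <- synth_config(n_channels = 3, duration = 60, rate = 500,
                      band_fractions = c(so = 0.95), noise_exponent = 0,
                      seed = 51)
  rec <- generate_lfp(cfg)$rec
  res <- connectivity_matrices(rec, "so")
  ut <- upper.tri(res$coeff)
  expect_true(all(res$coeff[ut] > 0.9))
  expect_lt(max(abs(res$latency_ms)), 2)
})

test_that("regional averaging reduces matrices coherently", {
  depths <- 2300 - 100 * (0:23)
  regions <- region_scheme(depths)
  expect_true(all(table(regions$region) >= 2))

  v <- 0.42
  res <- structure(list(coeff = matrix(v, 24, 24), latency_ms = matrix(0, 24, 24),
                        band = "so", depths = depths),
                   class = "connectivity_result")
  diag(res$coeff) <- 1
  reg <- regionalize(res, regions)
  expect_true(all(abs(reg$intra$coeff - v) < 1e-12))
  expect_true(all(abs(reg$cross$coeff - v) < 1e-12))

  # constructed lags: cross-regional latency is the mean of pair lags
  lat <- outer(seq_len(24), seq_len(24), function(i, j) 5 * (i - j))
  res$latency_ms <- lat
  reg2 <- regionalize(res, regions)
  dg <- regions$channel[which(regions$region == "DG")]
  l46 <- regions$channel[which(regions$region == "L4/6")]
  expect_equal(
    reg2$cross$latency_ms[reg2$cross$region_a == "L4/6" &
                            reg2$cross$region_b == "DG"],
    mean(lat[l46, dg]))

  # swapping the region order flips the cross-regional sign
  regions_rev <- region_scheme(depths, ranges = list(
    "DG" = c(1700, 2300), "CA1" = c(1100, 1600),
    "L4/6" = c(500, 1000), "L2/3" = c(100, 400)))
  reg3 <- regionalize(res, regions_rev)
  m1 <- reg2$cross$latency_ms[reg2$cross$region_a == "L4/6" &
                                reg2$cross$region_b == "DG"]
  m2 <- reg3$cross$latency_ms[reg3$cross$region_a == "DG" &
                                reg3$cross$region_b == "L4/6"]
  expect_equal(m1, -m2)

  expect_error(regionalize(res, region_scheme(depths, ranges = list(
    "L2/3" = c(100, 400), "tiny" = c(2300, 2300)))), "fewer than 2")
})

test_that("a cortex-leads-DG configuration prints a negative cross-regional latency", {
  # deepest channels (DG) delayed by ~68 ms relative to mid-cortical ones
  depths_lag <- function(d) ifelse(d >= 1700, 68, ifelse(d >= 1100, 30, 0))
  depths <- 2300 - 100 * (0:23)
  cfg <- synth_config(n_channels = 24, duration = 60, rate = 500,
                      band_fractions = c(so = 0.9, delta = 0.08),
                      noise_exponent = 0,
                      so_lag_ms = rev(depths_lag(rev(depths))), seed = 52)
  # channel order is deepest first: lags must align with depths
  cfg$so_lag_ms <- depths_lag(depths)
  g <- generate_lfp(cfg)
  res <- connectivity_matrices(g$rec, "so")
  reg <- regionalize(res, region_scheme(depths))
  lag_cx_dg <- reg$cross$latency_ms[reg$cross$region_a == "L4/6" &
                                      reg$cross$region_b == "DG"]
  expect_lt(lag_cx_dg, -50)
  expect_gt(lag_cx_dg, -85)
})

test_that("adding an in-band constant-phase copy to both channels leaves latency unchanged", {
  cfg <- synth_config(n_channels = 2, duration = 60, rate = 500,
                      band_fractions = c(so = 0.9), noise_exponent = 0,
                      so_lag_ms = c(0, 40), seed = 53)
  rec <- generate_lfp(cfg)$rec
  env0 <- instantaneous_amplitude(rec, "so")
  base <- xcorr_max(env0$samples[1, ], env0$samples[2, ], 500, 500)
  common <- tone(1, 60, 500, amp = 0.2 * sd(rec$samples[1, ]))
  rec2 <- rec
  rec2$samples[1, ] <- rec2$samples[1, ] + common
  rec2$samples[2, ] <- rec2$samples[2, ] + common
  env2 <- instantaneous_amplitude(rec2, "so")
  res2 <- xcorr_max(env2$samples[1, ], env2$samples[2, ], 500, 500)
  expect_equal(res2[["latency_ms"]], base[["latency_ms"]], tolerance = 4)
})
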