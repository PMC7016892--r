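test_that("identical config and seed reproduce signals bit for bit", {
  cfg <- synth_config(n_channels = 2, duration = 20, rate = 500,
                      so_lag_ms = c(0, 30),
                      pac = list(list(phase = "so", amp = "fast_gamma",
                                      depth = 0.5)),
                      unstable_epochs = data.frame(start = 5, end = 10,
                                                   offset = 1, trace = "resp"),
                      seed = 99)
  a <- generate_lfp(cfg); b <- generate_lfp(cfg)
  expect_identical(a$rec$samples, b$rec$samples)
  pa <- generate_physio(cfg); pb <- generate_physio(cfg)
  expect_identical(pa$ecg$samples, pb$ecg$samples)
  expect_identical(pa$resp$samples, pb$resp$samples)
})

test_that("configured band fractions are realized in the generated spectrum", {
  cfg <- synth_config(n_channels = 2, duration = 120, rate = 500, seed = 4)
  g <- generate_lfp(cfg)
  # ground truth (periodogram binning) close to configured + background share
  gt <- g$truth$band_fractions
  conf <- cfg$band_fractions
  # every configured rhythm's share must at least reach its configured
  # fraction (the background only adds)
  for (b in names(conf))
    expect_gt(gt[1, b], 0.85 * conf[[b]])
  expect_true(all(abs(rowSums(gt) - 1) < 0.05))  # bands tile almost all power
})

test_that("noise-only configuration has no envelope connectivity structure", {
  cfg <- synth_config(n_channels = 2, duration = 120, rate = 500,
                      band_fractions = c(so = 0), seed = 12)
  rec <- generate_lfp(cfg)$rec
  env <- instantaneous_amplitude(rec, "so")
  obs <- xcorr_max(env$samples[1, ], env$samples[2, ], rec$rate, 500)
  # circular-shift null for the maximum |r|
  set.seed(1)
  null_r <- replicate(20, {
    sh <- sample(1000:50000, 1)
    b <- c(env$samples[2, -(1:sh)], env$samples[2, 1:sh])
    xcorr_max(env$samples[1, ], b, rec$rate, 500)[["r_max"]]
  })
  expect_lt(abs(obs[["r_max"]]), quantile(abs(null_r), 0.95) * 1.5 + 0.05)
})

test_that("injected lag ground truth is antisymmetric with the leader negative", {
  cfg <- synth_config(n_channels = 2, duration = 10, rate = 500,
                      so_lag_ms = c(0, 40), seed = 2)
  tr <- generate_lfp(cfg)$truth
  expect_equal(tr$lag_ms[1, 2], -40)   # channel 1 leads
  expect_equal(tr$lag_ms, -t(tr$lag_ms))
  expect_true(all(diag(tr$lag_ms) == 0))
})

test_that("PAC injection raises the oracle regression index far above the null", {
  base <- list(n_channels = 1, duration = 120, rate = 500, seed = 71)
  cfg0 <- do.call(synth_config, base)
  cfg8 <- do.call(synth_config, c(base, list(
    pac = list(list(phase = "so", amp = "fast_gamma", depth = 0.8)))))
  idx_of <- function(cfg) {
    rec <- generate_lfp(cfg)$rec
    ph <- instantaneous_phase(rec, "so")$samples[1, ]
    env <- instantaneous_amplitude(rec, "fast_gamma")$samples[1, ]
    pac_oracle_r2(ph, env)
  }
  i0 <- idx_of(cfg0)
  i8 <- idx_of(cfg8)
  expect_gt(i8, 10 * i0)
})

test_that("generator validates its invariants", {
  expect_error(synth_config(duration = 10, rate = 500, so_lag_ms = 20000),
               "lag exceeds")
  expect_error(synth_config(pac = list(list(phase = "so", amp = "fast_gamma",
                                            depth = 1.5))), "depth")
  expect_error(synth_config(band_fractions = c(so = 0.9, delta = 0.2)),
               "sum")
  expect_error(synth_config(duration = 1.0001, rate = 1000), "integer")
  expect_error(synth_config(unstable_epochs = data.frame(
    start = -5, end = 10, offset = 1, trace = "resp"), duration = 20,
    rate = 500), "epochs")
})

test_that("physiology traces have the configured event rates", {
  cfg <- synth_config(n_channels = 1, duration = 60, rate = 500,
                      physio_rate = 200, ecg_rate = 2, seed = 15)
  ph <- generate_physio(cfg)
  expect_equal(length(ph$beat_times), 120, tolerance = 1/120 * 2)
  # event-to-event intervals constant to within the jitter parameter
  iei <- diff(ph$beat_times)
  expect_lt(sd(iei) / mean(iei), 3 * cfg$cycle_jitter)

  # breath-peak count from the ground-truth phase: resp_rate breaths/s
  cfg2 <- synth_config(n_channels = 1, duration = 100, rate = 500,
                       physio_rate = 200, resp_rate = 0.5, seed = 16)
  ph2 <- generate_physio(cfg2)
  n_breaths <- diff(range(ph2$breath_phase)) / pi
  expect_equal(n_breaths, 50, tolerance = 0.05)
})

test_that("unstable epochs offset the instantaneous rate of the named trace", {
  cfg <- synth_config(n_channels = 1, duration = 300, rate = 500,
                      physio_rate = 200, resp_rate = 1,
                      unstable_epochs = data.frame(start = 100, end = 200,
                                                   offset = 1, trace = "resp"),
                      seed = 30)
  ph <- generate_physio(cfg)
  phase <- ph$breath_phase
  fsp <- cfg$physio_rate
  breaths_in <- (phase[200 * fsp] - phase[100 * fsp]) / pi
  breaths_out <- (phase[100 * fsp] - phase[1]) / pi
  expect_equal(breaths_in, (1 + 1) * 100, tolerance = 0.07)
  expect_equal(breaths_out, 1 * 100, tolerance = 0.07)
  expect_equal(ph$epochs$start_idx, 100 * fsp + 1)
})
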