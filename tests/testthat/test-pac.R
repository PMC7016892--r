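test_that("instantaneous phase advances linearly and wraps at pi", {
  fs <- 500
  ph <- instantaneous_phase(vec_rec(tone(3, 30, fs), fs),
                            c(2, 4))$samples[1, ]
  expect_true(all(ph > -pi & ph <= pi))
  mid <- (5 * fs):(25 * fs)
  dph <- diff(ph[mid])
  dph <- dph[dph > -pi]                 # drop the wraps
  expect_equal(median(dph), 2 * pi * 3 / fs, tolerance = 0.01)

  # quarter-period shift: constant phase difference of pi/2
  x1 <- tone(3, 30, fs)
  x2 <- tone(3, 30, fs, phase = -pi / 2)
  p1 <- instantaneous_phase(vec_rec(x1, fs), c(2, 4))$samples[1, mid]
  p2 <- instantaneous_phase(vec_rec(x2, fs), c(2, 4))$samples[1, mid]
  d <- Arg(exp(1i * (p1 - p2)))
  expect_equal(mean(d), pi / 2, tolerance = 0.02)
  expect_lt(sd(d), 0.02)
})

test_that("phase of band-passed noise is uniform", {
  set.seed(60)
  fs <- 500
  x <- rnorm(300 * fs)
  ph <- instantaneous_phase(vec_rec(x, fs), c(4.7, 12))$samples[1, ]
  h <- hist(ph, breaks = seq(-pi, pi, length.out = 21), plot = FALSE)$counts
  cs <- suppressWarnings(chisq.test(h)$statistic)
  # phase samples are serially dependent; compare against a generous bound
  expect_lt(unname(cs) / (length(ph) / sum(h > 0)), 50)
  expect_gt(max(abs(h / sum(h) - 1 / 20)), 0)  # sanity: counts exist
})

test_that("glm_pac equals the least-squares oracle and behaves at the extremes", {
  set.seed(61)
  phi <- runif(20000, -pi, pi)
  amp <- 1 + 0.5 * cos(phi)
  expect_equal(glm_pac(phi, amp), 1.0, tolerance = 1e-9)

  amp_n <- 1 + rnorm(20000, sd = 0.3)
  expect_lt(glm_pac(phi, amp_n), 0.01)

  for (case in 1:10) {
    m <- runif(1, 0.1, 0.9)
    p0 <- runif(1, -pi, pi)
    a <- 1 + m * cos(phi + p0) + rnorm(length(phi), sd = 0.4)
    expect_equal(glm_pac(phi, a), pac_oracle_r2(phi, a), tolerance = 1e-9)
  }

  expect_equal(glm_pac(phi, rep(2, length(phi))), 0)
  expect_equal(glm_pac(phi, amp, index = "r"), 1, tolerance = 1e-9)
})

test_that("the index is invariant to constant phase rotation", {
  set.seed(62)
  phi <- runif(5000, -pi, pi)
  a <- 1 + 0.4 * cos(phi) + rnorm(5000, sd = 0.3)
  i0 <- glm_pac(phi, a)
  for (rot in c(0.7, -2.1, pi / 3)) {
    phi_r <- Arg(exp(1i * (phi + rot)))
    expect_equal(glm_pac(phi_r, a), i0, tolerance = 1e-9)
  }
})

test_that("pac_matrix orders depth-graded coupling and localizes cross coupling", {
  depths_m <- c(0.0, 0.25, 0.6)
  cfg <- synth_config(n_channels = 3, duration = 120, rate = 500,
                      band_fractions = c(so = 0.5, fast_gamma = 0.3),
                      pac = list(list(phase = "so", amp = "fast_gamma",
                                      depth = depths_m)),
                      noise_exponent = 0, seed = 63)
  rec <- generate_lfp(cfg)$rec
  res <- pac_matrix(rec, "so", "fast_gamma", mode = "intra")
  expect_equal(order(res$index), order(depths_m))
  expect_lt(res$index[1], 0.01)

  # cross mode: only the coupled (phase ch 1, amp ch 1) pair is strong
  pairs <- data.frame(phase_channel = c(3, 3), amp_channel = c(3, 1))
  res_cross <- pac_matrix(rec, "so", "fast_gamma", mode = "cross",
                          pairs = pairs)
  expect_gt(res_cross$index[1], 5 * res_cross$index[2])

  expect_error(pac_matrix(rec, "so", "fast_gamma", mode = "cross",
                          pairs = data.frame(phase_channel = 9,
                                             amp_channel = 1)),
               "outside the recording")
})

test_that("amplitude low-pass option keeps coupled indices high and null indices low", {
  cfg <- synth_config(n_channels = 1, duration = 120, rate = 500,
                      band_fractions = c(so = 0.5, fast_gamma = 0.3),
                      pac = list(list(phase = "so", amp = "fast_gamma",
                                      depth = 0.7)),
                      noise_exponent = 0, seed = 64)
  rec <- generate_lfp(cfg)$rec
  plain <- pac_matrix(rec, "so", "fast_gamma", mode = "intra")$index
  lp <- pac_matrix(rec, "so", "fast_gamma", mode = "intra",
                   amp_lowpass = TRUE)$index
  expect_gt(lp, 0.1)
  expect_gt(lp, plain)   # smoothing removes unexplainable fast variance
})

test_that("glm_pac rejects mismatched series", {
  expect_error(glm_pac(runif(100), runif(99)), "equal length")
})
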