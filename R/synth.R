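#' Configuration for the synthetic LFP / physiology generator
#'
#' The generator emulates the statistical structure of laminar LFP under
#' anesthesia with fully known ground truth: a 1/f background plus
#' band-limited Gaussian rhythms with configurable variance fractions
#' (slow oscillations and delta dominating, together about 70% of total
#' power by default), slow-oscillation components propagated across
#' channels with configurable lags of tens of milliseconds, controllable
#' nesting of high-frequency amplitude on slow phase, and ECG/respiration
#' traces with stable baseline rates plus injectable anomalous epochs.
#'
#' @param n_channels number of LFP channels (default 24; electrode depths
#'   are assigned as `2300 - 100*(k-1)` um, deepest first).
#' @param duration recording length in seconds.
#' @param rate native LFP sampling rate in Hz (default 10000);
#'   `duration * rate` must be an integer.
#' @param band_fractions named vector of variance fractions per elementary
#'   band (names from [band_scheme]); non-negative, summing to at most 1.
#'   The remainder is broadband `1/f^a` background noise.
#' @param so_lag_ms per-channel lag (ms) of that channel's slow-oscillation
#'   component relative to channel 1; length `n_channels` (recycled scalar
#'   allowed). Positive lag = the channel trails channel 1.
#' @param pac list of couplings, each `list(phase, amp, depth)` where
#'   `phase`/`amp` name bands and `depth` is the modulation depth m in
#'   `[0, 1]` (scalar, or one value per channel for depth-graded coupling).
#' @param noise_exponent spectral slope a of the `1/f^a` background
#'   (power exponent; 0 gives a flat background).
#' @param total_sd total signal standard deviation in arbitrary
#'   microvolt-scaled units.
#' @param ecg_rate,resp_rate baseline heart and breath rates, Hz
#'   (anesthetized mouse defaults: 5 and 1.5 Hz).
#' @param physio_rate native sampling rate of the physiological traces, Hz.
#' @param cycle_jitter fractional cycle-to-cycle jitter of the heart and
#'   breath periods.
#' @param unstable_epochs data.frame with columns `start`, `end` (s),
#'   `offset` (Hz, added to the instantaneous rate) and `trace`
#'   (`"ecg"` or `"resp"`).
#' @param scheme a [band_scheme] (defaults to the standard one).
#' @param seed integer seed; identical config + seed reproduce the signals
#'   bit for bit.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 24, duration = 300, rate = 10000,
                         band_fractions = c(so = 0.55, delta = 0.15,
                                            theta = 0.04, beta = 0.03,
                                            slow_gamma = 0.03,
                                            fast_gamma = 0.05,
                                            epsilon = 0.05),
                         so_lag_ms = 0, pac = list(),
                         noise_exponent = 1, total_sd = 200,
                         ecg_rate = 5, resp_rate = 1.5, physio_rate = 500,
                         cycle_jitter = 0.02,
                         unstable_epochs = NULL,
                         scheme = band_scheme(), seed = 1L) {
  n <- duration * rate
  if (abs(n - round(n)) > 1e-8)
    stop("duration * rate must be an integer sample count")
  if (any(band_fractions < 0)) stop("band fractions must be non-negative")
  if (sum(band_fractions) > 1 + 1e-12)
    stop("band fractions must sum to at most 1")
  if (!all(names(band_fractions) %in% names(scheme$bands)))
    stop("unknown band in band_fractions: ",
         paste(setdiff(names(band_fractions), names(scheme$bands)),
               collapse = ", "))
  so_lag_ms <- rep_len(so_lag_ms, n_channels)
  if (any(abs(so_lag_ms) / 1000 >= duration))
    stop("slow-oscillation lag exceeds the recording duration")
  for (p in pac) {
    if (!all(c("phase", "amp", "depth") %in% names(p)))
      stop("each pac entry needs fields phase, amp, depth")
    if (any(p$depth < 0 | p$depth > 1))
      stop("pac modulation depth must lie in [0, 1]")
  }
  if (!is.null(unstable_epochs)) {
    ue <- as.data.frame(unstable_epochs)
    stopifnot(all(c("start", "end", "offset", "trace") %in% names(ue)))
    if (any(ue$start < 0) || any(ue$end > duration) || any(ue$end <= ue$start))
      stop("unstable epochs must satisfy 0 <= start < end <= duration")
    if (!all(ue$trace %in% c("ecg", "resp")))
      stop("epoch trace must be 'ecg' or 'resp'")
    unstable_epochs <- ue
  }
  structure(
    list(n_channels = n_channels, duration = duration, rate = rate,
         band_fractions = band_fractions, so_lag_ms = so_lag_ms, pac = pac,
         noise_exponent = noise_exponent, total_sd = total_sd,
         ecg_rate = ecg_rate, resp_rate = resp_rate,
         physio_rate = physio_rate, cycle_jitter = cycle_jitter,
         unstable_epochs = unstable_epochs, scheme = scheme,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# spectral amplitude shape of the 1/f^a background on a two-sided grid;
# amplitude is held flat below f_floor so the background carries no drift
noise_amplitude <- function(f, exponent, f_floor = 0.1) {
  a <- pmax(abs(f), f_floor)^(-exponent / 2)
  a[f == 0] <- 0
  a
}

# band-limited unit-variance Gaussian component: white noise shaped by the
# zero-phase Butterworth band-pass used in analysis, so synthesis and
# analysis share band edges exactly
band_component <- function(n, fs, interval, order = 5) {
  z <- stats::fft(stats::rnorm(n))
  g <- butter_bandpass_pow(fft_freqs(n, fs), interval[1L], interval[2L], order)
  x <- Re(stats::fft(z * g, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic multichannel LFP recording with ground truth
#'
#' Each channel is a sum of band-limited Gaussian processes scaled to the
#' requested variance fractions plus a `1/f` background. The
#' slow-oscillation component of channel k is the channel-1 component
#' delayed by `so_lag_ms[k]` (exact fractional delay); all other components
#' are independent across channels. For each configured coupling the
#' amplitude-band component is multiplied by
#' `(1 + m cos(phase)) / sqrt(1 + m^2/2)`, which preserves its variance, so
#' power ground truth and coupling ground truth stay orthogonal.
#'
#' @param config a [synth_config].
#' @return list with `rec` (an [lfp_recording]) and `truth`, a list holding
#'   `lag_ms` (antisymmetric channel-pair lag matrix under the connectivity
#'   sign convention: entry (i,j) negative when channel i leads),
#'   `band_fractions` (the realized relative spectral content per channel
#'   and band, including the background's in-band share, from exact
#'   periodogram binning of the generated signal), `configured_fractions`,
#'   and `pac` (the injected couplings with per-channel depths).
#' @export
generate_lfp <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- as.integer(round(config$duration * config$rate))
  fs <- config$rate
  nch <- config$n_channels
  scheme <- config$scheme
  fr <- config$band_fractions
  fr <- fr[fr > 0]
  noise_frac <- 1 - sum(fr)

  so_base <- if ("so" %in% names(fr))
    band_component(n, fs, scheme$bands$so) else NULL

  pac_truth <- lapply(config$pac, function(p)
    list(phase = p$phase, amp = p$amp,
         depth = rep_len(p$depth, nch)))

  samples <- matrix(0, nrow = nch, ncol = n)
  for (k in seq_len(nch)) {
    comps <- list()
    for (b in names(fr)) {
      comps[[b]] <- if (b == "so") {
        d <- config$so_lag_ms[k] / 1000
        if (d != 0) fractional_delay(so_base, d, fs) else so_base
      } else {
        band_component(n, fs, scheme$bands[[b]])
      }
    }
    # nest amplitude-band components on phase-band components
    for (p in pac_truth) {
      m <- p$depth[k]
      if (m > 0 && !is.null(comps[[p$amp]]) && !is.null(comps[[p$phase]])) {
        phi <- Arg(analytic_signal(comps[[p$phase]]))
        comps[[p$amp]] <- comps[[p$amp]] * (1 + m * cos(phi)) /
          sqrt(1 + m^2 / 2)
      }
    }
    x <- numeric(n)
    for (b in names(comps)) {
      c_b <- comps[[b]]
      x <- x + c_b / stats::sd(c_b) * sqrt(fr[[b]]) * config$total_sd
    }
    if (noise_frac > 0) {
      z <- stats::fft(stats::rnorm(n))
      amp <- noise_amplitude(fft_freqs(n, fs), config$noise_exponent)
      nz <- Re(stats::fft(z * amp, inverse = TRUE)) / n
      x <- x + nz / stats::sd(nz) * sqrt(noise_frac) * config$total_sd
    }
    samples[k, ] <- x
  }

  depths <- 2300 - 100 * (seq_len(nch) - 1)
  rec <- lfp_recording(samples, fs, depths)

  lag <- outer(config$so_lag_ms, config$so_lag_ms, `-`)  # (i,j) < 0: i leads
  truth <- list(
    lag_ms = lag,
    band_fractions = realized_band_fractions(samples, fs, scheme),
    configured_fractions = config$band_fractions,
    pac = pac_truth
  )
  list(rec = rec, truth = truth)
}

# exact relative spectral content per channel and elementary band from
# periodogram bin sums over the Total range (ground truth for the
# realization, independent of the Welch/trapezoid estimator)
realized_band_fractions <- function(samples, fs, scheme) {
  n <- ncol(samples)
  f <- fft_freqs(n, fs)
  total <- scheme$composites$total
  out <- matrix(NA_real_, nrow(samples), length(scheme$bands),
                dimnames = list(NULL, names(scheme$bands)))
  for (k in seq_len(nrow(samples))) {
    p <- Mod(stats::fft(samples[k, ]))^2
    tot <- sum(p[abs(f) >= total[1L] & abs(f) <= total[2L]])
    for (b in names(scheme$bands)) {
      iv <- scheme$bands[[b]]
      hi_closed <- abs(iv[2L] - total[2L]) < 1e-9
      inb <- abs(f) >= iv[1L] &
        (if (hi_closed) abs(f) <= iv[2L] else abs(f) < iv[2L])
      out[k, b] <- sum(p[inb]) / tot
    }
  }
  out
}

#' Generate synthetic ECG and respiration traces with ground truth
#'
#' The ECG is a train of 20 ms biphasic spike templates at the configured
#' heart rate; respiration is a rectified-sine oscillation at the breath
#' rate. Within each configured unstable epoch the instantaneous rate of
#' the named trace is offset by the requested amount. Cycle-to-cycle
#' jitter is multiplicative on the period. Both traces share the LFP clock
#' (t = 0 at the first sample).
#'
#' @param config a [synth_config].
#' @return list with `ecg` and `resp` ([physio_trace]s at
#'   `config$physio_rate`), `beat_times` and `breath_phase` (ground-truth
#'   event times / cumulative phase), and `epochs` (the injected unstable
#'   epochs with sample indices at the physio rate).
#' @export
generate_physio <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed((config$seed + 999983L) %% .Machine$integer.max)
  fs <- config$physio_rate
  dur <- config$duration
  n <- as.integer(round(dur * fs))
  ue <- config$unstable_epochs

  rate_at <- function(t, base, which) {
    r <- rep(base, length(t))
    if (!is.null(ue)) {
      for (i in seq_len(nrow(ue))) {
        if (ue$trace[i] != which) next
        r <- r + ue$offset[i] * (t >= ue$start[i] & t < ue$end[i])
      }
    }
    if (any(r <= 0)) stop("rate offset drives the ", which, " rate below zero")
    r
  }

  # ECG: integrate the instantaneous rate into beat times
  beats <- numeric(0)
  t <- stats::runif(1, 0, 1 / config$ecg_rate)
  while (t < dur) {
    beats <- c(beats, t)
    period <- 1 / rate_at(t, config$ecg_rate, "ecg")
    t <- t + period * (1 + config$cycle_jitter * stats::rnorm(1))
  }
  if (length(beats) < 2L) stop("recording too short for the configured heart rate")
  # biphasic beat complex, 40 ms: dominant lobe below the 25 Hz ECG
  # low-pass so the preprocessed beat amplitude is alignment-stable
  bw <- 0.04
  tmpl_t <- seq(0, bw, by = 1 / fs)
  template <- sin(2 * pi * tmpl_t / bw) * sin(pi * tmpl_t / bw)^2
  ecg <- numeric(n)
  idx0 <- round(beats * fs) + 1L
  for (i0 in idx0[idx0 <= n]) {
    ii <- i0:min(i0 + length(template) - 1L, n)
    ecg[ii] <- ecg[ii] + template[seq_along(ii)]
  }
  ecg <- ecg + 0.02 * stats::rnorm(n)

  # respiration: rectified sine with phase advancing at the breath rate
  tt <- (seq_len(n) - 1L) / fs
  r_resp <- rate_at(tt, config$resp_rate, "resp")
  slow <- apply_fd_gain(stats::rnorm(n), fs, function(f)
    butter_lowpass_pow(f, 0.1, 2))
  r_resp <- r_resp * (1 + config$cycle_jitter * slow / max(stats::sd(slow), 1e-12))
  phase <- pi * cumsum(r_resp) / fs
  resp <- abs(sin(phase)) + 0.02 * stats::rnorm(n)

  epochs <- NULL
  if (!is.null(ue)) {
    epochs <- ue
    epochs$start_idx <- pmax(1L, as.integer(floor(ue$start * fs)) + 1L)
    epochs$end_idx <- pmin(n, as.integer(ceiling(ue$end * fs)))
  }

  list(
    ecg = physio_trace(ecg, fs, "ecg"),
    resp = physio_trace(resp, fs, "respiration"),
    beat_times = beats,
    breath_phase = phase,
    epochs = epochs
  )
}
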