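#' Remove mains noise with a Gaussian comb notch
#'
#' Attenuates the line frequency and its harmonics with Gaussian notches in
#' the frequency domain: the gain is `1 - sum_h exp(-(f - h f0)^2 / (2 s^2))`
#' (depth 1 at each center, width `sigma`), applied with zero phase so the
#' signal length and timing are unchanged.
#'
#' @param x an [lfp_recording], [physio_trace] or numeric vector.
#' @param center line frequency in Hz (default 50).
#' @param n_harmonics number of harmonics to notch, counting the
#'   fundamental (default 3: 50, 100, 150 Hz).
#' @param sigma notch width (Gaussian standard deviation) in Hz.
#' @param rate sampling rate; taken from `x` when it is a recording/trace.
#' @return same type as `x`.
#' @export
remove_line_noise <- function(x, center = 50, n_harmonics = 3, sigma = 1,
                              rate = NULL) {
  apply_to_signal(x, rate, function(v, fs) {
    if (center * n_harmonics >= fs / 2)
      stop("notch harmonic ", center * n_harmonics,
           " Hz is at or above Nyquist (", fs / 2, " Hz)")
    centers <- center * seq_len(n_harmonics)
    apply_fd_gain(v, fs, function(f) {
      g <- rep(1, length(f))
      for (c0 in centers)
        g <- g - exp(-(abs(f) - c0)^2 / (2 * sigma^2))
      pmax(g, 0)
    }, pad = "none")
  })
}

#' Zero-phase Butterworth filtering
#'
#' Applies the effective magnitude of a forward-backward order-`order`
#' Butterworth filter (the square of the single-pass magnitude response)
#' with exactly zero phase: band-limited features are attenuated without
#' any shift of envelope or phase. The response is evaluated analytically
#' on the frequency grid, which keeps narrow designs such as the
#' slow-oscillation band-pass (0.1-1.7 Hz at a 500 Hz rate) exact where a
#' time-domain IIR realization loses stability.
#'
#' @param x recording, trace or numeric vector.
#' @param kind `"low-pass"`, `"high-pass"` or `"band-pass"`.
#' @param edges cutoff (Hz): one value for low/high-pass, `c(low, high)`
#'   for band-pass.
#' @param order Butterworth order of each pass (default 5).
#' @param rate sampling rate override for bare vectors.
#' @return same type as `x`.
#' @export
zero_phase_filter <- function(x, kind = c("low-pass", "band-pass", "high-pass"),
                              edges, order = 5, rate = NULL) {
  kind <- match.arg(kind)
  n_edges <- if (kind == "band-pass") 2L else 1L
  if (length(edges) != n_edges)
    stop(kind, " needs ", n_edges, " edge(s)")
  apply_to_signal(x, rate, function(v, fs) {
    if (any(edges <= 0) || any(edges >= fs / 2))
      stop("filter edges must lie strictly inside (0, ", fs / 2, ") Hz")
    apply_fd_gain(v, fs, function(f)
      butter_zerophase_gain(f, kind, edges, order))
  })
}

#' Remove baseline drift with a running median
#'
#' Subtracts a running median of window `window_s` seconds; window edges
#' are handled by shrinking windows (`stats::runmed` end rule "median"),
#' so the output has the same length. Drift slower than roughly
#' `1/window_s` Hz is suppressed while in-band rhythms pass.
#'
#' @param x recording, trace or numeric vector.
#' @param window_s running-median window, seconds. Defaults: 10 s is
#'   appropriate for LFP (spares the slow-oscillation band), 1 s for ECG,
#'   5 s for respiration.
#' @param rate sampling rate override for bare vectors.
#' @export
remove_baseline <- function(x, window_s = 10, rate = NULL) {
  apply_to_signal(x, rate, function(v, fs) {
    k <- round(window_s * fs)
    if (k < 3) stop("baseline window must span at least 3 samples")
    if (k > length(v)) stop("baseline window exceeds the trace length")
    if (k %% 2L == 0L) k <- k - 1L
    v - stats::runmed(v, k, endrule = "median")
  })
}

#' Decimate to a lower sampling rate
#'
#' Keeps every `rate/target`-th sample. An anti-alias low-pass (190 Hz for
#' LFP before 500 Hz, 25 Hz for ECG before 50 Hz, 10 Hz for respiration
#' before 20 Hz) must have been applied first; this function does not
#' filter.
#'
#' @param x recording, trace or numeric vector.
#' @param target target rate in Hz; the native rate must be an integer
#'   multiple.
#' @param rate sampling rate override for bare vectors.
#' @export
downsample <- function(x, target, rate = NULL) {
  fs <- signal_rate(x, rate)
  q <- fs / target
  if (abs(q - round(q)) > 1e-9)
    stop("native rate ", fs, " Hz is not an integer multiple of ", target, " Hz")
  q <- as.integer(round(q))
  pick <- function(v) v[seq.int(1L, by = q, length.out = length(v) %/% q)]
  if (inherits(x, "lfp_recording")) {
    lfp_recording(t(apply(x$samples, 1L, pick)), target, x$depths, x$t0)
  } else if (inherits(x, "physio_trace")) {
    physio_trace(pick(x$samples), target, x$kind, x$t0)
  } else {
    pick(x)
  }
}

#' Standard preprocessing chains
#'
#' `preprocess_lfp` runs notch -> baseline removal -> 190 Hz low-pass ->
#' decimation to 500 Hz on every channel; `preprocess_ecg` and
#' `preprocess_resp` run baseline removal -> low-pass (25 / 10 Hz) ->
#' decimation (50 / 20 Hz). Filter order is 5 throughout.
#'
#' @param rec an [lfp_recording] at the native rate.
#' @param line_freq mains frequency for the comb notch; `NULL` skips the
#'   notch (useful when the native Nyquist is below the harmonics).
#' @param n_harmonics,notch_sigma comb notch parameters.
#' @param median_window_s running-median window, seconds.
#' @param lp_cutoff anti-alias low-pass cutoff, Hz.
#' @param target_rate decimation target, Hz.
#' @param order Butterworth order.
#' @return preprocessed object at `target_rate`.
#' @export
preprocess_lfp <- function(rec, line_freq = 50, n_harmonics = 3,
                           notch_sigma = 1, median_window_s = 10,
                           lp_cutoff = 190, target_rate = 500, order = 5) {
  if (!is.null(line_freq) && line_freq * n_harmonics < rec$rate / 2)
    rec <- remove_line_noise(rec, line_freq, n_harmonics, notch_sigma)
  rec <- remove_baseline(rec, median_window_s)
  rec <- zero_phase_filter(rec, "low-pass", lp_cutoff, order)
  downsample(rec, target_rate)
}

#' @rdname preprocess_lfp
#' @param trace a [physio_trace] at the native rate.
#' @export
preprocess_ecg <- function(trace, median_window_s = 1, lp_cutoff = 25,
                           target_rate = 50, order = 5) {
  trace <- remove_baseline(trace, median_window_s)
  trace <- zero_phase_filter(trace, "low-pass", lp_cutoff, order)
  downsample(trace, target_rate)
}

#' @rdname preprocess_lfp
#' @export
preprocess_resp <- function(trace, median_window_s = 5, lp_cutoff = 10,
                            target_rate = 20, order = 5) {
  trace <- remove_baseline(trace, median_window_s)
  trace <- zero_phase_filter(trace, "low-pass", lp_cutoff, order)
  downsample(trace, target_rate)
}

# dispatch a per-channel vector operation over the supported signal types
apply_to_signal <- function(x, rate, fun) {
  if (inherits(x, "lfp_recording")) {
    out <- t(apply(x$samples, 1L, fun, fs = x$rate))
    lfp_recording(out, x$rate, x$depths, x$t0)
  } else if (inherits(x, "physio_trace")) {
    physio_trace(fun(x$samples, x$rate), x$rate, x$kind, x$t0)
  } else {
    if (is.null(rate)) stop("rate must be given for bare numeric signals")
    fun(as.numeric(x), rate)
  }
}

signal_rate <- function(x, rate = NULL) {
  if (inherits(x, "lfp_recording") || inherits(x, "physio_trace")) x$rate
  else if (!is.null(rate)) rate
  else stop("rate must be given for bare numeric signals")
}
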