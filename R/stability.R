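#' Detect heartbeat or breath events on a preprocessed trace
#'
#' Events are local maxima above an adaptive threshold
#' `median + k * MAD`, separated by at least a refractory period.
#' Candidates are accepted in order of decreasing amplitude, so of two
#' peaks closer than the refractory period the larger wins. Defaults are
#' sized to the anesthetized mouse: ECG uses k = 2 with an 80 ms
#' refractory (heart rates up to ~12 Hz resolvable; at tachycardic rates
#' the beat duty cycle inflates the MAD, so a spike-oriented k = 4 would
#' miss beats), respiration uses k = 0.5 with a 200 ms refractory, since
#' a smooth quasi-sinusoidal breath trace never exceeds median + 4 MAD.
#'
#' @param trace a preprocessed [physio_trace] (50 Hz ECG or 20 Hz
#'   respiration).
#' @param k MAD multiplier of the threshold; default by trace kind.
#' @param refractory_s minimum event spacing, seconds; default by kind.
#' @return event times in seconds on the recording clock.
#' @export
detect_events <- function(trace, k = NULL, refractory_s = NULL) {
  stopifnot(inherits(trace, "physio_trace"))
  if (is.null(k)) k <- if (trace$kind == "ecg") 2 else 0.5
  if (is.null(refractory_s))
    refractory_s <- if (trace$kind == "ecg") 0.08 else 0.2
  x <- trace$samples
  n <- length(x)
  med <- stats::median(x)
  spread <- k * stats::mad(x)
  if (trace$kind == "ecg") {
    # guard against noise crossings at low duty cycles: never set the
    # threshold below 40% of the beat amplitude (0.995 quantile)
    spread <- max(spread, 0.4 * (stats::quantile(x, 0.995) - med))
  }
  thr <- med + spread
  # one event per contiguous above-threshold excursion (its maximum), so
  # noise ripples on a broad peak cannot split one event into several
  above <- x > thr
  if (!any(above)) stop("fewer than 10 ", trace$kind,
                        " events detected; trace unusable for rate gating")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- which(r$values)
  cand <- vapply(reg, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(x[seg])]
  }, integer(1))
  # amplitude-priority refractory enforcement across excursions
  cand <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- max(1L, round(refractory_s * trace$rate))
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) >= min_gap)) taken <- c(taken, i)
  }
  taken <- sort(taken)
  if (length(taken) < 10L)
    stop("fewer than 10 ", trace$kind, " events detected; ",
         "trace unusable for rate gating")
  (taken - 1L) / trace$rate + trace$t0
}

#' Instantaneous event rate from inter-event intervals
#'
#' One rate per inter-event interval, `1 / IEI`, timestamped at the
#' interval midpoint.
#'
#' @param events event times, seconds, strictly increasing.
#' @return object of class `rate_series`: data.frame with `time` (s) and
#'   `rate` (Hz), plus the event times as an attribute.
#' @export
event_rates <- function(events) {
  if (length(events) < 2L) stop("need at least two events for a rate")
  if (any(diff(events) <= 0)) stop("event times must be strictly increasing")
  iei <- diff(events)
  out <- data.frame(time = events[-length(events)] + iei / 2, rate = 1 / iei)
  attr(out, "events") <- events
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Stability bounds on an event rate
#'
#' Lower/upper bounds are the median rate minus/plus a fixed constant:
#' 0.5 Hz for respiration and 2 Hz for heartbeats by convention. A
#' non-positive lower bound is clamped to zero with a warning.
#'
#' @param rates rate values in Hz (or a `rate_series`).
#' @param constant the rate constant in Hz.
#' @return `c(lower, upper)` in Hz.
#' @export
rate_bounds <- function(rates, constant) {
  if (inherits(rates, "rate_series")) rates <- rates$rate
  if (length(rates) < 10L) stop("need at least 10 rate values")
  m <- stats::median(rates)
  lower <- m - constant
  if (lower <= 0) {
    warning("lower rate bound clamped to 0")
    lower <- 0
  }
  c(lower = lower, upper = m + constant)
}

#' Per-sample stability mask on a target clock
#'
#' A sample is stable iff the event rate of the enclosing inter-event
#' interval lies within `bounds`. Samples before the first and after the
#' last event inherit the nearest interval's rate. Stable runs are then
#' eroded by one interval at every stability transition (an interval
#' adjacent to an out-of-bounds interval counts as unstable), so a
#' partially affected boundary interval cannot leak into the selected
#' window; a fully stable trace is untouched by the erosion.
#'
#' @param rates a `rate_series` from [event_rates].
#' @param bounds `c(lower, upper)` from [rate_bounds].
#' @param n_samples,rate,t0 the target clock (typically the preprocessed
#'   LFP clock) on which the mask is laid out.
#' @return logical vector of length `n_samples`.
#' @export
stable_mask <- function(rates, bounds, n_samples, rate, t0 = 0) {
  stopifnot(inherits(rates, "rate_series"))
  events <- attr(rates, "events")
  ok <- rates$rate >= bounds[1L] & rates$rate <= bounds[2L]
  # erode by one interval at transitions
  nI <- length(ok)
  ok_er <- ok
  if (nI > 1L) {
    ok_er <- ok & c(ok[1L], ok[-nI]) & c(ok[-1L], ok[nI])
  }
  t <- (seq_len(n_samples) - 1L) / rate + t0
  # interval index of each sample: findInterval over interior breakpoints,
  # clamped so edge samples inherit the nearest interval
  idx <- findInterval(t, events[-c(1L, length(events))]) + 1L
  idx <- pmin(pmax(idx, 1L), nI)
  ok_er[idx]
}

#' Select the earliest stable analysis window
#'
#' Intersects the ECG and respiration stability masks (both on the same
#' clock) and returns the earliest contiguous all-stable run of at least
#' `duration_s`, trimmed to exactly `duration_s` from its start.
#'
#' @param mask_ecg,mask_resp logical masks of equal length on one clock.
#' @param rate the clock rate, Hz.
#' @param duration_s window length, seconds (default 300: the five-minute
#'   analysis window).
#' @param t0 clock origin, seconds.
#' @return object of class `stable_window`: list with `start`, `end`
#'   (seconds) and `start_idx`, `end_idx` (1-based sample indices).
#' @export
select_window <- function(mask_ecg, mask_resp, rate, duration_s = 300, t0 = 0) {
  if (length(mask_ecg) != length(mask_resp))
    stop("stability masks must share one clock")
  both <- mask_ecg & mask_resp
  need <- as.integer(round(duration_s * rate))
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    stop("no stable window: longest joint stable run is ",
         round(max(c(0, r$lengths[r$values])) / rate, 1),
         " s, need ", duration_s, " s")
  s <- starts[hit[1L]]
  structure(
    list(start = (s - 1L) / rate + t0,
         end = (s - 1L + need) / rate + t0,
         start_idx = s, end_idx = s + need - 1L),
    class = "stable_window"
  )
}

#' @export
print.stable_window <- function(x, ...) {
  cat(sprintf("stable window: [%.2f, %.2f] s\n", x$start, x$end))
  invisible(x)
}

#' Run the full three-step stability gating for a recording session
#'
#' Detects events on the preprocessed ECG and respiration, computes rate
#' bounds (median +/- 2 Hz for heartbeats, +/- 0.5 Hz for respiration),
#' lays both stability masks on the LFP clock and selects the earliest
#' joint stable window.
#'
#' @param ecg,resp preprocessed [physio_trace]s.
#' @param n_lfp,lfp_rate length and rate of the preprocessed LFP the
#'   window will index into.
#' @param constant_ecg,constant_resp rate constants, Hz.
#' @param duration_s window length, seconds.
#' @return list with the `stable_window`, per-trace bounds and masks.
#' @export
gate_stable_window <- function(ecg, resp, n_lfp, lfp_rate,
                               constant_ecg = 2, constant_resp = 0.5,
                               duration_s = 300) {
  ev_e <- detect_events(ecg)
  ev_r <- detect_events(resp)
  rs_e <- event_rates(ev_e)
  rs_r <- event_rates(ev_r)
  b_e <- rate_bounds(rs_e, constant_ecg)
  b_r <- rate_bounds(rs_r, constant_resp)
  m_e <- stable_mask(rs_e, b_e, n_lfp, lfp_rate)
  m_r <- stable_mask(rs_r, b_r, n_lfp, lfp_rate)
  win <- select_window(m_e, m_r, lfp_rate, duration_s)
  list(window = win, bounds_ecg = b_e, bounds_resp = b_r,
       mask_ecg = m_e, mask_resp = m_r)
}

#' Crop a recording to a stable window
#' @param rec an [lfp_recording].
#' @param window a `stable_window` on `rec`'s clock.
#' @export
crop_recording <- function(rec, window) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(window, "stable_window"))
  lfp_recording(rec$samples[, window$start_idx:window$end_idx, drop = FALSE],
                rec$rate, rec$depths, t0 = window$start)
}
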