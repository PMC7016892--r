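#' Instantaneous band amplitude (Hilbert envelope)
#'
#' Band-passes each channel with the zero-phase order-5 Butterworth
#' response for the named band, then takes the modulus of the analytic
#' signal. Output is non-negative, same length and clock as the input.
#'
#' @param rec an [lfp_recording] (preprocessed, stable window applied).
#' @param band band name resolved in `scheme`, or a `c(low, high)` Hz pair.
#' @param scheme a [band_scheme].
#' @param order Butterworth order.
#' @return an [lfp_recording] holding the envelopes.
#' @export
instantaneous_amplitude <- function(rec, band = "so", scheme = band_scheme(),
                                    order = 5) {
  iv <- if (is.character(band)) band_interval(scheme, band) else band
  if (iv[2L] >= rec$rate / 2)
    stop("band upper edge ", iv[2L], " Hz is at or above Nyquist")
  bp <- zero_phase_filter(rec, "band-pass", iv, order)
  env <- t(apply(bp$samples, 1L, function(v) Mod(analytic_signal(v))))
  lfp_recording(env, rec$rate, rec$depths, rec$t0)
}

#' Instantaneous band phase
#'
#' Argument of the analytic signal of the band-passed trace, radians in
#' `(-pi, pi]`.
#'
#' @inheritParams instantaneous_amplitude
#' @return an [lfp_recording] holding the phases.
#' @export
instantaneous_phase <- function(rec, band = "so", scheme = band_scheme(),
                                order = 5) {
  iv <- if (is.character(band)) band_interval(scheme, band) else band
  if (iv[2L] >= rec$rate / 2)
    stop("band upper edge ", iv[2L], " Hz is at or above Nyquist")
  bp <- zero_phase_filter(rec, "band-pass", iv, order)
  ph <- t(apply(bp$samples, 1L, function(v) Arg(analytic_signal(v))))
  lfp_recording(ph, rec$rate, rec$depths, rec$t0)
}

#' Maximal envelope cross-correlation and latency
#'
#' Normalized cross-correlation `c(tau) = corr(a(t + tau), b(t))` of two
#' mean-subtracted envelopes over a lag grid `|tau| <= max_lag_ms`,
#' maximizing `|c|`. Sign convention: a negative latency of (a, b) means
#' a leads b, so a cortical channel anticipating a hippocampal one prints
#' a negative lag. By default the discrete peak is refined by parabolic
#' interpolation over its two neighbours, the standard sub-sample
#' refinement in time-delay estimation; `interp = FALSE` reports the raw
#' lag grid value.
#'
#' @param env_a,env_b numeric envelope vectors of equal length.
#' @param rate sampling rate, Hz.
#' @param max_lag_ms lag search range, ms (default 500, appropriate for
#'   slow oscillations; use ~250 for delta).
#' @param interp logical: parabolic sub-sample peak refinement.
#' @return `c(r_max, latency_ms)`.
#' @export
xcorr_max <- function(env_a, env_b, rate, max_lag_ms = 500, interp = TRUE) {
  n <- length(env_a)
  if (length(env_b) != n) stop("envelopes must have equal length")
  max_lag <- as.integer(round(max_lag_ms / 1000 * rate))
  if (max_lag > n %/% 2L)
    stop("max lag exceeds half the window length")
  a <- env_a - mean(env_a)
  b <- env_b - mean(env_b)
  np <- next_fft_len(n + max_lag + 1L)
  fa <- stats::fft(c(a, numeric(np - n)))
  fb <- stats::fft(c(b, numeric(np - n)))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / np
  lags <- (-max_lag):max_lag
  idx <- ifelse(lags >= 0L, lags + 1L, np + lags + 1L)
  r <- cc[idx] / sqrt(sum(a^2) * sum(b^2))
  k <- which.max(abs(r))
  lag <- as.numeric(lags[k])
  if (interp && k > 1L && k < length(r)) {
    y1 <- abs(r[k - 1L]); y2 <- abs(r[k]); y3 <- abs(r[k + 1L])
    den <- y1 - 2 * y2 + y3
    if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  c(r_max = r[k], latency_ms = 1000 * lag / rate)
}

#' All-pairs envelope connectivity matrices
#'
#' Maximal envelope cross-correlation and signed latency for every channel
#' pair of a band. The coefficient matrix is symmetric with unit diagonal;
#' the latency matrix is antisymmetric with zero diagonal (computed on the
#' upper triangle and reflected).
#'
#' @param rec preprocessed [lfp_recording] (stable window applied).
#' @param band band name or `c(low, high)` Hz.
#' @param max_lag_ms lag search range, ms.
#' @param scheme a [band_scheme].
#' @param interp parabolic peak refinement (see [xcorr_max]).
#' @return object of class `connectivity_result`: list with `coeff`,
#'   `latency_ms` (channel x channel matrices), `band`, `depths`.
#' @export
connectivity_matrices <- function(rec, band = "so", max_lag_ms = 500,
                                  scheme = band_scheme(), interp = TRUE) {
  env <- instantaneous_amplitude(rec, band, scheme)
  nch <- n_channels(rec)
  coeff <- diag(1, nch)
  lat <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      res <- xcorr_max(env$samples[i, ], env$samples[j, ], rec$rate,
                       max_lag_ms, interp)
      coeff[i, j] <- coeff[j, i] <- res[["r_max"]]
      lat[i, j] <- res[["latency_ms"]]
      lat[j, i] <- -res[["latency_ms"]]
    }
  }
  structure(
    list(coeff = coeff, latency_ms = lat,
         band = if (is.character(band)) band else paste(band, collapse = "-"),
         depths = rec$depths),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("connectivity (%s band): %d channels, mean |r| = %.3f, latency range [%.1f, %.1f] ms\n",
              x$band, nrow(x$coeff), mean(abs(x$coeff[upper.tri(x$coeff)])),
              min(x$latency_ms), max(x$latency_ms)))
  invisible(x)
}

#' Regional averaging of connectivity matrices
#'
#' Intraregional values average the within-region channel pairs (diagonal
#' excluded); cross-regional values average the between-region pairs with
#' a fixed region order (the order of `scheme`'s levels, cortex first by
#' default), so latency signs are coherent: latency(A, B) < 0 means
#' region A leads region B.
#'
#' @param result a `connectivity_result`.
#' @param regions a [region_scheme] covering the matrix's channels.
#' @return list of two data.frames: `intra` (region, coeff, latency_ms)
#'   and `cross` (region_a, region_b, coeff, latency_ms).
#' @export
regionalize <- function(result, regions) {
  stopifnot(inherits(result, "connectivity_result"),
            inherits(regions, "region_scheme"))
  lv <- levels(regions$region)
  idx <- lapply(lv, function(r) regions$channel[which(regions$region == r)])
  names(idx) <- lv

  intra <- do.call(rbind, lapply(lv, function(r) {
    ch <- idx[[r]]
    if (length(ch) < 2L)
      stop("region ", r, " has fewer than 2 channels for intraregional averaging")
    ut <- upper.tri(matrix(0, length(ch), length(ch)))
    data.frame(region = r,
               coeff = mean(result$coeff[ch, ch][ut]),
               latency_ms = mean(abs(result$latency_ms[ch, ch][ut])))
  }))

  combs <- utils::combn(lv, 2L)
  cross <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- idx[[combs[1L, k]]]
    b <- idx[[combs[2L, k]]]
    data.frame(region_a = combs[1L, k], region_b = combs[2L, k],
               coeff = mean(result$coeff[a, b]),
               latency_ms = mean(result$latency_ms[a, b]))
  }))
  list(intra = intra, cross = cross)
}
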