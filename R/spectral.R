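#' Welch power spectral density
#'
#' Average of Hann-windowed, mean-detrended periodograms over 50%
#' overlapping segments. The default 10 s segment gives 0.1 Hz resolution
#' at the 500 Hz analysis rate, enough to resolve the 0.1 Hz lower edge of
#' the slow-oscillation band. The density is one-sided
#' (microvolt^2 per Hz); its integral over `[0, rate/2]` satisfies
#' Parseval within a few percent of the signal variance.
#'
#' @param x an [lfp_recording], [physio_trace] or numeric vector.
#' @param seg_s segment length in seconds (default 10).
#' @param overlap fractional segment overlap (default 0.5).
#' @param rate sampling rate for bare vectors.
#' @return object of class `power_spectrum`: list with `freq` (Hz) and
#'   `density` (channels x frequency matrix, uV^2/Hz).
#' @export
compute_psd <- function(x, seg_s = 10, overlap = 0.5, rate = NULL) {
  fs <- signal_rate(x, rate)
  mat <- if (inherits(x, "lfp_recording")) x$samples
         else matrix(if (inherits(x, "physio_trace")) x$samples
                     else as.numeric(x), nrow = 1L)
  nseg <- as.integer(round(seg_s * fs))
  n <- ncol(mat)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  if (n < nseg + step)
    stop("signal shorter than two Welch segments (", seg_s, " s each)")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  nf <- nseg %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * fs / nseg
  dens <- matrix(0, nrow(mat), nf)
  for (k in seq_len(nrow(mat))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- mat[k, s:(s + nseg - 1L)]
      seg <- (seg - mean(seg)) * w
      p <- Mod(stats::fft(seg)[seq_len(nf)])^2
      acc <- acc + p
    }
    acc <- acc / length(starts) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when present)
    sc <- rep(2, nf)
    sc[1L] <- 1
    if (nseg %% 2L == 0L) sc[nf] <- 1
    dens[k, ] <- acc * sc
  }
  structure(list(freq = freq, density = dens, rate = fs),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power spectrum: %d channel(s), %.3g-%.4g Hz at %.3g Hz resolution\n",
              nrow(x$density), x$freq[1L], max(x$freq), x$freq[2L] - x$freq[1L]))
  invisible(x)
}

# trapezoidal integral of a density over [a, b] with linear interpolation
# at the interval ends; vectorized over the rows of a density matrix
trapz_band <- function(freq, dens, a, b) {
  if (a < freq[1L] - 1e-9 || b > freq[length(freq)] + 1e-9)
    stop("band [", a, ", ", b, "] outside the PSD support")
  grid <- sort(unique(c(a, b, freq[freq > a & freq < b])))
  vals <- apply(dens, 1L, function(d) stats::approx(freq, d, xout = grid)$y)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1L)
  dx <- diff(grid)
  as.numeric(crossprod(vals[-1L, , drop = FALSE] +
                         vals[-length(grid), , drop = FALSE], dx) / 2)
}

#' Band power table
#'
#' Absolute power per channel and band is the trapezoidal integral of the
#' Welch density over the band interval; relative power is the percentage
#' of that channel's total (0.1-190 Hz) power. Because the elementary
#' bands tile the total range and integrals are evaluated on a common
#' grid, the elementary relative powers sum to 100% per channel by
#' construction.
#'
#' @param psd a `power_spectrum` from [compute_psd].
#' @param scheme a [band_scheme].
#' @param depths optional electrode depths, carried into the table.
#' @return object of class `band_power_table`: list of two data.frames,
#'   `absolute` (uV^2) and `relative` (%), rows = channels, columns =
#'   elementary bands plus Low/High/Total.
#' @export
band_powers <- function(psd, scheme = band_scheme(), depths = NULL) {
  stopifnot(inherits(psd, "power_spectrum"))
  all_bands <- c(scheme$bands, scheme$composites)
  absolute <- sapply(names(all_bands), function(b) {
    iv <- all_bands[[b]]
    trapz_band(psd$freq, psd$density, iv[1L], iv[2L])
  })
  if (is.null(dim(absolute)))
    absolute <- matrix(absolute, nrow = 1L,
                       dimnames = list(NULL, names(all_bands)))
  absolute <- as.data.frame(absolute)
  relative <- 100 * absolute / absolute$total
  out <- list(absolute = absolute, relative = relative,
              bands = names(scheme$bands), depths = depths)
  class(out) <- "band_power_table"
  out
}

#' @export
print.band_power_table <- function(x, ...) {
  cat("relative band power (% of total) per channel:\n")
  print(round(x$relative[, x$bands], 2))
  invisible(x)
}

#' Power ratio between two bands
#'
#' Ratio of absolute band powers, per channel: `so / delta` indexes the
#' low-range power imbalance, `low / high` the broad imbalance between
#' 0.1-4.7 Hz and 4.7-190 Hz.
#'
#' @param table a `band_power_table`.
#' @param a,b band names (elementary or composite).
#' @return numeric vector, one dimensionless ratio per channel;
#'   `NA` where the denominator power is zero.
#' @export
power_ratio <- function(table, a, b) {
  stopifnot(inherits(table, "band_power_table"))
  for (nm in c(a, b))
    if (!nm %in% names(table$absolute)) stop("band not in table: ", nm)
  num <- table$absolute[[a]]
  den <- table$absolute[[b]]
  out <- ifelse(den > 0, num / den, NA_real_)
  if (any(den == 0)) warning("zero denominator power; ratio flagged NA")
  out
}

#' Total power per channel (integral of the PSD over 0.1-190 Hz)
#' @param psd a `power_spectrum`.
#' @param scheme a [band_scheme].
#' @export
total_power <- function(psd, scheme = band_scheme()) {
  iv <- scheme$composites$total
  trapz_band(psd$freq, psd$density, iv[1L], iv[2L])
}
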