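# Independent oracles and small fixture builders used across the suite.

# single-channel recording from a bare vector
vec_rec <- function(x, rate, depth = 1500) {
  lfp_recording(matrix(x, nrow = 1L), rate, depth)
}

tone <- function(freq, duration, rate, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(duration * rate - 1)) / rate + phase)
}

# Kruskal-Wallis H by the direct rank-sum formula (no tie correction;
# used on tie-free data only)
kw_oracle_H <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  N <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  12 / (N * (N + 1)) * sum(rs^2 / lengths(groups)) - 3 * (N + 1)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data); doubled smaller tail, capped at 1, matching the
# standard exact two-sided convention for the symmetric U distribution
mw_oracle_p <- function(a, b) {
  x <- c(a, b)
  stopifnot(!any(duplicated(x)))
  n1 <- length(a)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(x), n1)
  ud <- apply(combs, 2L, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(ud <= u_obs), mean(ud >= u_obs)))
}

# PAC oracle: R^2 of lm(amplitude ~ cos(phase) + sin(phase))
pac_oracle_r2 <- function(phase, amplitude) {
  summary(stats::lm(amplitude ~ cos(phase) + sin(phase)))$r.squared
}

significance_flag_test <- function(p) lfposc:::significance_flag(p)

# band power from a power_spectrum by plain bin summation (independent of
# the package's trapezoid-with-edge-interpolation path)
trapz_band_test <- function(psd, lo, hi) {
  df <- psd$freq[2L] - psd$freq[1L]
  sel <- psd$freq >= lo & psd$freq <= hi
  sum(psd$density[1L, sel]) * df
}

# maximum-correlation lag by direct O(n * lags) evaluation, for tiny cases
xcorr_oracle <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  best <- c(r = 0, lag = 0)
  for (lag in -max_lag:max_lag) {
    ia <- seq_len(n) + lag
    ok <- ia >= 1 & ia <= n
    r <- sum(a[ia[ok]] * b[ok]) / sqrt(sum(a^2) * sum(b^2))
    if (abs(r) >= abs(best[["r"]])) best <- c(r = r, lag = lag)
  }
  best
}
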