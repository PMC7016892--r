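#' General linear model phase-amplitude coupling index
#'
#' Least-squares regression of the amplitude series on
#' `{cos(phase), sin(phase), 1}`; the index is the coefficient of
#' determination (explained over total sum of squares), in `[0, 1]`.
#' Because the cos/sin pair spans every phase offset, the index is
#' invariant to a constant rotation of the phase. `index = "r"` returns
#' the square root (the multiple correlation), a monotone transform some
#' formulations prefer.
#'
#' A constant amplitude has no modulation to explain and returns 0.
#'
#' @param phase phase series, radians.
#' @param amplitude amplitude series, same length and clock.
#' @param index `"r2"` (default) or `"r"`.
#' @return coupling index in `[0, 1]`.
#' @export
glm_pac <- function(phase, amplitude, index = c("r2", "r")) {
  index <- match.arg(index)
  n <- length(phase)
  if (length(amplitude) != n)
    stop("phase and amplitude series must have equal length")
  y <- amplitude - mean(amplitude)
  tss <- sum(y^2)
  if (tss <= 0) return(0)
  X <- cbind(cos(phase), sin(phase))
  X <- sweep(X, 2L, colMeans(X))
  # normal equations on the centered 2-column harmonic design
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- solve(XtX, Xty)
  r2 <- as.numeric(crossprod(Xty, beta)) / tss
  r2 <- min(max(r2, 0), 1)
  if (index == "r") sqrt(r2) else r2
}

#' PAC indices across channels and bands
#'
#' Computes the GLM coupling index between a phase band and one or more
#' amplitude bands. In `"intra"` mode phase and amplitude come from the
#' same channel, at every channel; in `"cross"` mode the requested
#' (phase channel, amplitude channel) pairs are evaluated. The canonical
#' cortico-hippocampal pair couples slow-oscillation phase in cortical
#' L4/5 (600 um) with fast-gamma amplitude in CA1 sr-lm (1500 um).
#'
#' @param rec preprocessed [lfp_recording] (stable window applied).
#' @param phase_band band name or `c(low, high)` Hz for the phase.
#' @param amp_bands character vector of amplitude band names (or a list
#'   of `c(low, high)` pairs, which must then be named).
#' @param mode `"intra"` or `"cross"`.
#' @param pairs for `"cross"`: data.frame with columns `phase_channel`,
#'   `amp_channel` (1-based channel indices).
#' @param scheme a [band_scheme].
#' @param index `"r2"` or `"r"` (see [glm_pac]).
#' @param amp_lowpass if `TRUE`, low-pass the amplitude series at the
#'   phase band's upper edge before the regression, restricting the index
#'   to envelope fluctuations the phase rhythm could drive. Off by
#'   default: with the standard bands the envelope varies slowly relative
#'   to the fast bands already and the smoothing changes indices only
#'   marginally.
#' @return object of class `pac_result`: data.frame with columns
#'   `phase_channel`, `amp_channel`, `phase_band`, `amp_band`, `index`.
#' @export
pac_matrix <- function(rec, phase_band = "so", amp_bands = "fast_gamma",
                       mode = c("intra", "cross"), pairs = NULL,
                       scheme = band_scheme(), index = "r2",
                       amp_lowpass = FALSE) {
  mode <- match.arg(mode)
  nch <- n_channels(rec)
  if (mode == "intra") {
    pairs <- data.frame(phase_channel = seq_len(nch),
                        amp_channel = seq_len(nch))
  } else if (is.null(pairs)) {
    stop("cross mode needs a pairs data.frame (phase_channel, amp_channel)")
  }
  if (any(pairs$phase_channel > nch) || any(pairs$amp_channel > nch) ||
      any(pairs$phase_channel < 1L) || any(pairs$amp_channel < 1L))
    stop("pair references a channel outside the recording")

  ph <- instantaneous_phase(rec, phase_band, scheme)
  ph_iv <- if (is.character(phase_band)) band_interval(scheme, phase_band)
           else phase_band
  band_names <- if (is.list(amp_bands)) names(amp_bands) else amp_bands
  out <- list()
  for (bi in seq_along(amp_bands)) {
    b <- if (is.list(amp_bands)) amp_bands[[bi]] else amp_bands[[bi]]
    env <- instantaneous_amplitude(rec, b, scheme)
    if (amp_lowpass)
      env <- zero_phase_filter(env, "low-pass", ph_iv[2L])
    vals <- vapply(seq_len(nrow(pairs)), function(r) {
      glm_pac(ph$samples[pairs$phase_channel[r], ],
              env$samples[pairs$amp_channel[r], ], index = index)
    }, numeric(1))
    out[[bi]] <- data.frame(
      phase_channel = pairs$phase_channel,
      amp_channel = pairs$amp_channel,
      phase_band = if (is.character(phase_band)) phase_band else "custom",
      amp_band = band_names[bi],
      index = vals
    )
  }
  res <- do.call(rbind, out)
  attr(res, "mode") <- mode
  class(res) <- c("pac_result", "data.frame")
  res
}
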