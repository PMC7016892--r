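#' Multichannel LFP recording container
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param rate sampling rate in Hz.
#' @param depths electrode depth per channel, micrometers, strictly
#'   monotone (deepest channel first by convention).
#' @param t0 time of the first sample in seconds.
#' @return object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, rate, depths, t0 = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (length(depths) != nrow(samples))
    stop("need one electrode depth per channel (got ", length(depths),
         " depths for ", nrow(samples), " channels)")
  d <- diff(depths)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("channel depths must be strictly monotone")
  structure(
    list(samples = samples, rate = as.numeric(rate),
         depths = as.numeric(depths), t0 = as.numeric(t0)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d channels x %d samples @ %g Hz (%.1f s), depths %g-%g um\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, min(x$depths), max(x$depths)))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec an [lfp_recording].
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Single-channel physiological trace (ECG or respiration)
#'
#' @param samples numeric vector.
#' @param rate sampling rate, Hz.
#' @param kind `"ecg"` or `"respiration"`.
#' @param t0 time of the first sample, seconds (shared clock with the LFP).
#' @export
physio_trace <- function(samples, rate, kind = c("ecg", "respiration"), t0 = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate), kind = kind,
         t0 = as.numeric(t0)),
    class = "physio_trace"
  )
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d samples @ %g Hz (%.1f s)\n",
              x$kind, length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Write / read a recording container
#'
#' The container is a flat little-endian float64 binary file (channels
#' stored contiguously, deepest first) with a JSON sidecar `<path>.json`
#' carrying the sampling rate, per-channel depths, shape and start time.
#' The round trip is bit-exact. Loaders never resample or rescale.
#'
#' @param rec an [lfp_recording].
#' @param path file path for the binary payload; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [lfp_recording].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  meta <- list(
    format = "lfposc-recording-v1",
    n_channels = n_channels(rec),
    n_samples = n_samples(rec),
    rate = rec$rate,
    depths_um = rec$depths,
    t0 = rec$t0,
    dtype = "float64",
    byte_order = "little"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$samples)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("rate", "depths_um", "n_channels", "n_samples"))
    if (is.null(meta[[f]]))
      stop("recording metadata lacks required field '", f, "'")
  nc <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = nc * ns, size = 8L, endian = "little")
  if (length(x) != nc * ns)
    stop("truncated recording payload: expected ", nc * ns,
         " samples, read ", length(x))
  lfp_recording(matrix(x, nrow = nc, byrow = TRUE), meta$rate,
                meta$depths_um, t0 = meta$t0 %||% 0)
}

#' Read a CSV fixture as a recording
#'
#' Columns are channels (deepest first), rows are time points. Rate and
#' depths come from a JSON sidecar `<path>.json`; a fixture without depth
#' metadata is an error, never a silent default.
#'
#' @param path CSV file path.
#' @export
read_recording_csv <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$rate)) stop("recording metadata lacks required field 'rate'")
  if (is.null(meta$depths_um))
    stop("recording metadata lacks required field 'depths_um'")
  tab <- utils::read.csv(path, header = FALSE)
  m <- t(as.matrix(tab))
  dimnames(m) <- NULL
  lfp_recording(m, meta$rate, meta$depths_um, t0 = meta$t0 %||% 0)
}

#' Write / read a physiological trace (binary + JSON sidecar)
#' @param trace a [physio_trace].
#' @param path payload path; sidecar at `paste0(path, ".json")`.
#' @export
write_physio <- function(trace, path) {
  stopifnot(inherits(trace, "physio_trace"))
  jsonlite::write_json(
    list(format = "lfposc-physio-v1", kind = trace$kind, rate = trace$rate,
         n_samples = length(trace$samples), t0 = trace$t0,
         dtype = "float64", byte_order = "little"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(trace$samples, con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_physio
#' @export
read_physio <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing metadata sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("rate", "kind", "n_samples"))
    if (is.null(meta[[f]])) stop("physio metadata lacks required field '", f, "'")
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = as.integer(meta$n_samples), size = 8L,
               endian = "little")
  physio_trace(x, meta$rate, meta$kind, t0 = meta$t0 %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
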