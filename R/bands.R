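#' Frequency band scheme
#'
#' The elementary bands tile 0.1-190 Hz and follow the conventions used for
#' urethane-anesthetized mouse LFP: slow oscillations (SO) 0.1-1.7 Hz and
#' delta 1.7-4.7 Hz anchor the low range, fast gamma is 45-90 Hz and epsilon
#' extends to 190 Hz. Theta, beta and slow-gamma edges complete a disjoint
#' tiling and can be overridden. Composite bands Low (0.1-4.7 Hz),
#' High (4.7-190 Hz) and Total (0.1-190 Hz) are carried alongside for the
#' imbalance ratios.
#'
#' Intervals are half-open `[low, high)` except the last elementary band and
#' Total/High, which close at 190 Hz, so elementary bands never double-count
#' spectral mass.
#'
#' @param bands named list of `c(low, high)` Hz pairs for the elementary
#'   bands, in ascending order. Defaults to the scheme above.
#' @return an object of class `band_scheme`: list with `bands` (elementary)
#'   and `composites` (Low/High/Total).
#' @examples
#' sch <- band_scheme()
#' names(sch$bands)
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- list(
      so         = c(0.1, 1.7),
      delta      = c(1.7, 4.7),
      theta      = c(4.7, 12),
      beta       = c(12, 30),
      slow_gamma = c(30, 45),
      fast_gamma = c(45, 90),
      epsilon    = c(90, 190)
    )
  }
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  if (any(hi <= lo)) stop("band upper edge must exceed lower edge")
  if (any(abs(lo[-1L] - hi[-length(hi)]) > 1e-9))
    stop("elementary bands must be contiguous and disjoint")
  total <- c(lo[1L], hi[length(hi)])
  split <- if ("delta" %in% names(bands)) bands$delta[2L] else lo[which(lo > 5)[1L]]
  structure(
    list(
      bands = bands,
      composites = list(
        low   = c(total[1L], split),
        high  = c(split, total[2L]),
        total = total
      )
    ),
    class = "band_scheme"
  )
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Band scheme (Hz):\n")
  for (nm in names(x$bands))
    cat(sprintf("  %-11s [%6.1f, %6.1f)\n", nm, x$bands[[nm]][1L], x$bands[[nm]][2L]))
  cat(sprintf("  composites: low [%.1f,%.1f)  high [%.1f,%.1f]  total [%.1f,%.1f]\n",
              x$composites$low[1L], x$composites$low[2L],
              x$composites$high[1L], x$composites$high[2L],
              x$composites$total[1L], x$composites$total[2L]))
  invisible(x)
}

# look up an interval (elementary or composite) by name
band_interval <- function(scheme, name) {
  if (name %in% names(scheme$bands)) return(scheme$bands[[name]])
  if (name %in% names(scheme$composites)) return(scheme$composites[[name]])
  stop("unknown band: ", name)
}

#' Map channels to laminar regions by electrode depth
#'
#' Default regions for a 24-channel, 100-um probe spanning the posterior
#' parietal cortex and dorsal hippocampus: cortical layers 2/3 (100-400 um)
#' and 4/6 (500-1000 um), CA1 (1100-1600 um) and dentate gyrus
#' (1700-2300 um). Channels outside every range (e.g. the most superficial
#' site) are left unassigned (`NA`).
#'
#' @param depths electrode depths in micrometers, one per channel.
#' @param ranges named list of `c(min_depth, max_depth)` per region. The
#'   order of the names fixes the region order used for sign-coherent
#'   cross-regional latencies (cortex first by default).
#' @return object of class `region_scheme`: data.frame with `channel`,
#'   `depth`, `region` (factor, levels in region order).
#' @export
region_scheme <- function(depths,
                          ranges = list(
                            "L2/3" = c(100, 400),
                            "L4/6" = c(500, 1000),
                            "CA1"  = c(1100, 1600),
                            "DG"   = c(1700, 2300)
                          )) {
  region <- rep(NA_character_, length(depths))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    region[depths >= r[1L] & depths <= r[2L]] <- nm
  }
  structure(
    data.frame(
      channel = seq_along(depths),
      depth = depths,
      region = factor(region, levels = names(ranges))
    ),
    class = c("region_scheme", "data.frame")
  )
}

# The seven depths used for the per-depth power and statistics tables
# (lo-sg, up-sg, sr-lm, sp, L6, L4/5, L2/3).
analysis_depths <- function() c(2100, 1900, 1500, 1200, 900, 600, 300)
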