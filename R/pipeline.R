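#' Pipeline configuration
#'
#' Bundles the per-stage settings for a full session analysis. Input is
#' either a [synth_config] (the session is generated) or paths to a
#' recording container plus ECG/respiration traces written by
#' [write_recording]/[write_physio].
#'
#' @param synth a [synth_config], or `NULL` when reading from files.
#' @param lfp_path,ecg_path,resp_path input file paths (ignored when
#'   `synth` is given).
#' @param out_dir output directory for the report bundle; `NULL` skips
#'   writing.
#' @param scheme a [band_scheme].
#' @param lfp_rate,ecg_rate,resp_rate preprocessing target rates, Hz.
#' @param line_freq mains frequency for the notch (`NULL` to skip).
#' @param window_s stable-window duration, seconds.
#' @param conn_band,max_lag_ms connectivity band and lag range.
#' @param pac_phase_band,pac_amp_bands PAC bands.
#' @param run_connectivity,run_pac stage switches (both on by default).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, lfp_path = NULL, ecg_path = NULL,
                            resp_path = NULL, out_dir = NULL,
                            scheme = band_scheme(),
                            lfp_rate = 500, ecg_rate = 50, resp_rate = 20,
                            line_freq = 50, window_s = 300,
                            conn_band = "so", max_lag_ms = 500,
                            pac_phase_band = "so",
                            pac_amp_bands = c("fast_gamma"),
                            run_connectivity = TRUE, run_pac = TRUE) {
  if (is.null(synth) && (is.null(lfp_path) || is.null(ecg_path) ||
                         is.null(resp_path)))
    stop("either a synth config or all three input paths are required")
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline for one session
#'
#' Input acquisition (synthetic or from files), preprocessing of LFP, ECG
#' and respiration, physiology-gated stable-window selection, band-power
#' and ratio tables, envelope connectivity with regional averages, and
#' PAC indices. When `out_dir` is set, writes band-power and ratio CSVs,
#' connectivity matrices and regional JSON, a PAC CSV and a JSON manifest
#' (package version, configuration hash, seed, selected window). For a
#' fixed seed the run is deterministic end to end.
#'
#' @param config a [pipeline_config].
#' @return list with the preprocessed recording (cropped to the stable
#'   window), the window, tables and result objects, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  inp <- stage("input", {
    if (!is.null(config$synth)) {
      gen <- generate_lfp(config$synth)
      phys <- generate_physio(config$synth)
      list(rec = gen$rec, truth = gen$truth, ecg = phys$ecg,
           resp = phys$resp, seed = config$synth$seed)
    } else {
      list(rec = read_recording(config$lfp_path),
           truth = NULL,
           ecg = read_physio(config$ecg_path),
           resp = read_physio(config$resp_path),
           seed = NA_integer_)
    }
  })

  prep <- stage("preprocess", {
    list(
      lfp = preprocess_lfp(inp$rec, line_freq = config$line_freq,
                           target_rate = config$lfp_rate),
      ecg = preprocess_ecg(inp$ecg, target_rate = config$ecg_rate),
      resp = preprocess_resp(inp$resp, target_rate = config$resp_rate)
    )
  })

  gate <- stage("stability", {
    gate_stable_window(prep$ecg, prep$resp, n_samples(prep$lfp),
                       prep$lfp$rate, duration_s = config$window_s)
  })
  lfp <- stage("stability", crop_recording(prep$lfp, gate$window))

  spec_res <- stage("spectral", {
    psd <- compute_psd(lfp)
    bp <- band_powers(psd, config$scheme, depths = lfp$depths)
    ratios <- data.frame(
      channel = seq_len(n_channels(lfp)),
      depth = lfp$depths,
      so_delta = power_ratio(bp, "so", "delta"),
      low_high = power_ratio(bp, "low", "high")
    )
    list(psd = psd, band_powers = bp, ratios = ratios)
  })

  conn <- regional <- NULL
  if (config$run_connectivity) {
    conn <- stage("connectivity",
                  connectivity_matrices(lfp, config$conn_band,
                                        config$max_lag_ms, config$scheme))
    regions <- region_scheme(lfp$depths)
    counts <- table(regions$region)
    if (length(counts) && all(counts >= 2L))
      regional <- stage("connectivity", regionalize(conn, regions))
  }

  pac <- NULL
  if (config$run_pac) {
    pac <- stage("pac",
                 pac_matrix(lfp, config$pac_phase_band, config$pac_amp_bands,
                            mode = "intra", scheme = config$scheme))
  }

  manifest <- list(
    package = "lfposc",
    version = as.character(utils::packageVersion("lfposc")),
    seed = inp$seed,
    config_hash = config_hash(config),
    window = list(start = gate$window$start, end = gate$window$end),
    n_channels = n_channels(lfp),
    lfp_rate = lfp$rate
  )

  out <- list(recording = lfp, window = gate$window, gate = gate,
              spectral = spec_res, connectivity = conn, regional = regional,
              pac = pac, truth = inp$truth, manifest = manifest)

  if (!is.null(config$out_dir)) stage("report", write_bundle(out, config))
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

write_bundle <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  bp <- out$spectral$band_powers
  utils::write.csv(
    cbind(channel = seq_len(nrow(bp$absolute)), depth = bp$depths,
          bp$absolute),
    p("band_power_absolute.csv"), row.names = FALSE)
  utils::write.csv(
    cbind(channel = seq_len(nrow(bp$relative)), depth = bp$depths,
          bp$relative),
    p("band_power_relative.csv"), row.names = FALSE)
  utils::write.csv(out$spectral$ratios, p("power_ratios.csv"),
                   row.names = FALSE)
  if (!is.null(out$connectivity)) {
    utils::write.csv(as.data.frame(out$connectivity$coeff),
                     p("connectivity_coeff.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(out$connectivity$latency_ms),
                     p("connectivity_latency_ms.csv"), row.names = FALSE)
  }
  if (!is.null(out$regional))
    jsonlite::write_json(out$regional, p("connectivity_regional.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(out$pac))
    utils::write.csv(as.data.frame(out$pac), p("pac.csv"), row.names = FALSE)
  jsonlite::write_json(out$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Rescale one band's amplitude in a fraction vector
#'
#' Helper for constructing altered cohorts: scales the named band's
#' amplitude by `amp_scale` (its variance by `amp_scale^2`) while all
#' other absolute band powers stay fixed, and renormalizes so the result
#' is again a fraction vector (the implied total variance changes, which
#' is what an amplitude change does to a real signal).
#'
#' @param fractions named fraction vector (see [synth_config]).
#' @param band band to rescale.
#' @param amp_scale amplitude scale factor (0.5 halves the amplitude).
#' @export
scale_band_fraction <- function(fractions, band, amp_scale) {
  if (!band %in% names(fractions)) stop("band not in fractions: ", band)
  w <- rep(1, length(fractions) + 1L)  # last entry: broadband remainder
  v <- c(fractions, 1 - sum(fractions))
  w[match(band, names(fractions))] <- amp_scale^2
  v <- v * w
  out <- v[seq_along(fractions)] / sum(v)
  names(out) <- names(fractions)
  out
}

#' Simulated two-group cohort comparison of the SO/delta ratio
#'
#' Generates `n_per_group` synthetic animals per group at the analysis
#' rate, with the slow-oscillation amplitude of the altered group scaled
#' by `so_amp_scale`; computes each animal's SO/delta power ratio at the
#' recorded channel and runs the gatekept comparison ([compare_metric])
#' against the control group.
#'
#' @param n_per_group animals per group (default 10).
#' @param so_amp_scale slow-oscillation amplitude scale of the altered
#'   group (default 0.5, i.e. a 50% amplitude reduction).
#' @param duration per-animal recording length, seconds.
#' @param rate sampling rate (the analysis rate; generation happens
#'   directly at this rate).
#' @param seed integer seed for the whole cohort.
#' @param alpha,k comparison parameters (see [compare_metric]).
#' @return list with `groups` (per-animal ratios) and `comparison`
#'   (a `comparison_result`).
#' @export
run_cohort_study <- function(n_per_group = 10, so_amp_scale = 0.5,
                             duration = 60, rate = 500, seed = 1L,
                             alpha = 0.05, k = 4) {
  base_fr <- c(so = 0.55, delta = 0.15)
  tg_fr <- scale_band_fraction(base_fr, "so", so_amp_scale)
  animal_ratio <- function(fr, s) {
    cfg <- synth_config(n_channels = 1, duration = duration, rate = rate,
                        band_fractions = fr, seed = s)
    rec <- generate_lfp(cfg)$rec
    bp <- band_powers(compute_psd(rec))
    power_ratio(bp, "so", "delta")[1L]
  }
  seeds <- seed + seq_len(2L * n_per_group)
  wt <- vapply(seeds[seq_len(n_per_group)], function(s)
    animal_ratio(base_fr, s), numeric(1))
  tg <- vapply(seeds[n_per_group + seq_len(n_per_group)], function(s)
    animal_ratio(tg_fr, s), numeric(1))
  groups <- list(WT = wt, TG = tg)
  list(groups = groups,
       comparison = compare_metric(groups, alpha = alpha, k = k,
                                   reference = "WT"))
}
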