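# Configuration handling and the command entry point.

.default_config <- function() {
  list(
    seed = 1,
    upconversion = list(pump_nm = 1064, band_nm = c(3576, 4625), qe = 0.01,
                        poling_um = 23),
    source = list(shape = "flat"),
    spectrometer = list(n_pixels = 4096, lambda_range_nm = c(796, 879),
                        resolution_fwhm_nm = 2.7, bit_depth = 10,
                        line_rate_hz = 45e3, distortion = c(0, 0)),
    phantom = list(type = "mirror", opd_um = 300, r = 0.05),
    scan = list(speed_mm_s = 3, integration_ms = 3, n_lines = 2,
                step_um = 10),
    mc = list(t_total_ps = 14.4, dt_fs = 24, na = 0.1, nphoton = 2000,
              width_um = 15, lateral_step_um = 10,
              wavelength_tag = "4.0"),
    characterize = list(n_probes = 10, max_opd_um = 2500),
    output = list(format = "tiff", dynamic_range_db = 40)
  )
}

config_get <- function(cfg, path_keys) {
  cur <- cfg
  for (k in path_keys) {
    if (!is.list(cur) || is.null(cur[[k]]))
      stop_domain(sprintf("config schema error: missing required key '%s'",
                          paste(path_keys, collapse = ".")))
    cur <- cur[[k]]
  }
  cur
}

validate_config <- function(cfg) {
  num_keys <- list(c("seed"),
                   c("upconversion", "pump_nm"),
                   c("upconversion", "band_nm"),
                   c("spectrometer", "n_pixels"),
                   c("spectrometer", "resolution_fwhm_nm"),
                   c("mc", "t_total_ps"), c("mc", "dt_fs"),
                   c("scan", "integration_ms"))
  for (ks in num_keys) {
    v <- config_get(cfg, ks)
    if (!is.numeric(v) || any(!is.finite(v)))
      stop_domain(sprintf("config schema error: key '%s' must be numeric",
                          paste(ks, collapse = ".")))
  }
  if (length(config_get(cfg, c("upconversion", "band_nm"))) != 2L)
    stop_domain("config schema error: key 'upconversion.band_nm' must have 2 entries")
  ptype <- config_get(cfg, c("phantom", "type"))
  if (identical(ptype, "wafer"))
    config_get(cfg, c("phantom", "n_group"))  # required, no default
  invisible(cfg)
}

#' Read and validate a run configuration (YAML)
#'
#' Missing sections/keys are filled from the package defaults; schema
#' violations are reported with the dotted path to the offending key. The
#' `wafer` phantom requires `phantom.n_group` (the group index is not a
#' package default).
#'
#' @param path YAML file, or `NULL` for the packaged defaults.
#' @param overrides named list merged over the file (nested lists merge
#'   recursively).
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_domain("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

cfg_spectrometer <- function(cfg) {
  s <- cfg$spectrometer
  spectrometer_model(n_pixels = s$n_pixels,
                     lambda_range_nm = s$lambda_range_nm,
                     distortion = s$distortion %||% c(0, 0),
                     resolution_fwhm_nm = s$resolution_fwhm_nm,
                     bit_depth = s$bit_depth,
                     line_rate_hz = s$line_rate_hz %||% 45e3,
                     pump_nm = cfg$upconversion$pump_nm)
}

cfg_source <- function(cfg) {
  make_source_spectrum(cfg$upconversion$band_nm, cfg$source$shape %||% "flat")
}

cfg_stack <- function(cfg) {
  p <- cfg$phantom
  switch(config_get(cfg, c("phantom", "type")),
         mirror = reflector_stack(p$opd_um %||% 300, p$r %||% 0.05),
         ceramic_stack = ceramic_stack_reflectors(
           ceramic_stack_spec(gap_c2_c3_um = p$gap_c2_c3_um %||% 0),
           standoff_um = p$standoff_um %||% 100,
           through_valley = isTRUE(p$through_valley)),
         wafer = wafer_reflectors(p$thickness_um %||% 255,
                                  probe = as.character(p$probe %||% "4.0"),
                                  n_group = config_get(cfg,
                                    c("phantom", "n_group")),
                                  standoff_um = p$standoff_um %||% 100),
         stop_domain("config schema error: unknown 'phantom.type'"))
}

cfg_domain <- function(cfg) {
  p <- cfg$phantom
  tag <- as.character(cfg$mc$wavelength_tag %||% "4.0")
  switch(config_get(cfg, c("phantom", "type")),
         ceramic_stack = ceramic_stack_domain(
           ceramic_stack_spec(gap_c2_c3_um = p$gap_c2_c3_um %||% 0),
           wavelength_tag = tag),
         tape_on_foil = tape_on_foil_domain(p$tape_um %||% 24,
                                            p$foil_um %||% 62,
                                            wavelength_tag = tag),
         stop_domain("config schema error: 'phantom.type' has no voxel ",
                     "representation (use ceramic_stack or tape_on_foil)"))
}

#' Run a pipeline command from a configuration
#'
#' Thin command dispatcher over the package's functions; every stochastic
#' step receives a seed derived from the global `seed`, so a fixed
#' configuration gives byte-identical numeric outputs.
#'
#' Commands:
#' \describe{
#'   \item{`characterize`}{band map, sampling resolutions, MC depth
#'     sampling, forward roll-off simulation with 6 dB depth, inferred
#'     spectral resolution and axial resolution; writes
#'     `characterization.json` and `rolloff.csv`.}
#'   \item{`simulate-frame`}{synthesize sample/reference/dark frames for
#'     the configured phantom; writes CSV and binary frames.}
#'   \item{`reconstruct`}{synthesize (or read) frames, build the
#'     calibration, reconstruct one A-scan per line and assemble a B-scan;
#'     writes `ascan.csv` and an image.}
#'   \item{`phantom`}{write the configured voxel domain container.}
#'   \item{`mc-bscan`}{run the Monte Carlo B-scan; writes an image and the
#'     flux matrix CSV.}
#' }
#'
#' @param command one of the commands above.
#' @param config path to a YAML config, a `run_config`, or `NULL` for
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @param overrides named list of config overrides.
#' @param seed optional seed override.
#' @param verbose print progress (default `FALSE`).
#' @return list with the command's main results (also written to
#'   `out_dir`), invisibly for file-only commands.
#' @export
oct_run <- function(command = c("characterize", "simulate-frame",
                                "reconstruct", "phantom", "mc-bscan"),
                    config = NULL, out_dir = tempdir(), overrides = list(),
                    seed = NULL, verbose = FALSE) {
  command <- match.arg(command)
  cfg <- if (inherits(config, "run_config")) {
    if (length(overrides)) {
      tmp <- modifyList(unclass(config), overrides)
      validate_config(tmp)
      structure(tmp, class = c("run_config", "list"))
    } else config
  } else read_run_config(config, overrides)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  if (command == "characterize") {
    ucfg <- upconversion_config(cfg$upconversion$pump_nm,
                                cfg$upconversion$band_nm,
                                cfg$upconversion$qe %||% 0.01,
                                cfg$upconversion$poling_um %||% 23)
    bm <- map_band(ucfg)
    spec <- cfg_spectrometer(cfg)
    lam_pix <- downconvert_wavelength(pixel_wavelength(spec), spec$pump_nm)
    n_detected <- sum(lam_pix >= ucfg$band_nm[1] & lam_pix <= ucfg$band_nm[2])
    samp <- sampling_resolutions(ucfg$band_nm, n_detected,
                                 cfg$scan$speed_mm_s, cfg$scan$integration_ms)
    tg <- time_grid(cfg$mc$t_total_ps, cfg$mc$dt_fs)
    say("forward roll-off simulation ...")
    ro <- simulate_rolloff(spec, band_nm = ucfg$band_nm,
                           n_probes = cfg$characterize$n_probes %||% 10,
                           max_opd_um = cfg$characterize$max_opd_um %||% 2500)
    lam0 <- band_center_nm(ucfg$band_nm)
    res_nm <- spectral_resolution_from_rolloff(ro$curve$z6db_um, lam0)
    ax <- tryCatch(as.numeric(axial_resolution(ro$ascans[[1]])),
                   error = function(e) NA_real_)
    report <- list(
      nearir_band_nm = bm$nearir_band,
      nearir_bandwidth_nm = bm$nearir_bandwidth,
      midir_bandwidth_nm = bm$midir_bandwidth,
      detected_pixels = n_detected,
      spectral_sampling_nm = samp$spectral_nm,
      lateral_sampling_um = samp$lateral_um,
      mc_depth_sampling_um = tg$dz_um,
      rolloff_6db_um = ro$curve$z6db_um,
      inferred_spectral_resolution_nm = res_nm,
      axial_resolution_um = ax,
      seed = cfg$seed)
    jsonlite::write_json(report, file.path(out_dir, "characterization.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(opd_um = ro$curve$opd_um,
                         sensitivity_db = ro$curve$sensitivity_db),
              file.path(out_dir, "rolloff.csv"), row.names = FALSE)
    return(report)
  }

  if (command == "simulate-frame") {
    spec <- cfg_spectrometer(cfg)
    frames <- synth_interferogram(cfg_stack(cfg), cfg_source(cfg), spec,
                                  integration_ms = cfg$scan$integration_ms,
                                  noise = isTRUE(cfg$output$noise),
                                  seed = cfg$seed)
    for (k in c("sample", "reference", "dark")) {
      write_frame_csv(frames[[k]], file.path(out_dir, paste0(k, ".csv")))
      write_frame_bin(frames[[k]], file.path(out_dir, paste0(k, ".bin")))
    }
    return(invisible(frames))
  }

  if (command == "reconstruct") {
    spec <- cfg_spectrometer(cfg)
    cal <- build_calibration(generate_calibration_frames(spec))
    stack <- cfg_stack(cfg)
    n_lines <- max(2L, as.integer(cfg$scan$n_lines %||% 2L))
    ascans <- lapply(seq_len(n_lines), function(i) {
      fr <- synth_interferogram(stack, cfg_source(cfg), spec,
                                integration_ms = cfg$scan$integration_ms,
                                noise = isTRUE(cfg$output$noise),
                                seed = cfg$seed * 1000 + i)
      reconstruct_ascan(preprocess_frames(fr$sample, fr$dark, fr$reference),
                        cal)
    })
    bscan <- assemble_scan(ascans, "continuous_x",
                           speed_mm_s = cfg$scan$speed_mm_s,
                           integration_ms = cfg$scan$integration_ms)
    write_ascan_csv(ascans[[1]], file.path(out_dir, "ascan.csv"))
    fmt <- cfg$output$format %||% "tiff"
    export_image(bscan, file.path(out_dir, paste0("bscan.", fmt)),
                 dynamic_range_db = cfg$output$dynamic_range_db %||% 40,
                 format = fmt)
    return(invisible(bscan))
  }

  if (command == "phantom") {
    dom <- cfg_domain(cfg)
    write_domain(dom, file.path(out_dir, "domain.bin"))
    return(invisible(dom))
  }

  # mc-bscan
  dom <- cfg_domain(cfg)
  tg <- time_grid(cfg$mc$t_total_ps, cfg$mc$dt_fs)
  bs <- run_mc_bscan(dom, tg, na = cfg$mc$na %||% 0.1,
                     lateral_step_um = cfg$mc$lateral_step_um %||% 10,
                     nphoton = cfg$mc$nphoton %||% 2000,
                     seed = cfg$seed, width_um = cfg$mc$width_um %||% 15)
  fmt <- cfg$output$format %||% "tiff"
  export_image(bs, file.path(out_dir, paste0("mc_bscan.", fmt)),
               dynamic_range_db = cfg$output$dynamic_range_db %||% 40,
               format = fmt)
  write.csv(bs$flux, file.path(out_dir, "mc_flux.csv"), row.names = FALSE)
  invisible(bs)
}

#' Forward-simulate a sensitivity roll-off experiment
#'
#' Synthesizes noiseless single-mirror frame triples at probe OPDs spanning
#' the requested range, reconstructs each A-scan against a two-interferogram
#' calibration, and builds the roll-off curve.
#'
#' @param spec a [spectrometer_model()] (its `resolution_fwhm_nm` sets the
#'   roll-off).
#' @param band_nm source band, nm.
#' @param n_probes number of probe depths (>= 5).
#' @param min_opd_um,max_opd_um probed OPD range, um.
#' @param r mirror amplitude reflectivity.
#' @param window reconstruction window.
#' @return list with `curve` (an `oct_rolloff`), `ascans`, and `cal`.
#' @export
simulate_rolloff <- function(spec, band_nm = c(3576, 4625), n_probes = 10,
                             min_opd_um = 100, max_opd_um = 2500, r = 0.05,
                             window = "hanning") {
  source <- make_source_spectrum(band_nm, "flat")
  cal <- build_calibration(generate_calibration_frames(spec))
  opds <- seq(min_opd_um, max_opd_um, length.out = n_probes)
  ascans <- lapply(opds, function(z) {
    fr <- synth_interferogram(reflector_stack(z, r), source, spec)
    reconstruct_ascan(preprocess_frames(fr$sample, fr$dark, fr$reference),
                      cal, window = window)
  })
  list(curve = rolloff_curve(ascans, opds_um = opds), ascans = ascans,
       cal = cal, opds_um = opds)
}
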