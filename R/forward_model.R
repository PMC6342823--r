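#' Group-delay dispersion phase over a wavenumber grid
#'
#' Quadratic spectral phase accumulated by propagation through a dispersive
#' material: `phi(k) = 0.5 * GDD * (omega(k) - omega0)^2` with
#' `omega(k) = c * k` and `GDD = gvd * length * (2 if double_pass)`.
#'
#' @param gvd_fs2_per_mm group-velocity dispersion, fs^2/mm.
#' @param length_mm physical propagation length, mm (>= 0).
#' @param k_grid wavenumber grid, rad/um.
#' @param double_pass logical; OCT sample-arm light traverses the material
#'   twice (default `TRUE`).
#' @param k0 reference wavenumber (rad/um) where the phase and group delay
#'   vanish; default: grid centre.
#' @return list with `phase` (rad, same length as `k_grid`) and `gdd_fs2`
#'   (the scalar GDD actually applied).
#' @export
dispersion_phase <- function(gvd_fs2_per_mm, length_mm, k_grid,
                             double_pass = TRUE, k0 = NULL) {
  if (length_mm < 0) stop_domain("'length_mm' must be >= 0")
  gdd <- gvd_fs2_per_mm * length_mm * if (double_pass) 2 else 1
  if (is.null(k0)) k0 <- (min(k_grid) + max(k_grid)) / 2
  omega <- .C_UM_PER_FS * k_grid   # rad/fs
  omega0 <- .C_UM_PER_FS * k0
  list(phase = 0.5 * gdd * (omega - omega0)^2, gdd_fs2 = gdd)
}

# Quadratic phase from an explicit GDD value (fs^2) about k0.
gdd_phase <- function(gdd_fs2, k_grid, k0) {
  0.5 * gdd_fs2 * (.C_UM_PER_FS * (k_grid - k0))^2
}

#' Sensitivity roll-off amplitude factor
#'
#' Fringe-amplitude attenuation at one-way OPD `z` caused by the finite
#' spectral resolution of the spectrometer, modelled as a Gaussian kernel of
#' FWHM `delta_lambda` (on the mid-IR scale):
#' `A(z) = exp(-z^2 * dk^2 / (4 ln 2))` with `dk = 2 pi delta_lambda /
#' lambda0^2`. The peak *sensitivity* (in dB, `20 log10`) falls by 6.02 dB at
#' `z = ln2 * lambda0^2 / (pi * delta_lambda)`.
#'
#' @param z_um one-way OPD(s), um (>= 0).
#' @param resolution_fwhm_nm spectral resolution FWHM, nm (> 0).
#' @param center_wavelength_nm centre wavelength lambda0, nm; the package
#'   convention is the geometric mean of the band edges.
#' @return amplitude factor(s) in (0, 1].
#' @export
rolloff_attenuation <- function(z_um, resolution_fwhm_nm,
                                center_wavelength_nm) {
  if (any(z_um < 0)) stop_domain("'z_um' must be >= 0")
  if (resolution_fwhm_nm <= 0) stop_domain("resolution FWHM must be > 0")
  dk <- rolloff_dk(resolution_fwhm_nm, center_wavelength_nm)  # rad/um
  exp(-(z_um^2 * dk^2) / (4 * log(2)))
}

# Spectral-resolution kernel FWHM in wavenumber (rad/um) from a wavelength
# FWHM (nm) at centre wavelength lambda0 (nm).
rolloff_dk <- function(resolution_fwhm_nm, center_wavelength_nm) {
  2 * pi * resolution_fwhm_nm * 1000 / center_wavelength_nm^2
}

# Geometric-mean centre wavelength of a band (nm).
band_center_nm <- function(band_nm) sqrt(band_nm[1] * band_nm[2])

# Raw spectrometer frame constructor.
raw_frame <- function(counts, kind, spec, integration_ms, seed = NULL,
                      mask = NULL) {
  structure(list(counts = counts, kind = kind, spec = spec,
                 integration_ms = integration_ms, seed = seed, mask = mask),
            class = "oct_raw_frame")
}

#' @export
print.oct_raw_frame <- function(x, ...) {
  cat(sprintf("Raw %s frame: %d pixels, %d-bit, %.3g ms integration\n",
              x$kind, length(x$counts), x$spec$bit_depth, x$integration_ms))
  invisible(x)
}

# Gaussian smoothing of a uniformly sampled spectrum in k via FFT circular
# convolution; the source grid carries a zero margin so wrap-around is
# negligible.
gaussian_smooth_k <- function(values, dk_grid, fwhm_k) {
  if (fwhm_k <= 0) return(values)
  n <- length(values)
  sig <- fwhm_k / (2 * sqrt(2 * log(2)))
  # kernel centred at index 1 (circular)
  idx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * dk_grid
  kern <- exp(-idx^2 / (2 * sig^2))
  kern <- kern / sum(kern)
  Re(fft(fft(values) * fft(kern), inverse = TRUE)) / n
}

# Evaluate the per-interface phase terms phi_j(k) for a reflector stack.
stack_phase <- function(stack, k, k0) {
  lapply(seq_along(stack$z_um), function(j) {
    ph <- gdd_phase(stack$gdd_fs2[j], k, k0)
    if (!is.null(stack$phase_poly) && !is.null(stack$phase_poly[[j]])) {
      co <- stack$phase_poly[[j]]
      dkk <- k - k0
      for (m in seq_along(co)) ph <- ph + co[m] * dkk^(m - 1)
    }
    ph
  })
}

# Spectral interference intensity on a dense k grid (before the resolution
# kernel): S(k) * [rho + sum r_j^2 + sum 2 sqrt(rho) r_j cos(2 k z_j + phi_j)]
interference_intensity <- function(stack, source, rho_ref, k0) {
  k <- source$k_grid
  modulation <- rep(rho_ref + sum(stack$r^2), length(k))
  phases <- stack_phase(stack, k, k0)
  for (j in seq_along(stack$z_um)) {
    modulation <- modulation +
      2 * sqrt(rho_ref) * stack$r[j] * cos(2 * k * stack$z_um[j] + phases[[j]])
  }
  source$envelope * modulation
}

#' Synthesize a raw interferogram frame triple
#'
#' Forward-models the spectrometer output for a reflector stack: fringe
#' formation on a dense mid-IR wavenumber grid, per-interface dispersion
#' phase, convolution with the Gaussian spectral-resolution kernel (which
#' produces the sensitivity roll-off), sampling through the pixel map,
#' scaling by integration time, optional Poisson shot noise plus Gaussian
#' dark noise, and quantization to the ADC bit depth (round-half-even). The
#' reference frame omits the sample and interference terms; the dark frame
#' contains only the dark level.
#'
#' Count scaling: an ideal reference frame at `spec$full_well_integration_ms`
#' reaches 80 percent of full scale, so mean counts scale linearly with
#' integration time until clipping.
#'
#' @param stack a [reflector_stack()]; must be non-empty for the sample frame.
#' @param source a [make_source_spectrum()].
#' @param spec a [spectrometer_model()].
#' @param rho_ref reference-arm intensity fraction (default 0.5, ideal
#'   splitter arm).
#' @param integration_ms integration time, ms.
#' @param noise logical: Poisson shot noise + Gaussian dark noise (default
#'   `FALSE`).
#' @param seed RNG seed used when `noise = TRUE`.
#' @param dark_fraction mean dark level as a fraction of full scale
#'   (default 0.02).
#' @param dark_sd Gaussian dark/read noise standard deviation, counts
#'   (default 1.5; only with `noise = TRUE`).
#' @param quantize quantize to integer counts (default `TRUE`).
#' @return list of class `oct_frame_set` with elements `sample`, `reference`,
#'   `dark` (each an `oct_raw_frame`); carries attribute `aliased` if any
#'   interface lies beyond the unambiguous depth range (the fringe is still
#'   synthesized and aliases).
#' @export
synth_interferogram <- function(stack, source, spec, rho_ref = 0.5,
                                integration_ms = 3, noise = FALSE,
                                seed = NULL, dark_fraction = 0.02,
                                dark_sd = 1.5, quantize = TRUE) {
  stopifnot(inherits(stack, "reflector_stack"),
            inherits(source, "source_spectrum"),
            inherits(spec, "spectrometer_model"))
  # An empty stack is allowed: the sample frame then equals the reference.
  aliased <- FALSE
  zmax <- unambiguous_range(spec)
  if (any(stack$z_um > zmax)) {
    warning(sprintf("interface OPD beyond the unambiguous range (%.0f um); ",
                    zmax), "the fringe will alias", call. = FALSE)
    aliased <- TRUE
  }
  k <- source$k_grid
  dk_grid <- k[2] - k[1]
  k0 <- wavelength_to_k(band_center_nm(source$band_nm))
  fwhm_k <- rolloff_dk(spec$resolution_fwhm_nm, band_center_nm(source$band_nm))

  i_sample <- interference_intensity(stack, source, rho_ref, k0)
  i_ref <- source$envelope * rho_ref
  i_sample <- gaussian_smooth_k(i_sample, dk_grid, fwhm_k)
  i_ref <- gaussian_smooth_k(i_ref, dk_grid, fwhm_k)

  k_pix <- pixel_k_midir(spec)
  sample_pix <- spectrum_at_pixels(k, i_sample, k_pix)
  ref_pix <- spectrum_at_pixels(k, i_ref, k_pix)

  full <- 2^spec$bit_depth - 1
  gain <- 0.8 * full / (max(ref_pix) * spec$full_well_integration_ms)
  dark_mean <- dark_fraction * full
  finish <- function(x_float, kind) {
    counts <- x_float
    if (noise) counts <- counts + rnorm(length(counts), 0, dark_sd)
    counts <- pmin(pmax(counts, 0), full)
    if (quantize) counts <- round(counts)
    raw_frame(counts, kind, spec, integration_ms, seed)
  }
  with_seed(if (noise) seed else NULL, {
    s_float <- sample_pix * gain * integration_ms
    r_float <- ref_pix * gain * integration_ms
    if (noise) {
      s_float <- rpois(length(s_float), s_float)
      r_float <- rpois(length(r_float), r_float)
    }
    out <- structure(list(
      sample = finish(s_float + dark_mean, "sample"),
      reference = finish(r_float + dark_mean, "reference"),
      dark = finish(rep(dark_mean, spec$n_pixels), "dark")),
      class = "oct_frame_set", aliased = aliased)
    out
  })
}

# Interpolate a densely gridded spectrum at pixel wavenumbers (spline inside
# the grid, zero outside).
spectrum_at_pixels <- function(k_grid, values, k_pix) {
  f <- splinefun(k_grid, values, method = "fmm")
  out <- f(k_pix)
  out[k_pix < min(k_grid) | k_pix > max(k_grid)] <- 0
  pmax(out, 0)
}

#' Generate the two wavenumber-calibration frames
#'
#' Synthesizes the pair of noiseless single-mirror reference interferograms
#' from which [build_calibration()] recovers the pixel-to-wavenumber map and
#' the interferometer dispersion mismatch. The frames embed the configured
#' pixel-map nonlinearity and the supplied dispersion mismatch. The
#' spectral-resolution attenuation is deliberately omitted: these frames
#' carry phase information only, and attenuating the deeper-OPD fringe would
#' degrade the phase estimate without adding realism to the calibration.
#'
#' The default source is flat over the full mid-IR span seen by the
#' spectrometer so that every pixel observes a fringe; the default OPD pair
#' is 1/4 and 3/4 of the calibration-safe depth range (half the unambiguous
#' range, where the fringe keeps >= 4 samples per period).
#'
#' @param spec a [spectrometer_model()].
#' @param opds_um the two mirror one-way OPDs, um (distinct, nonzero).
#' @param source optional [make_source_spectrum()]; default: flat over the
#'   spectrometer's mid-IR span.
#' @param dispersion_gdd_fs2 interferometer dispersion mismatch applied as a
#'   quadratic phase (double-pass GDD, fs^2; default 0).
#' @param r mirror amplitude reflectivity (default 0.3).
#' @param rho_ref reference-arm intensity fraction (default 0.5).
#' @param quantize quantize to the ADC bit depth (default `FALSE`: keep the
#'   noiseless frames exact).
#' @return list of class `oct_calibration_frames`: `frame_a`, `frame_b`
#'   (`oct_raw_frame`s), `opds_um`, `gdd_fs2`.
#' @export
generate_calibration_frames <- function(spec, opds_um = NULL, source = NULL,
                                        dispersion_gdd_fs2 = 0, r = 0.3,
                                        rho_ref = 0.5, quantize = FALSE) {
  stopifnot(inherits(spec, "spectrometer_model"))
  zmax <- unambiguous_range(spec)
  if (is.null(opds_um)) opds_um <- (zmax / 2) * c(0.25, 0.75)
  if (length(opds_um) != 2L || any(opds_um <= 0))
    stop_domain("'opds_um' must be two positive OPDs")
  if (abs(diff(opds_um)) < 1e-9)
    stop_domain("degenerate calibration: the two OPDs must be distinct")
  if (max(opds_um) > zmax)
    stop_domain("calibration OPD beyond the unambiguous range")
  if (max(opds_um) > zmax / 2)
    warning("calibration OPD beyond half the unambiguous range: fringe has ",
            "< 4 samples/period", call. = FALSE)
  k_pix <- pixel_k_midir(spec)
  if (is.null(source)) {
    band <- sort(downconvert_wavelength(spec$lambda_range_nm, spec$pump_nm))
    pad <- 0.005 * diff(band)
    source <- make_source_spectrum(band + c(-pad, pad), "flat")
  }
  k0 <- wavelength_to_k(band_center_nm(source$band_nm))
  env_pix <- spectrum_at_pixels(source$k_grid, source$envelope, k_pix)
  full <- 2^spec$bit_depth - 1
  base <- rho_ref + r^2
  gain <- 0.8 * full / (max(env_pix) * (base + 2 * sqrt(rho_ref) * r))
  phi_d <- gdd_phase(dispersion_gdd_fs2, k_pix, k0)
  mk <- function(z) {
    counts <- env_pix * gain *
      (base + 2 * sqrt(rho_ref) * r * cos(2 * k_pix * z + phi_d))
    if (quantize) counts <- round(pmin(pmax(counts, 0), full))
    raw_frame(counts, "calibration", spec, NA_real_)
  }
  structure(list(frame_a = mk(opds_um[1]), frame_b = mk(opds_um[2]),
                 opds_um = as.numeric(opds_um),
                 gdd_fs2 = dispersion_gdd_fs2),
            class = "oct_calibration_frames")
}
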