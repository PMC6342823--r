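#' Axial resolution by Gaussian fit of an A-scan peak
#'
#' Least-squares Gaussian fit (`a * exp(-(z - mu)^2 / (2 sigma^2)) + c`)
#' over +/- 3 nominal widths around the peak of a zero-padded A-scan
#' magnitude; returns the FWHM in um of one-way OPD. The peak must stand at
#' least 10 dB above the local noise floor, and a secondary peak inside the
#' fit window above half the primary is rejected rather than silently
#' fitted.
#'
#' @param ascan an `oct_ascan`.
#' @param peak_opd_hint_um optional OPD near which to look for the peak
#'   (+/- `hint_window_um`); default: global maximum.
#' @param hint_window_um half-width of the hint search window (default 50).
#' @param min_prominence_db required peak height above the noise floor
#'   (default 10).
#' @param method `"gaussian"` (least-squares fit, the default — appropriate
#'   for smooth near-Gaussian peaks) or `"halfmax"` (direct interpolated
#'   half-maximum crossings — appropriate for non-Gaussian shapes such as
#'   the sinc response of an unapodized flat spectrum).
#' @return the FWHM in um, with the fit (`nls` object; Gaussian method),
#'   centre and the fit window attached as attributes.
#' @export
axial_resolution <- function(ascan, peak_opd_hint_um = NULL,
                             hint_window_um = 50, min_prominence_db = 10,
                             method = c("gaussian", "halfmax")) {
  method <- match.arg(method)
  stopifnot(inherits(ascan, "oct_ascan"))
  mag <- ascan$magnitude
  z <- ascan$depth_um
  search <- if (is.null(peak_opd_hint_um)) seq_along(mag)
            else which(abs(z - peak_opd_hint_um) <= hint_window_um)
  if (!length(search)) stop_domain("hint window contains no depth bins")
  pk <- search[which.max(mag[search])]
  floor_db <- 20 * log10(max(ascan$noise_floor, 1e-300))
  if (20 * log10(max(mag[pk], 1e-300)) - floor_db < min_prominence_db)
    stop_domain("no peak at least ", min_prominence_db,
                " dB above the noise floor")
  # nominal width from half-maximum crossings around the peak
  half <- mag[pk] / 2
  lo <- pk; while (lo > 1 && mag[lo] > half) lo <- lo - 1
  hi <- pk; while (hi < length(mag) && mag[hi] > half) hi <- hi + 1
  nominal <- max(z[hi] - z[lo], 2 * (z[2] - z[1]))
  if (method == "halfmax") {
    # interpolated half-maximum crossings on the zero-padded magnitude
    xl <- z[lo] + (z[lo + 1] - z[lo]) * (half - mag[lo]) /
      (mag[lo + 1] - mag[lo])
    xr <- z[hi - 1] + (z[hi] - z[hi - 1]) * (mag[hi - 1] - half) /
      (mag[hi - 1] - mag[hi])
    return(structure(xr - xl, center_um = z[pk],
                     window_um = c(z[lo], z[hi])))
  }
  win <- which(z >= z[pk] - 3 * nominal & z <= z[pk] + 3 * nominal)
  # reject multi-modal windows: a secondary local max above half the peak
  wmag <- mag[win]
  locmax <- which(diff(sign(diff(wmag))) == -2) + 1L
  big <- locmax[wmag[locmax] > 0.5 * mag[pk]]
  if (length(big) > 1L)
    stop_domain("ambiguous peak: multiple comparable maxima in the fit window")
  df <- data.frame(z = z[win], y = wmag)
  # Levenberg-Marquardt: robust also on (near-)zero-residual synthetic peaks
  fit <- minpack.lm::nlsLM(y ~ a * exp(-(z - mu)^2 / (2 * sigma^2)) + c0,
                           data = df,
                           start = list(a = mag[pk], mu = z[pk],
                                        sigma = nominal / 2.3548,
                                        c0 = min(wmag)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  sigma <- abs(coef(fit)[["sigma"]])
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  structure(fwhm, fit = fit, center_um = coef(fit)[["mu"]],
            window_um = range(df$z))
}

#' Sensitivity roll-off curve from mirror A-scans at probed OPDs
#'
#' Peak sensitivity per probe depth in dB relative to the shallowest probe
#' (`20 log10` of the peak-magnitude ratio), with the 6 dB depth found by
#' linear interpolation in dB between the bracketing probes. If the curve
#' never drops 6 dB the deepest probe is reported as a lower bound.
#'
#' @param ascans list of >= 5 `oct_ascan`s of mirror frames at increasing
#'   OPD.
#' @param opds_um optional known probe OPDs (default: each A-scan's peak
#'   location).
#' @return object of class `oct_rolloff`: `opd_um`, `sensitivity_db`,
#'   `z6db_um`, `z6db_is_lower_bound`.
#' @export
rolloff_curve <- function(ascans, opds_um = NULL) {
  if (length(ascans) < 5L) stop_domain("need >= 5 probe depths")
  stopifnot(all(vapply(ascans, inherits, TRUE, "oct_ascan")))
  peaks <- vapply(ascans, function(a) max(a$magnitude), 0)
  if (is.null(opds_um))
    opds_um <- vapply(ascans, function(a) a$depth_um[which.max(a$magnitude)],
                      0)
  ord <- order(opds_um)
  opds_um <- opds_um[ord]; peaks <- peaks[ord]
  sens <- 20 * log10(peaks / peaks[1])
  below <- which(sens <= -6)
  if (length(below)) {
    i <- below[1]
    if (i == 1L) {
      z6 <- opds_um[1]
    } else {
      z6 <- opds_um[i - 1] + (opds_um[i] - opds_um[i - 1]) *
        (-6 - sens[i - 1]) / (sens[i] - sens[i - 1])
    }
    lower <- FALSE
  } else {
    z6 <- max(opds_um)
    lower <- TRUE
  }
  structure(list(opd_um = opds_um, sensitivity_db = sens, z6db_um = z6,
                 z6db_is_lower_bound = lower),
            class = "oct_rolloff")
}

#' @export
print.oct_rolloff <- function(x, ...) {
  cat(sprintf("Sensitivity roll-off over %.0f-%.0f um OPD (%d probes)\n",
              min(x$opd_um), max(x$opd_um), length(x$opd_um)))
  if (x$z6db_is_lower_bound)
    cat(sprintf("  6 dB depth: > %.0f um (not bracketed)\n", x$z6db_um))
  else cat(sprintf("  6 dB depth: %.0f um\n", x$z6db_um))
  invisible(x)
}

#' @export
plot.oct_rolloff <- function(x, ...) {
  graphics::plot(x$opd_um / 1000, x$sensitivity_db, type = "b",
                 xlab = "one-way OPD (mm)", ylab = "sensitivity (dB)", ...)
  graphics::abline(h = -6, lty = 2)
}

#' Spectral resolution from a 6 dB roll-off depth
#'
#' Inverts the Gaussian roll-off model: a spectral-resolution kernel of
#' FWHM `delta_lambda` attenuates the peak sensitivity by 6 dB at one-way
#' OPD `z = ln2 * lambda0^2 / (pi * delta_lambda)`, so
#' `delta_lambda = ln2 * lambda0^2 / (pi * z6db)`.
#'
#' @param z6db_um 6 dB roll-off depth, um (one-way OPD).
#' @param lambda0_nm centre wavelength, nm (package convention: geometric
#'   mean of the band edges).
#' @return spectral resolution FWHM, nm.
#' @examples
#' spectral_resolution_from_rolloff(1350, sqrt(3576 * 4625))  # ~2.7 nm
#' @export
spectral_resolution_from_rolloff <- function(z6db_um, lambda0_nm) {
  if (z6db_um <= 0 || lambda0_nm <= 0) stop_domain("inputs must be > 0")
  log(2) * lambda0_nm^2 / (pi * z6db_um * 1000)
}

#' Physical thickness from an OPD thickness
#'
#' Divides a measured OPD thickness by the refractive index; the
#' uncertainty is twice the digital sampling resolution divided by the
#' index.
#'
#' @param opd_um OPD thickness (difference of interface OPDs), um.
#' @param n refractive index of the layer.
#' @param sampling_um digital depth sampling resolution, um.
#' @return object of class `thickness_result`: `thickness_um`,
#'   `uncertainty_um` and the inputs.
#' @examples
#' thickness_from_opd(809.9, 2.138, 4.05)  # 378.8 +/- 3.8 um
#' @export
thickness_from_opd <- function(opd_um, n, sampling_um) {
  if (opd_um <= 0 || n <= 0 || sampling_um <= 0)
    stop_domain("all inputs must be > 0")
  structure(list(thickness_um = opd_um / n,
                 uncertainty_um = 2 * sampling_um / n,
                 opd_um = opd_um, n = n, sampling_um = sampling_um),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("thickness %.1f +/- %.1f um (OPD %.1f um / n = %.3f)\n",
              x$thickness_um, x$uncertainty_um, x$opd_um, x$n))
  invisible(x)
}

#' Spectral and lateral sampling resolutions
#'
#' Average spectral sampling = detected bandwidth / number of detected
#' pixels; lateral sampling = stage speed x line integration time.
#'
#' @param band_nm detected band edges `c(min, max)`, nm (mid-IR scale).
#' @param n_detected_pixels number of pixels covering the band.
#' @param speed_mm_s stage speed, mm/s.
#' @param integration_ms line integration time, ms.
#' @return list with `spectral_nm` and `lateral_um`.
#' @examples
#' sampling_resolutions(c(3576, 4625), 2286, 3, 3)  # 0.46 nm, 9 um
#' @export
sampling_resolutions <- function(band_nm, n_detected_pixels, speed_mm_s,
                                 integration_ms) {
  if (n_detected_pixels <= 0 || speed_mm_s < 0 || integration_ms < 0)
    stop_domain("inputs must be positive")
  list(spectral_nm = diff(range(band_nm)) / n_detected_pixels,
       lateral_um = speed_mm_s * integration_ms)
}
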