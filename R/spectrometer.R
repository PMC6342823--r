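#' Spectrometer model (near-IR line camera behind the upconversion stage)
#'
#' Describes the line-scan spectrometer that records the upconverted
#' interferogram. Pixels map monotonically to near-IR wavelength over
#' `lambda_range_nm`; each near-IR wavelength corresponds to a mid-IR
#' wavelength through the inverse upconversion map, which is where the fringe
#' phase lives. The pixel map defaults to linear in wavelength with optional
#' endpoint-preserving quadratic/cubic distortion, standing in for the real
#' (unpublished) spectrometer calibration:
#' `lambda(u) = lmin + Dl * (u + c2*u*(u-1) + c3*u*(u-1)*(u-1/2))`, u in
#' \[0, 1\].
#'
#' @param n_pixels number of pixels (default 4096).
#' @param lambda_range_nm near-IR wavelength range `c(min, max)` in nm
#'   (default `c(796, 879)`).
#' @param distortion `c(c2, c3)` pixel-map nonlinearity coefficients
#'   (default both 0: linear map).
#' @param resolution_fwhm_nm spectral resolution as a Gaussian kernel FWHM,
#'   expressed on the *mid-IR* wavelength scale via the upconversion map
#'   (default 2.7 nm).
#' @param bit_depth ADC bit depth (default 10).
#' @param line_rate_hz maximum line rate (default 45e3).
#' @param pump_nm upconversion pump wavelength used to translate pixels to
#'   mid-IR wavenumbers (default 1064).
#' @param full_well_integration_ms integration time at which an ideal
#'   reference frame reaches 80 percent of full scale (default 3 ms); counts
#'   scale linearly with integration time around this anchor.
#' @param pixel_lambda_nm optional explicit per-pixel near-IR wavelength
#'   table overriding the parametric map (length `n_pixels`, strictly
#'   monotone).
#' @return object of class `spectrometer_model`.
#' @export
spectrometer_model <- function(n_pixels = 4096L,
                               lambda_range_nm = c(796, 879),
                               distortion = c(0, 0),
                               resolution_fwhm_nm = 2.7,
                               bit_depth = 10L,
                               line_rate_hz = 45e3,
                               pump_nm = 1064,
                               full_well_integration_ms = 3,
                               pixel_lambda_nm = NULL) {
  n_pixels <- as.integer(n_pixels)
  if (n_pixels < 2L) stop_domain("'n_pixels' must be >= 2")
  if (resolution_fwhm_nm <= 0) stop_domain("'resolution_fwhm_nm' must be > 0")
  if (length(distortion) == 1L) distortion <- c(distortion, 0)
  if (!is.null(pixel_lambda_nm)) {
    if (length(pixel_lambda_nm) != n_pixels)
      stop_domain("'pixel_lambda_nm' must have length n_pixels")
    d <- diff(pixel_lambda_nm)
    if (!(all(d > 0) || all(d < 0)))
      stop_domain("'pixel_lambda_nm' must be strictly monotone")
    lambda_range_nm <- range(pixel_lambda_nm)
  }
  obj <- structure(list(n_pixels = n_pixels,
                        lambda_range_nm = as.numeric(lambda_range_nm),
                        distortion = as.numeric(distortion),
                        resolution_fwhm_nm = resolution_fwhm_nm,
                        bit_depth = as.integer(bit_depth),
                        line_rate_hz = line_rate_hz,
                        pump_nm = pump_nm,
                        full_well_integration_ms = full_well_integration_ms,
                        pixel_lambda_nm = pixel_lambda_nm),
                   class = "spectrometer_model")
  lam <- pixel_wavelength(obj)
  if (!(all(diff(lam) > 0) || all(diff(lam) < 0)))
    stop_domain("pixel map is not strictly monotone; reduce distortion")
  obj
}

#' Per-pixel near-IR wavelength of a spectrometer model
#' @param spec a [spectrometer_model()].
#' @return numeric vector of length `n_pixels`, nm.
#' @export
pixel_wavelength <- function(spec) {
  stopifnot(inherits(spec, "spectrometer_model"))
  if (!is.null(spec$pixel_lambda_nm)) return(spec$pixel_lambda_nm)
  u <- seq(0, 1, length.out = spec$n_pixels)
  c2 <- spec$distortion[1]; c3 <- spec$distortion[2]
  f <- u + c2 * u * (u - 1) + c3 * u * (u - 1) * (u - 0.5)
  spec$lambda_range_nm[1] + diff(spec$lambda_range_nm) * f
}

#' Per-pixel mid-IR wavenumber of a spectrometer model
#'
#' Translates each pixel's near-IR wavelength back through the upconversion
#' map to the mid-IR and returns the corresponding wavenumber. Note that k
#' decreases with pixel index when the near-IR wavelength increases.
#'
#' @param spec a [spectrometer_model()].
#' @return numeric vector of length `n_pixels`, rad/um (strictly monotone).
#' @export
pixel_k_midir <- function(spec) {
  wavelength_to_k(downconvert_wavelength(pixel_wavelength(spec), spec$pump_nm))
}

#' Nominal (distortion-free) per-pixel mid-IR wavenumber
#' @param spec a [spectrometer_model()].
#' @return numeric vector, rad/um; the linear-in-wavelength ideal map.
#' @keywords internal
pixel_k_nominal <- function(spec) {
  u <- seq(0, 1, length.out = spec$n_pixels)
  lam <- spec$lambda_range_nm[1] + diff(spec$lambda_range_nm) * u
  wavelength_to_k(downconvert_wavelength(lam, spec$pump_nm))
}

#' Unambiguous (Nyquist) one-way OPD range of a spectrometer model
#'
#' The fringe `cos(2 k z)` sampled at the mean pixel wavenumber pitch
#' `dk` aliases beyond `z_max = pi / (2 dk)`.
#'
#' @param spec a [spectrometer_model()].
#' @return maximum unambiguous one-way OPD in um.
#' @export
unambiguous_range <- function(spec) {
  k <- pixel_k_midir(spec)
  dk <- abs(diff(range(k))) / (spec$n_pixels - 1)
  pi / (2 * dk)
}

#' @export
print.spectrometer_model <- function(x, ...) {
  cat("Spectrometer model\n")
  cat(sprintf("  pixels:       %d over %.0f-%.0f nm (near-IR)\n",
              x$n_pixels, x$lambda_range_nm[1], x$lambda_range_nm[2]))
  cat(sprintf("  mid-IR span:  %.0f-%.0f nm (pump %.0f nm)\n",
              downconvert_wavelength(x$lambda_range_nm[1], x$pump_nm),
              downconvert_wavelength(x$lambda_range_nm[2], x$pump_nm),
              x$pump_nm))
  cat(sprintf("  resolution:   %.2f nm FWHM (mid-IR scale)\n",
              x$resolution_fwhm_nm))
  cat(sprintf("  bit depth:    %d, line rate %.0f Hz\n",
              x$bit_depth, x$line_rate_hz))
  cat(sprintf("  unambiguous range: %.0f um one-way OPD\n",
              unambiguous_range(x)))
  invisible(x)
}
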