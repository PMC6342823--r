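#' Upconversion configuration
#'
#' Parameters of the sum-frequency upconversion stage that shifts the mid-IR
#' OCT signal into the near-IR for silicon-based detection. A strong pump at
#' `pump_nm` mixes with the mid-IR signal in a periodically poled crystal so
#' that `1/lambda_pump + 1/lambda_ir = 1/lambda_up` (energy conservation).
#'
#' @param pump_nm pump wavelength in nm (default 1064, Nd:YVO4 line).
#' @param band_nm mid-IR band edges in nm, `c(min, max)` (default
#'   `c(3576, 4625)`).
#' @param qe flat scalar quantum efficiency of the conversion over the band,
#'   in (0, 1] (default 0.01, i.e. 1 percent). A wavelength-dependent QE can
#'   be supplied to [remap_spectrum()] as a table override.
#' @param poling_um poling period Lambda of the quasi-phase-matching grating
#'   in um (default 23).
#' @return an object of class `upconversion_config`.
#' @export
upconversion_config <- function(pump_nm = 1064, band_nm = c(3576, 4625),
                                qe = 0.01, poling_um = 23) {
  if (!is.numeric(pump_nm) || length(pump_nm) != 1L || !is.finite(pump_nm) ||
      pump_nm <= 0)
    stop_domain("'pump_nm' must be a single positive finite number")
  if (length(band_nm) != 2L || any(!is.finite(band_nm)) || any(band_nm <= 0) ||
      band_nm[1] >= band_nm[2])
    stop_domain("'band_nm' must be two positive wavelengths with min < max")
  if (!is.finite(qe) || qe <= 0 || qe > 1)
    stop_domain("'qe' must be in (0, 1]")
  if (!is.finite(poling_um) || poling_um <= 0)
    stop_domain("'poling_um' must be positive")
  structure(list(pump_nm = pump_nm, band_nm = as.numeric(band_nm),
                 qe = qe, poling_um = poling_um),
            class = "upconversion_config")
}

#' @export
print.upconversion_config <- function(x, ...) {
  cat("Upconversion configuration\n")
  cat(sprintf("  pump:      %.1f nm\n", x$pump_nm))
  cat(sprintf("  mid-IR in: %.0f-%.0f nm\n", x$band_nm[1], x$band_nm[2]))
  cat(sprintf("  QE:        %.3g (flat)\n", x$qe))
  cat(sprintf("  poling:    %.2f um\n", x$poling_um))
  invisible(x)
}

#' Sum-frequency upconverted wavelength
#'
#' Energy conservation for sum-frequency generation:
#' `1/lambda_pump + 1/lambda_ir = 1/lambda_up`.
#'
#' @param lambda_ir_nm mid-IR signal wavelength(s), nm.
#' @param lambda_p_nm pump wavelength, nm.
#' @return upconverted wavelength(s) in nm; always smaller than both inputs.
#' @examples
#' upconvert_wavelength(3576, 1064)  # ~820 nm
#' upconvert_wavelength(4625, 1064)  # ~865 nm
#' @export
upconvert_wavelength <- function(lambda_ir_nm, lambda_p_nm) {
  if (any(!is.finite(lambda_ir_nm)) || any(lambda_ir_nm <= 0))
    stop_domain("mid-IR wavelength must be finite and positive")
  if (any(!is.finite(lambda_p_nm)) || any(lambda_p_nm <= 0))
    stop_domain("pump wavelength must be finite and positive")
  (lambda_ir_nm * lambda_p_nm) / (lambda_ir_nm + lambda_p_nm)
}

#' Inverse of the upconversion map
#'
#' Recovers the mid-IR wavelength from an upconverted (sum-frequency)
#' wavelength: `1/lambda_ir = 1/lambda_up - 1/lambda_pump`.
#'
#' @param lambda_up_nm upconverted wavelength(s), nm; must be below the pump.
#' @param lambda_p_nm pump wavelength, nm.
#' @return mid-IR wavelength(s) in nm.
#' @export
downconvert_wavelength <- function(lambda_up_nm, lambda_p_nm) {
  if (any(!is.finite(lambda_up_nm)) || any(lambda_up_nm <= 0))
    stop_domain("upconverted wavelength must be finite and positive")
  if (any(!is.finite(lambda_p_nm)) || any(lambda_p_nm <= 0))
    stop_domain("pump wavelength must be finite and positive")
  if (any(lambda_up_nm >= lambda_p_nm))
    stop_domain("upconverted wavelength must be below the pump wavelength")
  (lambda_up_nm * lambda_p_nm) / (lambda_p_nm - lambda_up_nm)
}

#' Map the mid-IR band through the upconversion stage
#'
#' Applies [upconvert_wavelength()] to both band edges and reports the
#' near-IR detection band and both bandwidths.
#'
#' @param cfg an [upconversion_config()].
#' @return a list of class `band_map_result` with `nearir_band` (nm pair),
#'   `nearir_bandwidth` (nm) and `midir_bandwidth` (nm).
#' @examples
#' map_band(upconversion_config())  # ~(820, 865), 45 nm / 1049 nm
#' @export
map_band <- function(cfg = upconversion_config()) {
  stopifnot(inherits(cfg, "upconversion_config"))
  lo <- upconvert_wavelength(cfg$band_nm[1], cfg$pump_nm)
  hi <- upconvert_wavelength(cfg$band_nm[2], cfg$pump_nm)
  structure(list(nearir_band = c(lo, hi),
                 nearir_bandwidth = hi - lo,
                 midir_bandwidth = diff(cfg$band_nm)),
            class = "band_map_result")
}

#' @export
print.band_map_result <- function(x, ...) {
  cat(sprintf("near-IR band: %.2f-%.2f nm (bandwidth %.2f nm)\n",
              x$nearir_band[1], x$nearir_band[2], x$nearir_bandwidth))
  cat(sprintf("mid-IR bandwidth: %.1f nm\n", x$midir_bandwidth))
  invisible(x)
}

#' Remap a mid-IR spectral density onto the upconverted wavelength axis
#'
#' Transforms a photon-count (or power) spectral density tabulated against the
#' mid-IR wavelength onto the near-IR axis defined by the upconversion map,
#' conserving the integrated count up to the scalar quantum efficiency.
#' The change-of-variables Jacobian is
#' `|d lambda_up / d lambda_ir| = (lambda_up / lambda_ir)^2`, so
#' `N_up(lambda_up) = qe * N_ir(lambda_ir) / (lambda_up/lambda_ir)^2`.
#'
#' @param lambda_ir_nm strictly monotonic mid-IR wavelength grid (nm), inside
#'   the configured band.
#' @param density non-negative spectral density per nm at `lambda_ir_nm`.
#' @param cfg an [upconversion_config()].
#' @param qe_table optional override for the flat QE: a `data.frame`/list with
#'   `lambda_nm` and `qe`, linearly interpolated over the band.
#' @return list with `lambda_up_nm` (strictly monotonic grid) and `density`
#'   (per nm on the upconverted axis).
#' @export
remap_spectrum <- function(lambda_ir_nm, density, cfg = upconversion_config(),
                           qe_table = NULL) {
  stopifnot(inherits(cfg, "upconversion_config"))
  if (length(lambda_ir_nm) != length(density))
    stop_domain("grid and density lengths differ")
  d <- diff(lambda_ir_nm)
  if (length(d) == 0L || !(all(d > 0) || all(d < 0)))
    stop_domain("wavelength grid must be strictly monotonic")
  if (any(density < 0)) stop_domain("spectral density must be non-negative")
  tol <- 1e-9 * diff(cfg$band_nm)
  if (min(lambda_ir_nm) < cfg$band_nm[1] - tol ||
      max(lambda_ir_nm) > cfg$band_nm[2] + tol)
    stop_domain("wavelength grid lies outside the configured mid-IR band")
  qe <- if (is.null(qe_table)) rep(cfg$qe, length(lambda_ir_nm))
        else approx(qe_table$lambda_nm, qe_table$qe, xout = lambda_ir_nm,
                    rule = 2)$y
  lup <- upconvert_wavelength(lambda_ir_nm, cfg$pump_nm)
  jac <- (lup / lambda_ir_nm)^2
  list(lambda_up_nm = lup, density = qe * density / jac)
}

#' Collinear first-order quasi-phase-matching mismatch
#'
#' Scalar collinear phase mismatch for sum-frequency generation in a
#' periodically poled crystal with first-order grating compensation:
#' `dk = 2*pi * (n_up/lambda_up - n_p/lambda_p - n_ir/lambda_ir - 1/Lambda)`,
#' in rad/um with all wavelengths converted to um. Sign convention: positive
#' when the sum-frequency wave's momentum exceeds the pump + signal + grating
#' momenta; perfect quasi-phase matching gives 0.
#'
#' @param lambda_ir_nm,lambda_p_nm signal and pump wavelengths, nm.
#' @param n_ir,n_p,n_up refractive indices at the signal, pump and
#'   sum-frequency wavelengths (caller-supplied; no Sellmeier tables are
#'   bundled).
#' @param poling_um poling period Lambda, um; `Inf` disables the grating term.
#' @return mismatch dk in rad/um.
#' @export
qpm_mismatch <- function(lambda_ir_nm, lambda_p_nm, n_ir, n_p, n_up,
                         poling_um) {
  if (any(c(n_ir, n_p, n_up) <= 0))
    stop_domain("refractive indices must be positive")
  if (!is.finite(poling_um) && !identical(poling_um, Inf))
    stop_domain("'poling_um' must be positive (or Inf)")
  if (poling_um <= 0) stop_domain("'poling_um' must be positive")
  lup <- upconvert_wavelength(lambda_ir_nm, lambda_p_nm)
  2 * pi * (n_up / (lup / 1000) - n_p / (lambda_p_nm / 1000) -
            n_ir / (lambda_ir_nm / 1000) - 1 / poling_um)
}
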