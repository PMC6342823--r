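#' Source spectral envelope on a uniform wavenumber grid
#'
#' Builds the illumination power envelope `S(k)` used by the interferogram
#' forward model. The envelope is tabulated on a dense, strictly increasing,
#' uniform wavenumber grid (rad/um) that covers the band with a small
#' zero-valued margin on either side (so that spectral-resolution convolution
#' does not wrap energy across the grid ends), and is normalized so that its
#' integral over k equals 1. The envelope is identically zero outside the
#' band.
#'
#' @param band_nm wavelength band edges `c(min, max)` in nm.
#' @param shape `"flat"`, `"gaussian"` or `"tabulated"`.
#' @param n_k number of grid points; the default (32768) is 8x the default
#'   4096-pixel spectrometer, comfortably oversampling the fringes.
#' @param fwhm_nm Gaussian full width at half maximum in nm (shape
#'   `"gaussian"`; default: the band width). The Gaussian is centred at the
#'   band-centre wavenumber and truncated at the band edges.
#' @param table for shape `"tabulated"`: a list/data.frame with `lambda_nm`
#'   and `value`; linearly interpolated (in wavelength), zero outside the
#'   tabulated range.
#' @param margin fractional wavenumber margin added on each side of the band
#'   (default 0.04).
#' @return object of class `source_spectrum`: list with `k_grid` (rad/um,
#'   uniform, increasing), `envelope` (>= 0, integral 1 over k) and `band_nm`.
#' @export
make_source_spectrum <- function(band_nm = c(3576, 4625),
                                 shape = c("flat", "gaussian", "tabulated"),
                                 n_k = 32768L, fwhm_nm = NULL, table = NULL,
                                 margin = 0.04) {
  shape <- match.arg(shape)
  if (length(band_nm) != 2L || band_nm[1] >= band_nm[2] || any(band_nm <= 0))
    stop_domain("'band_nm' must satisfy 0 < min < max")
  k_hi <- wavelength_to_k(band_nm[1])   # short wavelength -> large k
  k_lo <- wavelength_to_k(band_nm[2])
  pad <- margin * (k_hi - k_lo)
  k <- seq(k_lo - pad, k_hi + pad, length.out = as.integer(n_k))
  in_band <- k >= k_lo & k <= k_hi
  env <- numeric(length(k))
  if (shape == "flat") {
    env[in_band] <- 1
  } else if (shape == "gaussian") {
    if (is.null(fwhm_nm)) fwhm_nm <- diff(band_nm)
    k_c <- (k_lo + k_hi) / 2
    lambda_c <- k_to_wavelength(k_c)
    # FWHM given in wavelength; convert to wavenumber at band centre
    fwhm_k <- wavelength_to_k(lambda_c - fwhm_nm / 2) -
              wavelength_to_k(lambda_c + fwhm_nm / 2)
    sig <- fwhm_k / (2 * sqrt(2 * log(2)))
    env[in_band] <- exp(-(k[in_band] - k_c)^2 / (2 * sig^2))
  } else {
    if (is.null(table) || is.null(table$lambda_nm) || is.null(table$value))
      stop_domain("shape 'tabulated' needs a table with lambda_nm and value")
    lam <- k_to_wavelength(k)
    v <- approx(table$lambda_nm, table$value, xout = lam)$y
    v[is.na(v)] <- 0
    env <- v
    env[!in_band] <- 0
  }
  if (any(env < 0)) stop_domain("envelope must be non-negative")
  dk <- k[2] - k[1]
  total <- sum(env) * dk
  if (total <= 0) stop_domain("envelope is identically zero")
  structure(list(k_grid = k, envelope = env / total,
                 band_nm = as.numeric(band_nm), shape = shape),
            class = "source_spectrum")
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf("Source spectrum (%s): %.0f-%.0f nm, %d k-points\n",
              x$shape, x$band_nm[1], x$band_nm[2], length(x$k_grid)))
  invisible(x)
}

#' @export
plot.source_spectrum <- function(x, ...) {
  graphics::plot(x$k_grid, x$envelope, type = "l",
                 xlab = "wavenumber k (rad/um)",
                 ylab = "relative power density", ...)
}
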