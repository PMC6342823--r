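#' Dark-subtract and reference-normalize a raw frame
#'
#' Implements the first stage of the processing chain: the raw sample
#' spectrum is dark-signal subtracted and normalized to the reference-arm
#' signal, yielding the zero-mean fringe term
#' `(sample - dark) / (reference - dark) - 1`.
#'
#' Pixels where `reference - dark <= eps` and saturated pixels (counts at
#' full scale in the sample or reference frame) are masked: the returned
#' vector holds `NA` there and carries the logical mask as attribute
#' `"mask"`, so later fits can exclude them.
#'
#' @param sample,dark,reference `oct_raw_frame`s of equal length and bit
#'   depth.
#' @param eps reference-level floor in counts; default 5 percent of the
#'   dark-subtracted reference maximum (the same threshold that defines the
#'   occupied spectral support downstream — dividing by a near-zero
#'   reference amplifies out-of-band leakage into spurious bandwidth).
#' @return numeric fringe signal per pixel with attribute `"mask"`.
#' @export
preprocess_frames <- function(sample, dark, reference, eps = NULL) {
  frames <- list(sample, dark, reference)
  stopifnot(all(vapply(frames, inherits, TRUE, "oct_raw_frame")))
  n <- length(sample$counts)
  if (length(dark$counts) != n || length(reference$counts) != n)
    stop_domain("frames have different lengths")
  bits <- vapply(frames, function(f) f$spec$bit_depth, 0L)
  if (length(unique(bits)) != 1L)
    stop_domain("frames have different bit depths")
  full <- 2^bits[1] - 1
  denom <- reference$counts - dark$counts
  if (is.null(eps)) eps <- max(1, 0.05 * max(denom))
  if (all(denom <= eps))
    stop_domain("calibration error: reference frame carries no signal")
  saturated <- sample$counts >= full | reference$counts >= full
  mask <- denom <= eps | saturated
  fringe <- (sample$counts - dark$counts) / denom - 1
  fringe[mask] <- NA_real_
  attr(fringe, "mask") <- mask
  # occupied spectral support: contiguous pixel range where the reference
  # arm exceeds 5 percent of its maximum (used for apodization downstream)
  ok <- which(denom > 0.05 * max(denom))
  attr(fringe, "support") <- c(ok[1], ok[length(ok)])
  fringe
}

# One-sided ("analytic signal") band-pass of a real fringe: FFT, zero the
# negative-frequency half and a low-frequency guard below the fringe
# carrier, double the positive half, inverse FFT. dc_cut_frac sets the guard
# as a fraction of the detected carrier bin.
analytic_fringe <- function(x, dc_cut_frac = 1 / 3) {
  n <- length(x)
  xf <- fft(x - mean(x))
  half <- n %/% 2
  mag <- Mod(xf[2:(half + 1)])
  carrier <- which.max(mag)                   # bin offset from DC
  dc_cut <- max(2L, as.integer(floor(carrier * dc_cut_frac)))
  h <- numeric(n)
  h[(dc_cut + 1L):(half + 1L)] <- 2
  if (n %% 2 == 0) h[half + 1L] <- 1
  fft(xf * h, inverse = TRUE) / n
}

# Phase-unwrap with failure diagnostics: jumps are judged after removing the
# median per-pixel phase increment (the carrier slope).
unwrap_checked <- function(phase_wrapped, what = "fringe") {
  ph <- signal::unwrap(phase_wrapped)
  dp <- diff(ph)
  detrended <- dp - median(dp)
  bad <- which(abs(detrended) > pi)
  if (length(bad))
    stop_domain(sprintf(
      "calibration error: phase unwrap failure in %s at pixel %d", what,
      bad[1] + 1L))
  ph
}

#' Build a pixel-to-wavenumber calibration from two reference interferograms
#'
#' Recovers the spectrometer's pixel-to-wavenumber map and the interferometer
#' dispersion mismatch from two single-mirror interferograms at distinct
#' known one-way OPDs, by exploiting the phase across the pixel array:
#' per-pixel analytic-signal phases `phi_a(p)`, `phi_b(p)` are extracted
#' (one-sided spectral filtering around the fringe carrier) and unwrapped;
#' then `k(p) = (phi_a - phi_b) / (2 (z_a - z_b))` up to a constant offset,
#' and `dispersion_phase(p) = phi_a(p) - 2 k(p) z_a`.
#'
#' The unknown offset is anchored by matching the mean of `k(p)` to the mean
#' of the spectrometer's nominal (linear-in-wavelength) map over the usable
#' band — exact for pixel-map distortions with zero mean over the band and
#' accurate to the distortion mean otherwise. Constant and linear residuals
#' in the dispersion phase are harmless (they shift the A-scan by a fixed
#' sub-bin amount and leave magnitudes unchanged).
#'
#' @param frame_a,frame_b `oct_raw_frame`s (or an `oct_calibration_frames`
#'   pair passed as `frame_a` with the rest `NULL`).
#' @param opd_a_um,opd_b_um the two known mirror OPDs, um.
#' @param trim fraction of pixels dropped at each array edge before use
#'   (analytic-signal edge leakage; default 0.02).
#' @param support_threshold fringe-envelope amplitude threshold (fraction of
#'   max) defining the usable band (default 0.05).
#' @param n_out number of uniform-wavenumber resampling points (default
#'   `n_pixels / 2`).
#' @return object of class `calibration_map`: `k_of_pixel` (rad/um, full
#'   pixel array, `NA` outside the usable range), `usable` (first/last usable
#'   pixel), `k_uniform` (increasing uniform grid), `dk_uniform`,
#'   `resample_positions` (fractional pixel indices for `k_uniform`),
#'   `dispersion_phase` (rad per uniform-k sample), `opds_um`, `spec`.
#' @export
build_calibration <- function(frame_a, frame_b = NULL, opd_a_um = NULL,
                              opd_b_um = NULL, trim = 0.02,
                              support_threshold = 0.05, n_out = NULL) {
  if (inherits(frame_a, "oct_calibration_frames")) {
    cf <- frame_a
    frame_b <- cf$frame_b; opd_a_um <- cf$opds_um[1]; opd_b_um <- cf$opds_um[2]
    frame_a <- cf$frame_a
  }
  stopifnot(inherits(frame_a, "oct_raw_frame"),
            inherits(frame_b, "oct_raw_frame"))
  if (is.null(opd_a_um) || is.null(opd_b_um) ||
      abs(opd_a_um - opd_b_um) < 1e-9)
    stop_domain("degenerate calibration: need two distinct known OPDs")
  spec <- frame_a$spec
  n <- spec$n_pixels
  if (is.null(n_out)) n_out <- n %/% 2L

  aa <- analytic_fringe(frame_a$counts)
  ab <- analytic_fringe(frame_b$counts)
  phi_a <- unwrap_checked(Arg(aa), "frame_a")
  phi_b <- unwrap_checked(Arg(ab), "frame_b")

  amp <- pmin(Mod(aa) / max(Mod(aa)), Mod(ab) / max(Mod(ab)))
  margin <- max(1L, as.integer(ceiling(trim * n)))
  ok <- amp >= support_threshold
  ok[seq_len(margin)] <- FALSE
  ok[(n - margin + 1L):n] <- FALSE
  if (!any(ok)) stop_domain("calibration error: no usable fringe support")
  p1 <- which(ok)[1]; p2 <- tail(which(ok), 1)
  idx <- p1:p2

  k_rel <- (phi_a - phi_b) / (2 * (opd_a_um - opd_b_um))
  k_nom <- pixel_k_nominal(spec)
  # the analytic-signal phase carries a global sign ambiguity (the fringe is
  # a cosine); orient it along the nominal map
  if (sign(k_rel[p2] - k_rel[p1]) != sign(k_nom[p2] - k_nom[p1])) {
    phi_a <- -phi_a; phi_b <- -phi_b
    k_rel <- -k_rel
  }
  offset <- mean(k_nom[idx] - k_rel[idx])
  k_pix <- k_rel + offset
  dkp <- diff(k_pix[idx])
  if (!(all(dkp > 0) || all(dkp < 0)))
    stop_domain("calibration error: recovered wavenumber map not monotone")

  disp_pix <- phi_a - 2 * k_pix * opd_a_um

  k_lo <- min(k_pix[idx]); k_hi <- max(k_pix[idx])
  k_uniform <- seq(k_lo, k_hi, length.out = n_out)
  dk_uniform <- k_uniform[2] - k_uniform[1]
  ord <- if (k_pix[p2] > k_pix[p1]) idx else rev(idx)
  pos_fun <- splinefun(k_pix[ord], ord, method = "fmm")
  resample_positions <- pos_fun(k_uniform)
  disp_fun <- splinefun(idx, disp_pix[idx], method = "fmm")
  dispersion_phase <- disp_fun(resample_positions)

  k_full <- rep(NA_real_, n); k_full[idx] <- k_pix[idx]
  structure(list(k_of_pixel = k_full, usable = c(p1, p2),
                 k_uniform = k_uniform, dk_uniform = dk_uniform,
                 resample_positions = resample_positions,
                 dispersion_phase = dispersion_phase,
                 opds_um = c(opd_a_um, opd_b_um), spec = spec),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat("Pixel-to-wavenumber calibration map\n")
  cat(sprintf("  usable pixels: %d-%d of %d\n", x$usable[1], x$usable[2],
              x$spec$n_pixels))
  cat(sprintf("  uniform k grid: %d points, %.5g-%.5g rad/um\n",
              length(x$k_uniform), min(x$k_uniform), max(x$k_uniform)))
  cat(sprintf("  calibration OPDs: %.1f / %.1f um\n",
              x$opds_um[1], x$opds_um[2]))
  invisible(x)
}

# Contiguous occupied spectral support of a resampled fringe: smoothed
# analytic-signal amplitude above threshold * max.
occupied_support <- function(s, threshold = 0.05) {
  amp <- Mod(analytic_fringe(s))
  w <- max(5L, length(s) %/% 64L)
  amp <- as.numeric(stats::filter(amp, rep(1 / w, w), sides = 2))
  amp[is.na(amp)] <- 0
  ok <- amp >= threshold * max(amp)
  if (!any(ok)) return(c(1L, length(s)))
  c(which(ok)[1], tail(which(ok), 1))
}

#' Reconstruct an A-scan from a fringe signal
#'
#' Fixed pipeline order: cubic-spline resampling onto the calibration's
#' uniform wavenumber grid, multiplication by
#' `exp(-i * dispersion_phase)`, spectral windowing over the occupied
#' support, zero padding, Fourier transform, magnitude. Depth bin:
#' `pi / (K * zero_pad_factor)` with `K = n_uniform * dk_uniform` the
#' uniform-wavenumber span; the depth axis is one-way OPD in air.
#'
#' @param fringe per-pixel fringe signal from [preprocess_frames()] (masked
#'   pixels, `NA`, are zeroed before resampling).
#' @param cal a [build_calibration()] map from the same spectrometer model.
#' @param window `"hanning"` (over the occupied spectral support — taken
#'   from the fringe's `"support"` attribute set by [preprocess_frames()]
#'   (reference arm above 5 percent of max), falling back to
#'   analytic-amplitude detection) or `"none"`.
#' @param zero_pad_factor integer >= 1 (default 4).
#' @param interp `"spline"` (cubic, default) or `"linear"` resampling.
#' @param support_threshold occupied-support amplitude threshold (fraction
#'   of max, default 0.05).
#' @param keep_complex keep the complex depth profile (default `TRUE`).
#' @return object of class `oct_ascan`: `magnitude` (linear), `db`
#'   (`20 log10(magnitude / noise-floor median)`), `depth_um` (uniform, from
#'   0), `zero_pad_factor`, `dk_uniform`, optional `complex_profile`, plus
#'   `spectral_power` / `profile_power` (Parseval pair: windowed spectral
#'   power in, total depth-profile power out).
#' @export
reconstruct_ascan <- function(fringe, cal, window = c("hanning", "none"),
                              zero_pad_factor = 4L, interp = c("spline",
                              "linear"), support_threshold = 0.05,
                              keep_complex = TRUE) {
  window <- match.arg(window)
  interp <- match.arg(interp)
  stopifnot(inherits(cal, "calibration_map"))
  zero_pad_factor <- as.integer(zero_pad_factor)
  if (zero_pad_factor < 1L) stop_domain("'zero_pad_factor' must be >= 1")
  if (length(fringe) != cal$spec$n_pixels)
    stop_domain("fringe length does not match the calibration's spectrometer")
  x <- as.numeric(fringe)
  x[is.na(x)] <- 0
  p <- seq_along(x)
  s <- if (interp == "spline") splinefun(p, x, method = "fmm")(cal$resample_positions)
       else approx(p, x, xout = cal$resample_positions, rule = 2)$y
  sc <- s * exp(-1i * cal$dispersion_phase)
  w <- rep(1, length(sc))
  if (window == "hanning") {
    pix_sup <- attr(fringe, "support")
    sup <- if (!is.null(pix_sup)) {
      # pixel-domain support (reference arm > 5 percent of max) mapped onto
      # the uniform-k grid
      inside <- which(cal$resample_positions >= pix_sup[1] &
                      cal$resample_positions <= pix_sup[2])
      if (length(inside)) range(inside) else occupied_support(s, support_threshold)
    } else occupied_support(s, support_threshold)
    w <- numeric(length(sc))
    nw <- sup[2] - sup[1] + 1L
    w[sup[1]:sup[2]] <- if (nw >= 2) signal::hanning(nw) else 1
  }
  n_u <- length(sc)
  n_fft <- n_u * zero_pad_factor
  padded <- c(sc * w, complex(real = numeric(n_fft - n_u)))
  spectrum <- fft(padded)
  # Parseval bookkeeping: spectral power in, depth-profile power out
  spectral_power <- sum(Mod(sc * w)^2)
  profile_power <- sum(Mod(spectrum)^2) / n_fft
  n_keep <- n_fft %/% 2L
  prof <- spectrum[seq_len(n_keep)]
  magnitude <- Mod(prof)
  depth_bin <- pi / (n_fft * cal$dk_uniform)
  floor_est <- median(magnitude)
  if (!is.finite(floor_est) || floor_est <= 0)
    floor_est <- max(magnitude, 1e-300) * 1e-12
  structure(list(magnitude = magnitude,
                 db = 20 * log10(pmax(magnitude, 1e-300) / floor_est),
                 depth_um = (seq_len(n_keep) - 1L) * depth_bin,
                 zero_pad_factor = zero_pad_factor,
                 dk_uniform = cal$dk_uniform,
                 window = window,
                 noise_floor = floor_est,
                 spectral_power = spectral_power,
                 profile_power = profile_power,
                 complex_profile = if (keep_complex) prof else NULL),
            class = "oct_ascan")
}

#' @export
print.oct_ascan <- function(x, ...) {
  pk <- which.max(x$magnitude)
  cat(sprintf("A-scan: %d depth bins, bin %.3f um, window %s\n",
              length(x$magnitude), x$depth_um[2] - x$depth_um[1], x$window))
  cat(sprintf("  peak %.1f dB at %.1f um one-way OPD (in air)\n",
              x$db[pk], x$depth_um[pk]))
  invisible(x)
}

#' @export
plot.oct_ascan <- function(x, db = TRUE, ...) {
  graphics::plot(x$depth_um, if (db) x$db else x$magnitude, type = "l",
                 xlab = "one-way OPD in air (um)",
                 ylab = if (db) "magnitude (dB)" else "magnitude", ...)
}

#' Assemble A-scans into a B-scan (or B-scans into a volume)
#'
#' Lateral spacing is `speed * integration` for continuous stage motion or
#' the programmed step for stepped scanning; total acquisition time is
#' `n_lines * integration` in continuous mode.
#'
#' @param scans a list of >= 2 `oct_ascan`s sharing a depth axis (B-scan) or
#'   a list of >= 2 `oct_bscan`s (volume; use `mode = "stepped_y"`).
#' @param mode `"continuous_x"` or `"stepped_y"`.
#' @param speed_mm_s stage speed, mm/s (continuous mode).
#' @param integration_ms per-line integration time, ms (continuous mode).
#' @param step_um lateral step, um (stepped mode).
#' @return `oct_bscan` (magnitude matrix depth x lines, depth/lateral axes,
#'   acquisition metadata) or `oct_volume` (3-D array).
#' @export
assemble_scan <- function(scans, mode = c("continuous_x", "stepped_y"),
                          speed_mm_s = NULL, integration_ms = NULL,
                          step_um = NULL) {
  mode <- match.arg(mode)
  if (!is.list(scans) || length(scans) < 2L)
    stop_domain("need at least 2 scans to assemble")
  if (mode == "continuous_x") {
    if (is.null(speed_mm_s) || is.null(integration_ms))
      stop_domain("continuous mode needs 'speed_mm_s' and 'integration_ms'")
    spacing <- speed_mm_s * integration_ms   # mm/s * ms = um
    total_s <- length(scans) * integration_ms / 1000
  } else {
    if (is.null(step_um)) stop_domain("stepped mode needs 'step_um'")
    spacing <- step_um
    total_s <- NA_real_
  }
  if (spacing <= 0) stop_domain("lateral spacing must be > 0")
  lateral <- (seq_along(scans) - 1L) * spacing
  if (all(vapply(scans, inherits, TRUE, "oct_ascan"))) {
    depth <- scans[[1]]$depth_um
    for (s in scans)
      if (!isTRUE(all.equal(s$depth_um, depth)))
        stop_domain("inconsistent depth axes across A-scans")
    structure(list(magnitude = vapply(scans, `[[`, depth * 0, "magnitude"),
                   db = vapply(scans, `[[`, depth * 0, "db"),
                   depth_um = depth, lateral_um = lateral,
                   meta = list(mode = mode, speed_mm_s = speed_mm_s,
                               integration_ms = integration_ms,
                               step_um = step_um, total_time_s = total_s)),
              class = "oct_bscan")
  } else if (all(vapply(scans, inherits, TRUE, "oct_bscan"))) {
    depth <- scans[[1]]$depth_um
    for (s in scans)
      if (!isTRUE(all.equal(s$depth_um, depth)))
        stop_domain("inconsistent depth axes across B-scans")
    vol <- array(unlist(lapply(scans, `[[`, "magnitude")),
                 dim = c(dim(scans[[1]]$magnitude), length(scans)))
    structure(list(magnitude = vol, depth_um = depth,
                   lateral_um = scans[[1]]$lateral_um, slow_um = lateral,
                   meta = list(mode = mode, step_um = step_um)),
              class = "oct_volume")
  } else {
    stop_domain("'scans' must be all A-scans or all B-scans")
  }
}

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf("B-scan: %d depth bins x %d lines, lateral pitch %.2f um\n",
              nrow(x$magnitude), ncol(x$magnitude),
              x$lateral_um[2] - x$lateral_um[1]))
  if (is.finite(x$meta$total_time_s %||% NA))
    cat(sprintf("  acquisition time %.2f s (%s)\n", x$meta$total_time_s,
                x$meta$mode))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
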