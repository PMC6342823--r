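#' Run a time-resolved voxel Monte Carlo transport simulation
#'
#' Launches photon packets into a voxel domain and tracks them with exact
#' ray-voxel boundary stepping: step lengths sampled as optical depth
#' `-ln(U)`, weight `mua/(mua+mus)` deposited per interaction,
#' Henyey-Greenstein sampling of the deflection cosine, unpolarized Fresnel
#' reflection/refraction at refractive-index steps (deterministic weight
#' splitting above `split_min`, stochastic branch selection below), optical
#' time advanced by `n * ds / c`, Russian roulette termination below
#' `roulette_threshold`. Packets leaving the top face are recorded with exit
#' position, direction (in the exterior medium, after refraction), weight
#' and time.
#'
#' Reproducibility: the engine uses its own counter-based RNG stream keyed
#' by `source$seed`, so results are bit-identical for a fixed seed and
#' independent of R's RNG state.
#'
#' @param domain a [voxel_domain()].
#' @param source an [mc_source()]; must lie inside the domain footprint.
#' @param time a [time_grid()]; packets older than the grid are booked as
#'   residual.
#' @param na system numerical aperture in (0, 1\]; stored for extraction
#'   metadata (gating happens in [extract_mc_ascan()]).
#' @param n_outside refractive index of the exterior (default 1, air).
#' @param split_min weight above which Fresnel splitting is deterministic
#'   (default 1e-3).
#' @param roulette_threshold Russian-roulette weight threshold (default
#'   1e-4; survival probability 0.1).
#' @param record_exits keep the per-photon top-face exit records (default
#'   `TRUE`).
#' @param absorbed_map accumulate the per-voxel absorbed-weight map
#'   (default `FALSE`).
#' @return object of class `mc_result`: `exits` (matrix with columns x_um,
#'   y_um, ux, uy, uz, weight, t_ps), `ledger` (launched, absorbed,
#'   exit_top, exit_bottom, exit_side, residual, roulette_net; the ledger
#'   sums to launched exactly up to floating point), optional
#'   `absorbed_map` (array), and the inputs as metadata.
#' @export
mc_simulate <- function(domain, source, time, na = 0.1, n_outside = 1,
                        split_min = 1e-3, roulette_threshold = 1e-4,
                        record_exits = TRUE, absorbed_map = FALSE) {
  stopifnot(inherits(domain, "voxel_domain"), inherits(source, "mc_source"),
            inherits(time, "time_grid"))
  if (na <= 0 || na > 1) stop_domain("'na' must be in (0, 1]")
  ext <- domain_extent(domain)
  if (source$x_um < 0 || source$x_um > ext[1] ||
      source$y_um < 0 || source$y_um > ext[2])
    stop_domain("source outside the domain footprint")
  res <- mc_simulate_cpp(as.numeric(domain$mua), as.numeric(domain$mus),
                         as.numeric(domain$g), as.numeric(domain$n),
                         domain$dims, domain$voxel_um,
                         as.integer(source$nphoton), as.numeric(source$seed),
                         source$x_um, source$y_um, source$width_um / 2,
                         time$t_total_ps, n_outside, split_min,
                         roulette_threshold, record_exits, absorbed_map)
  ledger <- c(launched = res$launched, absorbed = res$absorbed,
              exit_top = res$exit_top, exit_bottom = res$exit_bottom,
              exit_side = res$exit_side, residual = res$residual,
              roulette_net = res$roulette_net)
  amap <- NULL
  if (absorbed_map) {
    amap <- array(res$absorbed_map, dim = domain$dims)
  }
  structure(list(exits = res$exits, ledger = ledger, absorbed_map = amap,
                 time = time, na = na, source = source,
                 domain_dims = domain$dims, voxel_um = domain$voxel_um),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC result: %d photons launched, %d top-face exit records\n",
              as.integer(x$ledger["launched"]), nrow(x$exits)))
  led <- x$ledger
  bal <- sum(led[c("absorbed", "exit_top", "exit_bottom", "exit_side",
                   "residual", "roulette_net")])
  cat(sprintf("  ledger: absorbed %.4g, top %.4g, bottom %.4g, side %.4g, ",
              led["absorbed"], led["exit_top"], led["exit_bottom"],
              led["exit_side"]))
  cat(sprintf("residual %.4g (closes to %.3g)\n",
              led["residual"], bal - led["launched"]))
  invisible(x)
}

#' Extract an OCT A-scan from Monte Carlo exit records
#'
#' Emulates time-domain OCT detection: per time gate, sums the weight of
#' photons returning through the top face within the collection cone of the
#' system, i.e. whose exit polar angle in air satisfies `sin(theta) <= NA`.
#' The gate index maps to depth as `z = gate * dz` with `dz = c dt / 2`
#' (one-way OPD in air). Flux is normalized by the number of launched
#' photons.
#'
#' @param sim an [mc_simulate()] result (with exit records).
#' @param time a [time_grid()] (default: the grid used in the simulation).
#' @param na numerical aperture for the acceptance cone (default: the
#'   simulation's).
#' @return object of class `mc_ascan`: `flux` (per gate, normalized),
#'   `depth_um`, `na`, `seed`.
#' @export
extract_mc_ascan <- function(sim, time = NULL, na = NULL) {
  stopifnot(inherits(sim, "mc_result"))
  if (is.null(time)) time <- sim$time
  if (is.null(na)) na <- sim$na
  ex <- sim$exits
  if (is.null(ex) || nrow(ex) == 0) {
    flux <- numeric(time$n_gates)
    message("no top-face exit records: returning an all-zero A-scan")
  } else {
    sin_theta <- sqrt(ex[, "ux"]^2 + ex[, "uy"]^2)
    keep <- sin_theta <= na
    gate <- pmin(floor(ex[keep, "t_ps"] / time$dt_ps) + 1L, time$n_gates)
    flux <- numeric(time$n_gates)
    if (any(keep)) {
      acc <- tapply(ex[keep, "weight"], gate, sum)
      flux[as.integer(names(acc))] <- acc
    }
    flux <- flux / sim$ledger[["launched"]]
  }
  structure(list(flux = flux,
                 depth_um = seq_len(time$n_gates) * time$dz_um,
                 na = na, seed = sim$source$seed,
                 source_x_um = sim$source$x_um),
            class = "mc_ascan")
}

#' @export
print.mc_ascan <- function(x, ...) {
  pk <- which.max(x$flux)
  cat(sprintf("MC A-scan: %d gates; peak flux %.3g at %.1f um (one-way OPD in air)\n",
              length(x$flux), x$flux[pk], x$depth_um[pk]))
  invisible(x)
}

#' @export
plot.mc_ascan <- function(x, db = TRUE, ...) {
  y <- if (db) {
    fl <- x$flux[x$flux > 0]
    ref <- if (length(fl)) median(fl) else 1
    10 * log10(pmax(x$flux, ref * 1e-6) / ref)
  } else x$flux
  graphics::plot(x$depth_um, y, type = "l",
                 xlab = "one-way OPD in air (um)",
                 ylab = if (db) "flux (dB)" else "flux", ...)
}

#' Confocal Gaussian-beam overlap configuration
#'
#' Parameters of the depth-dependent collection-efficiency correction: the
#' overlap between the focused Gaussian beam (e^-2 radius `w0_um`, focal
#' depth `zf_um`) and the beam reflected at depth z, which — due to the
#' double pass — looks like the input Gaussian at distance `2 (z - zF)` from
#' focus.
#'
#' @param w0_um beam e^-2 radius at focus, um.
#' @param lambda_um wavelength, um.
#' @param zf_um focal depth, um (e.g. sample top surface + 50).
#' @return object of class `overlap_config`.
#' @export
overlap_config <- function(w0_um, lambda_um, zf_um) {
  if (w0_um <= 0 || lambda_um <= 0)
    stop_domain("'w0_um' and 'lambda_um' must be > 0")
  structure(list(w0_um = w0_um, lambda_um = lambda_um, zf_um = zf_um),
            class = "overlap_config")
}

#' Confocal overlap correction factor
#'
#' Closed-form overlap integral between the in-focus Gaussian mode and the
#' defocused return beam:
#' `C(z) = 4 w0^4 pi^2 (4 (z-zF)^2 L^2 + pi^2 w0^4) /
#'         (4 (z-zF)^2 L^2 + 2 pi^2 w0^4)^2`
#' with `L` the wavelength. `C = 1` exactly in focus and falls off as
#' `pi^2 w0^4 / ((z-zF)^2 L^2)` far from focus.
#'
#' @param z_um depth(s), um (>= 0).
#' @param cfg an [overlap_config()].
#' @return factor(s) in (0, 1].
#' @export
overlap_correction <- function(z_um, cfg) {
  stopifnot(inherits(cfg, "overlap_config"))
  if (any(z_um < 0)) stop_domain("'z_um' must be >= 0")
  w0 <- cfg$w0_um; lam <- cfg$lambda_um
  d2 <- (z_um - cfg$zf_um)^2
  4 * w0^4 * pi^2 * (4 * d2 * lam^2 + pi^2 * w0^4) /
    (4 * d2 * lam^2 + 2 * pi^2 * w0^4)^2
}

#' Apply roll-off and overlap corrections to an MC A-scan
#'
#' Multiplies the gated flux elementwise by a sensitivity roll-off curve and
#' the confocal overlap factor, `flux(z) * rolloff(z) * C(z)`; the two
#' corrections commute.
#'
#' @param ascan an [extract_mc_ascan()] result.
#' @param rolloff `NULL`, a function of depth (um) returning a power factor,
#'   or a numeric vector over the A-scan's gates.
#' @param overlap `NULL` or an [overlap_config()].
#' @return the corrected `mc_ascan`.
#' @export
apply_corrections <- function(ascan, rolloff = NULL, overlap = NULL) {
  stopifnot(inherits(ascan, "mc_ascan"))
  fac <- rep(1, length(ascan$flux))
  if (!is.null(rolloff)) {
    r <- if (is.function(rolloff)) rolloff(ascan$depth_um) else rolloff
    if (length(r) != length(ascan$flux))
      stop_domain("roll-off curve does not span the A-scan depth range")
    if (any(!is.finite(r)))
      stop_domain("roll-off curve not defined over the full depth range")
    fac <- fac * r
  }
  if (!is.null(overlap)) fac <- fac * overlap_correction(ascan$depth_um, overlap)
  ascan$flux <- ascan$flux * fac
  ascan
}

#' Monte Carlo B-scan across the domain's X extent
#'
#' Runs one NA-gated A-scan per lateral source position, stepping the source
#' by `lateral_step_um` across the full X extent of the domain (line count
#' `floor(extent / step)`, positions centred in each step). Each line gets
#' an independent, reproducible RNG stream keyed by
#' `(seed, line index)` as `seed * 1000003 + line`.
#'
#' @param domain a [voxel_domain()].
#' @param time a [time_grid()].
#' @param na numerical aperture.
#' @param lateral_step_um source step, um.
#' @param nphoton photons per line.
#' @param seed global seed.
#' @param width_um source Gaussian e^-2 radius, um (default 15).
#' @param y_um source Y position, um (default: domain centre).
#' @param line_seeds optional explicit per-line seeds (recycled), overriding
#'   the keyed-stream policy — e.g. a single value to run every line from
#'   the same stream.
#' @return object of class `mc_bscan`: `flux` matrix (gates x lines),
#'   `depth_um`, `lateral_um`, `seeds`, metadata.
#' @export
run_mc_bscan <- function(domain, time, na = 0.1, lateral_step_um = 10,
                         nphoton = 1e4, seed = 1, width_um = 15,
                         y_um = NULL, line_seeds = NULL) {
  stopifnot(inherits(domain, "voxel_domain"), inherits(time, "time_grid"))
  ext <- domain_extent(domain)
  if (lateral_step_um <= 0) stop_domain("'lateral_step_um' must be > 0")
  if (lateral_step_um > ext[1])
    stop_domain("lateral step larger than the domain X extent")
  n_lines <- floor(ext[1] / lateral_step_um)
  if (is.null(y_um)) y_um <- ext[2] / 2
  xs <- (seq_len(n_lines) - 0.5) * lateral_step_um
  seeds <- if (is.null(line_seeds)) seed * 1000003 + seq_len(n_lines)
           else rep_len(line_seeds, n_lines)
  flux <- matrix(0, nrow = time$n_gates, ncol = n_lines)
  for (i in seq_len(n_lines)) {
    src <- mc_source(xs[i], y_um, width_um, nphoton, seeds[i])
    sim <- mc_simulate(domain, src, time, na = na)
    flux[, i] <- extract_mc_ascan(sim)$flux
  }
  structure(list(flux = flux,
                 depth_um = seq_len(time$n_gates) * time$dz_um,
                 lateral_um = xs, seeds = seeds, na = na,
                 nphoton = nphoton, width_um = width_um),
            class = "mc_bscan")
}

#' @export
print.mc_bscan <- function(x, ...) {
  cat(sprintf("MC B-scan: %d gates x %d lines (%.0f um pitch), %g photons/line\n",
              nrow(x$flux), ncol(x$flux),
              x$lateral_um[2] - x$lateral_um[1], x$nphoton))
  invisible(x)
}

#' Sample Henyey-Greenstein deflection cosines
#'
#' Direct access to the engine's single-scatter sampler, mainly for
#' verification: the sample mean converges to the anisotropy `g`.
#'
#' @param n number of samples.
#' @param g anisotropy in \[-1, 1\].
#' @param seed RNG seed.
#' @return numeric vector of deflection cosines.
#' @export
sample_hg <- function(n, g, seed = 1) {
  if (abs(g) > 1) stop_domain("|g| must be <= 1")
  mc_sample_hg_cpp(as.integer(n), g, as.numeric(seed))
}
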