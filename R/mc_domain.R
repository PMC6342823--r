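#' Voxelized optical domain for Monte Carlo photon transport
#'
#' A 3-D grid of optical properties: absorption `mua` and scattering `mus`
#' coefficients (mm^-1), Henyey-Greenstein anisotropy `g` (-1..1) and
#' refractive index `n` (>= 1). Depth is the third (z) axis; photons enter
#' through the top face (z = 0).
#'
#' @param dims integer `c(nx, ny, nz)` voxel counts.
#' @param voxel_um isotropic voxel pitch, um (default 5).
#' @param mua,mus,g,n scalar fill values or arrays of dimension `dims`.
#' @return object of class `voxel_domain`.
#' @export
voxel_domain <- function(dims, voxel_um = 5, mua = 0, mus = 0, g = 0, n = 1) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop_domain("'dims' must be three positive voxel counts")
  if (voxel_um <= 0) stop_domain("'voxel_um' must be > 0")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- array(x, dim = dims)
    if (!identical(dim(x), dims)) {
      dim_ok <- !is.null(dim(x)) && all(dim(x) == dims)
      if (!dim_ok) stop_domain(sprintf("'%s' must be scalar or a %s array",
                                       name, paste(dims, collapse = "x")))
    }
    x
  }
  mua <- expand(mua, "mua"); mus <- expand(mus, "mus")
  g <- expand(g, "g"); n <- expand(n, "n")
  if (any(mua < 0) || any(mus < 0)) stop_domain("mua and mus must be >= 0")
  if (any(abs(g) > 1)) stop_domain("|g| must be <= 1")
  if (any(n < 1)) stop_domain("refractive index must be >= 1")
  structure(list(dims = dims, voxel_um = voxel_um,
                 mua = mua, mus = mus, g = g, n = n),
            class = "voxel_domain")
}

#' @export
print.voxel_domain <- function(x, ...) {
  ext <- x$dims * x$voxel_um
  cat(sprintf("Voxel domain: %d x %d x %d voxels at %.3g um = %.0f x %.0f x %.0f um^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_um,
              ext[1], ext[2], ext[3]))
  cat(sprintf("  mua %.3g-%.3g, mus %.3g-%.3g mm^-1; g %.2g-%.2g; n %.3g-%.3g\n",
              min(x$mua), max(x$mua), min(x$mus), max(x$mus),
              min(x$g), max(x$g), min(x$n), max(x$n)))
  invisible(x)
}

#' Physical extent of a voxel domain
#' @param domain a [voxel_domain()].
#' @return `c(x, y, z)` extent in um.
#' @export
domain_extent <- function(domain) {
  stopifnot(inherits(domain, "voxel_domain"))
  domain$dims * domain$voxel_um
}

#' Monte Carlo source description
#'
#' A pencil-like source entering the top face along +z with a Gaussian
#' transverse intensity profile of constant width (geometrical-optics
#' transport cannot carry a diverging Gaussian beam). `width_um` is the
#' e^-2 intensity radius; samples are drawn with per-axis standard deviation
#' `width_um / 2`.
#'
#' @param x_um,y_um entry position, um (defaults: domain centre must be set
#'   by the caller; here plain numbers).
#' @param width_um Gaussian e^-2 radius, um (e.g. 5 at 1.3 um centre
#'   wavelength, 15 at 4 um).
#' @param nphoton number of photon packets to launch.
#' @param seed RNG seed (any non-negative integer; streams are keyed by it).
#' @return object of class `mc_source`.
#' @export
mc_source <- function(x_um, y_um, width_um = 15, nphoton = 1e5, seed = 1) {
  if (width_um <= 0) stop_domain("'width_um' must be > 0")
  if (nphoton < 1) stop_domain("'nphoton' must be >= 1")
  structure(list(x_um = x_um, y_um = y_um, width_um = width_um,
                 nphoton = as.integer(nphoton), seed = seed),
            class = "mc_source")
}

#' Time gating grid for the Monte Carlo detector
#'
#' Time-of-flight gates of width `dt_fs` spanning `t_total_ps`; the
#' equivalent depth sampling in air is `dz = c * dt / 2` (one-way, because
#' light travels to depth z and back in time `2 z / c`).
#'
#' @param t_total_ps total recorded time, ps (default 14.4).
#' @param dt_fs gate width, fs (default 24).
#' @return object of class `time_grid` with `n_gates`, `dz_um` and the gate
#'   edges.
#' @export
time_grid <- function(t_total_ps = 14.4, dt_fs = 24) {
  if (t_total_ps <= 0 || dt_fs <= 0) stop_domain("times must be > 0")
  dt_ps <- dt_fs / 1000
  n_gates <- round(t_total_ps / dt_ps)
  if (abs(n_gates - t_total_ps / dt_ps) > 1e-6)
    warning("t_total_ps is not an integer multiple of dt_fs; truncating",
            call. = FALSE)
  dz <- .C_UM_PER_FS * dt_fs / 2
  structure(list(t_total_ps = n_gates * dt_ps, dt_fs = dt_fs,
                 dt_ps = dt_ps, n_gates = as.integer(n_gates), dz_um = dz),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Time grid: %d gates of %.3g fs (%.3g ps total), dz = %.4g um\n",
              x$n_gates, x$dt_fs, x$t_total_ps, x$dz_um))
  invisible(x)
}
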