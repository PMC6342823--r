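#' Ceramic stack sample specification
#'
#' The three-plate ceramic test sample: C1 a zirconia plate, C2 an alumina
#' plate with valleys laser-milled into its top surface, C3 an alumina
#' backing plate. Default geometry: 375 um zirconia (n 2.138), 475 um
#' alumina (n 1.675) with 60-um-deep valleys, 300 um alumina.
#'
#' The default valley widths follow the simulation geometry (5 to 180 um in
#' steps of 5); `valley_widths = "experimental"` selects the physical
#' sample's 5-300 um range instead.
#'
#' Optical properties: the zirconia/alumina absorption and scattering
#' coefficients are not published with the sample; the defaults shipped here
#' are *placeholders* chosen once to reproduce the qualitative wavelength
#' ordering (alumina scatters strongly at 1.3 um, weakly at 4 um; absorption
#' negligible for both materials from 0.5-4 um). Supply measured values via
#' `materials` for quantitative work.
#'
#' @param c1_um,c2_um,c3_um plate thicknesses, um.
#' @param n_zirconia,n_alumina refractive indices.
#' @param valley_depth_um valley depth milled into C2's top, um
#'   (<= `c2_um`).
#' @param valley_widths `"simulation"` (5-180 um step 5), `"experimental"`
#'   (5-300 um step 5) or a numeric vector of widths in um.
#' @param gap_c2_c3_um air gap between C2 and C3, um (default 0). In the
#'   voxel domain a nonzero gap is carved out of the top of C3 so the total
#'   depth is preserved.
#' @param materials named list `list(tag = list(zirconia = c(mua, mus, g),
#'   alumina = c(mua, mus, g)))` in mm^-1 for the wavelength tags `"1.3"`
#'   and `"4.0"`.
#' @return object of class `ceramic_stack_spec`.
#' @export
ceramic_stack_spec <- function(c1_um = 375, c2_um = 475, c3_um = 300,
                               n_zirconia = 2.138, n_alumina = 1.675,
                               valley_depth_um = 60,
                               valley_widths = "simulation",
                               gap_c2_c3_um = 0,
                               materials = NULL) {
  if (any(c(c1_um, c2_um, c3_um) <= 0)) stop_domain("thicknesses must be > 0")
  if (valley_depth_um < 0 || valley_depth_um > c2_um)
    stop_domain("'valley_depth_um' must lie in [0, c2_um]")
  widths <- if (is.character(valley_widths)) {
    switch(match.arg(valley_widths, c("simulation", "experimental")),
           simulation = seq(5, 180, by = 5),
           experimental = seq(5, 300, by = 5))
  } else as.numeric(valley_widths)
  if (is.null(materials)) {
    # placeholders (see Details): strong alumina scattering at 1.3 um only
    materials <- list(
      "1.3" = list(zirconia = c(mua = 0.01, mus = 5, g = 0.7),
                   alumina = c(mua = 0.01, mus = 20, g = 0.7)),
      "4.0" = list(zirconia = c(mua = 0.01, mus = 1, g = 0.3),
                   alumina = c(mua = 0.01, mus = 2, g = 0.3)))
  }
  structure(list(c1_um = c1_um, c2_um = c2_um, c3_um = c3_um,
                 n_zirconia = n_zirconia, n_alumina = n_alumina,
                 valley_depth_um = valley_depth_um, valley_widths = widths,
                 gap_c2_c3_um = gap_c2_c3_um, materials = materials),
            class = "ceramic_stack_spec")
}

#' @export
print.ceramic_stack_spec <- function(x, ...) {
  cat(sprintf("Ceramic stack: C1 %.0f um zirconia (n %.3f) / C2 %.0f um alumina (n %.3f) / C3 %.0f um alumina\n",
              x$c1_um, x$n_zirconia, x$c2_um, x$n_alumina, x$c3_um))
  cat(sprintf("  %d valleys, depth %.0f um, widths %.0f-%.0f um\n",
              length(x$valley_widths), x$valley_depth_um,
              min(x$valley_widths), max(x$valley_widths)))
  invisible(x)
}

# Layer thickness in voxels; layers must be voxel-aligned in the defaults.
layer_voxels <- function(um, voxel_um, what) {
  nv <- round(um / voxel_um)
  if (abs(nv * voxel_um - um) > 1e-6)
    warning(sprintf("%s (%.3g um) is not a multiple of the voxel pitch; using %d voxels",
                    what, um, nv), call. = FALSE)
  as.integer(nv)
}

#' Voxel domain for the ceramic stack
#'
#' Builds the Monte Carlo domain for the ceramic stack: by default
#' 1400 x 9 x 230 voxels at 5 um (7000 x 45 x 1150 um^3), uniform along Y,
#' with the valleys (air) milled into the top of C2, their widths increasing
#' across X, centres evenly spread over the X extent. A nonzero
#' `gap_c2_c3_um` is carved out of the top of C3 as air so the outer
#' dimensions are unchanged.
#'
#' @param spec a [ceramic_stack_spec()].
#' @param wavelength_tag `"4.0"` or `"1.3"` — selects the material property
#'   set.
#' @param voxel_um voxel pitch, um (default 5).
#' @param nx,ny lateral voxel counts (defaults 1400, 9).
#' @param valleys include the valleys (default `TRUE`).
#' @return a [voxel_domain()].
#' @export
ceramic_stack_domain <- function(spec = ceramic_stack_spec(),
                                 wavelength_tag = c("4.0", "1.3"),
                                 voxel_um = 5, nx = 1400L, ny = 9L,
                                 valleys = TRUE) {
  stopifnot(inherits(spec, "ceramic_stack_spec"))
  wavelength_tag <- match.arg(wavelength_tag)
  mat <- spec$materials[[wavelength_tag]]
  if (is.null(mat)) stop_domain("no material set for tag ", wavelength_tag)
  nz1 <- layer_voxels(spec$c1_um, voxel_um, "C1")
  nz2 <- layer_voxels(spec$c2_um, voxel_um, "C2")
  nz3 <- layer_voxels(spec$c3_um, voxel_um, "C3")
  nzv <- layer_voxels(spec$valley_depth_um, voxel_um, "valley depth")
  nzg <- layer_voxels(spec$gap_c2_c3_um, voxel_um, "C2-C3 gap")
  if (nzv > nz2) stop_domain("valley depth exceeds the C2 layer")
  if (nzg > nz3) stop_domain("C2-C3 gap exceeds the C3 layer")
  nz <- nz1 + nz2 + nz3
  dims <- c(as.integer(nx), as.integer(ny), nz)

  z_layer <- c(rep(1L, nz1), rep(2L, nz2), rep(3L, nz3))  # 1 zir, 2/3 alu
  prop <- function(layer, field) {
    v <- c(mat$zirconia[[field]], mat$alumina[[field]], mat$alumina[[field]])
    v[layer]
  }
  mua <- array(rep(prop(z_layer, "mua"), each = nx * ny), dim = dims)
  mus <- array(rep(prop(z_layer, "mus"), each = nx * ny), dim = dims)
  g <- array(rep(prop(z_layer, "g"), each = nx * ny), dim = dims)
  nidx <- array(rep(c(spec$n_zirconia, spec$n_alumina,
                      spec$n_alumina)[z_layer], each = nx * ny), dim = dims)

  set_air <- function(ixs, izs) {
    mua[ixs, , izs] <<- 0; mus[ixs, , izs] <<- 0
    g[ixs, , izs] <<- 0; nidx[ixs, , izs] <<- 1
  }
  if (valleys && nzv > 0 && length(spec$valley_widths)) {
    nw <- length(spec$valley_widths)
    centers_um <- (seq_len(nw) - 0.5) * (nx * voxel_um) / nw
    for (i in seq_len(nw)) {
      wv <- max(1L, round(spec$valley_widths[i] / voxel_um))
      cx <- round(centers_um[i] / voxel_um)
      ix1 <- max(1L, cx - wv %/% 2L + 1L)
      ix2 <- min(as.integer(nx), ix1 + wv - 1L)
      set_air(ix1:ix2, (nz1 + 1L):(nz1 + nzv))
    }
  }
  if (nzg > 0) set_air(seq_len(nx), (nz1 + nz2 + 1L):(nz1 + nz2 + nzg))
  voxel_domain(dims, voxel_um, mua = mua, mus = mus, g = g, n = nidx)
}

#' Reflector stack for the ceramic sample
#'
#' Interfaces at cumulative one-way OPDs `sum(n_i d_i)` with Fresnel
#' normal-incidence amplitude reflectivities between adjacent indices.
#' Equal-index interfaces (C2/C3 without an air gap) have zero reflectivity
#' and are dropped.
#'
#' @param spec a [ceramic_stack_spec()].
#' @param standoff_um air OPD in front of the sample, um (default 100;
#'   keeps the first peak away from DC).
#' @param through_valley route the beam through a valley: the top
#'   `valley_depth_um` of C2 is air, giving the C1/air and air/C2 interface
#'   pair and shifting deeper interfaces up by `depth * (n_alumina - 1)`.
#' @return a [reflector_stack()].
#' @export
ceramic_stack_reflectors <- function(spec = ceramic_stack_spec(),
                                     standoff_um = 100,
                                     through_valley = FALSE) {
  stopifnot(inherits(spec, "ceramic_stack_spec"))
  nz <- spec$n_zirconia; na_ <- spec$n_alumina
  z <- standoff_um
  zs <- z; rs <- fresnel_r(1, nz)              # air / C1
  z <- z + spec$c1_um * nz
  if (through_valley && spec$valley_depth_um > 0) {
    zs <- c(zs, z); rs <- c(rs, fresnel_r(nz, 1))       # C1 / air (valley)
    z <- z + spec$valley_depth_um                        # air path
    zs <- c(zs, z); rs <- c(rs, fresnel_r(1, na_))       # air / C2
    z <- z + (spec$c2_um - spec$valley_depth_um) * na_
  } else {
    zs <- c(zs, z); rs <- c(rs, fresnel_r(nz, na_))      # C1 / C2
    z <- z + spec$c2_um * na_
  }
  if (spec$gap_c2_c3_um > 0) {
    zs <- c(zs, z); rs <- c(rs, fresnel_r(na_, 1))       # C2 / air gap
    z <- z + spec$gap_c2_c3_um
    zs <- c(zs, z); rs <- c(rs, fresnel_r(1, na_))       # gap / C3
  } else {
    zs <- c(zs, z); rs <- c(rs, fresnel_r(na_, na_))     # C2 / C3 (r = 0)
  }
  # the gap is carved out of the top of C3 (total stack depth preserved,
  # matching ceramic_stack_domain)
  z <- z + (spec$c3_um - spec$gap_c2_c3_um) * na_
  zs <- c(zs, z); rs <- c(rs, fresnel_r(na_, 1))         # C3 / air
  keep <- rs > 0
  reflector_stack(zs[keep], rs[keep])
}

#' Reflector stack for a plane-parallel wafer with dispersion
#'
#' Two interfaces: the front face and a back face whose reflection
#' accumulates the double-pass group-delay dispersion
#' `GDD = 2 * thickness * GVD(probe)`. The group index is a required input
#' (it is not part of the sample description; standard literature values
#' for silicon are about 3.6 at 1.3 um and 3.43 at 4 um — external
#' knowledge, supply your own).
#'
#' @param thickness_um wafer thickness, um (0 gives a single interface).
#' @param probe `"1.3"` or `"4.0"` — selects the default GVD.
#' @param n_group group refractive index (required; sets the optical
#'   thickness and the Fresnel reflectivities).
#' @param gvd_fs2_per_mm group-velocity dispersion, fs^2/mm; defaults to
#'   1576 (probe 1.3) or 385 (probe 4.0).
#' @param standoff_um air OPD in front of the wafer, um (default 100).
#' @return a [reflector_stack()].
#' @export
wafer_reflectors <- function(thickness_um = 255, probe = c("4.0", "1.3"),
                             n_group = NULL, gvd_fs2_per_mm = NULL,
                             standoff_um = 100) {
  probe <- match.arg(probe)
  if (is.null(n_group)) stop_domain("'n_group' is required (group index)")
  if (thickness_um < 0) stop_domain("'thickness_um' must be >= 0")
  if (is.null(gvd_fs2_per_mm))
    gvd_fs2_per_mm <- switch(probe, "1.3" = 1576, "4.0" = 385)
  if (thickness_um == 0)
    return(reflector_stack(standoff_um, fresnel_r(1, n_group)))
  gdd <- 2 * (thickness_um / 1000) * gvd_fs2_per_mm
  reflector_stack(c(standoff_um, standoff_um + thickness_um * n_group),
                  c(fresnel_r(1, n_group), fresnel_r(n_group, 1)),
                  gdd_fs2 = c(0, gdd))
}

#' Voxel domain for alumina tape on an acetate foil
#'
#' Two-layer phantom: a strongly scattering alumina green tape (n ~1.68)
#' over a weakly scattering cellulose acetate foil (n 1.48). The tape's
#' scattering is high at the 1.3-um tag and low at the 4.0-um tag
#' (placeholder coefficients; see [ceramic_stack_spec()] for the caveat).
#'
#' @param tape_um tape thickness, um (0 gives a foil-only domain).
#' @param foil_um foil thickness, um (default 62).
#' @param wavelength_tag `"4.0"` or `"1.3"`.
#' @param voxel_um voxel pitch, um (default 2).
#' @param nx,ny lateral voxel counts (defaults 250, 9).
#' @param materials optional override: list with `tape` and `foil`, each
#'   `c(mua, mus, g)` in mm^-1.
#' @return a [voxel_domain()].
#' @export
tape_on_foil_domain <- function(tape_um, foil_um = 62,
                                wavelength_tag = c("4.0", "1.3"),
                                voxel_um = 2, nx = 250L, ny = 9L,
                                materials = NULL) {
  wavelength_tag <- match.arg(wavelength_tag)
  if (tape_um < 0 || foil_um < 0) stop_domain("thicknesses must be >= 0")
  if (is.null(materials)) {
    materials <- switch(wavelength_tag,
      "1.3" = list(tape = c(mua = 0.05, mus = 40, g = 0.8),
                   foil = c(mua = 0.05, mus = 0.5, g = 0.5)),
      "4.0" = list(tape = c(mua = 0.05, mus = 3, g = 0.3),
                   foil = c(mua = 0.05, mus = 0.5, g = 0.5)))
  }
  nzt <- layer_voxels(tape_um, voxel_um, "tape")
  nzf <- layer_voxels(foil_um, voxel_um, "foil")
  nz <- nzt + nzf
  if (nz < 1L) stop_domain("empty domain")
  dims <- c(as.integer(nx), as.integer(ny), nz)
  layer <- c(rep(1L, nzt), rep(2L, nzf))
  pick <- function(field) {
    v <- c(materials$tape[[field]], materials$foil[[field]])[layer]
    array(rep(v, each = nx * ny), dim = dims)
  }
  voxel_domain(dims, voxel_um,
               mua = pick("mua"), mus = pick("mus"), g = pick("g"),
               n = array(rep(c(1.68, 1.48)[layer], each = nx * ny),
                         dim = dims))
}
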