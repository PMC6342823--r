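#' Reflector stack
#'
#' An ordered list of discrete reflecting interfaces driving the interferogram
#' forward model. Depths are one-way optical path differences (OPD) in air;
#' the fringe phase of interface j is `2 k z_j` plus any accumulated
#' dispersion phase.
#'
#' @param z_um one-way OPDs in air, um; non-negative and strictly increasing.
#' @param r amplitude reflectivities in \[0, 1\], recycled to `length(z_um)`.
#' @param gdd_fs2 accumulated double-pass group-delay dispersion per
#'   interface, fs^2 (default 0).
#' @param phase_poly optional list (one element per interface) of polynomial
#'   coefficients in `(k - k0)` (rad, rad*um, rad*um^2, ...) for higher-order
#'   phase; `NULL` entries mean none.
#' @return object of class `reflector_stack`.
#' @export
reflector_stack <- function(z_um, r, gdd_fs2 = 0, phase_poly = NULL) {
  n <- length(z_um)
  if (n > 0) {
    if (any(z_um < 0)) stop_domain("interface OPDs must be >= 0")
    if (n > 1 && any(diff(z_um) <= 0))
      stop_domain("interface OPDs must be strictly increasing")
  }
  r <- rep_len(r, n)
  if (any(r < 0 | r > 1))
    stop_domain("amplitude reflectivities must lie in [0, 1]")
  gdd_fs2 <- rep_len(gdd_fs2, n)
  if (!is.null(phase_poly) && length(phase_poly) != n)
    stop_domain("'phase_poly' must have one entry per interface")
  structure(list(z_um = as.numeric(z_um), r = as.numeric(r),
                 gdd_fs2 = as.numeric(gdd_fs2), phase_poly = phase_poly),
            class = "reflector_stack")
}

#' @export
print.reflector_stack <- function(x, ...) {
  cat(sprintf("Reflector stack with %d interface(s)\n", length(x$z_um)))
  if (length(x$z_um)) {
    df <- data.frame(opd_um = x$z_um, r = x$r, gdd_fs2 = x$gdd_fs2)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
length.reflector_stack <- function(x) length(x$z_um)

# Fresnel amplitude reflectivity at normal incidence between indices n1, n2.
fresnel_r <- function(n1, n2) abs((n1 - n2) / (n1 + n2))
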