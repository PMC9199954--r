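#' Optical properties of a homogeneous turbid medium
#'
#' The measurand pair of diffuse optics: the absorption coefficient
#' \eqn{\mu_a} and the reduced scattering coefficient \eqn{\mu_s'}, both in
#' cm\eqn{^{-1}}, together with the refractive index of the medium.
#'
#' @param mua Absorption coefficient, cm^-1 (>= 0).
#' @param musp Reduced scattering coefficient, cm^-1 (> 0).
#' @param n_medium Refractive index of the medium (>= 1). Defaults to 1.55,
#'   typical of epoxy-resin solid phantoms.
#'
#' @return An object of class `"optical_props"`.
#' @examples
#' optical_props(0.1, 10)
#' @export
optical_props <- function(mua, musp, n_medium = 1.55) {
  stopifnot(is.numeric(mua), length(mua) == 1L, is.finite(mua),
            is.numeric(musp), length(musp) == 1L, is.finite(musp),
            is.numeric(n_medium), length(n_medium) == 1L, is.finite(n_medium))
  if (mua < 0) stop("'mua' must be >= 0")
  if (musp <= 0) stop("'musp' must be > 0")
  if (n_medium < 1) stop("'n_medium' must be >= 1")
  structure(list(mua = mua, musp = musp, n_medium = n_medium),
            class = "optical_props")
}

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf("Optical properties: mua = %.4g cm^-1, mus' = %.4g cm^-1, n = %.3g\n",
              x$mua, x$musp, x$n_medium))
  invisible(x)
}

#' Measurement geometry
#'
#' Source--detector arrangement on the medium boundary: reflectance on a
#' semi-infinite half-space, or transmittance through a slab.
#'
#' @param mode `"reflectance"` or `"transmittance"`.
#' @param rho_mm Source--detector separation, mm (>= 0). The default 30 mm is
#'   a typical interfiber distance for adult measurements.
#' @param thickness_mm Slab thickness, mm; required for transmittance.
#' @param n_external Refractive index of the outside medium (air = 1).
#'
#' @return An object of class `"dtof_geometry"`.
#' @export
geometry <- function(mode = c("reflectance", "transmittance"),
                     rho_mm = 30, thickness_mm = NULL, n_external = 1.0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(rho_mm), length(rho_mm) == 1L, is.finite(rho_mm))
  if (rho_mm < 0) stop("'rho_mm' must be >= 0")
  if (mode == "transmittance") {
    if (is.null(thickness_mm) || !is.finite(thickness_mm) || thickness_mm <= 0)
      stop("transmittance geometry requires 'thickness_mm' > 0")
  }
  structure(list(mode = mode, rho_mm = rho_mm,
                 thickness_mm = if (is.null(thickness_mm)) NA_real_ else thickness_mm,
                 n_external = n_external),
            class = "dtof_geometry")
}

#' Absorbing-inclusion specification
#'
#' A small localized absorber inside an otherwise homogeneous medium,
#' reduced -- as in the switchable solid phantom used for depth-sensitivity
#' testing -- to an equivalent absorption change `delta_mua` acting over an
#' effective volume. The default (0.17 cm^-1 over 1 cm^3) is the equivalent
#' perturbation of the standard black cylindrical inclusion (0.5 cm diameter
#' and length) for a 10 cm^-1 reduced-scattering background.
#'
#' @param depth_mm Depth of the inclusion centre below the surface, mm (> 0).
#' @param lateral_mm Lateral offset from the source--detector midline, mm.
#' @param delta_mua Equivalent absorption change, cm^-1.
#' @param volume_cm3 Effective volume, cm^3 (> 0).
#'
#' @return An object of class `"inclusion_spec"`.
#' @export
inclusion_spec <- function(depth_mm, lateral_mm = 0,
                           delta_mua = 0.17, volume_cm3 = 1.0) {
  stopifnot(is.numeric(depth_mm), length(depth_mm) == 1L, is.finite(depth_mm))
  if (depth_mm <= 0) stop("'depth_mm' must be > 0")
  if (volume_cm3 <= 0) stop("'volume_cm3' must be > 0")
  structure(list(depth_mm = depth_mm, lateral_mm = lateral_mm,
                 delta_mua = delta_mua, volume_cm3 = volume_cm3),
            class = "inclusion_spec")
}
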