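# Analytic diffusion-theory forward model for time-resolved diffuse
# reflectance/transmittance. Internal units: cm and ps; public interfaces
# take mm for distances and cm^-1 for optical properties.

# speed of light in vacuum, cm/ps
.C_CM_PS <- 0.0299792458

# Internal-reflection parameter A for the extrapolated-boundary condition,
# from the polynomial approximation of the effective Fresnel reflection
# coefficient r_d (Groenhuis-style fit); n_rel = n_in / n_out.
.boundary_A <- function(n_rel) {
  if (n_rel == 1) return(1)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}

# Diffusion parameters in internal units. D deliberately excludes mua so the
# time-domain Beer-Lambert factorization exp(-mua * v * t) is exact.
.diffusion_pars <- function(props, n_external = 1.0) {
  D <- 1 / (3 * props$musp)              # cm
  v <- .C_CM_PS / props$n_medium         # cm/ps
  z0 <- 1 / props$musp                   # cm
  zb <- 2 * .boundary_A(props$n_medium / n_external) * D
  list(D = D, v = v, z0 = z0, zb = zb)
}

.check_time_grid <- function(t_ps) {
  if (!is.numeric(t_ps) || any(!is.finite(t_ps)))
    stop("time grid must be finite numeric")
  if (length(t_ps) > 1 && any(diff(t_ps) <= 0))
    stop("time grid must be strictly increasing")
}

#' Time-resolved diffuse reflectance of a semi-infinite medium
#'
#' Photon return rate per unit area at the surface of a homogeneous
#' semi-infinite turbid medium, per injected photon, from the
#' extrapolated-boundary dipole solution of the time-dependent diffusion
#' equation. An isotropic point source is placed at depth \eqn{z_0 = 1/\mu_s'}
#' and its negative image at \eqn{-(z_0 + 2 z_b)}, with extrapolation length
#' \eqn{z_b = 2AD}.
#'
#' @param rho_mm Source--detector separation, mm (>= 0).
#' @param t_ps Strictly increasing vector of times since the source pulse, ps.
#' @param props [optical_props()].
#' @param geom [geometry()]; supplies the external refractive index. Defaults
#'   to reflectance on air.
#'
#' @return Numeric vector, same length as `t_ps`, in cm^-2 ps^-1 per injected
#'   photon; identically 0 for `t_ps <= 0`.
#' @examples
#' t <- seq(100, 4000, by = 100)
#' R <- td_reflectance(30, t, optical_props(0.1, 10))
#' @export
td_reflectance <- function(rho_mm, t_ps, props, geom = geometry()) {
  stopifnot(inherits(props, "optical_props"))
  if (!is.numeric(rho_mm) || length(rho_mm) != 1L || !is.finite(rho_mm) || rho_mm < 0)
    stop("'rho_mm' must be a single finite value >= 0")
  .check_time_grid(t_ps)
  p <- .diffusion_pars(props, geom$n_external)
  rho <- rho_mm / 10
  out <- numeric(length(t_ps))
  ok <- t_ps > 0
  if (any(ok)) {
    t <- t_ps[ok]
    Dvt4 <- 4 * p$D * p$v * t
    zp <- p$z0
    zm <- p$z0 + 2 * p$zb
    out[ok] <- exp(-props$mua * p$v * t - rho^2 / Dvt4) /
      (2 * (4 * pi * p$D * p$v)^1.5 * t^2.5) *
      (zp * exp(-zp^2 / Dvt4) + zm * exp(-zm^2 / Dvt4))
  }
  out
}

#' Time-resolved diffuse transmittance of a slab
#'
#' Photon exit rate at the far face of a homogeneous slab, per injected
#' photon, from the image-source (dipole-chain) series solution with
#' extrapolated boundaries. The series is truncated once an added image
#' pair's peak contribution falls below `tol` times the running sum's peak.
#'
#' @param t_ps Strictly increasing vector of times since the source pulse, ps.
#' @param props [optical_props()].
#' @param geom [geometry()] with `mode = "transmittance"` and a slab
#'   `thickness_mm`; `rho_mm` is the lateral offset of the detector from the
#'   source axis (0 for on-axis collection).
#' @param tol Relative truncation tolerance for the image series.
#'
#' @return Numeric vector in cm^-2 ps^-1 per injected photon; 0 for
#'   `t_ps <= 0`.
#' @export
td_transmittance <- function(t_ps, props, geom, tol = 1e-9) {
  stopifnot(inherits(props, "optical_props"), inherits(geom, "dtof_geometry"))
  if (geom$mode != "transmittance" || !is.finite(geom$thickness_mm))
    stop("'geom' must be a transmittance geometry with a slab thickness")
  .check_time_grid(t_ps)
  p <- .diffusion_pars(props, geom$n_external)
  s <- geom$thickness_mm / 10
  rho <- geom$rho_mm / 10
  out <- numeric(length(t_ps))
  ok <- t_ps > 0
  if (!any(ok)) return(out)
  t <- t_ps[ok]
  Dvt4 <- 4 * p$D * p$v * t
  # truncation is judged on the absorption-free weight so the retained
  # image order is independent of mua and the Beer-Lambert factorization
  # stays exact to machine precision
  pref0 <- exp(-rho^2 / Dvt4) / (2 * (4 * pi * p$D * p$v)^1.5 * t^2.5)
  acc <- numeric(length(t))
  for (m in 0:50) {
    term <- numeric(length(t))
    for (mm in unique(c(m, -m))) {
      z1 <- s * (1 - 2 * mm) - 4 * mm * p$zb - p$z0
      z2 <- s * (1 - 2 * mm) - (4 * mm - 2) * p$zb + p$z0
      term <- term + z1 * exp(-z1^2 / Dvt4) - z2 * exp(-z2^2 / Dvt4)
    }
    acc <- acc + term
    if (m >= 1 && max(abs(pref0 * term)) < tol * max(abs(pref0 * acc))) break
  }
  out[ok] <- pmax(pref0 * exp(-props$mua * p$v * t) * acc, 0)
  out
}

#' Time-resolved reflectance perturbed by a small absorbing inclusion
#'
#' First-order (Born) perturbation of [td_reflectance()] by a point-like
#' absorber of strength `delta_mua * volume_cm3` at the inclusion position.
#' The perturbation is the time convolution of the fluence Green's function
#' from the source to the inclusion with the escape (reflectance) Green's
#' function from the inclusion to the detector, evaluated by trapezoid
#' quadrature on a uniform intermediate-time grid.
#'
#' The source sits at the coordinate origin and the detector at
#' (`rho_mm`, 0); the inclusion centre is below the source--detector midpoint
#' at depth `incl$depth_mm`, offset laterally by `incl$lateral_mm`.
#'
#' If the (negative) Born term exceeds the unperturbed signal anywhere, the
#' first-order regime is violated: the result is clipped at 0 and flagged via
#' the `"born_clipped"` attribute, with a warning.
#'
#' @inheritParams td_reflectance
#' @param incl [inclusion_spec()].
#' @param dt_quad_ps Quadrature step for the intermediate-time convolution,
#'   ps. Default 25/4 ps.
#'
#' @return Numeric vector, same length as `t_ps`; attribute `"born_clipped"`
#'   is `TRUE` when clipping occurred.
#' @export
td_perturbed_reflectance <- function(rho_mm, t_ps, props, incl,
                                     geom = geometry(), dt_quad_ps = 25 / 4) {
  stopifnot(inherits(incl, "inclusion_spec"))
  R0 <- td_reflectance(rho_mm, t_ps, props, geom)
  if (incl$delta_mua == 0) {
    attr(R0, "born_clipped") <- FALSE
    return(R0)
  }
  p <- .diffusion_pars(props, geom$n_external)
  rho <- rho_mm / 10
  xi <- rho / 2
  yi <- incl$lateral_mm / 10
  zi <- incl$depth_mm / 10
  # source -> inclusion distances (true source and its boundary image)
  d1sq <- xi^2 + yi^2 + (zi - p$z0)^2
  d2sq <- xi^2 + yi^2 + (zi + p$z0 + 2 * p$zb)^2
  # inclusion -> detector lateral distance
  rid2 <- (rho - xi)^2 + yi^2

  mua_v <- props$mua * p$v
  n <- length(t_ps)
  dR <- numeric(n)
  pos <- which(t_ps > 0)
  if (length(pos)) {
    tmax <- max(t_ps[pos])
    tq <- seq(dt_quad_ps, tmax - dt_quad_ps / 2, by = dt_quad_ps)
    if (length(tq)) {
      Dv4 <- 4 * p$D * p$v
      # fluence Green's function at the inclusion, per injected photon
      phi <- p$v * (pi * Dv4 * tq)^(-1.5) * exp(-mua_v * tq) *
        (exp(-d1sq / (Dv4 * tq)) - exp(-d2sq / (Dv4 * tq)))
      # escape Green's function for a source at depth zi (dipole form),
      # evaluated on the tau = t - t' matrix
      tau <- outer(t_ps[pos], tq, "-")
      keep <- tau > 0
      tauv <- tau[keep]
      Dvt4 <- Dv4 * tauv
      esc <- exp(-mua_v * tauv - rid2 / Dvt4) /
        (2 * (pi * Dv4)^1.5 * tauv^2.5) *
        (zi * exp(-zi^2 / Dvt4) + (zi + 2 * p$zb) * exp(-(zi + 2 * p$zb)^2 / Dvt4))
      K <- matrix(0, nrow = length(pos), ncol = length(tq))
      K[keep] <- esc
      dR[pos] <- -(incl$delta_mua * incl$volume_cm3) *
        as.vector(K %*% phi) * dt_quad_ps
    }
  }
  out <- R0 + dR
  clipped <- any(out < 0)
  if (clipped) {
    warning("Born perturbation exceeds the unperturbed signal in ",
            sum(out < 0), " time point(s); result clipped at 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  attr(out, "born_clipped") <- clipped
  out
}
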