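#' Funnel restraint geometry
#'
#' Cone + cylinder wall confining the ligand near the binding axis: inside
#' the cavity region (z < `z_cc`) the allowed radius widens linearly with
#' slope `slope` towards the host, `R(z) = R_cyl + slope * (z_cc - z)`; for
#' z >= `z_cc` it is the cylinder radius `R_cyl`. Outside the allowed surface
#' the wall is one-sided harmonic with stiffness `k_wall`; an outer wall at
#' `z_max` closes the funnel on the solvent side. The restraint is zero
#' strictly inside and continuously differentiable at the boundary.
#'
#' @param origin,direction binding-axis definition (direction normalized
#'   internally).
#' @param z_cc cone-to-cylinder switch position along the axis (nm).
#' @param R_cyl cylinder radius (nm, > 0).
#' @param slope cone wall slope (dimensionless, >= 0).
#' @param k_wall wall stiffness (kcal mol^-1 nm^-2); default 1000.
#' @param z_max outer wall position along the axis (nm, > z_cc).
#' @return object of class `funnel_geometry`.
#' @export
funnel_geometry <- function(origin = c(0, 0, 0), direction = c(0, 0, 1),
                            z_cc = 0.4, R_cyl = 0.6, slope = 1.2,
                            k_wall = 1000, z_max = 2) {
  stopifnot(R_cyl > 0, z_cc < z_max, k_wall > 0, slope >= 0)
  structure(list(origin = origin,
                 direction = direction / sqrt(sum(direction^2)),
                 z_cc = z_cc, R_cyl = R_cyl, slope = slope,
                 k_wall = k_wall, z_max = z_max),
            class = "funnel_geometry")
}

funnel_radius <- function(z, geom) {
  ifelse(z < geom$z_cc, geom$R_cyl + geom$slope * (geom$z_cc - z), geom$R_cyl)
}

#' Funnel restraint energy
#'
#' @param position length-3 point or n x 3 matrix (nm).
#' @param geom a [funnel_geometry()].
#' @return energy (kcal mol^-1), vectorized over rows: zero inside the
#'   funnel, `k_wall/2 * overshoot^2` outside (radial wall plus the outer
#'   axial wall).
#' @export
funnel_energy <- function(position, geom) {
  stopifnot(inherits(geom, "funnel_geometry"))
  P <- matrix(position, ncol = 3)
  rel <- sweep(P, 2, geom$origin)
  z <- drop(rel %*% geom$direction)
  radial <- rel - tcrossprod(z, geom$direction)
  r <- sqrt(rowSums(radial^2))
  over_r <- pmax(r - funnel_radius(z, geom), 0)
  over_z <- pmax(z - geom$z_max, 0)
  geom$k_wall / 2 * (over_r^2 + over_z^2)
}

#' Analytic gradient of the funnel restraint
#'
#' @inheritParams funnel_energy
#' @return n x 3 matrix of forces' negatives (dU/dx, kcal mol^-1 nm^-1).
#' @export
funnel_gradient <- function(position, geom) {
  stopifnot(inherits(geom, "funnel_geometry"))
  P <- matrix(position, ncol = 3)
  rel <- sweep(P, 2, geom$origin)
  z <- drop(rel %*% geom$direction)
  radial <- rel - tcrossprod(z, geom$direction)
  r <- sqrt(rowSums(radial^2))
  Rz <- funnel_radius(z, geom)
  over_r <- pmax(r - Rz, 0)
  over_z <- pmax(z - geom$z_max, 0)
  rhat <- radial / ifelse(r > 1e-12, r, 1)
  dRdz <- ifelse(z < geom$z_cc, -geom$slope, 0)
  # d/dx [k/2 (r - R(z))_+^2] = k (r - R)_+ (rhat - R'(z) zhat)
  g <- geom$k_wall * over_r * (rhat - tcrossprod(dRdz, geom$direction)) +
    geom$k_wall * tcrossprod(over_z, geom$direction)
  g
}

#' Standard-state funnel correction
#'
#' When the unbound ligand is confined to a cylinder of radius `R_cyl`, the
#' free energy profile along the axis corresponds to a concentration of one
#' molecule per `pi R_cyl^2` per unit length. Converting to the standard
#' concentration `C0` contributes the analytic entropic term
#' `-kBT log(C0 pi R_cyl^2 * 1 nm)`; the axial reference length enters
#' explicitly through the binding integral in [delta_g_standard()], which is
#' why no separate length parameter is exposed.
#'
#' @param R_cyl funnel cylinder radius (nm, > 0).
#' @param thermo a [thermo_params()].
#' @param standard_conc standard concentration (molecules nm^-3); default
#'   1 mol L^-1 = 1/1.660 nm^-3.
#' @return correction energy (kcal mol^-1).
#' @export
funnel_correction <- function(R_cyl, thermo = thermo_params(),
                              standard_conc = 1 / 1.660) {
  thermo <- as_thermo(thermo)
  if (R_cyl <= 0) stop("`R_cyl` must be positive")
  -thermo$kBT * log(standard_conc * pi * R_cyl^2)
}
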