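#' Jeffreys fluid
#'
#' A single-mode Jeffreys fluid: a solvent dashpot of viscosity `eta1`
#' connected in parallel with a Maxwell element (spring of modulus `G` in
#' series with a dashpot of viscosity `eta2`). The Maxwell relaxation time is
#' `tau2 = eta2 / G`; the zero-shear viscosity is `eta1 + eta2`. Setting
#' `eta2 = 0` degenerates to a Newtonian fluid of viscosity `eta1`, and every
#' operation in the package honours that reduction.
#'
#' @param eta1 Solvent (background dashpot) viscosity, Pa s. Must be > 0.
#' @param eta2 Maxwell-branch viscosity, Pa s. Must be >= 0.
#' @param G Maxwell spring modulus, Pa. Required (> 0) when `eta2 > 0`.
#'
#' @return An object of class `jeffreys_fluid`: a list with fields `eta1`,
#'   `eta2`, `G`, the relaxation times `tau1 = eta1/G` and `tau2 = eta2/G`,
#'   and the zero-shear viscosity `eta0 = eta1 + eta2`.
#' @examples
#' actin_like <- jeffreys_fluid(eta1 = 1e-3, eta2 = 1, G = 1e-3)
#' actin_like$tau2 # 1000 s
#' water <- newtonian_fluid(1e-3)
#' @export
jeffreys_fluid <- function(eta1, eta2 = 0, G = NULL) {
  check_number(eta1, "eta1", lower = 0, allow_zero = FALSE)
  check_number(eta2, "eta2", lower = 0)
  if (eta2 > 0) {
    if (is.null(G)) abort("`G` is required when `eta2 > 0`.")
    check_number(G, "G", lower = 0, allow_zero = FALSE)
  } else if (!is.null(G)) {
    check_number(G, "G", lower = 0, allow_zero = FALSE)
  }
  tau2 <- if (eta2 > 0) eta2 / G else 0
  tau1 <- if (!is.null(G)) eta1 / G else NA_real_
  structure(
    list(eta1 = eta1, eta2 = eta2, G = if (is.null(G)) NA_real_ else G,
         tau1 = tau1, tau2 = tau2, eta0 = eta1 + eta2),
    class = "jeffreys_fluid"
  )
}

#' @rdname jeffreys_fluid
#' @param eta Viscosity of the Newtonian fluid, Pa s.
#' @export
newtonian_fluid <- function(eta) jeffreys_fluid(eta1 = eta, eta2 = 0)

#' @export
print.jeffreys_fluid <- function(x, ...) {
  if (x$eta2 == 0) {
    cat(sprintf("<Newtonian fluid> eta = %g Pa s\n", x$eta1))
  } else {
    cat(sprintf(
      "<Jeffreys fluid> eta1 = %g Pa s, eta2 = %g Pa s, G = %g Pa (tau = %g s)\n",
      x$eta1, x$eta2, x$G, x$tau2))
  }
  invisible(x)
}

is_newtonian <- function(fluid) fluid$eta2 == 0

#' Probe particle
#'
#' The spherical probe whose thermal motion reports on the fluid. The thermal
#' energy `kBT` is computed from the SI-exact Boltzmann constant
#' (1.380649e-23 J/K); room temperature (298 K) is the default.
#'
#' @param radius Bead radius, m. Must be > 0.
#' @param temperature Absolute temperature, K. Must be > 0.
#' @return An object of class `probe_particle` with fields `radius`,
#'   `temperature` and `kBT` (J).
#' @examples
#' probe_particle(1e-6)$kBT
#' @export
probe_particle <- function(radius, temperature = 298) {
  check_number(radius, "radius", lower = 0, allow_zero = FALSE)
  check_number(temperature, "temperature", lower = 0, allow_zero = FALSE)
  structure(
    list(radius = radius, temperature = temperature,
         kBT = .kB * temperature),
    class = "probe_particle"
  )
}

#' @export
print.probe_particle <- function(x, ...) {
  cat(sprintf("<probe particle> a = %g m, T = %g K, kBT = %.4g J\n",
              x$radius, x$temperature, x$kBT))
  invisible(x)
}

#' Toroidal (halo) trap geometry
#'
#' Geometry of the ring-shaped optical trap: the generator circle of major
#' radius `major_R` in the `z = 0` plane, with harmonic restoring stiffness
#' `kappa_r` towards the circle in the radial direction and `kappa_z` in the
#' axial direction. The azimuthal stiffness is identically zero (the defining
#' property of the halo trap), so it is not stored. The thermal minor radius
#' `b = sqrt(kBT / kappa_r)` is derived on demand by [minor_radius()].
#'
#' @param major_R Major (ring) radius, m. Must be > 0.
#' @param kappa_r Radial stiffness, N/m. Must be > 0.
#' @param kappa_z Axial stiffness, N/m. Must be > 0.
#' @return An object of class `trap_geometry`.
#' @examples
#' geom <- trap_geometry(major_R = 1e-5, kappa_r = 1e-6, kappa_z = 1e-6 / 3)
#' minor_radius(geom, probe_particle(1e-6))
#' @export
trap_geometry <- function(major_R, kappa_r, kappa_z) {
  check_number(major_R, "major_R", lower = 0, allow_zero = FALSE)
  check_number(kappa_r, "kappa_r", lower = 0, allow_zero = FALSE)
  check_number(kappa_z, "kappa_z", lower = 0, allow_zero = FALSE)
  structure(list(major_R = major_R, kappa_r = kappa_r, kappa_z = kappa_z),
            class = "trap_geometry")
}

#' @rdname trap_geometry
#' @param geometry A [trap_geometry()].
#' @param particle A [probe_particle()].
#' @export
minor_radius <- function(geometry, particle) {
  sqrt(particle$kBT / geometry$kappa_r)
}

#' @export
print.trap_geometry <- function(x, ...) {
  cat(sprintf(
    "<toroidal trap> R = %g m, kappa_r = %g N/m, kappa_z = %g N/m (kappa_theta = 0)\n",
    x$major_R, x$kappa_r, x$kappa_z))
  invisible(x)
}
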