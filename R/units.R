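#' Effective stiffness of the Maxwell element
#'
#' The elastic branch of the Jeffreys fluid acts on the probe like a spring
#' of stiffness `kappa_star = 6 pi a G`, where `G` is the modulus of the
#' elastic element and `a` the bead radius.
#'
#' @param G Elastic modulus, Pa (>= 0).
#' @param a Bead radius, m (> 0).
#' @return Stiffness in N/m.
#' @examples
#' effective_stiffness(G = 1e-3, a = 1e-6) # ~1.88e-8 N/m
#' @export
effective_stiffness <- function(G, a) {
  check_number(G, "G", lower = 0)
  check_number(a, "a", lower = 0, allow_zero = FALSE)
  6 * pi * a * G
}

#' Natural (dimensionless) unit system of the trapped probe
#'
#' The package integrates the dynamics in natural units: the unit of length
#' is the thermal width of the radial confinement, `sqrt(kBT / kappa_r)`,
#' and the unit of time is the inverse corner frequency `zeta0 / kappa_r`,
#' where `zeta0 = 6 pi a eta1` is the Stokes friction in the solvent. SI
#' conversion happens only at the I/O boundary, through the converters
#' returned here.
#'
#' @param kappa_r Radial trap stiffness, N/m.
#' @param fluid A [jeffreys_fluid()]; only the solvent viscosity `eta1`
#'   enters the time unit.
#' @param particle A [probe_particle()].
#' @return An object of class `unit_system` with fields `length_unit` (m),
#'   `time_unit` (s), `zeta0` (N s/m), `kappa_r`, and the dimensionless
#'   probe radius `a_hat`.
#' @examples
#' us <- unit_system(1e-6, newtonian_fluid(1e-3), probe_particle(1e-6))
#' us$length_unit # ~6.41e-8 m
#' to_dimensionless(us, length = 1e-5) # R_hat ~ 155.9
#' @export
unit_system <- function(kappa_r, fluid, particle) {
  check_number(kappa_r, "kappa_r", lower = 0, allow_zero = FALSE)
  zeta0 <- 6 * pi * particle$radius * fluid$eta1
  length_unit <- sqrt(particle$kBT / kappa_r)
  structure(
    list(length_unit = length_unit,
         time_unit = zeta0 / kappa_r,
         zeta0 = zeta0,
         kappa_r = kappa_r,
         a_hat = particle$radius / length_unit),
    class = "unit_system"
  )
}

#' @rdname unit_system
#' @param us A `unit_system`.
#' @param length,time SI quantities (m, s) to convert; give one or both.
#' @return For the converters, a named list with the converted entries.
#' @export
to_dimensionless <- function(us, length = NULL, time = NULL) {
  out <- list()
  if (!is.null(length)) out$length <- length / us$length_unit
  if (!is.null(time)) out$time <- time / us$time_unit
  if (length(out) == 1L) out[[1L]] else out
}

#' @rdname unit_system
#' @export
to_si <- function(us, length = NULL, time = NULL) {
  out <- list()
  if (!is.null(length)) out$length <- length * us$length_unit
  if (!is.null(time)) out$time <- time * us$time_unit
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.unit_system <- function(x, ...) {
  cat(sprintf(
    "<unit system> length %.4g m, time %.4g s, zeta0 %.4g N s/m, a_hat %.4g\n",
    x$length_unit, x$time_unit, x$zeta0, x$a_hat))
  invisible(x)
}

#' Dimensionless groups of the trapped-probe/Jeffreys system
#'
#' The fluid-side Deborah number `De = tau * kappa_star / zeta0` compares the
#' fluid relaxation time `tau = eta2 / G` with the corner time of a particle
#' held by a (virtual) trap of stiffness `kappa_star = 6 pi a G` in the pure
#' solvent. Algebraically `De = eta2 / eta1`. The companion number
#' `De2 = De * kappa_r / kappa_star = tau * kappa_r / zeta0` refers the same
#' relaxation time to the actual radial trap. This `De` is distinct from the
#' observation-based ratio returned by [feasibility_diagnostics()].
#'
#' @param fluid A [jeffreys_fluid()]. Newtonian input yields `De = 0`.
#' @param particle A [probe_particle()].
#' @param geometry A [trap_geometry()].
#' @return A one-row tibble with `De`, `De2`, `kappa_star` (N/m),
#'   `ratio_kstar_kr`, `ratio_kz_kr` and `zeta0`.
#' @examples
#' fl <- jeffreys_fluid(1e-3, eta2 = 1, G = 1e-3) # tau = 1000 s
#' pp <- probe_particle(1e-6)
#' geo <- trap_geometry(1e-5, 1e-6, 1e-6 / 3)
#' dimensionless_groups(fl, pp, geo)$De # 1000
#' @export
dimensionless_groups <- function(fluid, particle, geometry) {
  zeta0 <- 6 * pi * particle$radius * fluid$eta1
  if (zeta0 <= 0) abort("zero solvent friction: eta1 and radius must be > 0.")
  kstar <- if (is_newtonian(fluid)) 0 else effective_stiffness(fluid$G, particle$radius)
  De <- if (is_newtonian(fluid)) 0 else fluid$tau2 * kstar / zeta0
  tibble(
    De = De,
    De2 = fluid$tau2 * geometry$kappa_r / zeta0,
    kappa_star = kstar,
    ratio_kstar_kr = kstar / geometry$kappa_r,
    ratio_kz_kr = geometry$kappa_z / geometry$kappa_r,
    zeta0 = zeta0
  )
}

#' Feasibility diagnostics for particle-tracking microrheology
#'
#' Compares the characteristic diffusion time `tau_D = 6 pi eta a d^2 / kBT`
#' (time for the probe to diffuse a distance `d`) with the observation lag
#' `tau_ob` between frames. When `tau_D / tau_ob > 1` the particle appears
#' stationary at the detector's resolution and apparent moduli are inflated;
#' for water, a micron bead and a spatial resolution of `d^2 = 1e-17 m^2`
#' this happens at acquisition rates of the order of 20 kHz and above. The
#' numerical coincidence `tau_D ~ eta/20` (seconds, with eta in Pa s) for
#' those figures is reported as `threshold_lag`.
#'
#' @param eta Fluid viscosity, Pa s.
#' @param particle A [probe_particle()].
#' @param d2 Squared displacement scale (spatial resolution squared), m^2.
#' @param tau_ob Observation lag between frames, s (optional).
#' @param L Technique length scale for the traversal time `tau_tr = L^2/D`,
#'   m (optional).
#' @return A one-row tibble: `tau_D` (s), `De_obs` (= tau_D / tau_ob, NA if
#'   `tau_ob` missing), `threshold_lag` (= eta/20, s), `threshold_rate`
#'   (= 1/tau_D, Hz), `tau_tr` (s, NA if `L` missing).
#' @examples
#' feasibility_diagnostics(1e-3, probe_particle(1e-6))$threshold_rate # ~2e4 Hz
#' @export
feasibility_diagnostics <- function(eta, particle, d2 = 1e-17,
                                    tau_ob = NULL, L = NULL) {
  check_number(eta, "eta", lower = 0, allow_zero = FALSE)
  check_number(d2, "d2", lower = 0, allow_zero = FALSE)
  zeta <- 6 * pi * eta * particle$radius
  tau_D <- zeta * d2 / particle$kBT
  D <- particle$kBT / zeta
  tibble(
    tau_D = tau_D,
    De_obs = if (is.null(tau_ob)) NA_real_ else {
      check_number(tau_ob, "tau_ob", lower = 0, allow_zero = FALSE)
      tau_D / tau_ob
    },
    threshold_lag = eta / 20,
    threshold_rate = 1 / tau_D,
    tau_tr = if (is.null(L)) NA_real_ else {
      check_number(L, "L", lower = 0, allow_zero = FALSE)
      L^2 / D
    }
  )
}
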