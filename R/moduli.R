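#' Modulus curve container
#'
#' A tibble of class `modulus_curve` holding a complex shear modulus sampled
#' on a frequency grid: columns `omega` (rad/s), `g_prime` (storage modulus,
#' Pa), `g_loss` (loss modulus, Pa) and `g_star` (complex). Optional logical
#' columns `in_band` and `trap_dominated` flag frequencies outside the
#' data-supported band or where the recovered modulus is too soft relative
#' to the trap to be trusted.
#'
#' @param omega Strictly increasing positive frequency grid, rad/s.
#' @param g_star Complex modulus values, Pa.
#' @param ... Additional per-frequency columns (e.g. flags).
#' @return A `modulus_curve` tibble.
#' @export
modulus_curve <- function(omega, g_star, ...) {
  out <- tibble(omega = omega,
                g_prime = Re(g_star),
                g_loss = Im(g_star),
                g_star = g_star, ...)
  class(out) <- c("modulus_curve", class(out))
  out
}

#' Complex modulus of a Jeffreys fluid
#'
#' Evaluates the analytic complex shear modulus of the single-mode Jeffreys
#' fluid,
#' \deqn{G'(\omega) = G \frac{\omega^2 \tau_2^2}{1 + \omega^2 \tau_2^2},
#'   \qquad
#'   G''(\omega) = G \omega \left[\tau_1 +
#'     \frac{\tau_2}{1 + \omega^2 \tau_2^2}\right],}
#' with \eqn{\tau_1 = \eta_1/G}, \eqn{\tau_2 = \eta_2/G}; equivalently
#' \eqn{G^*(\omega) = i\omega\eta_1 + i\omega G\tau_2/(1 + i\omega\tau_2)}.
#' Limits: \eqn{G^*/(i\omega) \to \eta_1 + \eta_2} as \eqn{\omega \to 0}
#' (zero-shear viscosity) and \eqn{G' \to G}, \eqn{G'' \to \omega\eta_1} as
#' \eqn{\omega \to \infty}.
#'
#' @param fluid A [jeffreys_fluid()].
#' @param omega Strictly positive, sorted frequency grid, rad/s.
#' @return A [modulus_curve()].
#' @examples
#' fl <- jeffreys_fluid(1e-3, eta2 = 1, G = 1e-3)
#' complex_modulus_jeffreys(fl, 10^seq(-4, 2, 0.5))
#' @export
complex_modulus_jeffreys <- function(fluid, omega) {
  check_omega(omega)
  if (is_newtonian(fluid)) {
    return(complex_modulus_newtonian(fluid$eta1, omega))
  }
  tau2 <- fluid$tau2
  den <- 1 + omega^2 * tau2^2
  gp <- fluid$G * omega^2 * tau2^2 / den
  gl <- fluid$G * omega * (fluid$tau1 + tau2 / den)
  modulus_curve(omega, complex(real = gp, imaginary = gl))
}

#' Complex modulus of a Newtonian fluid
#'
#' Degenerate limit of the Jeffreys model: `G' = 0`, `G'' = omega * eta0`
#' exactly.
#'
#' @param eta0 Viscosity, Pa s (> 0).
#' @param omega Non-negative sorted frequency grid, rad/s.
#' @return A [modulus_curve()].
#' @export
complex_modulus_newtonian <- function(eta0, omega) {
  check_number(eta0, "eta0", lower = 0, allow_zero = FALSE)
  check_omega(omega, positive = FALSE)
  if (any(omega < 0)) abort("`omega` must be non-negative.")
  modulus_curve(omega, complex(real = 0, imaginary = omega * eta0))
}

#' Exponential memory kernel of the Jeffreys fluid
#'
#' The Maxwell branch contributes a temporally non-local drag with kernel
#' `zeta_p(t) = 6 pi a (eta2 / tau) exp(-t / tau)` for `t >= 0` (zero for
#' `t < 0`), whose unilateral Fourier transform is
#' `zeta_p_hat(omega) = 6 pi a eta2 / (1 + i omega tau)`. The kernel
#' integrates to `6 pi a eta2`, the Maxwell-branch friction.
#'
#' @param fluid A [jeffreys_fluid()] with `eta2 > 0` (a Newtonian fluid has
#'   a zero kernel).
#' @param particle A [probe_particle()].
#' @param t Times, s; must be >= 0.
#' @return `memory_kernel()`: kernel values, N s/m per s (same length as
#'   `t`). `memory_kernel_ft()`: complex friction, N s/m.
#' @export
memory_kernel <- function(fluid, particle, t) {
  check_number(t, "t", lower = 0, len = NULL)
  if (is_newtonian(fluid)) return(rep(0, length(t)))
  tau <- fluid$tau2
  6 * pi * particle$radius * (fluid$eta2 / tau) * exp(-t / tau)
}

#' @rdname memory_kernel
#' @param omega Frequency grid, rad/s.
#' @export
memory_kernel_ft <- function(fluid, particle, omega) {
  check_omega(omega, positive = FALSE)
  if (is_newtonian(fluid)) return(rep(0 + 0i, length(omega)))
  if (fluid$tau2 <= 0) abort("memory kernel transform needs tau = eta2/G > 0.")
  6 * pi * particle$radius * fluid$eta2 / (1 + 1i * omega * fluid$tau2)
}
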