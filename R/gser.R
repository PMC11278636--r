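#' Creep compliance from a probe MSD
#'
#' Thermal probe motion and macroscopic creep are linearly related:
#' for the full 3D MSD, `J(t) = (pi a / kBT) MSD(t)`; per tracked dimension
#' the factor scales as `J(t) = (3 pi a / (ndim kBT)) MSD_ndim(t)`. The
#' compliance of a viscoelastic fluid satisfies `J(0) = 0`, which the MSD
#' guarantees (`MSD(0) = 0`).
#'
#' @param lag Lag times, s.
#' @param msd Mean squared displacement at those lags, m^2, over `ndim`
#'   dimensions.
#' @param particle A [probe_particle()].
#' @param ndim Number of spatial dimensions the MSD sums over (1 for the
#'   azimuthal arc-length channel, 3 for a full 3D MSD).
#' @return A tibble: `lag`, `compliance` (1/Pa).
#' @export
compliance_from_msd <- function(lag, msd, particle, ndim = 1) {
  check_number(ndim, "ndim", lower = 1)
  if (length(lag) != length(msd)) abort("`lag` and `msd` lengths differ.")
  if (any(msd < 0)) abort("`msd` must be non-negative.")
  tibble(lag = lag,
         compliance = 3 * pi * particle$radius * msd / (ndim * particle$kBT))
}

## terminal and initial gradients of an MSD record (least squares)
msd_gradients <- function(lag, msd, terminal_frac = 0.1, initial_points = 4L) {
  term <- lag >= max(lag) * terminal_frac
  gi <- coef(lm(msd ~ lag, subset = seq_len(min(initial_points, length(lag)))))[2L]
  gt <- coef(lm(msd ~ lag, subset = which(term)))[2L]
  list(initial = unname(gi), terminal = unname(gt))
}

#' Free-particle GSER: modulus from the MSD of an untrapped component
#'
#' The generalized Stokes-Einstein inversion for a force-free channel (the
#' azimuthal arc length of the halo trap):
#' \deqn{G^*(\omega) = \frac{n_{dim}\, k_B T}
#'   {3\pi a\; i\omega\, \widehat{\Delta x^2}(\omega)},}
#' with the inertial term dropped (negligible below MHz for micron beads).
#' The transform of the MSD uses [ft_piecewise_linear()] with
#' `value_at_zero = 0`, the terminal gradient fitted on the last decade of
#' lags, and the initial gradient fitted on the first `initial_points`
#' points. For an exactly diffusive input `MSD = 2 D t` with
#' `D = kBT / (6 pi a eta)` the closed form returns `G' = 0`,
#' `G'' = omega eta` to machine precision, which pins the one-dimensional
#' prefactor.
#'
#' @param lag Lag times, s (strictly increasing; a leading 0 is dropped).
#' @param msd_values MSD over `ndim` dimensions, m^2.
#' @param particle A [probe_particle()].
#' @param omega Frequency grid, rad/s; `NULL` for 10 points/decade across
#'   the data-supported band.
#' @param ndim Dimensions summed in the MSD (default 1: azimuthal channel).
#' @param terminal_frac Fraction of the lag span (from the top) used to fit
#'   the terminal gradient.
#' @param initial_points Points used to fit the initial gradient.
#' @param terminal_gradient,initial_gradient Optional overrides for the
#'   fitted gradients. For a confined (plateauing) channel the true
#'   terminal gradient is 0, and fitting it from a still-relaxing tail
#'   biases the low-frequency moduli; pass `terminal_gradient = 0` there.
#' @return A [modulus_curve()] with an `in_band` flag column.
#' @export
gser_free <- function(lag, msd_values, particle, omega = NULL, ndim = 1,
                      terminal_frac = 0.1, initial_points = 4L,
                      terminal_gradient = NULL, initial_gradient = NULL) {
  keep <- lag > 0
  lag <- lag[keep]; msd_values <- msd_values[keep]
  grads <- msd_gradients(lag, msd_values, terminal_frac, initial_points)
  omega <- omega %||% default_omega_grid(lag)
  spec <- ft_spec(value_at_zero = 0,
                  terminal_gradient = terminal_gradient %||% grads$terminal,
                  initial_gradient = initial_gradient %||% grads$initial)
  ft <- ft_piecewise_linear(lag, msd_values, omega, spec)
  g_star <- ndim * particle$kBT /
    (3 * pi * particle$radius * 1i * omega * ft$ft)
  modulus_curve(omega, g_star, in_band = ft$in_band)
}

#' Trapped-particle GSER: modulus from NPAF or NMSD
#'
#' For a harmonically confined channel of known stiffness `kappa`, the
#' inversion uses the normalised position autocorrelation `A(tau)` or the
#' normalised MSD `Pi(tau) = 1 - A(tau)`:
#' \deqn{G^*(\omega)\frac{6\pi a}{\kappa}
#'   = \frac{1}{i\omega\hat\Pi(\omega)} - 1
#'   \equiv \left(\frac{1}{i\omega\hat A(\omega)} - 1\right)^{-1}
#'   \equiv \frac{\hat A(\omega)}{\hat\Pi(\omega)},}
#' the three forms being algebraically identical through
#' \eqn{i\omega\hat\Pi = 1 - i\omega\hat A}. Below the trap's corner
#' frequency the trap compliance overshadows the fluid's; frequencies where
#' the recovered `|G*| 6 pi a / kappa` falls under `trap_floor` are flagged
#' `trap_dominated` rather than silently returned.
#'
#' @param lag Lag times, s.
#' @param value `A(tau)` (`kind = "npaf"`) or `Pi(tau)` (`kind = "nmsd"`).
#' @param kappa Trap stiffness of the analysed channel, N/m.
#' @param particle A [probe_particle()].
#' @param kind Which normalised statistic `value` holds.
#' @param omega Frequency grid, rad/s; `NULL` for the data-supported band.
#' @param trap_floor Threshold on `|G*| 6 pi a / kappa` below which the
#'   frequency is flagged trap-dominated.
#' @return A [modulus_curve()] with `in_band` and `trap_dominated` flags.
#' @export
gser_trapped <- function(lag, value, kappa, particle,
                         kind = c("npaf", "nmsd"), omega = NULL,
                         trap_floor = 0.05) {
  kind <- match.arg(kind)
  check_number(kappa, "kappa", lower = 0, allow_zero = FALSE)
  keep <- lag > 0
  lag_p <- lag[keep]; val_p <- value[keep]
  omega <- omega %||% default_omega_grid(lag_p)
  v0 <- if (kind == "npaf") 1 else 0
  spec <- ft_spec(value_at_zero = v0, terminal_gradient = 0)
  ft <- ft_piecewise_linear(lag_p, val_p, omega, spec)
  pref <- kappa / (6 * pi * particle$radius)
  if (kind == "npaf") {
    x <- 1i * omega * ft$ft
    g_star <- pref * x / (1 - x)
    denom_floor <- abs(1 - x) < 1e-12
  } else {
    ip <- 1i * omega * ft$ft
    g_star <- pref * (1 / ip - 1)
    denom_floor <- abs(ip) < 1e-12
  }
  g_star[denom_floor] <- NA_complex_
  modulus_curve(omega, g_star,
                in_band = ft$in_band,
                trap_dominated = !is.na(g_star) &
                  abs(g_star) * 6 * pi * particle$radius / kappa < trap_floor)
}

#' The three equivalent trapped-GSER forms
#'
#' Given a transform `A_hat` of the normalised position autocorrelation,
#' evaluates the three printed forms of the trapped inversion (via
#' `i omega Pi_hat = 1 - i omega A_hat`). They agree to machine precision;
#' exposed for verification.
#'
#' @param omega Frequency grid.
#' @param A_hat Complex transform of `A(tau)` at `omega`.
#' @param kappa Channel stiffness, N/m.
#' @param particle A [probe_particle()].
#' @return Tibble with complex columns `from_nmsd`, `from_npaf_inverse`,
#'   `from_ratio`.
#' @export
gser_trapped_forms <- function(omega, A_hat, kappa, particle) {
  pref <- kappa / (6 * pi * particle$radius)
  iwA <- 1i * omega * A_hat
  Pi_hat <- (1 - iwA) / (1i * omega)
  tibble(
    omega = omega,
    from_nmsd = pref * (1 / (1i * omega * Pi_hat) - 1),
    from_npaf_inverse = pref / (1 / iwA - 1),
    from_ratio = pref * A_hat / Pi_hat
  )
}

#' Closed-form NPAF transform of a trapped probe in a Jeffreys fluid
#'
#' For the linear (harmonic) channel of stiffness `kappa`, the generalized
#' Langevin equation with the exponential memory kernel can be solved in
#' the frequency domain; inverting the trapped GSER at the analytic
#' Jeffreys modulus gives
#' \deqn{\hat A(\omega) = \frac{g(\omega)}{i\omega\,(1 + g(\omega))},
#'   \qquad g(\omega) = \frac{6\pi a\, G^*(\omega)}{\kappa}.}
#'
#' @param fluid A [jeffreys_fluid()].
#' @param particle A [probe_particle()].
#' @param kappa Channel stiffness, N/m.
#' @param omega Frequency grid, rad/s.
#' @return Complex vector `A_hat(omega)`.
#' @export
npaf_trapped_jeffreys_ft <- function(fluid, particle, kappa, omega) {
  check_omega(omega)
  gstar <- complex_modulus_jeffreys(fluid, omega)$g_star
  g <- 6 * pi * particle$radius * gstar / kappa
  g / (1i * omega * (1 + g))
}

#' Consistency of the Jeffreys GLE identity
#'
#' The frequency-domain solution of the generalized Langevin equation for a
#' trapped probe in a Jeffreys fluid equates
#' \deqn{\frac{\omega^2\tau\eta_2}{1+\omega^2\tau^2}
#'   + i\omega\left[\eta_1 + \frac{\eta_2}{1+\omega^2\tau^2}\right]
#'   = \frac{\kappa}{6\pi a}\,
#'     \frac{i\omega\hat A(\omega)}{1 - i\omega\hat A(\omega)}.}
#' The left side is identical to the analytic Jeffreys modulus; the right
#' side can be fed either the closed-form transform (default; residual at
#' machine precision) or a measured/estimated `A_hat`, in which case the
#' residual quantifies how well the data reproduce the model.
#'
#' @inheritParams npaf_trapped_jeffreys_ft
#' @param A_hat Optional complex transform of `A(tau)` at `omega`; `NULL`
#'   uses [npaf_trapped_jeffreys_ft()].
#' @return A tibble: `omega`, `lhs`, `rhs` (complex), `rel_residual`.
#' @export
jeffreys_gser_identity <- function(fluid, particle, kappa, omega,
                                   A_hat = NULL) {
  check_omega(omega)
  tau <- fluid$tau2
  den <- 1 + omega^2 * tau^2
  lhs <- complex(
    real = omega^2 * tau * fluid$eta2 / den,
    imaginary = omega * (fluid$eta1 + fluid$eta2 / den)
  )
  A_hat <- A_hat %||% npaf_trapped_jeffreys_ft(fluid, particle, kappa, omega)
  iwA <- 1i * omega * A_hat
  rhs <- kappa / (6 * pi * particle$radius) * iwA / (1 - iwA)
  tibble(omega = omega, lhs = lhs, rhs = rhs,
         rel_residual = Mod(lhs - rhs) / Mod(lhs))
}
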