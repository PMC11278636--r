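#' Simulation configuration
#'
#' Run-length, resolution and reproducibility settings shared by the
#' integrators. All quantities are dimensionless (see [unit_system()]).
#'
#' `dt_hat = NULL` (the default) selects `min(0.01, stability guard)`, where
#' the guard requires at least ~20 steps per fastest relaxation time of the
#' system being integrated (radial, axial, and for the Jeffreys embedding
#' the auxiliary-variable time `De / ((De + 1) kappa*/kappa_r)`). An
#' explicitly supplied `dt_hat` that violates the guard is an error, not a
#' silent adjustment.
#'
#' @param n_particles Ensemble size (>= 1).
#' @param t_max_hat Recorded (post burn-in) time span, dimensionless.
#' @param dt_hat Time step; `NULL` for the stability-guarded default 0.01.
#' @param seed Integer master seed. Per-particle streams are derived from it
#'   deterministically, so results are reproducible bit-for-bit.
#' @param burn_in_hat Equilibration span discarded before recording; `NULL`
#'   for the model-dependent default (10 for Newtonian runs,
#'   `max(10, 10 De kappa_r / kappa*)` for Jeffreys runs, i.e. ten fluid
#'   relaxation times).
#' @param save_stride Output decimation: record every `save_stride`-th step.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_particles = 50, t_max_hat = 50, seed = 7)
#' @export
sim_config <- function(n_particles, t_max_hat, dt_hat = NULL, seed = 1L,
                       burn_in_hat = NULL, save_stride = 1L) {
  check_number(n_particles, "n_particles", lower = 1)
  check_number(t_max_hat, "t_max_hat", lower = 0, allow_zero = FALSE)
  if (!is.null(dt_hat)) check_number(dt_hat, "dt_hat", lower = 0, allow_zero = FALSE)
  check_number(seed, "seed", lower = 0)
  if (!is.null(burn_in_hat)) check_number(burn_in_hat, "burn_in_hat", lower = 0)
  check_number(save_stride, "save_stride", lower = 1)
  structure(
    list(n_particles = as.integer(n_particles), t_max_hat = t_max_hat,
         dt_hat = dt_hat, seed = seed, burn_in_hat = burn_in_hat,
         save_stride = as.integer(save_stride)),
    class = "sim_config"
  )
}

## stability guard: >= 20 steps per fastest relaxation time, dt <= 0.05 * min(...)
stability_limit <- function(kz_over_kr, kstar_over_kr = 0, De = 0) {
  lims <- c(1, 1 / kz_over_kr)
  if (De > 0) lims <- c(lims, De / ((De + 1) * kstar_over_kr))
  0.05 * min(lims)
}

resolve_dt <- function(config, kz_over_kr, kstar_over_kr = 0, De = 0) {
  lim <- stability_limit(kz_over_kr, kstar_over_kr, De)
  if (is.null(config$dt_hat)) return(min(0.01, lim))
  if (config$dt_hat > lim) {
    abort(sprintf(
      "dt_hat = %g violates the stability guard (must be <= %.3g for these parameters).",
      config$dt_hat, lim))
  }
  config$dt_hat
}

#' Initial ensemble state on the ring
#'
#' Draws starting positions on the generator circle at uniformly random
#' azimuth, with Gaussian radial and axial offsets at their stationary
#' dimensionless variances (1 and `kappa_r / kappa_z`). For Jeffreys runs
#' the auxiliary variables start at the deterministic fixed point of their
#' own equation given the initial position (zero Maxwell-branch force);
#' burn-in completes equilibration.
#'
#' @param R_hat Dimensionless major radius.
#' @param kz_over_kr Axial-to-radial stiffness ratio.
#' @param n_particles Ensemble size.
#' @param seed Integer seed (drawing is done in a local RNG scope).
#' @param kstar_over_kr,De Jeffreys groups; both 0 for Newtonian runs.
#' @return List with `pos` (n x 3 matrix) and `Q` (n x 3 matrix, zeros for
#'   Newtonian input).
#' @export
initial_state <- function(R_hat, kz_over_kr, n_particles, seed,
                          kstar_over_kr = 0, De = 0) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    theta <- stats::runif(n_particles, 0, 2 * pi)
    u <- stats::rnorm(n_particles)
    z <- stats::rnorm(n_particles, sd = sqrt(1 / kz_over_kr))
    r <- R_hat + u
    if (any(r <= 0)) abort("initial radius <= 0: increase R_hat.")
    pos <- cbind(r * cos(theta), r * sin(theta), z)
    Q <- matrix(0, n_particles, 3)
    if (De > 0) {
      f <- trap_force(pos, trap_geometry(R_hat, 1, kz_over_kr)) # = -drift
      # fixed point of dQ: Q* = f * De / (kstar_over_kr * (De + 1))
      Q <- f * De / (kstar_over_kr * (De + 1))
    }
    list(pos = pos, Q = Q)
  })
}

new_halo_trajectory <- function(res, times, params, has_Q = FALSE) {
  P <- ncol(res$x)
  n_save <- nrow(res$x)
  out <- tibble(
    particle = rep(seq_len(P), each = n_save),
    t_hat = rep(times, P),
    x = as.vector(res$x), y = as.vector(res$y), z = as.vector(res$z)
  )
  if (has_Q) {
    out$qx <- as.vector(res$qx)
    out$qy <- as.vector(res$qy)
    out$qz <- as.vector(res$qz)
  }
  attr(out, "n_save") <- n_save
  attr(out, "n_particles") <- P
  attr(out, "params") <- params
  class(out) <- c("halo_trajectory", class(out))
  out
}

#' Trajectory accessors
#'
#' `traj_params()` returns the full provenance block of a simulated
#' ensemble; `traj_matrix()` reshapes one recorded variable into a
#' (time x particle) matrix for estimator code.
#'
#' @param traj A `halo_trajectory` (or `halo_components`) tibble.
#' @param var Column name, e.g. `"x"`, `"z"`, `"s"`.
#' @export
traj_matrix <- function(traj, var) {
  matrix(traj[[var]], nrow = attr(traj, "n_save"))
}

#' @rdname traj_matrix
#' @export
traj_params <- function(traj) attr(traj, "params")

#' Simulate a particle in a Newtonian fluid in the halo trap
#'
#' Euler-Maruyama integration of the dimensionless overdamped Brownian
#' dynamics
#' \deqn{d\hat x = -(1 - \hat R/\hat\rho)\,\hat x\, d\hat t + \sqrt2\, dW_x}
#' (and likewise for y; \eqn{d\hat z = -(\kappa_z/\kappa_r)\hat z\,d\hat t +
#' \sqrt2\, dW_z}), with \eqn{\hat\rho = \sqrt{\hat x^2 + \hat y^2}}. The
#' three Wiener increments are independent. Burn-in is integrated and
#' discarded. A compiled core with one deterministic RNG stream per particle
#' makes runs bit-reproducible for a given seed.
#'
#' @param R_hat Dimensionless major radius; must exceed 3 so the torus is
#'   wide compared with the thermal width.
#' @param kz_over_kr Axial-to-radial stiffness ratio (> 0).
#' @param config A [sim_config()].
#' @return A `halo_trajectory` tibble: columns `particle`, `t_hat`, `x`,
#'   `y`, `z`; provenance in `traj_params()`.
#' @examples
#' traj <- simulate_newtonian(150, 1 / 3, sim_config(8, 20, seed = 1))
#' @export
simulate_newtonian <- function(R_hat, kz_over_kr, config) {
  check_number(R_hat, "R_hat", lower = 3, allow_zero = FALSE)
  check_number(kz_over_kr, "kz_over_kr", lower = 0, allow_zero = FALSE)
  dt <- resolve_dt(config, kz_over_kr)
  burn <- config$burn_in_hat %||% 10
  stride <- config$save_stride
  n_steps <- as.integer(ceiling(config$t_max_hat / dt / stride)) * stride
  n_burn <- as.integer(ceiling(burn / dt))
  st <- initial_state(R_hat, kz_over_kr, config$n_particles, config$seed)
  res <- sim_halo_newtonian_cpp(R_hat, kz_over_kr, st$pos, dt,
                                n_burn, n_steps, stride, config$seed)
  times <- dt * stride * (0:(n_steps / stride))
  params <- list(model = "newtonian", R_hat = R_hat, kz_over_kr = kz_over_kr,
                 dt_hat = dt, burn_in_hat = burn, n_steps = n_steps,
                 save_stride = stride, n_particles = config$n_particles,
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("halorheo")))
  new_halo_trajectory(res, times, params)
}

#' Simulate a particle in a Jeffreys fluid in the halo trap
#'
#' Euler-Maruyama integration of the six coupled dimensionless equations of
#' the Markovian embedding of the generalized Langevin equation with
#' exponential memory. Each axis carries a position equation and a paired
#' auxiliary equation for \eqn{\hat Q}; the increment \eqn{dW^1} is shared
#' within a pair (correlated noise), \eqn{dW^0} acts on the position only.
#' Noise amplitudes are \eqn{\sqrt{2/(De+1)}}, \eqn{\sqrt{2 De/(De+1)}} and
#' \eqn{\sqrt{2(De+1)/De}}. These prefactors guarantee equipartition of the
#' confined coordinates independently of `De` and `kappa_star/kappa_r`, and
#' a terminal azimuthal diffusivity reduced by the factor `1/(1 + De)`
#' (total viscosity `eta1 (1 + De)`).
#'
#' @inheritParams simulate_newtonian
#' @param kstar_over_kr Maxwell stiffness over radial trap stiffness (> 0).
#' @param De Fluid Deborah number `tau kappa* / zeta0 = eta2/eta1`. `De = 0`
#'   is routed to [simulate_newtonian()] (the embedding divides by `De`).
#' @param save_Q Record the auxiliary variables as columns `qx`, `qy`, `qz`?
#' @return A `halo_trajectory` tibble.
#' @examples
#' traj <- simulate_jeffreys(150, 1 / 3, kstar_over_kr = 16, De = 1,
#'                           sim_config(8, 10, seed = 1))
#' @export
simulate_jeffreys <- function(R_hat, kz_over_kr, kstar_over_kr, De, config,
                              save_Q = FALSE) {
  check_number(R_hat, "R_hat", lower = 3, allow_zero = FALSE)
  check_number(kz_over_kr, "kz_over_kr", lower = 0, allow_zero = FALSE)
  check_number(De, "De", lower = 0)
  if (De == 0) return(simulate_newtonian(R_hat, kz_over_kr, config))
  check_number(kstar_over_kr, "kstar_over_kr", lower = 0, allow_zero = FALSE)
  dt <- resolve_dt(config, kz_over_kr, kstar_over_kr, De)
  burn <- config$burn_in_hat %||% max(10, 10 * De / kstar_over_kr)
  stride <- config$save_stride
  n_steps <- as.integer(ceiling(config$t_max_hat / dt / stride)) * stride
  n_burn <- as.integer(ceiling(burn / dt))
  st <- initial_state(R_hat, kz_over_kr, config$n_particles, config$seed,
                      kstar_over_kr, De)
  res <- sim_halo_jeffreys_cpp(R_hat, kz_over_kr, kstar_over_kr, De,
                               st$pos, st$Q, dt, n_burn, n_steps, stride,
                               config$seed, save_Q)
  times <- dt * stride * (0:(n_steps / stride))
  params <- list(model = "jeffreys", R_hat = R_hat, kz_over_kr = kz_over_kr,
                 kstar_over_kr = kstar_over_kr, De = De,
                 dt_hat = dt, burn_in_hat = burn, n_steps = n_steps,
                 save_stride = stride, n_particles = config$n_particles,
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("halorheo")))
  new_halo_trajectory(res, times, params, has_Q = save_Q)
}

#' Simulate a 1D harmonically trapped particle (Ornstein-Uhlenbeck)
#'
#' The 1D limit of the halo integrator (one confined coordinate, stiffness
#' `k_hat` in radial units): `dx = -k_hat x dt + sqrt(2) dW`. Its mean
#' squared displacement has the closed form
#' `MSD(t) = (2 / k_hat) (1 - exp(-k_hat t))`, which makes this channel the
#' brute-force validation oracle for the stochastic stepping.
#'
#' @param k_hat Dimensionless stiffness (> 0).
#' @param config A [sim_config()].
#' @param equilibrated Start from a stationary Gaussian draw (default) or
#'   from the origin.
#' @return A tibble (`particle`, `t_hat`, `x`) with the usual trajectory
#'   attributes.
#' @export
simulate_ou_1d <- function(k_hat = 1, config, equilibrated = TRUE) {
  check_number(k_hat, "k_hat", lower = 0, allow_zero = FALSE)
  dt <- config$dt_hat %||% min(0.01, 0.05 / k_hat)
  if (dt > 0.05 / k_hat) abort("dt_hat too large for this stiffness.")
  burn <- config$burn_in_hat %||% 10 / k_hat
  stride <- config$save_stride
  n_steps <- as.integer(ceiling(config$t_max_hat / dt / stride)) * stride
  n_burn <- as.integer(ceiling(burn / dt))
  x0 <- if (equilibrated) {
    withr::with_seed(as.integer(config$seed %% .Machine$integer.max),
                     stats::rnorm(config$n_particles, sd = sqrt(1 / k_hat)))
  } else {
    rep(0, config$n_particles)
  }
  X <- sim_ou_1d_cpp(k_hat, x0, dt, n_burn, n_steps, stride, config$seed)
  times <- dt * stride * (0:(n_steps / stride))
  out <- tibble(
    particle = rep(seq_len(config$n_particles), each = length(times)),
    t_hat = rep(times, config$n_particles),
    x = as.vector(X)
  )
  attr(out, "n_save") <- length(times)
  attr(out, "n_particles") <- config$n_particles
  attr(out, "params") <- list(model = "ou_1d", k_hat = k_hat, dt_hat = dt,
                              burn_in_hat = burn, save_stride = stride,
                              n_particles = config$n_particles,
                              seed = config$seed)
  class(out) <- c("halo_trajectory", class(out))
  out
}
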