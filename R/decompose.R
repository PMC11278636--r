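#' Decompose trajectories into torus-adapted components
#'
#' Converts Cartesian samples into the three independent components of the
#' motion in the halo trap: radial distance `r` (and the radial fluctuation
#' `dr = r - R_hat` used by the correlation estimators), axial position `z`,
#' and azimuthal arc length `s = R_hat * theta_unwrapped`. The angle is
#' unwrapped cumulatively per particle, so `s` is continuous across the
#' +/- pi branch cut; the arc length uses the *fixed* trap radius `R_hat`,
#' not the instantaneous particle radius, which makes the azimuthal MSD
#' independent of the ring size and directly comparable to 1D free
#' diffusion.
#'
#' @param traj A `halo_trajectory` from [simulate_newtonian()] /
#'   [simulate_jeffreys()].
#' @param R_hat Trap major radius; defaults to the value recorded in the
#'   trajectory's provenance.
#' @param unwrap Unwrap the azimuth into the arc-length channel `s`? Set to
#'   `FALSE` for analyses that only use the confined components (e.g. the
#'   radial anisotropy of small rings, where rare near-axis passes make the
#'   azimuthal step ill-defined); `s` is then `NA`.
#' @return A tibble of class `halo_components`: `particle`, `t_hat`, `r`,
#'   `dr`, `z`, `s`, `theta` (wrapped angle), carrying the provenance of the
#'   input.
#' @section Errors: if any per-sample angular step reaches ~pi the unwrap is
#'   unreliable (the particle may have wound the other way) and the
#'   decomposition aborts; sample more finely.
#' @examples
#' traj <- simulate_newtonian(50, 1, sim_config(4, 10, seed = 2))
#' comp <- cylindrical_decompose(traj)
#' @export
cylindrical_decompose <- function(traj, R_hat = NULL, unwrap = TRUE) {
  R_hat <- R_hat %||% traj_params(traj)$R_hat
  if (is.null(R_hat)) abort("`R_hat` not found in trajectory provenance; supply it.")
  X <- traj_matrix(traj, "x")
  Y <- traj_matrix(traj, "y")
  r <- sqrt(X^2 + Y^2)
  if (any(r <= 0)) abort("sample on the z-axis: cylindrical decomposition undefined.")
  theta <- atan2(Y, X)
  n <- nrow(theta)
  if (!unwrap) {
    unwrapped <- matrix(NA_real_, n, ncol(theta))
  } else if (n > 1L) {
    dtheta <- theta[-1L, , drop = FALSE] - theta[-n, , drop = FALSE]
    dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))
    if (max(abs(dtheta)) >= 0.95 * pi) {
      abort(paste0("angular step of ~pi between consecutive samples: ",
                   "unwrapping is unreliable at this sampling rate."))
    }
    unwrapped <- rbind(theta[1L, , drop = FALSE],
                       sweep(apply(dtheta, 2L, cumsum), 2L, theta[1L, ], "+"))
    if (n == 2L) unwrapped <- matrix(unwrapped, nrow = 2L)
  } else {
    unwrapped <- theta
  }
  out <- tibble(
    particle = traj$particle,
    t_hat = traj$t_hat,
    r = as.vector(r),
    dr = as.vector(r) - R_hat,
    z = traj$z,
    s = if (unwrap) R_hat * as.vector(unwrapped) else NA_real_,
    theta = as.vector(theta)
  )
  attr(out, "n_save") <- attr(traj, "n_save")
  attr(out, "n_particles") <- attr(traj, "n_particles")
  attr(out, "params") <- traj_params(traj)
  attr(out, "R_hat") <- R_hat
  class(out) <- c("halo_components", class(out))
  out
}
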