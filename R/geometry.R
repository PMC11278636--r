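#' Force from the toroidal optical trap
#'
#' Restoring force on a particle at `position = (x, y, z)`:
#' \deqn{F = -\kappa_r\left(1 - \frac{R}{\sqrt{x^2+y^2}}\right)(x, y, 0)
#'   - \kappa_z z\,(0, 0, 1),}
#' the negative gradient of
#' \eqn{U = \tfrac{\kappa_r}{2}(\sqrt{x^2+y^2} - R)^2 +
#' \tfrac{\kappa_z}{2} z^2}. The force vanishes on the generator circle and
#' is undefined on the z-axis (`x = y = 0`), which is rejected.
#'
#' @param position Numeric length-3 vector `(x, y, z)`, or an `n x 3` matrix
#'   of positions. Same length unit as `geometry$major_R`.
#' @param geometry A [trap_geometry()]. For dimensionless work pass
#'   `trap_geometry(R_hat, 1, kz_over_kr)`.
#' @return A force vector (or `n x 3` matrix), units `kappa * length`.
#' @examples
#' geo <- trap_geometry(10, 1, 1 / 3)
#' trap_force(c(10, 0, 0), geo) # zero: minimum of the potential
#' trap_force(c(10.5, 0, 2), geo) # (-0.5, 0, -2/3)
#' @export
trap_force <- function(position, geometry) {
  vec <- is.null(dim(position))
  pos <- if (vec) matrix(position, nrow = 1L) else as.matrix(position)
  if (ncol(pos) != 3L) abort("`position` must have 3 components (x, y, z).")
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  if (any(rho <= 0)) {
    abort("position on the z-axis (x = y = 0): the radial force direction is undefined.")
  }
  fac <- -geometry$kappa_r * (1 - geometry$major_R / rho)
  out <- cbind(fac * pos[, 1], fac * pos[, 2], -geometry$kappa_z * pos[, 3])
  if (vec) out[1L, ] else out
}

#' Inner/outer annulus area ratio of the torus cross-section
#'
#' The planar cross-section of the toroid splits into an inner annulus
#' `Ai = pi (R^2 - (R - b)^2)` and an outer annulus
#' `Ao = pi ((R + b)^2 - R^2)`; their ratio `(2R - b) / (2R + b)` runs from
#' 1/3 at `R = b` to 1 as `R -> Inf`. The deficit of inner area is the
#' geometric origin of the residual long-time radial position correlation of
#' small rings: the particle spends more time at radii beyond `R` than
#' inside it.
#'
#' @param R Major radius (> 0, any unit).
#' @param b Minor radius, same unit; requires `R >= b > 0` (the torus must
#'   not self-intersect).
#' @return The ratio `Ai / Ao`, dimensionless.
#' @examples
#' annulus_area_ratio(1, 1) # 1/3
#' annulus_area_ratio(1.5, 1) # 0.5
#' @export
annulus_area_ratio <- function(R, b) {
  check_number(R, "R", lower = 0, allow_zero = FALSE, len = NULL)
  check_number(b, "b", lower = 0, allow_zero = FALSE, len = NULL)
  if (any(R < b)) abort("`R` must be >= `b` (self-intersecting torus).")
  (2 * R - b) / (2 * R + b)
}
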