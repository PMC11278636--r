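#' Specification for the discrete unilateral Fourier transform
#'
#' The transform of a finite data record needs three pieces of information
#' the samples themselves cannot provide: the value at `t = 0`, the assumed
#' slope of the underlying function between 0 and the first sample, and the
#' assumed slope beyond the last sample. With those, the unilateral
#' transform of the piecewise-linear interpolant is closed-form and exact
#' for data that are truly piecewise linear.
#'
#' @param value_at_zero Data value at `t = 0`.
#' @param terminal_gradient Slope for `t > t[n]` (e.g. `2 D` for a diffusive
#'   MSD, 0 for a decayed correlation function).
#' @param initial_gradient Slope on `(0, t[1])`; `NULL` uses the chord from
#'   `(0, value_at_zero)` to the first sample.
#' @return A list of class `ft_spec`.
#' @export
ft_spec <- function(value_at_zero, terminal_gradient, initial_gradient = NULL) {
  check_number(value_at_zero, "value_at_zero")
  check_number(terminal_gradient, "terminal_gradient")
  if (!is.null(initial_gradient)) check_number(initial_gradient, "initial_gradient")
  structure(list(value_at_zero = value_at_zero,
                 terminal_gradient = terminal_gradient,
                 initial_gradient = initial_gradient),
            class = "ft_spec")
}

#' Unilateral Fourier transform of discretely sampled data
#'
#' Computes \eqn{\hat y(\omega) = \int_0^\infty y(t) e^{-i\omega t} dt}
#' for the piecewise-linear interpolant of `(t, y)`, extended below `t[1]`
#' by `value_at_zero + initial_gradient * t` and beyond `t[n]` by the
#' terminal gradient. Writing \eqn{\beta_k} for the segment slopes, the
#' closed form is
#' \deqn{(i\omega)^2 \hat y(\omega) = i\omega\, y(0^+)
#'   + \sum_k \beta_k (e^{-i\omega t_{k-1}} - e^{-i\omega t_k})
#'   + i\omega \sum_j \Delta y_j e^{-i\omega t_j}
#'   + g_\infty e^{-i\omega t_n},}
#' where the \eqn{\Delta y_j} term handles any jump between the assumed
#' initial ramp and the first sample. The result is exact for data that are
#' genuinely piecewise linear (so a sampled ramp transforms to
#' \eqn{1/(i\omega)^2} to machine precision).
#'
#' Frequencies outside the reliable band
#' `[2 pi / t[n], pi / min(diff(t))]` are returned but flagged
#' `in_band = FALSE` (and a warning is raised); the data cannot support
#' them.
#'
#' @param t Strictly increasing sample times, `t[1] >= 0`.
#' @param y Sample values, same length.
#' @param omega Positive target frequencies (rad per time unit of `t`).
#' @param spec An [ft_spec()].
#' @return A tibble: `omega`, `ft` (complex), `in_band`.
#' @examples
#' tt <- seq(0.1, 30, by = 0.1)
#' ft <- ft_piecewise_linear(tt, exp(-tt), 10^seq(-0.5, 0.5, 0.25),
#'                           ft_spec(1, 0))
#' @export
ft_piecewise_linear <- function(t, y, omega, spec) {
  if (length(t) != length(y) || length(t) < 2L) {
    abort("`t` and `y` must be equal-length vectors with >= 2 samples.")
  }
  if (anyNA(t) || anyNA(y) || any(!is.finite(y))) abort("`t`/`y` must be finite.")
  if (t[1L] < 0 || is.unsorted(t, strictly = TRUE)) {
    abort("`t` must be strictly increasing with t[1] >= 0.")
  }
  check_omega(omega)
  if (!inherits(spec, "ft_spec")) abort("`spec` must be an ft_spec().")

  y0 <- spec$value_at_zero
  yscale <- max(abs(y), abs(y0))
  jump_t <- numeric(0)
  jump_dy <- numeric(0)
  if (t[1L] > 0) {
    g0 <- spec$initial_gradient %||% ((y[1L] - y0) / t[1L])
    nodes_t <- c(0, t)
    slopes <- c(g0, diff(y) / diff(t))
    ramp_end <- y0 + g0 * t[1L]
    if (abs(ramp_end - y[1L]) > 1e-9 * yscale) {
      jump_t <- t[1L]
      jump_dy <- y[1L] - ramp_end
    }
  } else {
    nodes_t <- t
    slopes <- diff(y) / diff(t)
    if (abs(y[1L] - y0) > 1e-9 * yscale) {
      jump_t <- 0
      jump_dy <- y[1L] - y0
    }
  }
  t_end <- t[length(t)]
  g_inf <- spec$terminal_gradient

  ## E[k, w] = exp(-i w t_k) at the segment endpoints
  E <- exp(outer(nodes_t, omega, function(a, w) -1i * w * a))
  n_seg <- length(slopes)
  seg_sum <- crossprod(slopes, E[seq_len(n_seg), , drop = FALSE] -
                         E[-1L, , drop = FALSE])[1L, ]
  iw <- 1i * omega
  acc <- iw * y0 + seg_sum + g_inf * exp(-iw * t_end)
  if (length(jump_t)) acc <- acc + iw * jump_dy * exp(-iw * jump_t)
  ft <- acc / iw^2

  band_lo <- 2 * pi / t_end
  band_hi <- pi / min(diff(t))
  in_band <- omega >= band_lo & omega <= band_hi
  if (any(!in_band)) {
    warning(sprintf(
      "%d of %d frequencies outside the data-supported band [%.3g, %.3g].",
      sum(!in_band), length(omega), band_lo, band_hi), call. = FALSE)
  }
  tibble(omega = omega, ft = ft, in_band = in_band)
}

## default log-spaced frequency grid over the data-supported band
default_omega_grid <- function(t, points_per_decade = 10) {
  lo <- 2 * pi / max(t)
  hi <- pi / min(diff(t))
  n <- max(2L, ceiling(log10(hi / lo) * points_per_decade))
  10^seq(log10(lo), log10(hi), length.out = n)
}
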