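#' Plot methods
#'
#' `autoplot()` methods for the package's result types, in the ggplot2
#' idiom: trajectories (top view of the ring, coloured by time),
#' correlation sets (per-component MSD and autocorrelation on log axes),
#' modulus curves (storage/loss moduli), master curves, and Jeffreys fits
#' (data overlaid with the fitted model).
#'
#' @param object The object to plot.
#' @param particles How many particles of a trajectory to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @name halo-autoplot
NULL

#' @rdname halo-autoplot
#' @export
autoplot.halo_trajectory <- function(object, particles = 4L, ...) {
  keep <- object$particle %in% unique(object$particle)[seq_len(particles)]
  df <- object[keep, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$t_hat,
                                   group = .data$particle)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (thermal widths)", y = "y (thermal widths)",
                  colour = "t") +
    ggplot2::theme_minimal()
}

#' @rdname halo-autoplot
#' @export
autoplot.halo_correlations <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$lag_hat > 0)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, lag = .data$lag_hat, component = .data$component,
                     statistic = "MSD", value = .data$msd),
    dplyr::transmute(dplyr::filter(df, !is.na(.data$npaf)),
                     lag = .data$lag_hat, component = .data$component,
                     statistic = "NPAF", value = .data$npaf)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$lag, .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "lag (dimensionless)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname halo-autoplot
#' @export
autoplot.modulus_curve <- function(object, ...) {
  df <- as_tibble(object)
  if ("in_band" %in% names(df)) df <- df[df$in_band, ]
  long <- tidyr::pivot_longer(df, c("g_prime", "g_loss"),
                              names_to = "modulus", values_to = "value")
  long$modulus <- factor(long$modulus, c("g_prime", "g_loss"),
                         c("G' (storage)", "G'' (loss)"))
  long <- long[long$value > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$omega, .data$value,
                                     colour = .data$modulus)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(omega ~ "(rad/s)"), y = "modulus (Pa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname halo-autoplot
#' @export
autoplot.halo_master_curve <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$scaled_lag, .data$msd_norm,
                               colour = factor(.data$kz_over_kr))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(kappa[z] * t / kappa[r]),
                  y = "MSD_z / axial variance",
                  colour = expression(kappa[z] / kappa[r])) +
    ggplot2::theme_minimal()
}

#' @rdname halo-autoplot
#' @export
autoplot.jeffreys_fit <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$data, c("g_prime", "g_loss"),
                             names_to = "modulus", values_to = "value")
  fit <- tidyr::pivot_longer(as_tibble(object$fitted)[
    c("omega", "g_prime", "g_loss")],
    c("g_prime", "g_loss"), names_to = "modulus", values_to = "value")
  lab <- c(g_prime = "G'", g_loss = "G''")
  dat$modulus <- lab[dat$modulus]
  fit$modulus <- lab[fit$modulus]
  ggplot2::ggplot(dat[dat$value > 0, ],
                  ggplot2::aes(.data$omega, .data$value,
                               colour = .data$modulus)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = fit[fit$value > 0, ], linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(omega ~ "(rad/s)"), y = "modulus (Pa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
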