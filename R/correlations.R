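#' Pseudo-logarithmic lag grid
#'
#' Every sample interval up to 16, then multiplicative growth by 1.25
#' (multi-tau practice): covers several decades of lag at a cost that grows
#' only logarithmically with the series length.
#'
#' @param n_samples Series length.
#' @param max_frac Largest lag as a fraction of the series (default 1/4;
#'   longer lags have too few independent pairs to be useful).
#' @param growth Geometric growth factor after the dense head.
#' @return Integer lag indices (including 0).
#' @export
lag_grid <- function(n_samples, max_frac = 0.25, growth = 1.25) {
  max_lag <- floor(n_samples * max_frac)
  if (max_lag < 1L) abort("series too short for any lag.")
  dense <- 0:min(16L, max_lag)
  lag <- max(dense)
  geo <- integer(0)
  while (lag < max_lag) {
    lag <- min(max_lag, max(lag + 1L, floor(lag * growth)))
    geo <- c(geo, lag)
  }
  lags <- as.integer(c(dense, geo))
  # align long lags to the power-of-two decimation used by the estimators
  lags <- vapply(lags, function(l) {
    d <- decimation_of(l)
    as.integer((l %/% d) * d)
  }, 1L)
  unique(lags)
}

## multi-tau decimation: lags beyond `base` sample intervals are estimated
## on a series decimated by the largest power of two keeping lag/d >= base;
## long-lag origins are strongly correlated, so the statistical cost is nil
## while the compute cost per lag stays bounded.
decimation_of <- function(lag, base = 64L) {
  if (lag <= base) return(1L)
  as.integer(2^floor(log2(lag / base)))
}

## core pair-averaged estimators on a (time x particle) matrix ---------------
## Each returns per-particle statistics so callers can attach Monte-Carlo
## standard errors (spread across independent particles).

pair_stats <- function(M, lags, products) {
  n <- nrow(M)
  if (any(lags >= n)) {
    abort(sprintf("lag %d beyond series length %d.", max(lags), n))
  }
  d <- vapply(lags, decimation_of, 1L)
  d[lags %% d != 0L] <- 1L
  pair_stats_cpp(M, as.integer(lags), d, products)
}

#' Mean squared displacement of a sampled series
#'
#' Time-and-ensemble averaged MSD,
#' `MSD(tau) = <(x(t + tau) - x(t))^2>`, using all valid ordered pairs of
#' time origins and all particles. The reported standard error is the
#' spread of the per-particle time averages across the ensemble.
#'
#' @param x A numeric vector (one particle) or a time-by-particle matrix of
#'   uniformly sampled positions.
#' @param dt Sampling interval (time units of the series).
#' @param lags Integer lag indices (multiples of `dt`); default
#'   [lag_grid()].
#' @return A tibble: `lag` (in time units), `msd`, `se`, `n_pairs`.
#' @examples
#' msd(outer(1:100, rep(1, 4)) * 0.3, dt = 1, lags = 0:5) # ramp: v^2 tau^2
#' @export
msd <- function(x, dt = 1, lags = NULL) {
  M <- if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
  lags <- lags %||% lag_grid(nrow(M))
  res <- pair_stats(M, lags, products = FALSE)
  tibble(
    lag = lags * dt,
    msd = rowMeans(res$pp),
    se = if (ncol(M) > 1L) apply(res$pp, 1L, sd) / sqrt(ncol(M)) else NA_real_,
    n_pairs = res$n_pairs
  )
}

#' Normalised position autocorrelation and normalised MSD
#'
#' For a stationary confined component, the normalised position
#' autocorrelation is `A(tau) = <x(t) x(t + tau)> / <x^2>` and the
#' normalised MSD is `Pi(tau) = MSD(tau) / (2 <x^2>)`; for sufficiently long
#' stationary records the two satisfy `Pi = 1 - A`. No empirical mean is
#' subtracted: the radial fluctuation of a small ring has a genuinely
#' non-zero mean (`<r> > R_hat`), and keeping it is what produces the
#' residual long-time plateau `A_r(Inf) ~ 1/R_hat^2`.
#'
#' @inheritParams msd
#' @return A tibble: `lag`, `npaf` (or `nmsd`), `se`, `n_pairs`.
#' @export
npaf <- function(x, dt = 1, lags = NULL) {
  M <- if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
  m2 <- mean(M^2)
  if (m2 <= 0) abort("zero-variance series: autocorrelation undefined.")
  lags <- lags %||% lag_grid(nrow(M))
  res <- pair_stats(M, lags, products = TRUE)
  tibble(
    lag = lags * dt,
    npaf = rowMeans(res$pp) / m2,
    se = if (ncol(M) > 1L) {
      apply(res$pp / m2, 1L, sd) / sqrt(ncol(M))
    } else NA_real_,
    n_pairs = res$n_pairs
  )
}

#' @rdname npaf
#' @export
nmsd <- function(x, dt = 1, lags = NULL) {
  M <- if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
  m2 <- mean(M^2)
  if (m2 <= 0) abort("zero-variance series: normalised MSD undefined.")
  out <- msd(M, dt = dt, lags = lags)
  tibble(lag = out$lag, nmsd = out$msd / (2 * m2), se = out$se / (2 * m2),
         n_pairs = out$n_pairs)
}

#' Correlation set of a decomposed halo trajectory
#'
#' Computes, on one pseudo-logarithmic lag grid, the per-component MSDs
#' (radial fluctuation `dr`, axial `z`, azimuthal arc length `s`) and, for
#' the two confined components, the normalised position autocorrelation
#' `A(tau)` and normalised MSD `Pi(tau)`. The azimuthal component is free
#' (not stationary), so `npaf`/`nmsd` are `NA` there.
#'
#' @param comp A `halo_components` tibble from [cylindrical_decompose()].
#' @param lags Integer lag indices; default [lag_grid()] on the recording.
#' @return A tibble of class `halo_correlations` with columns `lag_hat`,
#'   `component` (`"r"`, `"z"`, `"theta"`), `msd`, `msd_se`, `npaf`,
#'   `npaf_se`, `nmsd`, `nmsd_se`, `n_pairs`. The raw second moments,
#'   sampling interval and provenance ride along as attributes.
#' @examples
#' traj <- simulate_newtonian(50, 1, sim_config(8, 40, seed = 3))
#' corr <- compute_correlations(cylindrical_decompose(traj))
#' @export
compute_correlations <- function(comp, lags = NULL) {
  if (!inherits(comp, "halo_components")) {
    abort("`comp` must come from cylindrical_decompose().")
  }
  n_save <- attr(comp, "n_save")
  dt_s <- comp$t_hat[2L] - comp$t_hat[1L]
  lags <- lags %||% lag_grid(n_save)
  mats <- list(r = matrix(comp$dr, nrow = n_save),
               z = matrix(comp$z, nrow = n_save),
               theta = matrix(comp$s, nrow = n_save))
  if (anyNA(mats$theta)) mats$theta <- NULL # decomposed with unwrap = FALSE
  rows <- lapply(names(mats), function(nm) {
    M <- mats[[nm]]
    m <- msd(M, dt = dt_s, lags = lags)
    if (nm == "theta") {
      tibble(lag_hat = m$lag, component = nm, msd = m$msd, msd_se = m$se,
             npaf = NA_real_, npaf_se = NA_real_, nmsd = NA_real_,
             nmsd_se = NA_real_, n_pairs = m$n_pairs)
    } else {
      a <- npaf(M, dt = dt_s, lags = lags)
      m2 <- mean(M^2)
      tibble(lag_hat = m$lag, component = nm, msd = m$msd, msd_se = m$se,
             npaf = a$npaf, npaf_se = a$se, nmsd = m$msd / (2 * m2),
             nmsd_se = m$se / (2 * m2), n_pairs = m$n_pairs)
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "second_moment") <- vapply(mats, function(M) mean(M^2), 0)
  attr(out, "dt_sample") <- dt_s
  attr(out, "R_hat") <- attr(comp, "R_hat")
  attr(out, "n_particles") <- attr(comp, "n_particles")
  attr(out, "params") <- attr(comp, "params")
  class(out) <- c("halo_correlations", class(out))
  out
}

#' Axial master curves across stiffness ratios
#'
#' Rescales the axial MSD and autocorrelation of runs at different
#' `kappa_z / kappa_r` onto common coordinates: lags are multiplied by
#' `kappa_z / kappa_r` and the MSD is normalised by the axial trap variance
#' (`kappa_r / kappa_z` in natural units). For an overdamped harmonic
#' coordinate the rescaled curves collapse exactly onto
#' `2 (1 - exp(-t))` and `exp(-t)`.
#'
#' @param corrsets A list of `halo_correlations` (or plain tibbles with the
#'   same columns), one per stiffness ratio, sharing the simulation
#'   protocol.
#' @param kz_over_kr Numeric vector of stiffness ratios, same length.
#' @param n_grid Number of common rescaled-lag points used for the collapse
#'   metric.
#' @return A list of class `halo_master_curve`: `curves` (tibble:
#'   `kz_over_kr`, `scaled_lag`, `msd_norm`, `npaf`), `collapse_msd` (max
#'   over overlapping lags of the inter-curve relative spread of the
#'   normalised MSD) and `collapse_npaf` (same, absolute spread of A_z).
#' @export
master_curve_axial <- function(corrsets, kz_over_kr, n_grid = 40L) {
  if (length(corrsets) != length(kz_over_kr)) {
    abort("`corrsets` and `kz_over_kr` lengths differ.")
  }
  curves <- purrr::map2_dfr(corrsets, kz_over_kr, function(co, kz) {
    z <- dplyr::filter(as_tibble(co), .data$component == "z", .data$lag_hat > 0)
    tibble(kz_over_kr = kz, scaled_lag = z$lag_hat * kz,
           msd_norm = z$msd * kz, npaf = z$npaf)
  })
  lo <- max(tapply(curves$scaled_lag, curves$kz_over_kr, min))
  hi <- min(tapply(curves$scaled_lag, curves$kz_over_kr, max))
  if (lo >= hi) abort("rescaled lag ranges do not overlap.")
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  interp <- function(sub, what) {
    approx(log(sub$scaled_lag), sub[[what]], xout = log(grid))$y
  }
  by_ratio <- split(curves, curves$kz_over_kr)
  msd_mat <- vapply(by_ratio, interp, numeric(n_grid), what = "msd_norm")
  npaf_mat <- vapply(by_ratio, interp, numeric(n_grid), what = "npaf")
  msd_mat <- matrix(msd_mat, nrow = n_grid)
  npaf_mat <- matrix(npaf_mat, nrow = n_grid)
  rel_spread <- apply(msd_mat, 1L, function(v) (max(v) - min(v)) / mean(v))
  abs_spread <- apply(npaf_mat, 1L, function(v) max(v) - min(v))
  structure(
    list(curves = curves,
         collapse_msd = if (length(by_ratio) > 1L) max(rel_spread) else 0,
         collapse_npaf = if (length(by_ratio) > 1L) max(abs_spread) else 0,
         grid = grid),
    class = "halo_master_curve"
  )
}

#' Long-time radial anisotropy across ring sizes
#'
#' For each supplied correlation set, estimates the long-time plateau of the
#' radial position autocorrelation `A_r` (mean over the terminal decade of
#' lags), then regresses `log(plateau)` on `log(R_hat)`. The stationary
#' geometry predicts `plateau = <dr>^2 / <dr^2> ~ 1 / R_hat^2`, i.e. a
#' power-law exponent of -2, vanishing for large rings.
#'
#' @param corrsets List of `halo_correlations`, one per ring size.
#' @param R_hat Numeric vector of dimensionless major radii, same length.
#' @param tail_slope_tol Refuse to read a plateau when the terminal trend of
#'   `A_r` versus log-lag exceeds this absolute slope (curve not plateaued).
#' @param window_frac Terminal window: lags above `window_frac * max(lag)`.
#' @return A list of class `halo_anisotropy`: `plateaus` (tibble `R_hat`,
#'   `plateau`, `se`), `exponent`, `exponent_se` (log-log fit; requires
#'   >= 3 positive plateaus).
#' @export
radial_anisotropy <- function(corrsets, R_hat, tail_slope_tol = 0.05,
                              window_frac = 0.1) {
  if (length(corrsets) != length(R_hat)) {
    abort("`corrsets` and `R_hat` lengths differ.")
  }
  plat <- purrr::map2_dfr(corrsets, R_hat, function(co, R) {
    rr <- dplyr::filter(as_tibble(co), .data$component == "r", .data$lag_hat > 0)
    win <- rr[rr$lag_hat >= window_frac * max(rr$lag_hat), ]
    if (nrow(win) < 3L) abort("too few terminal lags to read a plateau.")
    fit <- lm(win$npaf ~ log(win$lag_hat))
    if (abs(coef(fit)[2L]) > tail_slope_tol) {
      abort(sprintf(
        "A_r at R_hat = %g has not plateaued (terminal slope %.3g per e-fold of lag).",
        R, coef(fit)[2L]))
    }
    tibble(R_hat = R, plateau = mean(win$npaf), se = mean(win$npaf_se))
  })
  exponent <- exponent_se <- NA_real_
  pos <- plat[plat$plateau > 0, ]
  if (nrow(pos) >= 3L) {
    fit <- lm(log(pos$plateau) ~ log(pos$R_hat))
    exponent <- unname(coef(fit)[2L])
    exponent_se <- summary(fit)$coefficients[2L, 2L]
  }
  structure(list(plateaus = plat, exponent = exponent,
                 exponent_se = exponent_se),
            class = "halo_anisotropy")
}

#' Sample skewness of the radial position distribution
#'
#' Moment skewness of the radial fluctuation `dr = r - R_hat`, pooled over
#' time with a Monte-Carlo standard error from the spread of per-particle
#' skewnesses. The stationary distribution `p(r) ~ r exp(-(r - R_hat)^2/2)`
#' puts excess probability at radii beyond `R_hat`, so with this
#' outward-positive sign convention the skewness is slightly *positive*
#' (about `+2 / R_hat^3` in units of sigma^3) for small rings and vanishes
#' as the ring grows; an inward-positive radial coordinate (`R_hat - r`)
#' gives the mirrored, negative value.
#'
#' @param comp A `halo_components` tibble.
#' @return One-row tibble: `skewness`, `se`, `mean_dr`, `n_particles`.
#' @export
radial_skewness <- function(comp) {
  M <- matrix(comp$dr, nrow = attr(comp, "n_save"))
  skew1 <- function(v) {
    m <- mean(v)
    mean((v - m)^3) / (mean((v - m)^2))^1.5
  }
  pp <- apply(M, 2L, skew1)
  tibble(skewness = skew1(as.vector(M)),
         se = sd(pp) / sqrt(ncol(M)),
         mean_dr = mean(M),
         n_particles = ncol(M))
}
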