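# build a halo_trajectory by hand from per-particle (x, y, z) matrices
fake_traj <- function(xyz_list, dt = 0.1, R_hat = 10) {
  n <- nrow(xyz_list[[1]])
  P <- length(xyz_list)
  out <- tibble::tibble(
    particle = rep(seq_len(P), each = n),
    t_hat = rep(dt * (seq_len(n) - 1), P),
    x = unlist(lapply(xyz_list, function(m) m[, 1])),
    y = unlist(lapply(xyz_list, function(m) m[, 2])),
    z = unlist(lapply(xyz_list, function(m) m[, 3]))
  )
  attr(out, "n_save") <- n
  attr(out, "n_particles") <- P
  attr(out, "params") <- list(model = "fake", R_hat = R_hat)
  class(out) <- c("halo_trajectory", class(out))
  out
}

test_that("cylindrical decomposition unwraps the azimuth correctly", {
  R <- 10
  # static point: constant r and s
  static <- fake_traj(list(cbind(rep(R, 5), 0, 1)), R_hat = R)
  cs <- cylindrical_decompose(static)
  expect_equal(unique(cs$s), 0)
  expect_equal(unique(cs$r), R)

  # one full loop: delta s = 2 pi R, crossing the +/- pi branch cut
  th <- seq(0, 2 * pi, length.out = 201)
  loop <- fake_traj(list(cbind(R * cos(th), R * sin(th), 0)), R_hat = R)
  cl <- cylindrical_decompose(loop)
  expect_equal(max(cl$s) - min(cl$s), 2 * pi * R, tolerance = 1e-12)
  expect_lt(max(abs(diff(cl$s))), 2 * pi * R / 100) # continuous, no jumps

  # reconstruction reproduces the input positions
  tr <- fixture_ensemble("newtonian_ring_small")
  cs2 <- cylindrical_decompose(tr)
  expect_equal(cs2$r * cos(cs2$theta), tr$x, tolerance = 1e-12)
  expect_equal(cs2$r * sin(cs2$theta), tr$y, tolerance = 1e-12)

  # angular steps of ~pi are refused
  th3 <- cumsum(c(0, rep(0.99 * pi, 4)))
  bad <- fake_traj(list(cbind(R * cos(th3), R * sin(th3), 0)), R_hat = R)
  expect_error(cylindrical_decompose(bad), "unreliable|angular step")
})

test_that("MSD estimator handles ramps, white noise, and equals brute force", {
  # deterministic ramp x = v t: MSD = v^2 tau^2
  v <- 0.3
  x <- v * (0:99)
  m <- msd(x, dt = 1, lags = 0:8)
  expect_equal(m$msd, v^2 * m$lag^2)

  # iid Gaussian: MSD -> 2 sigma^2 for any lag >= 1
  set.seed(6)
  sig <- 1.7
  W <- matrix(rnorm(400 * 50, sd = sig), 400, 50)
  mw <- msd(W, dt = 1, lags = c(1, 3, 10))
  expect_equal(mw$msd, rep(2 * sig^2, 3), tolerance = 0.03)

  # short series: exact agreement with the O(N^2) double-loop oracle
  set.seed(7)
  for (P in c(1, 3)) {
    S <- matrix(cumsum(rnorm(64 * P)), 64, P)
    lags <- lag_grid(64)
    m2 <- msd(S, dt = 0.5, lags = lags)
    expect_equal(m2$msd, brute_msd(S, lags), tolerance = 1e-12)
  }
  expect_error(msd(x, lags = c(0, 200)), "beyond")
})

test_that("multi-tau decimation agrees with the undecimated estimator", {
  set.seed(8)
  S <- matrix(cumsum(rnorm(600 * 4)), 600, 4)
  lags <- c(96L, 128L) # decimated by construction
  m_fast <- msd(S, dt = 1, lags = lags)
  expect_equal(m_fast$msd, brute_msd(S, lags), tolerance = 0.1)
})

test_that("NPAF and NMSD satisfy their defining identities", {
  expect_equal(npaf(rnorm(100) + 1, lags = 0L)$npaf, 1) # A(0) = 1 exactly
  expect_error(npaf(rep(0, 50)), "zero-variance")

  # OU at unit stiffness: A(tau) = exp(-tau) within Monte-Carlo error
  tr <- simulate_ou_1d(1, sim_config(100, 30, dt_hat = 0.01, seed = 9))
  M <- traj_matrix(tr, "x")
  lags <- lag_grid(nrow(M))
  a <- npaf(M, dt = 0.01, lags = lags)
  sel <- a$lag <= 3
  expect_equal(a$npaf[sel], exp(-a$lag[sel]), tolerance = 0.05)
  # agreement with the brute-force product oracle on a short series
  short <- M[1:64, 1:3]
  lg <- lag_grid(64)
  expect_equal(npaf(short, lags = lg)$npaf, brute_acf(short, lg),
               tolerance = 1e-12)

  # Pi + A = 1 within 3 standard errors at every lag, on both confined
  # components of a simulated ring
  co <- compute_correlations(
    cylindrical_decompose(fixture_ensemble("newtonian_ring_small")))
  df <- dplyr::filter(tibble::as_tibble(co),
                      .data$component %in% c("r", "z"), .data$lag_hat > 0)
  zdev <- abs(df$nmsd + df$npaf - 1) / sqrt(df$nmsd_se^2 + df$npaf_se^2)
  expect_lt(max(zdev), 3)
})

test_that("axial master curves collapse exactly for analytic OU input", {
  kzs <- c(1 / 9, 1 / 3, 1, 3)
  scaled <- 10^seq(-2, 2, length.out = 60)
  curves <- lapply(kzs, function(kz) {
    lag <- scaled / kz # same rescaled grid for every ratio
    tibble::tibble(
      lag_hat = lag, component = "z",
      msd = 2 / kz * (1 - exp(-kz * lag)),
      npaf = exp(-kz * lag),
      msd_se = NA_real_, npaf_se = NA_real_,
      nmsd = NA_real_, nmsd_se = NA_real_, n_pairs = NA_real_
    )
  })
  mc <- master_curve_axial(curves, kzs)
  expect_lt(mc$collapse_msd, 1e-10)
  expect_lt(mc$collapse_npaf, 1e-10)
  # a single ratio: the rescaling is the identity, zero spread by definition
  mc1 <- master_curve_axial(curves[2], kzs[2])
  expect_equal(mc1$collapse_msd, 0)
  expect_equal(mc1$curves$scaled_lag, scaled)
  expect_error(master_curve_axial(curves[1:2], kzs[1]), "lengths differ")
})

test_that("radial anisotropy refuses unplateaued tails", {
  lag <- 10^seq(-1, 2, length.out = 40)
  drifting <- tibble::tibble(
    lag_hat = lag, component = "r",
    msd = NA_real_, msd_se = NA_real_,
    npaf = 0.5 - 0.2 * log10(lag), npaf_se = 0.01,
    nmsd = NA_real_, nmsd_se = NA_real_, n_pairs = NA_real_
  )
  expect_error(radial_anisotropy(list(drifting), 5), "plateaued")
})

test_that("annulus area ratio follows (2R - b)/(2R + b)", {
  expect_equal(annulus_area_ratio(1, 1), 1 / 3)
  expect_equal(annulus_area_ratio(1.5, 1), 0.5)
  expect_equal(annulus_area_ratio(1e6, 1), 1, tolerance = 1e-5)
  expect_error(annulus_area_ratio(0.5, 1), "self-intersecting")
  # equals the explicit area computation
  R <- 7.3; b <- 2.1
  Ai <- pi * (R^2 - (R - b)^2); Ao <- pi * ((R + b)^2 - R^2)
  expect_equal(annulus_area_ratio(R, b), Ai / Ao)
})
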