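test_that("piecewise-linear FT is exact on ramps and accurate on exponentials", {
  # ramp y = t sampled anywhere: (i w)^2 y_hat = 1 exactly
  tt <- c(0.3, 1.1, 2.2, 7.9, 20)
  ft <- ft_piecewise_linear(tt, tt, c(0.5, 1, 3), ft_spec(0, 1))
  expect_equal(ft$ft * (1i * ft$omega)^2, rep(1 + 0i, 3), tolerance = 1e-12)

  # exponential decay within 0.5% over two decades of omega * tc
  tc <- 2.5
  tt <- seq(0, 60 * tc, tc / 200)
  w <- 10^seq(-1, 1, 0.2) / tc
  ft2 <- suppressWarnings(
    ft_piecewise_linear(tt, exp(-tt / tc), w, ft_spec(1, 0)))
  expect_equal(ft2$ft, tc / (1 + 1i * w * tc), tolerance = 0.005)

  # arbitrary smooth decaying function against adaptive quadrature
  f <- function(t) exp(-t / 3) * (1 + 0.4 * sin(2 * t))
  tt3 <- seq(0, 80, 0.002)
  w3 <- c(0.2, 0.7, 1.9, 3.3)
  ft3 <- suppressWarnings(
    ft_piecewise_linear(tt3, f(tt3), w3, ft_spec(1, 0)))
  expect_equal(ft3$ft, ft_quadrature(f, w3, upper = 120), tolerance = 1e-4)
})

test_that("FT flags frequencies outside the data-supported band", {
  tt <- seq(0.1, 10, 0.1)
  expect_warning(
    ft <- ft_piecewise_linear(tt, tt, c(0.01, 1, 1000), ft_spec(0, 1)),
    "outside the data-supported band")
  expect_equal(ft$in_band, c(FALSE, TRUE, FALSE))
  expect_error(ft_piecewise_linear(c(1, 0.5), c(1, 2), 1, ft_spec(0, 0)),
               "increasing")
})

test_that("compliance from MSD carries the right prefactor and scalings", {
  pp <- ref_particle()
  expect_equal(compliance_from_msd(1:3, rep(0, 3), pp)$compliance, rep(0, 3))
  # Newtonian: 1D MSD = 2 D t gives J = t / eta
  eta <- 1e-3
  D <- pp$kBT / (6 * pi * pp$radius * eta)
  tt <- seq(0.1, 5, 0.1)
  J <- compliance_from_msd(tt, 2 * D * tt, pp, ndim = 1)
  expect_equal(J$compliance, tt / eta, tolerance = 1e-12)
  # doubling kBT at fixed MSD halves J
  hot <- probe_particle(pp$radius, 2 * pp$temperature)
  expect_equal(compliance_from_msd(tt, 2 * D * tt, hot)$compliance,
               J$compliance / 2)
  # 3D convention: J = pi a MSD / kBT
  expect_equal(compliance_from_msd(1, 6 * D, pp, ndim = 3)$compliance,
               pi * pp$radius * 6 * D / pp$kBT)
})

test_that("free GSER closes exactly on Newtonian input (1D prefactor lock)", {
  pp <- ref_particle()
  for (eta in c(1e-3, 0.05)) {
    D <- pp$kBT / (6 * pi * pp$radius * eta)
    lag <- seq(1e-3, 10, length.out = 400)
    cv <- suppressWarnings(
      gser_free(lag, 2 * D * lag, pp, omega = c(0.5, 5, 50)))
    expect_equal(cv$g_loss, cv$omega * eta, tolerance = 1e-10)
    expect_equal(cv$g_prime, rep(0, 3), tolerance = eta * 1e-8)
  }
})

test_that("modulus route equals the inverse compliance route", {
  pp <- ref_particle()
  # same transform both ways: G* = 1 / (i w J_hat), J = 3 pi a MSD / kBT
  lag <- seq(0.01, 20, 0.01)
  m <- 2 * 0.3 * lag + 0.8 * (1 - exp(-lag / 0.7)) # diffusive + transient
  w <- 10^seq(-0.5, 1.5, 0.25)
  g_direct <- suppressWarnings(
    gser_free(lag, m, pp, omega = w, terminal_gradient = 2 * 0.3,
              initial_gradient = m[1] / lag[1]))
  J <- compliance_from_msd(lag, m, pp)$compliance
  Jhat <- suppressWarnings(
    ft_piecewise_linear(lag, J, w,
                        ft_spec(0, 2 * 0.3 * 3 * pi * pp$radius / pp$kBT)))
  g_compliance <- 1 / (1i * w * Jhat$ft)
  expect_equal(g_direct$g_star, g_compliance, tolerance = 1e-12)
})

test_that("trapped GSER recovers i w eta from the analytic OU autocorrelation", {
  pp <- ref_particle()
  eta <- 1e-3
  kappa <- 1e-6
  tc <- 6 * pi * pp$radius * eta / kappa
  # exact transform: A_hat = tc / (1 + i w tc) gives G* = i w eta exactly
  w <- 10^seq(-1, 1, 0.25) / tc
  forms <- gser_trapped_forms(w, tc / (1 + 1i * w * tc), kappa, pp)
  expect_equal(forms$from_ratio, 1i * w * eta, tolerance = 1e-12)
  # discrete route from the sampled A(tau)
  lag <- seq(0, 25 * tc, tc / 300)
  cv <- suppressWarnings(
    gser_trapped(lag, exp(-lag / tc), kappa, pp, kind = "npaf",
                 omega = 10^seq(-0.5, 0.5, 0.25) / tc))
  expect_equal(cv$g_loss, cv$omega * eta, tolerance = 0.005)
  expect_lt(max(abs(cv$g_prime)), 0.005 * max(cv$g_loss))
})

test_that("the three trapped-GSER forms agree to machine precision", {
  pp <- ref_particle()
  set.seed(10)
  w <- sort(10^runif(12, -2, 2))
  A_hat <- complex(real = runif(12, -1, 1), imaginary = runif(12, -1, 1))
  forms <- gser_trapped_forms(w, A_hat, 2.3e-6, pp)
  expect_equal(forms$from_nmsd, forms$from_ratio, tolerance = 1e-12)
  expect_equal(forms$from_npaf_inverse, forms$from_ratio, tolerance = 1e-12)
})

test_that("NMSD and NPAF inversion routes agree on shared data", {
  pp <- ref_particle()
  kappa <- 1e-6
  tc <- 6 * pi * pp$radius * 1e-3 / kappa
  lag <- seq(0, 30 * tc, tc / 200)
  A <- exp(-lag / tc)
  w <- 10^seq(-0.5, 0.5, 0.25) / tc
  g_npaf <- suppressWarnings(gser_trapped(lag, A, kappa, pp, "npaf", w))
  g_nmsd <- suppressWarnings(gser_trapped(lag, 1 - A, kappa, pp, "nmsd", w))
  expect_equal(g_npaf$g_star, g_nmsd$g_star, tolerance = 1e-9)
})

test_that("the Jeffreys GLE identity holds against the analytic modulus", {
  pp <- ref_particle()
  fl <- jeffreys_fluid(1e-3, eta2 = 0.02, G = 4e-3) # tau = 5 s
  w <- 10^seq(-2.5, 2.5, 0.25)
  idn <- jeffreys_gser_identity(fl, pp, 1e-6, w)
  expect_lt(max(idn$rel_residual), 1e-6)
  # the left side is the analytic Jeffreys modulus itself
  expect_equal(idn$lhs, complex_modulus_jeffreys(fl, w)$g_star,
               tolerance = 1e-12)
  # terminal limit: G* -> i w (eta1 + eta2) as w -> 0
  lo <- jeffreys_gser_identity(fl, pp, 1e-6, 1e-5)
  expect_equal(lo$lhs / (1i * 1e-5), fl$eta1 + fl$eta2 + 0i, tolerance = 1e-6)
})

test_that("trapped inversion of the two-mode Jeffreys NPAF recovers G*", {
  # time-domain NPAF of a confined channel from the eigendecomposition of
  # the linear (u, Q) system -- an oracle independent of the package's
  # frequency-domain algebra -- pushed through the discrete transform and
  # the trapped GSER, against the analytic Jeffreys modulus.
  pp <- ref_particle()
  us <- unit_system(ref_si$kappa_r, newtonian_fluid(ref_si$eta1), pp)
  k_hat <- 1; q <- 4; De <- 2
  tau_hat <- seq(0, 60, 0.005)
  A <- jeffreys_npaf_time(k_hat, q, De, tau_hat)
  w_si <- 10^seq(-0.8, 1.2, 0.2) / us$time_unit
  cv <- suppressWarnings(
    gser_trapped(tau_hat * us$time_unit, A, ref_si$kappa_r, pp, "npaf", w_si))
  G_true <- q * ref_si$kappa_r / (6 * pi * ref_si$a)
  fl <- jeffreys_fluid(ref_si$eta1, De * ref_si$eta1, G = G_true)
  model <- complex_modulus_jeffreys(fl, w_si)
  expect_lt(max(Mod(cv$g_star - model$g_star) / Mod(model$g_star)), 0.01)
})

test_that("the Jeffreys fit recovers parameters and exposes tidy/glance", {
  fl <- jeffreys_fluid(1.3e-3, eta2 = 0.06, G = 2e-3)
  curve <- complex_modulus_jeffreys(fl, 10^seq(-3, 2, 0.2))
  fit <- fit_jeffreys(curve)
  expect_equal(unname(fit$estimate["G"]), fl$G, tolerance = 1e-4)
  expect_equal(unname(fit$estimate["tau"]), fl$tau2, tolerance = 1e-4)
  expect_equal(unname(fit$estimate["eta1"]), fl$eta1, tolerance = 1e-4)
  td <- tidy(fit)
  expect_equal(td$term, c("G", "tau", "eta1"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$rmse, 1e-6)
})
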