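test_that("constructors validate their physical domains", {
  expect_error(jeffreys_fluid(-1e-3), "eta1")
  expect_error(jeffreys_fluid(1e-3, eta2 = 0.1), "`G` is required")
  expect_error(jeffreys_fluid(1e-3, eta2 = 0.1, G = 0), "G")
  expect_error(probe_particle(0), "radius")
  expect_error(probe_particle(1e-6, -1), "temperature")
  expect_error(trap_geometry(0, 1e-6, 1e-6), "major_R")
  fl <- jeffreys_fluid(2e-3, eta2 = 1, G = 1e-3)
  expect_equal(fl$tau2, 1000)
  expect_equal(fl$tau1, 2)
  expect_equal(fl$eta0, 1.002)
})

test_that("Jeffreys complex modulus matches its closed form and limits", {
  pp <- ref_particle()
  # high-frequency plateau: actin-like fluid at omega = 1 rad/s, tau = 1000 s
  actin <- jeffreys_fluid(1e-3, eta2 = 1, G = 1e-3)
  cv <- complex_modulus_jeffreys(actin, 1)
  expect_equal(cv$g_prime, 1e-3, tolerance = 1e-5)

  # half-plateau point at omega * tau2 = 1, for assorted fluids
  for (G in c(1e-3, 0.05, 2)) {
    fl <- jeffreys_fluid(5e-4, eta2 = G * 7, G = G) # tau2 = 7
    expect_equal(complex_modulus_jeffreys(fl, 1 / 7)$g_prime, G / 2,
                 tolerance = 1e-12)
  }

  # random fluids against the independent complex-arithmetic oracle
  set.seed(1)
  for (i in 1:20) {
    fl <- jeffreys_fluid(10^runif(1, -4, -1), eta2 = 10^runif(1, -3, 1),
                         G = 10^runif(1, -4, 0))
    w <- sort(10^runif(5, -3, 3))
    oracle <- 1i * w * fl$eta1 + 1i * w * fl$G * fl$tau2 / (1 + 1i * w * fl$tau2)
    cv <- complex_modulus_jeffreys(fl, w)
    expect_equal(cv$g_star, oracle, tolerance = 1e-12)
  }

  # limits: zero-shear viscosity at omega*tau2 = 1e-3, plateau at 1e3
  fl <- jeffreys_fluid(1e-3, eta2 = 0.5, G = 0.05) # tau2 = 10
  lo <- complex_modulus_jeffreys(fl, 1e-4)
  expect_equal(Im(lo$g_star[1]) / 1e-4, fl$eta1 + fl$eta2, tolerance = 1e-5)
  hi <- complex_modulus_jeffreys(fl, 1e2)
  expect_equal(hi$g_prime, fl$G, tolerance = 1e-5)
  expect_equal(hi$g_loss, 1e2 * fl$eta1, tolerance = 1e-3)

  expect_error(complex_modulus_jeffreys(fl, c(0, 1)), "positive")
  expect_error(complex_modulus_jeffreys(fl, c(2, 1)), "increasing")
})

test_that("Newtonian modulus is the eta2 = 0 degenerate case", {
  w <- 10^seq(-2, 2, 0.5)
  cv <- complex_modulus_newtonian(1e-3, w)
  expect_equal(cv$g_loss, w * 1e-3)
  expect_equal(cv$g_prime, rep(0, length(w)))
  expect_equal(complex_modulus_newtonian(1e-3, 0)$g_star, 0 + 0i)
  degenerate <- complex_modulus_jeffreys(jeffreys_fluid(1e-3), w)
  expect_equal(degenerate$g_star, cv$g_star)
})

test_that("memory kernel, its transform, and the modulus are consistent", {
  pp <- ref_particle()
  fl <- jeffreys_fluid(1e-3, eta2 = 0.8, G = 0.02) # tau = 40 s
  zeta_m <- 6 * pi * pp$radius * fl$eta2

  expect_equal(memory_kernel_ft(fl, pp, 0), zeta_m + 0i)
  total <- stats::integrate(function(t) memory_kernel(fl, pp, t), 0, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(total, zeta_m, tolerance = 1e-8)
  expect_error(memory_kernel(fl, pp, -1), "t")

  # quadrature of the time-domain kernel against the closed-form transform
  for (wt in c(0.1, 1, 10)) {
    w <- wt / fl$tau2
    quad <- ft_quadrature(function(t) memory_kernel(fl, pp, t), w,
                          upper = 30 * fl$tau2)
    exact <- memory_kernel_ft(fl, pp, w)
    expect_lt(Mod(quad - exact) / Mod(exact), 1e-6)
  }

  # kernel consistency: G*(w) = i w eta1 + i w zeta_p_hat(w) / (6 pi a)
  w <- 10^seq(-3, 2, 0.25)
  lhs <- complex_modulus_jeffreys(fl, w)$g_star
  rhs <- 1i * w * fl$eta1 +
    1i * w * memory_kernel_ft(fl, pp, w) / (6 * pi * pp$radius)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("effective stiffness is 6 pi a G", {
  expect_equal(effective_stiffness(1e-3, 1e-6), 1.88e-8, tolerance = 0.005)
  expect_equal(effective_stiffness(0, 1e-6), 0)
  expect_equal(effective_stiffness(2 * 0.37, 1e-6),
               2 * effective_stiffness(0.37, 1e-6))
})

test_that("unit system reproduces the reference worked numbers", {
  pp <- ref_particle()
  us <- unit_system(1e-6, newtonian_fluid(1e-3), pp)
  expect_equal(us$length_unit, 6.41e-8, tolerance = 0.005)
  expect_equal(us$time_unit, 1.88e-2, tolerance = 0.005)
  expect_equal(us$a_hat, 15.6, tolerance = 0.005)
  expect_equal(to_dimensionless(us, length = 1e-5), 155.9, tolerance = 0.005)
  # round trip and scaling in kappa_r
  expect_equal(to_si(us, length = to_dimensionless(us, length = 3e-6)), 3e-6)
  us4 <- unit_system(4e-6, newtonian_fluid(1e-3), pp)
  expect_equal(us4$length_unit, us$length_unit / 2)
})

test_that("dimensionless groups reproduce De = 1000 and their identities", {
  pp <- ref_particle()
  geo <- trap_geometry(1e-5, 1e-6, 1e-6 / 3)
  actin <- jeffreys_fluid(1e-3, eta2 = 1, G = 1e-3) # tau = 1000 s
  g <- dimensionless_groups(actin, pp, geo)
  expect_equal(g$De, 1000, tolerance = 1e-10)
  expect_equal(g$ratio_kstar_kr, 1.88e-2, tolerance = 0.005)
  expect_equal(g$De2, g$De / g$ratio_kstar_kr) # ~5.3e4, arithmetic identity
  # eta2 = De * eta1 for arbitrary parameter sets
  set.seed(2)
  for (i in 1:10) {
    fl <- jeffreys_fluid(10^runif(1, -4, -2), eta2 = 10^runif(1, -3, 1),
                         G = 10^runif(1, -4, 0))
    gi <- dimensionless_groups(fl, pp, geo)
    expect_equal(gi$De * fl$eta1, fl$eta2, tolerance = 1e-12)
    expect_equal(gi$De, gi$De2 * gi$ratio_kstar_kr, tolerance = 1e-12)
  }
  # Newtonian fluid: De = 0
  expect_equal(dimensionless_groups(newtonian_fluid(1e-3), pp, geo)$De, 0)
})

test_that("feasibility diagnostics give the ~20 kHz water threshold", {
  pp <- ref_particle()
  d <- feasibility_diagnostics(1e-3, pp)
  expect_equal(signif(d$threshold_rate / 1e3, 1), 20) # kHz, 1 sig fig
  expect_equal(d$threshold_lag, 1e-3 / 20)
  # De = 1 when the observation lag equals the diffusion time
  d2 <- feasibility_diagnostics(1e-3, pp, tau_ob = d$tau_D)
  expect_equal(d2$De_obs, 1)
  # traversal time against independent arithmetic
  L <- 1e-3
  d3 <- feasibility_diagnostics(1e-3, pp, L = L)
  expect_equal(d3$tau_tr, L^2 * 6 * pi * 1e-3 * pp$radius / pp$kBT)
})
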