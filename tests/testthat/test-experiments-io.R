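test_that("fixtures are deterministic, bounded mini-ensembles", {
  expect_error(fixture_ensemble("nope"), "unknown fixture kind")
  f1 <- fixture_ensemble("ou_1d", seed = 42)
  f2 <- fixture_ensemble("ou_1d", seed = 42)
  expect_identical(f1, f2)
  expect_lte(attr(f1, "n_particles"), 32)
  expect_lte(attr(f1, "n_save"), 4096)

  # OU fixture MSD against the closed form (fixture-scale tolerance)
  M <- traj_matrix(f1, "x")
  m <- msd(M, dt = 0.01, lags = c(10L, 100L, 500L))
  expect_equal(m$msd, 2 * (1 - exp(-m$lag)), tolerance = 0.15)

  # Newtonian ring fixture stays within 6 thermal widths of the ring
  nr <- fixture_ensemble("newtonian_ring_small", seed = 42)
  r <- sqrt(nr$x^2 + nr$y^2)
  expect_true(all(r > 20 - 6 & r < 20 + 6))

  jf <- fixture_ensemble("jeffreys_ring_small", seed = 1)
  expect_identical(jf, fixture_ensemble("jeffreys_ring_small", seed = 1))
})

test_that("experiment presets resolve to complete parameter blocks", {
  p <- experiment_preset("fig6_actin")
  expect_equal(p$params$kstar_over_kr, 1.88e-2, tolerance = 0.005)
  expect_equal(p$params$De, 100)
  expect_equal(experiment_preset("fig6_actin", si_faithful = TRUE)$params$De,
               1000)
  expect_error(experiment_preset("fig9"), "arg")
  expect_error(experiment_preset("fig3_newtonian", scale = 2), "scale")
  p4 <- experiment_preset("fig4_jeffreys_soft", De_values = c(2, 5))
  expect_equal(p4$params$De_values, c(2, 5))
  expect_error(experiment_preset("fig3_newtonian", De_values = 1),
               "Jeffreys presets")
})

test_that("a scaled-down Newtonian experiment reproduces its diagnostics
           and is reproducible from its seed", {
  ex <- run_experiment(experiment_preset("fig3_newtonian", scale = 0.05),
                       seed = 3)
  s <- ex$summary
  expect_equal(s$msd_theta_slope, 2, tolerance = 0.15)
  expect_equal(s$msd_r_plateau, 2, tolerance = 0.15)
  expect_equal(s$msd_z_plateau, 6, tolerance = 0.15)
  expect_lt(s$master_collapse_msd, 0.35)
  ex2 <- run_experiment(experiment_preset("fig3_newtonian", scale = 0.05),
                        seed = 3)
  expect_identical(ex$summary, ex2$summary)
})

test_that("experiment artifacts are written with provenance and JSON summary", {
  dir <- withr::local_tempdir()
  ex <- run_experiment(experiment_preset("fig3_newtonian", scale = 0.02),
                       seed = 5, out_dir = dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(js$seed, 5)
  expect_equal(js$summary$msd_r_plateau, ex$summary$msd_r_plateau)
  corr_files <- list.files(dir, pattern = "^correlations", full.names = TRUE)
  expect_gt(length(corr_files), 0)
  back <- read_correlations_csv(corr_files[1])
  expect_s3_class(back, "halo_correlations")
})

test_that("trajectory CSV round-trips losslessly with embedded provenance", {
  dir <- withr::local_tempdir()
  tr <- fixture_ensemble("jeffreys_ring_small", seed = 2)
  path <- file.path(dir, "traj.csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$x, tr$x)
  expect_equal(back$z, tr$z)
  expect_equal(traj_params(back)$De, traj_params(tr)$De)
  # second write is byte-identical
  path2 <- file.path(dir, "traj2.csv")
  write_trajectory_csv(back, path2)
  expect_identical(readLines(path)[-1], readLines(path2)[-1])
  plain <- file.path(dir, "plain.csv")
  readr::write_csv(tibble::tibble(a = 1), plain)
  expect_error(read_trajectory_csv(plain), "provenance")
})

test_that("correlation and modulus tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  co <- compute_correlations(
    cylindrical_decompose(fixture_ensemble("newtonian_ring_small")))
  p1 <- file.path(dir, "corr.csv")
  write_correlations_csv(co, p1)
  back <- read_correlations_csv(p1)
  expect_equal(back$msd, co$msd)
  expect_equal(back$npaf, co$npaf)
  expect_equal(attr(back, "second_moment"), attr(co, "second_moment"))

  cv <- complex_modulus_jeffreys(jeffreys_fluid(1e-3, 0.01, G = 1e-3),
                                 10^seq(-2, 2, 0.5))
  p2 <- file.path(dir, "mod.csv")
  write_modulus_csv(cv, p2)
  backm <- read_modulus_csv(p2)
  expect_equal(backm$g_star, cv$g_star)
})

test_that("YAML configs are validated field-by-field and run", {
  dir <- withr::local_tempdir()
  cfg <- list(kind = "jeffreys", R_hat = 20, kz_over_kr = 1 / 3,
              n_particles = 4, t_max_hat = 2, kstar_over_kr = 4, De = 2,
              seed = 8, dt_hat = 0.005)
  path <- file.path(dir, "run.yml")
  write_halo_config(cfg, path)
  cfg2 <- read_halo_config(path)
  expect_equal(cfg2$kstar_over_kr, 4)
  tr <- simulate_from_config(cfg2)
  expect_s3_class(tr, "halo_trajectory")
  expect_equal(traj_params(tr)$De, 2)

  bad <- cfg
  bad$kz_over_kr <- NULL
  expect_error(validate_halo_config(bad), "kz_over_kr")
  expect_error(validate_halo_config(list(R_hat = 1)), "kind")
  bad2 <- cfg
  bad2$si <- list(kappa_r = list(value = 1e-6)) # missing unit
  expect_error(validate_halo_config(bad2), "unit")
})

test_that("autoplot methods return ggplot objects", {
  tr <- fixture_ensemble("newtonian_ring_small")
  co <- compute_correlations(cylindrical_decompose(tr))
  cv <- complex_modulus_jeffreys(jeffreys_fluid(1e-3, 0.01, G = 1e-3),
                                 10^seq(-2, 2, 0.5))
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(autoplot(co), "ggplot")
  expect_s3_class(autoplot(cv), "ggplot")
  fit <- fit_jeffreys(cv)
  expect_s3_class(autoplot(fit), "ggplot")
})
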