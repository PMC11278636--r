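#' Experiment presets
#'
#' Named, fully parameterised reproductions of the reference simulation
#' studies, at desk scale. Each preset resolves to a complete dimensionless
#' parameter block plus the SI reference context (water solvent, micron
#' bead, `kappa_r = 1e-6` N/m, room temperature) used when trajectories are
#' converted to physical units for the inversion stage.
#'
#' * `fig3_newtonian` - Newtonian runs on a large ring (`R_hat = 150`) at
#'   three axial stiffness ratios (master curves) plus small rings
#'   (`R_hat = 5, 10, 20`) for the radial-anisotropy scaling.
#' * `fig4_jeffreys_stiff` / `fig4_jeffreys_soft` - Jeffreys runs with the
#'   fluid's elastic element much stiffer (`kappa*/kappa_r = 16`) or much
#'   softer (`0.25`) than the radial trap, at a list of Deborah numbers.
#' * `fig5_sweep` - the crossed (De, kappa*/kappa_r) sweep.
#' * `fig6_actin` - the actin-solution-like scenario (`G = 0.001` Pa,
#'   plateau stiffness ratio `~1.88e-2`); desk mode runs `De = 100`, the
#'   long-running fluid-faithful value `De = 1000` is behind
#'   `si_faithful = TRUE`.
#'
#' `scale` multiplies the reference 1000-particle ensembles; desk-scale
#' defaults complete in minutes on one CPU.
#'
#' @param name Preset identifier.
#' @param scale Ensemble multiplier in `(0, 1]`.
#' @param De_values Override the preset's Deborah-number list (Jeffreys
#'   presets only).
#' @param si_faithful For `fig6_actin`: use the fluid-faithful `De = 1000`
#'   (long-running) instead of the desk value 100.
#' @return A list of class `experiment_preset`.
#' @export
experiment_preset <- function(name = c("fig3_newtonian", "fig4_jeffreys_stiff",
                                       "fig4_jeffreys_soft", "fig5_sweep",
                                       "fig6_actin"),
                              scale = 1, De_values = NULL,
                              si_faithful = FALSE) {
  name <- match.arg(name)
  check_number(scale, "scale", lower = 0, allow_zero = FALSE)
  if (scale > 1) abort("`scale` must be in (0, 1].")
  si <- list(kappa_r = 1e-6, a = 1e-6, temperature = 298, eta1 = 1e-3)
  base <- switch(
    name,
    fig3_newtonian = list(
      R_hat = 150, kz_list = c(1 / 9, 1 / 3, 1), kz_main = 1 / 3,
      R_aniso = c(5, 10, 20), t_max = 200, t_max_aniso = 300,
      n_particles = 1000, n_particles_aniso = 1000, stride = 5L
    ),
    fig4_jeffreys_stiff = list(
      R_hat = 150, kz_over_kr = 1 / 3, kstar_over_kr = 16,
      De_values = c(1, 10), n_particles = 1000
    ),
    fig4_jeffreys_soft = list(
      R_hat = 150, kz_over_kr = 1 / 3, kstar_over_kr = 0.25,
      De_values = c(1, 10), n_particles = 1000
    ),
    fig5_sweep = list(
      R_hat = 150, kz_over_kr = 1 / 3, kstar_list = c(0.25, 16),
      De_values = c(1, 100), n_particles = 1000
    ),
    fig6_actin = list(
      R_hat = 155.9, kz_over_kr = 0.33,
      kstar_over_kr = effective_stiffness(1e-3, si$a) / si$kappa_r,
      De = if (si_faithful) 1000 else 100,
      n_particles = 1000
    )
  )
  if (!is.null(De_values)) {
    if (is.null(base$De_values)) abort("`De_values` applies to Jeffreys presets only.")
    base$De_values <- De_values
  }
  structure(list(name = name, scale = scale, params = base, si = si),
            class = "experiment_preset")
}

## desk-scale ensemble size
scaled_n <- function(n, scale) max(8L, as.integer(round(n * scale)))

## Jeffreys run sized to cover two decades of omega*tau around 1:
## span >= 64 * tau_hat (and >= 60 to see the trap corner), sampling fine
## enough for omega*tau = 10.
## span >= 64 fluid relaxation times (low-frequency band edge at
## omega*tau ~ 0.1) and sampling resolving the Maxwell-branch memory time
## De/((De+1) q) with >= 8 samples (high-frequency fidelity of the MSD).
jeffreys_run_plan <- function(kstar_over_kr, De, kz_over_kr) {
  tau_hat <- De / kstar_over_kr
  memory_hat <- De / ((De + 1) * kstar_over_kr)
  dt <- min(0.01, stability_limit(kz_over_kr, kstar_over_kr, De))
  t_max <- max(64 * tau_hat, 60)
  # slowest axial mode of the (z, Q) pair: the lag window must cover several
  # of its relaxation times before the trapped-channel plateaus are readable
  a_tr <- kz_over_kr + kstar_over_kr * (De + 1) / De
  a_det <- kz_over_kr * kstar_over_kr / De
  t_max <- max(t_max, min(24 * a_tr / a_det, 2.5 * t_max))
  stride <- max(1L, as.integer(round(max(dt, memory_hat / 8) / dt)))
  list(dt = dt, t_max = t_max, stride = stride, tau_hat = tau_hat)
}

si_context <- function(si) {
  particle <- probe_particle(si$a, si$temperature)
  fluid_s <- newtonian_fluid(si$eta1)
  us <- unit_system(si$kappa_r, fluid_s, particle)
  list(particle = particle, us = us)
}

## dimensionless correlation set -> SI azimuthal inversion + Jeffreys fit
invert_azimuthal <- function(corr, si, kstar_over_kr, De, tau_hat) {
  ctx <- si_context(si)
  us <- ctx$us
  th <- dplyr::filter(as_tibble(corr), .data$component == "theta",
                      .data$lag_hat > 0)
  lag_s <- th$lag_hat * us$time_unit
  msd_m2 <- th$msd * us$length_unit^2
  tau_si <- tau_hat * us$time_unit
  omega <- 10^seq(log10(0.1 / tau_si), log10(10 / tau_si), length.out = 21)
  curve <- suppressWarnings(
    gser_free(lag_s, msd_m2, ctx$particle, omega = omega, ndim = 1)
  )
  G_true <- kstar_over_kr * si$kappa_r / (6 * pi * si$a)
  fit <- fit_jeffreys(curve, start = c(G = G_true, tau = tau_si,
                                       eta1 = si$eta1))
  truth <- jeffreys_fluid(si$eta1, eta2 = De * si$eta1, G = G_true)
  model <- complex_modulus_jeffreys(truth, curve$omega)
  list(curve = curve, fit = fit, truth = truth,
       G_rel_err = abs(fit$estimate[["G"]] - G_true) / G_true,
       tau_rel_err = abs(fit$estimate[["tau"]] - tau_si) / tau_si,
       max_rel_err_gp = max(abs(curve$g_prime - model$g_prime) / Mod(model$g_star)),
       max_rel_err_gl = max(abs(curve$g_loss - model$g_loss) / Mod(model$g_star)))
}

## trapped-channel free-GSER inversion: the trap shows up as a spurious
## low-frequency elastic plateau kappa/(6 pi a)
trapped_channel_plateau <- function(corr, si, component) {
  ctx <- si_context(si)
  us <- ctx$us
  comp_nm <- component
  ch <- dplyr::filter(as_tibble(corr), .data$component == comp_nm,
                      .data$lag_hat > 0)
  lag_s <- ch$lag_hat * us$time_unit
  msd_m2 <- ch$msd * us$length_unit^2
  omega_lo <- 2 * pi / max(lag_s)
  omega <- omega_lo * c(1, 1.25, 1.6, 2)
  curve <- suppressWarnings(
    gser_free(lag_s, msd_m2, ctx$particle, omega = omega, ndim = 1,
              terminal_gradient = 0)
  )
  median(curve$g_prime)
}

terminal_theta_slope <- function(corr, min_lag, max_lag = Inf) {
  th <- dplyr::filter(as_tibble(corr), .data$component == "theta",
                      .data$lag_hat >= min_lag, .data$lag_hat <= max_lag)
  if (nrow(th) < 3L) abort("too few terminal azimuthal lags for a slope.")
  unname(coef(lm(th$msd ~ th$lag_hat))[2L])
}

plateau_of <- function(corr, component, what = "msd", window_frac = 0.1) {
  comp_nm <- component
  ch <- dplyr::filter(as_tibble(corr), .data$component == comp_nm,
                      .data$lag_hat > 0)
  win <- ch[ch$lag_hat >= window_frac * max(ch$lag_hat), ]
  mean(win[[what]])
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)), parent = e)
  })
}

#' Run a preset experiment
#'
#' Executes the full pipeline of a preset - simulate, decompose, correlate,
#' invert - and collects the scalar diagnostics (plateaus, slopes, fitted
#' exponents, recovered moduli) in a JSON-able summary. With `out_dir`,
#' correlation and modulus tables (CSV) and the summary (JSON) are written;
#' on error, partially written artifacts are removed.
#'
#' @param preset An [experiment_preset()] (or a preset name).
#' @param seed Integer master seed; every stochastic stage derives its seed
#'   from it, so rerunning with the same seed reproduces the summary
#'   exactly.
#' @param out_dir Optional output directory.
#' @return A list of class `halo_experiment`: `name`, `seed`, `scale`,
#'   `params`, `summary` (named list), `correlations` (list of
#'   `halo_correlations`), `artifacts` (paths written).
#' @examples
#' \donttest{
#' ex <- run_experiment(experiment_preset("fig3_newtonian", scale = 0.02),
#'                      seed = 1)
#' ex$summary$msd_theta_slope
#' }
#' @export
run_experiment <- function(preset, seed = 1L, out_dir = NULL) {
  if (is.character(preset)) preset <- experiment_preset(preset)
  if (!inherits(preset, "experiment_preset")) {
    abort("`preset` must be an experiment_preset() or a preset name.")
  }
  written <- character(0)
  on_error_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }
  res <- tryCatch(
    run_experiment_impl(preset, seed, out_dir,
                        note_written = function(p) written <<- c(written, p)),
    error = on_error_cleanup
  )
  res
}

run_experiment_impl <- function(preset, seed, out_dir, note_written) {
  p <- preset$params
  si <- preset$si
  scale <- preset$scale
  summary <- list()
  corrs <- list()
  artifacts <- character(0)

  emit <- function(obj, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, file)
    if (inherits(obj, "halo_correlations")) write_correlations_csv(obj, path)
    else if (inherits(obj, "modulus_curve")) write_modulus_csv(obj, path)
    note_written(path)
    artifacts <<- c(artifacts, path)
  }

  if (preset$name == "fig3_newtonian") {
    n <- scaled_n(p$n_particles, scale)
    kz_corrs <- list()
    for (i in seq_along(p$kz_list)) {
      kz <- p$kz_list[[i]]
      traj <- with_stage("simulate", simulate_newtonian(
        p$R_hat, kz,
        sim_config(n, p$t_max, seed = seed + i, save_stride = p$stride)))
      co <- with_stage("correlate",
                       compute_correlations(cylindrical_decompose(traj)))
      kz_corrs[[i]] <- co
      emit(co, sprintf("correlations_kz%02d.csv", i))
    }
    main <- kz_corrs[[which(p$kz_list == p$kz_main)[1L]]]
    corrs <- kz_corrs
    mc <- with_stage("master_curve", master_curve_axial(kz_corrs, p$kz_list))
    na <- scaled_n(p$n_particles_aniso, scale)
    aniso_corrs <- list()
    skew <- NULL
    for (i in seq_along(p$R_aniso)) {
      traj <- with_stage("simulate", simulate_newtonian(
        p$R_aniso[[i]], p$kz_main,
        sim_config(na, p$t_max_aniso, seed = seed + 100 + i,
                   save_stride = p$stride)))
      comp <- cylindrical_decompose(traj, unwrap = FALSE)
      if (i == 1L) skew <- radial_skewness(comp)
      aniso_corrs[[i]] <- with_stage("correlate", compute_correlations(comp))
    }
    an <- with_stage("anisotropy", radial_anisotropy(aniso_corrs, p$R_aniso))
    # azimuthal diffusion is free (linear MSD at every lag), so the slope
    # is read where the estimator is most precise
    summary <- list(
      msd_theta_slope = terminal_theta_slope(main, min_lag = 1, max_lag = 20),
      msd_r_plateau = plateau_of(main, "r"),
      msd_z_plateau = plateau_of(main, "z"),
      master_collapse_msd = mc$collapse_msd,
      anisotropy_exponent = an$exponent,
      anisotropy_plateaus = setNames(an$plateaus$plateau,
                                     paste0("R", p$R_aniso)),
      radial_skewness_smallest_R = skew$skewness,
      n_particles = n
    )
  } else if (preset$name %in% c("fig4_jeffreys_stiff", "fig4_jeffreys_soft")) {
    n <- scaled_n(p$n_particles, scale)
    per_de <- list()
    for (i in seq_along(p$De_values)) {
      De <- p$De_values[[i]]
      plan <- jeffreys_run_plan(p$kstar_over_kr, De, p$kz_over_kr)
      traj <- with_stage("simulate", simulate_jeffreys(
        p$R_hat, p$kz_over_kr, p$kstar_over_kr, De,
        sim_config(n, plan$t_max, dt_hat = plan$dt, seed = seed + i,
                   save_stride = plan$stride)))
      co <- with_stage("correlate",
                       compute_correlations(cylindrical_decompose(traj)))
      corrs[[i]] <- co
      emit(co, sprintf("correlations_De%g.csv", De))
      inv <- with_stage("invert",
                        invert_azimuthal(co, si, p$kstar_over_kr, De,
                                         plan$tau_hat))
      emit(inv$curve, sprintf("modulus_De%g.csv", De))
      per_de[[paste0("De", De)]] <- list(
        terminal_theta_slope = terminal_theta_slope(
          co, min_lag = max(20 * plan$tau_hat, 10)),
        var_z_hat = plateau_of(co, "z") / 2,
        G_rel_err = inv$G_rel_err,
        tau_rel_err = inv$tau_rel_err,
        recovered_G = inv$fit$estimate[["G"]],
        recovered_tau = inv$fit$estimate[["tau"]]
      )
    }
    summary <- c(per_de, list(n_particles = n))
  } else if (preset$name == "fig5_sweep") {
    n <- scaled_n(p$n_particles, scale)
    cell <- list()
    k <- 0L
    for (q in p$kstar_list) for (De in p$De_values) {
      k <- k + 1L
      plan <- jeffreys_run_plan(q, De, p$kz_over_kr)
      traj <- with_stage("simulate", simulate_jeffreys(
        p$R_hat, p$kz_over_kr, q, De,
        sim_config(n, plan$t_max, dt_hat = plan$dt, seed = seed + k,
                   save_stride = plan$stride)))
      co <- with_stage("correlate",
                       compute_correlations(cylindrical_decompose(traj)))
      corrs[[k]] <- co
      emit(co, sprintf("correlations_q%g_De%g.csv", q, De))
      cell[[sprintf("q%g_De%g", q, De)]] <- list(
        terminal_theta_slope = terminal_theta_slope(
          co, min_lag = max(20 * plan$tau_hat, 10)),
        expected_terminal_slope = 2 / (1 + De),
        var_z_hat = plateau_of(co, "z") / 2
      )
    }
    summary <- c(cell, list(n_particles = n))
  } else if (preset$name == "fig6_actin") {
    n <- scaled_n(p$n_particles, scale)
    plan <- jeffreys_run_plan(p$kstar_over_kr, p$De, p$kz_over_kr)
    plan$t_max <- 20 * plan$tau_hat # horizon: twenty fluid relaxation times
    traj <- with_stage("simulate", simulate_jeffreys(
      p$R_hat, p$kz_over_kr, p$kstar_over_kr, p$De,
      sim_config(n, plan$t_max, dt_hat = plan$dt, seed = seed,
                 save_stride = plan$stride)))
    co <- with_stage("correlate",
                     compute_correlations(cylindrical_decompose(traj)))
    corrs[[1L]] <- co
    emit(co, "correlations_fig6.csv")
    inv <- with_stage("invert",
                      invert_azimuthal(co, si, p$kstar_over_kr, p$De,
                                       plan$tau_hat))
    emit(inv$curve, "modulus_fig6.csv")
    G_true <- p$kstar_over_kr * si$kappa_r / (6 * pi * si$a)
    summary <- list(
      De = p$De,
      configured_G = G_true,
      recovered_G = inv$fit$estimate[["G"]],
      recovered_tau = inv$fit$estimate[["tau"]],
      G_rel_err = inv$G_rel_err,
      tau_rel_err = inv$tau_rel_err,
      r_channel_g_prime_plateau = trapped_channel_plateau(co, si, "r"),
      z_channel_g_prime_plateau = trapped_channel_plateau(co, si, "z"),
      expected_r_plateau = si$kappa_r / (6 * pi * si$a),
      expected_z_plateau = p$kz_over_kr * si$kappa_r / (6 * pi * si$a),
      n_particles = n
    )
  }

  out <- structure(
    list(name = preset$name, seed = seed, scale = scale, params = p,
         si = si, summary = summary, correlations = corrs,
         artifacts = artifacts,
         package_version = as.character(utils::packageVersion("halorheo"))),
    class = "halo_experiment"
  )
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(name = out$name, seed = seed, scale = scale,
           package_version = out$package_version, summary = summary),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note_written(path)
    out$artifacts <- c(out$artifacts, path)
  }
  out
}

#' @export
print.halo_experiment <- function(x, ...) {
  cat(sprintf("<halo experiment> %s (seed %s, scale %g)\n",
              x$name, format(x$seed), x$scale))
  utils::str(x$summary, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Deterministic mini-ensembles for tests
#'
#' Sub-second fixtures (at most 32 particles, 4096 recorded steps) used by
#' the test-suite: a 1D trapped (Ornstein-Uhlenbeck) channel, a small
#' Newtonian ring, and a small Jeffreys ring. Bit-stable across runs at a
#' fixed seed.
#'
#' @param kind One of `"ou_1d"`, `"newtonian_ring_small"`,
#'   `"jeffreys_ring_small"`.
#' @param seed Integer seed.
#' @return A `halo_trajectory` tibble.
#' @export
fixture_ensemble <- function(kind = c("ou_1d", "newtonian_ring_small",
                                      "jeffreys_ring_small"), seed = 42L) {
  kind <- tryCatch(match.arg(kind), error = function(e) {
    abort(sprintf("unknown fixture kind '%s'.", paste(kind, collapse = ", ")))
  })
  switch(
    kind,
    ou_1d = simulate_ou_1d(1, sim_config(32, 20, dt_hat = 0.01, seed = seed)),
    newtonian_ring_small = simulate_newtonian(
      20, 1 / 3, sim_config(16, 40, dt_hat = 0.01, seed = seed)),
    jeffreys_ring_small = simulate_jeffreys(
      20, 1 / 3, kstar_over_kr = 4, De = 2,
      sim_config(16, 20, dt_hat = 0.005, seed = seed))
  )
}
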