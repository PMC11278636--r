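## Plain-text persistence. Every artifact carries an embedded JSON
## provenance line ("# halorheo: {...}") so it can be regenerated from the
## file alone; numeric payloads round-trip losslessly (shortest
## round-trippable decimal representation).

provenance_header <- function(meta) {
  paste0("# halorheo: ",
         jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"))
}

read_provenance <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# halorheo: ")) return(NULL)
  jsonlite::fromJSON(sub("^# halorheo: ", "", first), simplifyVector = TRUE)
}

write_with_header <- function(df, path, meta) {
  writeLines(provenance_header(meta), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

## base-R reader: strtod parsing is correctly rounded, so the shortest
## round-trippable decimals written by readr re-read to identical doubles
## (write -> read -> write is byte-identical)
read_body <- function(path, col_types = NULL) {
  as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Read and write trajectory ensembles as CSV
#'
#' Flat tabular form (`particle, t_hat, x, y, z[, qx, qy, qz]`) with the
#' full provenance block embedded as a JSON comment line. Positions
#' round-trip at full double precision. Intended for small runs; large
#' ensembles are cheaper to regenerate from their provenance.
#'
#' @param traj A `halo_trajectory`.
#' @param path File path.
#' @return `read_trajectory_csv()` returns the reconstructed
#'   `halo_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  meta <- list(type = "trajectory", params = traj_params(traj),
               n_save = attr(traj, "n_save"),
               n_particles = attr(traj, "n_particles"))
  write_with_header(as_tibble(traj), path, meta)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  meta <- read_provenance(path)
  if (is.null(meta) || !identical(meta$type, "trajectory")) {
    abort("not a halorheo trajectory file (missing provenance header).")
  }
  out <- read_body(path, readr::cols(particle = "i", .default = "d"))
  attr(out, "n_save") <- meta$n_save
  attr(out, "n_particles") <- meta$n_particles
  attr(out, "params") <- meta$params
  class(out) <- c("halo_trajectory", class(out))
  out
}

#' Read and write correlation sets as CSV
#'
#' Long dialect, one row per (lag, component, statistic):
#' `lag, component, statistic, estimate, se, n_pairs`, where `statistic` is
#' `msd`, `npaf` or `nmsd`. The second moments, sampling interval and run
#' provenance are embedded in the JSON header.
#'
#' @param corr A `halo_correlations`.
#' @param path File path.
#' @return `read_correlations_csv()` returns the reconstructed
#'   `halo_correlations`.
#' @export
write_correlations_csv <- function(corr, path) {
  wide <- as_tibble(corr)
  long <- tidyr::pivot_longer(
    wide,
    cols = c("msd", "npaf", "nmsd"),
    names_to = "statistic", values_to = "estimate"
  )
  long$se <- dplyr::case_when(
    long$statistic == "msd" ~ long$msd_se,
    long$statistic == "npaf" ~ long$npaf_se,
    TRUE ~ long$nmsd_se
  )
  long <- dplyr::filter(long, !is.na(.data$estimate))
  long <- dplyr::select(long, lag = "lag_hat", "component", "statistic",
                        "estimate", "se", "n_pairs")
  meta <- list(type = "correlations",
               second_moment = as.list(attr(corr, "second_moment")),
               dt_sample = attr(corr, "dt_sample"),
               R_hat = attr(corr, "R_hat"),
               n_particles = attr(corr, "n_particles"),
               params = attr(corr, "params"))
  write_with_header(long, path, meta)
  invisible(path)
}

#' @rdname write_correlations_csv
#' @export
read_correlations_csv <- function(path) {
  meta <- read_provenance(path)
  if (is.null(meta) || !identical(meta$type, "correlations")) {
    abort("not a halorheo correlations file (missing provenance header).")
  }
  long <- read_body(path, readr::cols(component = "c", statistic = "c",
                                      .default = "d"))
  wide <- tidyr::pivot_wider(long, id_cols = c("lag", "component", "n_pairs"),
                             names_from = "statistic",
                             values_from = c("estimate", "se"))
  ren <- c(lag_hat = "lag", msd = "estimate_msd", msd_se = "se_msd",
           npaf = "estimate_npaf", npaf_se = "se_npaf",
           nmsd = "estimate_nmsd", nmsd_se = "se_nmsd")
  ren <- ren[ren %in% names(wide)]
  wide <- dplyr::rename(wide, dplyr::all_of(ren))
  for (col in c("npaf", "npaf_se", "nmsd", "nmsd_se")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- dplyr::select(wide, "lag_hat", "component", "msd", "msd_se",
                       "npaf", "npaf_se", "nmsd", "nmsd_se", "n_pairs")
  out <- dplyr::arrange(out, match(.data$component, c("r", "z", "theta")),
                        .data$lag_hat)
  attr(out, "second_moment") <- unlist(meta$second_moment)
  attr(out, "dt_sample") <- meta$dt_sample
  attr(out, "R_hat") <- meta$R_hat
  attr(out, "n_particles") <- meta$n_particles
  attr(out, "params") <- meta$params
  class(out) <- c("halo_correlations", class(out))
  out
}

#' Read and write modulus curves as CSV
#'
#' Columns `omega, g_prime, g_loss` plus any logical flag columns
#' (`in_band`, `trap_dominated`). The complex `g_star` column is
#' reconstructed on read.
#'
#' @param curve A [modulus_curve()].
#' @param path File path.
#' @return `read_modulus_csv()` returns the reconstructed `modulus_curve`.
#' @export
write_modulus_csv <- function(curve, path) {
  df <- as_tibble(curve)
  df$g_star <- NULL
  write_with_header(df, path, list(type = "modulus"))
  invisible(path)
}

#' @rdname write_modulus_csv
#' @export
read_modulus_csv <- function(path) {
  meta <- read_provenance(path)
  if (is.null(meta) || !identical(meta$type, "modulus")) {
    abort("not a halorheo modulus file (missing provenance header).")
  }
  df <- read_body(path, readr::cols(omega = "d", g_prime = "d", g_loss = "d",
                                    .default = "l"))
  extra <- df[setdiff(names(df), c("omega", "g_prime", "g_loss"))]
  do.call(modulus_curve,
          c(list(omega = df$omega,
                 g_star = complex(real = df$g_prime, imaginary = df$g_loss)),
            as.list(extra)))
}

## YAML run configurations ---------------------------------------------------

config_schema <- list(
  newtonian = c("kind", "R_hat", "kz_over_kr", "n_particles", "t_max_hat"),
  jeffreys = c("kind", "R_hat", "kz_over_kr", "n_particles", "t_max_hat",
               "kstar_over_kr", "De")
)

#' YAML simulation configurations
#'
#' Flat key-value run descriptions. Required fields: `kind`
#' (`"newtonian"` or `"jeffreys"`), `R_hat`, `kz_over_kr`, `n_particles`,
#' `t_max_hat`; Jeffreys runs additionally need `kstar_over_kr` and `De`.
#' Optional: `dt_hat`, `seed`, `burn_in_hat`, `save_stride`. Any SI
#' quantities belong in an `si:` block with explicit `value`/`unit` pairs;
#' dimensionless conversion is always explicit through [unit_system()].
#' Schema violations are rejected with the offending field named.
#'
#' @param path YAML file path.
#' @param config A validated configuration list.
#' @return `read_halo_config()` returns the validated list;
#'   `simulate_from_config()` runs it and returns the trajectory.
#' @export
read_halo_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_halo_config(cfg)
}

#' @rdname read_halo_config
#' @export
write_halo_config <- function(config, path) {
  validate_halo_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_halo_config
#' @export
validate_halo_config <- function(config) {
  if (!is.list(config) || is.null(config$kind)) {
    abort("config field `kind` is missing.")
  }
  if (!config$kind %in% names(config_schema)) {
    abort(sprintf("config field `kind` must be one of %s.",
                  paste(names(config_schema), collapse = ", ")))
  }
  required <- config_schema[[config$kind]]
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(sprintf("config field `%s` is missing.", missing[1L]))
  }
  for (f in setdiff(required, "kind")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1L) {
      abort(sprintf("config field `%s` must be a single number.", f))
    }
  }
  if (!is.null(config$si)) {
    for (nm in names(config$si)) {
      entry <- config$si[[nm]]
      if (!is.list(entry) || is.null(entry$value) || is.null(entry$unit)) {
        abort(sprintf("config SI field `%s` needs `value` and `unit`.", nm))
      }
    }
  }
  config
}

#' @rdname read_halo_config
#' @export
simulate_from_config <- function(config) {
  config <- validate_halo_config(config)
  cfg <- sim_config(
    n_particles = config$n_particles,
    t_max_hat = config$t_max_hat,
    dt_hat = config$dt_hat,
    seed = config$seed %||% 1L,
    burn_in_hat = config$burn_in_hat,
    save_stride = config$save_stride %||% 1L
  )
  if (config$kind == "newtonian") {
    simulate_newtonian(config$R_hat, config$kz_over_kr, cfg)
  } else {
    simulate_jeffreys(config$R_hat, config$kz_over_kr,
                      config$kstar_over_kr, config$De, cfg)
  }
}
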