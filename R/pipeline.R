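## Pipeline orchestration and file I/O.  File formats:
##  - observations CSV: temperature_C, thickness_mm, duration_s,
##    release_pct, sigma_pct (one header row, decimal point, UTF-8)
##  - sweep CSV: temperature_C, thickness_mm, duration_s, n_atoms, seed,
##    release_pct
##  - activities CSV: material, C_initial_Bq, C_final_Bq, C_catcher_Bq
##  - fit report: JSON {E_des_hat, uncertainty, grid, engine, n_atoms,
##    seed, sse_profile[], config}
## Temperatures in files are degC, as in laboratory practice; kelvin
## internally.

.OBS_COLS <- c("temperature_C", "thickness_mm", "duration_s",
               "release_pct", "sigma_pct")

#' Run configuration
#'
#' Bundles every parameter of a pipeline run so the run is reproducible
#' from its report alone.
#'
#' @param E_des desorption energy for forward simulation, kJ/mol.
#' @param grid an [enthalpy_grid()] for fitting.
#' @param n_atoms Monte Carlo atoms per simulation.
#' @param seed master integer seed.
#' @param engine `"monte_carlo"` or `"semi_analytic"`.
#' @param noise a [noise_model()].
#' @param diff a [diffusion_law()].
#' @param tau0 desorption-law oscillation period, s.
#' @return An object of class `run_config` (a fully serialisable list).
#' @export
run_config <- function(E_des = 390, grid = enthalpy_grid(),
                       n_atoms = 10000L, seed = 1L,
                       engine = c("monte_carlo", "semi_analytic"),
                       noise = noise_model(), diff = diffusion_law(),
                       tau0 = 1.6e-13) {
  engine <- match.arg(engine)
  structure(list(E_des = E_des, grid = grid, n_atoms = as.integer(n_atoms),
                 seed = as.integer(seed), engine = engine, noise = noise,
                 diff = diff, tau0 = tau0),
            class = "run_config")
}

.config_as_list <- function(config) {
  list(E_des = config$E_des,
       grid = list(E_min = config$grid$E_min, E_max = config$grid$E_max,
                   step = config$grid$step),
       n_atoms = config$n_atoms, seed = config$seed, engine = config$engine,
       noise = list(counting_rel_sigma = config$noise$counting_rel_sigma,
                    systematic_rel_sigma = config$noise$systematic_rel_sigma),
       diffusion = list(slope = config$diff$slope,
                        intercept = config$diff$intercept),
       tau0 = config$tau0)
}

#' Forward simulation of release sweeps
#'
#' Runs the Monte Carlo temperature sweep (850-1150 degC in 25 degC steps
#' at 0.025 mm) and/or the thickness sweep (0.025-1 mm foils at 1100 degC),
#' both at 2 h heating, and writes one CSV per sweep.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param sweeps which sweeps to run, subset of
#'   `c("temperature", "thickness")`.
#' @return (invisibly) named list of written file paths.
#' @export
run_simulate <- function(config = run_config(), out_dir = ".",
                         sweeps = c("temperature", "thickness")) {
  stopifnot(inherits(config, "run_config"))
  sweeps <- match.arg(sweeps, several.ok = TRUE)
  if (config$n_atoms < 1L) stop("`n_atoms` must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  des <- desorption_law(config$E_des, tau0 = config$tau0)
  paths <- list()
  if ("temperature" %in% sweeps) {
    sw <- sweep_temperature(d = 0.0025, t_exp = 7200, diff = config$diff,
                            des = des, n_atoms = config$n_atoms,
                            seed = config$seed)
    out <- data.frame(temperature_C = sw$temperature_K - 273.15,
                      thickness_mm = 0.025, duration_s = 7200,
                      n_atoms = config$n_atoms, seed = sw$seed,
                      release_pct = 100 * sw$release_fraction)
    paths$temperature <- file.path(out_dir, "sweep_temperature.csv")
    utils::write.csv(out, paths$temperature, row.names = FALSE)
  }
  if ("thickness" %in% sweeps) {
    sw <- sweep_thickness(T = celsius(1100), t_exp = 7200, diff = config$diff,
                          des = des, n_atoms = config$n_atoms,
                          seed = config$seed + 1L)
    out <- data.frame(temperature_C = 1100,
                      thickness_mm = 10 * sw$thickness_cm, duration_s = 7200,
                      n_atoms = config$n_atoms, seed = sw$seed,
                      release_pct = 100 * sw$release_fraction)
    paths$thickness <- file.path(out_dir, "sweep_thickness.csv")
    utils::write.csv(out, paths$thickness, row.names = FALSE)
  }
  message("run_simulate: wrote ", length(paths), " sweep file(s) to ", out_dir,
          " (seed ", config$seed, ")")
  invisible(paths)
}

#' Synthesize a measurement dataset on disk
#'
#' Generates a synthetic dataset ([generate_dataset()]) and writes the
#' observations CSV, the activities CSV and a sidecar JSON recording the
#' generating truth and the full configuration.
#'
#' @param config a [run_config()]; `E_des` is the generating truth.
#' @param out_dir output directory.
#' @param conditions condition list; default [reference_conditions()].
#' @return (invisibly) list of written paths (`observations`,
#'   `activities`, `truth`).
#' @export
run_synthesize <- function(config = run_config(), out_dir = ".",
                           conditions = reference_conditions()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(true_E_des = config$E_des, conditions = conditions,
                         diff = config$diff, noise = config$noise,
                         seed = config$seed)
  obs_df <- observations_to_df(ds$observations)
  act_df <- data.frame(
    material = names(ds$activity_triples),
    C_initial_Bq = vapply(ds$activity_triples, `[[`, numeric(1), "C_initial"),
    C_final_Bq = vapply(ds$activity_triples, `[[`, numeric(1), "C_final"),
    C_catcher_Bq = vapply(ds$activity_triples, `[[`, numeric(1), "C_catcher"),
    row.names = NULL)
  paths <- list(observations = file.path(out_dir, "observations.csv"),
                activities = file.path(out_dir, "activities.csv"),
                truth = file.path(out_dir, "truth.json"))
  utils::write.csv(obs_df, paths$observations, row.names = FALSE)
  utils::write.csv(act_df, paths$activities, row.names = FALSE)
  jsonlite::write_json(
    list(true_E_des = ds$true_E_des,
         true_recovery = as.list(ds$true_recovery),
         config = .config_as_list(config)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("run_synthesize: wrote dataset (", length(ds$observations),
          " observations, seed ", config$seed, ") to ", out_dir)
  invisible(paths)
}

#' Observations list -> standard data.frame
#' @param observations list of [release_observation()]s.
#' @return data.frame with the standard observation columns.
#' @export
observations_to_df <- function(observations) {
  data.frame(
    temperature_C = vapply(observations, function(o)
      o$condition$temperature - 273.15, numeric(1)),
    thickness_mm = vapply(observations, function(o)
      10 * o$condition$thickness, numeric(1)),
    duration_s = vapply(observations, function(o)
      o$condition$duration, numeric(1)),
    release_pct = vapply(observations, `[[`, numeric(1), "release_pct"),
    sigma_pct = vapply(observations, `[[`, numeric(1), "sigma_pct"))
}

#' Read an observations CSV into a list of release observations
#'
#' Validates the schema (columns `temperature_C`, `thickness_mm`,
#' `duration_s`, `release_pct`, `sigma_pct`) and every row's physical
#' ranges; errors name the offending row and column.
#'
#' @param path path to the CSV file.
#' @return list of [release_observation()]s.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  missing <- setdiff(.OBS_COLS, names(df))
  if (length(missing)) {
    stop("observations file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    for (col in .OBS_COLS) {
      if (!is.numeric(row[[col]]) || is.na(row[[col]])) {
        stop("row ", i, ", column '", col, "': non-numeric or missing value",
             call. = FALSE)
      }
    }
    tryCatch(
      release_observation(
        experiment_condition(celsius(row$temperature_C),
                             row$thickness_mm / 10, row$duration_s),
        row$release_pct, row$sigma_pct),
      error = function(e) {
        stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
      })
  })
}

#' Fit the desorption enthalpy from an observations file
#'
#' Reads the observations CSV, runs [fit_enthalpy()] and
#' [estimate_uncertainty()], and writes a JSON fit report embedding the
#' configuration.
#'
#' @param config a [run_config()].
#' @param observations_csv path to the observations CSV.
#' @param out path of the JSON report.
#' @param n_bootstrap bootstrap replicates for the uncertainty.
#' @return (invisibly) the completed [fit_enthalpy()] result.
#' @export
run_fit <- function(config = run_config(), observations_csv,
                    out = "fit_report.json", n_bootstrap = 50L) {
  stopifnot(inherits(config, "run_config"))
  obs <- read_observations(observations_csv)
  des_template <- desorption_law(config$E_des, tau0 = config$tau0)
  fit <- fit_enthalpy(obs, config$grid, config$diff, des_template,
                      n_atoms = config$n_atoms, seed = config$seed,
                      engine = config$engine)
  fit <- estimate_uncertainty(fit, obs, n_bootstrap = n_bootstrap,
                              seed = config$seed, diff = config$diff,
                              des_template = des_template)
  report <- list(
    E_des_hat = fit$E_des_hat,
    adsorption_enthalpy = -fit$E_des_hat,
    uncertainty = fit$uncertainty,
    uncertainty_method = sprintf("residual bootstrap, %d replicates",
                                 as.integer(n_bootstrap)),
    at_boundary = fit$at_boundary,
    grid = list(E_min = fit$grid$E_min, E_max = fit$grid$E_max,
                step = fit$grid$step),
    engine = fit$engine, n_atoms = fit$n_atoms_per_point, seed = fit$seed,
    sse_profile = fit$sse_profile,
    n_observations = length(obs),
    config = .config_as_list(config))
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  message("run_fit: E_des = ", fit$E_des_hat, " +/- ", round(fit$uncertainty, 2),
          " kJ/mol (", fit$engine, " engine); report at ", out)
  invisible(fit)
}

#' Human-readable run summary
#'
#' Renders a table of observed versus modelled release at the fitted
#' enthalpy, alongside the diffusion-only arrival probability, and flags
#' the temperatures where desorption (not diffusion) limits the release —
#' i.e. where the diffusion-only curve exceeds the full model
#' appreciably.
#'
#' @param fit_report_json path to a JSON report from [run_fit()].
#' @param observations_csv path to the observations CSV used for the fit.
#' @param threshold_pct flag conditions where the diffusion-only curve
#'   exceeds the full model by more than this many percentage points.
#'   Default 5.
#' @return (invisibly) the summary data.frame (one row per observation:
#'   condition, observed, model_pct, diffusion_only_pct,
#'   desorption_limited).
#' @export
run_report <- function(fit_report_json, observations_csv, threshold_pct = 5) {
  rep <- tryCatch(jsonlite::read_json(fit_report_json, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse fit report ", fit_report_json, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (fld in c("E_des_hat", "config")) {
    if (is.null(rep[[fld]])) {
      stop("fit report lacks field '", fld, "'", call. = FALSE)
    }
  }
  obs <- read_observations(observations_csv)
  diff <- diffusion_law(rep$config$diffusion$slope,
                        rep$config$diffusion$intercept)
  des <- desorption_law(rep$E_des_hat, tau0 = rep$config$tau0)

  if (length(obs) == 0) {
    warning("no observations; nothing to summarise", call. = FALSE)
    return(invisible(data.frame()))
  }
  model_pct <- 100 * vapply(lapply(obs, `[[`, "condition"),
                            semi_analytic_release, numeric(1),
                            diff = diff, des = des)
  diffusion_pct <- 100 * vapply(obs, function(o)
    arrival_cdf(diff, o$condition, o$condition$duration), numeric(1))
  df <- observations_to_df(obs)
  df$model_pct <- model_pct
  df$diffusion_only_pct <- diffusion_pct
  df$desorption_limited <- diffusion_pct - model_pct > threshold_pct

  cat(sprintf("Desorption-enthalpy fit: E_des = %.1f kJ/mol (dH_a = %.1f), +/- %.1f kJ/mol\n",
              rep$E_des_hat, -rep$E_des_hat,
              if (is.null(rep$uncertainty)) NA_real_ else rep$uncertainty))
  cat("Observed vs modelled release (percent):\n")
  print(format(df, digits = 4), row.names = FALSE)
  lim <- df$temperature_C[df$desorption_limited]
  if (length(lim)) {
    cat(sprintf(
      "Desorption limits the release at %d condition(s) (e.g. %s degC): the diffusion-only curve overpredicts by > %g points there.\n",
      length(lim), paste(utils::head(unique(lim), 6), collapse = ", "),
      threshold_pct))
  } else {
    cat("Release is diffusion-limited at every condition.\n")
  }
  invisible(df)
}
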