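## Grid-search least-squares extraction of the Sc/Ti desorption enthalpy
## from release-versus-condition observations.  The release curve as a
## function of temperature is a sigmoid whose position is very sensitive to
## the desorption energy, so a coarse 1 kJ/mol grid already localises it.

#' Desorption-energy search grid
#'
#' @param E_min,E_max grid bounds in kJ/mol (`E_min < E_max`). Defaults
#'   385 and 395.
#' @param step grid step in kJ/mol (> 0, must divide the span exactly).
#'   Default 1.
#' @return An object of class `enthalpy_grid`.
#' @export
enthalpy_grid <- function(E_min = 385, E_max = 395, step = 1) {
  stopifnot(is.numeric(E_min), is.numeric(E_max), is.numeric(step))
  if (E_min >= E_max) stop("`E_min` must be < `E_max`", call. = FALSE)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  n_int <- (E_max - E_min) / step
  if (abs(n_int - round(n_int)) > 1e-9) {
    stop("(E_max - E_min) must be a whole number of steps", call. = FALSE)
  }
  structure(list(E_min = E_min, E_max = E_max, step = step),
            class = "enthalpy_grid")
}

#' Grid values of an enthalpy grid, kJ/mol
#' @param grid an [enthalpy_grid()].
#' @return numeric vector of desorption energies.
#' @export
grid_values <- function(grid) {
  stopifnot(inherits(grid, "enthalpy_grid"))
  seq(grid$E_min, grid$E_max, by = grid$step)
}

#' Sum of squared residuals between observed and predicted release
#'
#' Residuals are taken on the percent-release scale,
#' `obs_pct - 100 * predicted_fraction`. With `weighting = "none"` all
#' weights are 1; with `"inverse_variance"` each squared residual is
#' divided by the observation's `sigma_pct^2`.
#'
#' @param observations list of [release_observation()]s.
#' @param predictions numeric vector of predicted release fractions, one
#'   per observation, in the same order (conditions must correspond).
#' @param weighting `"none"` (default) or `"inverse_variance"`.
#' @return the (weighted) sum of squared residuals, in percent^2.
#' @export
sse <- function(observations, predictions,
                weighting = c("none", "inverse_variance")) {
  weighting <- match.arg(weighting)
  stopifnot(is.list(observations), is.numeric(predictions))
  if (length(observations) != length(predictions)) {
    stop("`observations` and `predictions` must align one-to-one",
         call. = FALSE)
  }
  obs_pct <- vapply(observations, function(o) o$release_pct, numeric(1))
  resid <- obs_pct - 100 * predictions
  w <- if (weighting == "inverse_variance") {
    sig <- vapply(observations, function(o) o$sigma_pct, numeric(1))
    if (any(sig <= 0)) {
      stop("inverse-variance weighting needs strictly positive sigma_pct",
           call. = FALSE)
    }
    1 / sig^2
  } else {
    rep(1, length(resid))
  }
  sum(w * resid^2)
}

## forward model: predicted release fractions for a set of conditions at one
## desorption energy.  The MC engine reuses the same master seed for every
## energy value (common random numbers), which makes the SSE profile smooth
## in E and its argmin stable at 10^4 atoms.
.predict_release <- function(conditions, diff, des, engine, n_atoms, seed) {
  if (engine == "semi_analytic") {
    vapply(conditions, semi_analytic_release, numeric(1),
           diff = diff, des = des)
  } else {
    seeds <- .sub_seeds(seed, length(conditions))
    vapply(seq_along(conditions), function(i) {
      simulate_release(conditions[[i]], diff, des, n_atoms,
                       seeds[i])$release_fraction
    }, numeric(1))
  }
}

#' Grid-search least-squares fit of the desorption enthalpy
#'
#' Evaluates the forward release model at every desorption energy of the
#' grid and returns the energy minimising the (optionally weighted) sum of
#' squared release residuals. With `engine = "monte_carlo"` the same master
#' seed is reused at every grid value, so the noise in the SSE profile is
#' common across energies and the argmin is stable; with
#' `engine = "semi_analytic"` the profile is noise-free.
#'
#' Observations are sorted internally by (temperature, thickness,
#' duration), so the estimate is invariant to their order. Ties in the SSE
#' profile resolve to the smallest energy.
#'
#' @param observations list of [release_observation()]s; at least two,
#'   spanning at least two distinct temperatures (otherwise the sigmoid
#'   position is unidentifiable and a warning is raised).
#' @param grid an [enthalpy_grid()].
#' @param diff a [diffusion_law()].
#' @param des_template a [desorption_law()] supplying `tau0`; its `E_des`
#'   is ignored.
#' @param n_atoms Monte Carlo atoms per (grid value, condition) pair.
#' @param seed master integer seed (used by the MC engine).
#' @param weighting passed to [sse()].
#' @param refine if `TRUE`, a parabolic interpolation through the three
#'   profile points around the minimum refines the estimate below the grid
#'   step. Off by default: the estimator reports a grid value.
#' @param engine `"monte_carlo"` (default) or `"semi_analytic"`.
#' @return An object of class `fit_result`: `E_des_hat` (kJ/mol),
#'   `sse_profile` (data.frame E_des, sse), `uncertainty` (kJ/mol, NA until
#'   [estimate_uncertainty()] is run), `n_atoms_per_point`, `seed`,
#'   `engine`, `weighting`, `at_boundary`.
#' @export
fit_enthalpy <- function(observations, grid = enthalpy_grid(), diff,
                         des_template = desorption_law(390), n_atoms = 10000L,
                         seed = 1L,
                         weighting = c("none", "inverse_variance"),
                         refine = FALSE,
                         engine = c("monte_carlo", "semi_analytic")) {
  engine <- match.arg(engine)
  weighting <- match.arg(weighting)
  stopifnot(inherits(grid, "enthalpy_grid"), inherits(diff, "diffusion_law"),
            inherits(des_template, "desorption_law"))
  if (length(observations) == 0) {
    stop("no observations supplied", call. = FALSE)
  }
  ## canonical observation order -> order-invariant estimator
  key <- vapply(observations, function(o) {
    sprintf("%.9e|%.9e|%.9e", o$condition$temperature,
            o$condition$thickness, o$condition$duration)
  }, character(1))
  observations <- observations[order(key)]
  conditions <- lapply(observations, `[[`, "condition")

  temps <- vapply(conditions, `[[`, numeric(1), "temperature")
  if (length(observations) < 2L || length(unique(temps)) < 2L) {
    warning("fit is degenerate: need >= 2 observations at >= 2 distinct temperatures",
            call. = FALSE)
  }

  E_vals <- grid_values(grid)
  sse_vals <- vapply(E_vals, function(E) {
    des <- desorption_law(E, tau0 = des_template$tau0)
    pred <- .predict_release(conditions, diff, des, engine, n_atoms, seed)
    sse(observations, pred, weighting)
  }, numeric(1))

  if (max(sse_vals) - min(sse_vals) == 0) {
    warning("SSE profile is flat across the grid; estimate is not informative",
            call. = FALSE)
  }
  i_min <- which.min(sse_vals)
  E_hat <- E_vals[i_min]
  at_boundary <- i_min == 1L || i_min == length(E_vals)
  if (at_boundary) {
    warning("SSE minimum lies on the grid boundary (", E_hat,
            " kJ/mol); widen the grid", call. = FALSE)
  }
  if (refine && !at_boundary) {
    ## parabola through the three points bracketing the minimum
    y <- sse_vals[(i_min - 1L):(i_min + 1L)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom > 0) {
      E_hat <- E_hat + grid$step * 0.5 * (y[1] - y[3]) / denom
    }
  }

  structure(list(E_des_hat = E_hat,
                 sse_profile = data.frame(E_des = E_vals, sse = sse_vals),
                 uncertainty = NA_real_,
                 n_atoms_per_point = as.integer(n_atoms),
                 seed = as.integer(seed),
                 engine = engine,
                 weighting = weighting,
                 grid = grid,
                 at_boundary = at_boundary),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  unc <- if (is.na(x$uncertainty)) "not estimated" else
    sprintf("+/- %.1f kJ/mol (bootstrap)", x$uncertainty)
  cat(sprintf(
    "Desorption-enthalpy fit (%s engine, %s weighting)\n  E_des = %.2f kJ/mol (adsorption enthalpy dH_a = %.2f kJ/mol)\n  uncertainty: %s\n  grid: %g..%g kJ/mol, step %g; %d atoms/point; seed %d\n",
    x$engine, x$weighting, x$E_des_hat, -x$E_des_hat, unc,
    x$grid$E_min, x$grid$E_max, x$grid$step, x$n_atoms_per_point, x$seed))
  invisible(x)
}

#' Residual-bootstrap uncertainty of the fitted desorption enthalpy
#'
#' Resamples the percent-scale residuals of the fitted model with
#' replacement, adds them back onto the fitted curve, refits each
#' replicate, and reports the half-width of the central 68% interval of
#' the refitted energies, floored at half the grid step (a grid search
#' cannot resolve the estimate below that).
#'
#' @param fit a [fit_result] from [fit_enthalpy()].
#' @param observations the observation list used in the fit (>= 3).
#' @param n_bootstrap number of bootstrap replicates (>= 1; fewer than 10
#'   triggers a warning).
#' @param seed integer seed for the resampling.
#' @param diff the [diffusion_law()] used in the fit.
#' @param des_template [desorption_law()] template (for `tau0`).
#' @param engine engine for the bootstrap refits; the noise-free
#'   semi-analytic engine is the default regardless of the point fit's
#'   engine (the two profiles share their argmin).
#' @return the `fit_result` with its `uncertainty` field (kJ/mol) filled
#'   in, plus a `bootstrap_estimates` vector.
#' @export
estimate_uncertainty <- function(fit, observations, n_bootstrap = 50L, seed = 1L,
                                 diff = diffusion_law(),
                                 des_template = desorption_law(390),
                                 engine = "semi_analytic") {
  stopifnot(inherits(fit, "fit_result"))
  if (length(observations) < 3L) {
    stop("bootstrap needs at least 3 observations to resample residuals from",
         call. = FALSE)
  }
  n_bootstrap <- as.integer(n_bootstrap)
  if (is.na(n_bootstrap) || n_bootstrap < 1L) {
    stop("`n_bootstrap` must be >= 1", call. = FALSE)
  }
  if (n_bootstrap < 10L) {
    warning("fewer than 10 bootstrap replicates; uncertainty is crude",
            call. = FALSE)
  }

  conditions <- lapply(observations, `[[`, "condition")
  des_hat <- desorption_law(fit$E_des_hat, tau0 = des_template$tau0)
  fitted_pct <- 100 * vapply(conditions, semi_analytic_release, numeric(1),
                             diff = diff, des = des_hat)
  obs_pct <- vapply(observations, function(o) o$release_pct, numeric(1))
  resid <- obs_pct - fitted_pct

  reps <- withr::with_seed(as.integer(seed), {
    replicate(n_bootstrap, {
      new_pct <- pmin(100, pmax(0, fitted_pct +
                                  sample(resid, length(resid), replace = TRUE)))
      new_obs <- lapply(seq_along(observations), function(i) {
        release_observation(conditions[[i]], new_pct[i],
                            observations[[i]]$sigma_pct)
      })
      suppressWarnings(
        fit_enthalpy(new_obs, fit$grid, diff, des_template,
                     n_atoms = fit$n_atoms_per_point, seed = fit$seed,
                     weighting = fit$weighting, engine = engine)$E_des_hat
      )
    })
  })
  half_width <- unname(diff_quantile_halfwidth(reps))
  fit$uncertainty <- max(half_width, fit$grid$step / 2)
  fit$bootstrap_estimates <- reps
  fit
}

## half-width of the central 68% interval
diff_quantile_halfwidth <- function(x) {
  q <- stats::quantile(x, c(0.16, 0.84), names = FALSE, type = 7)
  (q[2] - q[1]) / 2
}
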