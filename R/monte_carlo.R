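## Two-step atom-history Monte Carlo: each simulated Sc atom first diffuses
## to the foil surface (arrival time drawn from the truncated first-term
## slab CDF), then waits an exponential adsorption residence time before
## evaporating into vacuum.  Vacuum is a perfect sink; atoms are independent
## (tracer level).

#' Inverse-CDF sample of the surface-arrival time
#'
#' Maps uniform deviates onto the arrival-time distribution implied by the
#' first-term slab CDF, truncated at the experiment duration:
#' * `u <= 1 - 8/pi^2` -> arrival at t = 0 (the point mass of immediate
#'   surface presence);
#' * `u <= F(t_exp)` -> `t = -tau_D * log(pi^2 (1 - u) / 8)` with
#'   `tau_D = d^2/D(T)`;
#' * `u > F(t_exp)` -> the atom never reaches the surface (NA_real_).
#'
#' Sampling is exact and rejection-free. A zero-duration experiment gives
#' no time for transport: every atom is reported as never arriving.
#'
#' @param u uniform(0,1) deviate(s); vectorised. Values must lie in \[0, 1).
#' @param condition an [experiment_condition()].
#' @param diff a [diffusion_law()].
#' @return arrival time(s) in seconds within \[0, t_exp\], or `NA_real_`
#'   for atoms that never arrive.
#' @export
sample_arrival_time <- function(u, condition, diff) {
  stopifnot(is.numeric(u), inherits(condition, "experiment_condition"),
            inherits(diff, "diffusion_law"))
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1)) {
    stop("`u` must lie in [0, 1)", call. = FALSE)
  }
  if (condition$duration == 0) {
    return(rep(NA_real_, length(u)))
  }
  p0 <- 1 - 8 / pi^2
  F_end <- arrival_cdf(diff, condition, condition$duration)
  tau_d <- condition$thickness^2 /
    diffusion_coefficient(diff, condition$temperature)
  t <- ifelse(u <= p0, 0, -tau_d * log(pi^2 * (1 - u) / 8))
  t[u > F_end] <- NA_real_
  t
}

#' Simulate the history of a single Sc atom
#'
#' Draws a surface-arrival time; an atom that never arrives is retained in
#' the bulk.  An arrived atom draws an exponential residence time with mean
#' [mean_residence_time()]; if arrival + residence falls within the
#' experiment duration the atom has evaporated into vacuum, otherwise it is
#' still adsorbed on the surface at the end of the run.
#'
#' Consumes exactly two deviates from the current RNG stream (arrival and
#' residence; the residence draw is discarded for retained atoms) so that
#' stream alignment is independent of atom fates.
#'
#' @param condition an [experiment_condition()].
#' @param diff a [diffusion_law()].
#' @param des a [desorption_law()].
#' @return a list with `category` (one of `"retained_in_bulk"`,
#'   `"adsorbed_on_surface"`, `"evaporated"`) and `arrival_time` (seconds,
#'   or `NA_real_` for retained atoms), of class `atom_fate`.
#' @export
simulate_atom <- function(condition, diff, des) {
  u <- stats::runif(2L)
  arrival <- sample_arrival_time(u[1L], condition, diff)
  if (is.na(arrival)) {
    fate <- list(category = "retained_in_bulk", arrival_time = NA_real_)
  } else {
    tau_a <- mean_residence_time(des, condition$temperature)
    residence <- -tau_a * log1p(-u[2L])
    category <- if (arrival + residence <= condition$duration) {
      "evaporated"
    } else {
      "adsorbed_on_surface"
    }
    fate <- list(category = category, arrival_time = arrival)
  }
  structure(fate, class = "atom_fate")
}

#' Monte Carlo release simulation
#'
#' Simulates `n_atoms` independent atom histories at one experimental
#' condition and tallies the three fates. Each atom consumes exactly two
#' uniform deviates in atom order, so a run is bit-reproducible for a fixed
#' seed and the same deviates are reused across desorption-law values when
#' the seed is held fixed (common random numbers).
#'
#' @param condition an [experiment_condition()].
#' @param diff a [diffusion_law()].
#' @param des a [desorption_law()].
#' @param n_atoms number of atom histories (>= 1). Default 10000.
#' @param seed integer seed for reproducibility.
#' @return An object of class `mc_release`: counts `n_atoms`,
#'   `n_evaporated`, `n_surface`, `n_bulk` (summing to `n_atoms`),
#'   `release_fraction = n_evaporated/n_atoms`, and the `seed`.
#' @examples
#' cond <- experiment_condition(celsius(1100), 0.0025, 7200)
#' simulate_release(cond, diffusion_law(), desorption_law(390), seed = 1)
#' @export
simulate_release <- function(condition, diff, des, n_atoms = 10000L, seed) {
  stopifnot(inherits(condition, "experiment_condition"),
            inherits(diff, "diffusion_law"),
            inherits(des, "desorption_law"))
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop("`n_atoms` must be >= 1", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)

  ## deviates drawn in atom order: u[2i-1] -> arrival, u[2i] -> residence
  u <- withr::with_seed(as.integer(seed), stats::runif(2L * n_atoms))
  u_arr <- u[seq(1L, 2L * n_atoms, by = 2L)]
  u_res <- u[seq(2L, 2L * n_atoms, by = 2L)]

  arrival <- sample_arrival_time(u_arr, condition, diff)
  arrived <- !is.na(arrival)

  tau_a <- mean_residence_time(des, condition$temperature)
  residence <- -tau_a * log1p(-u_res)
  evaporated <- arrived & (arrival + residence <= condition$duration)

  n_evap <- sum(evaporated)
  n_surf <- sum(arrived) - n_evap
  n_bulk <- n_atoms - sum(arrived)

  structure(list(n_atoms = n_atoms,
                 n_evaporated = n_evap,
                 n_surface = n_surf,
                 n_bulk = n_bulk,
                 release_fraction = n_evap / n_atoms,
                 seed = as.integer(seed)),
            class = "mc_release")
}

#' @export
print.mc_release <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo release: %d atoms (seed %d)\n  evaporated %d | on surface %d | in bulk %d\n  release fraction %.4f\n",
    x$n_atoms, x$seed, x$n_evaporated, x$n_surface, x$n_bulk,
    x$release_fraction))
  invisible(x)
}

## deterministic sub-seeds for sweep elements, derived from the master seed
.sub_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Default temperature sweep, kelvin (850-1150 degC in 25 degC steps)
#' @return numeric vector of 13 kelvin temperatures.
#' @export
default_temperatures <- function() celsius(seq(850, 1150, by = 25))

#' Default foil-thickness set, cm (0.025-1 mm foils)
#' @return numeric vector of 6 thicknesses in cm.
#' @export
default_thicknesses <- function() c(0.0025, 0.005, 0.01, 0.025, 0.05, 0.1)

#' Release-versus-temperature sweep
#'
#' Runs one Monte Carlo release simulation per temperature at fixed foil
#' thickness and duration. Each temperature uses an independent sub-seed
#' derived deterministically from the master seed.
#'
#' @param T_list strictly increasing kelvin temperatures; default
#'   [default_temperatures()].
#' @param d foil thickness, cm.
#' @param t_exp heating duration, s.
#' @param diff,des diffusion and desorption laws.
#' @param n_atoms atom histories per temperature.
#' @param seed master integer seed.
#' @return data.frame with columns `temperature_K`, `release_fraction`,
#'   plus list-column-free bookkeeping (`n_evaporated`, `n_surface`,
#'   `n_bulk`, `seed`).
#' @export
sweep_temperature <- function(T_list = default_temperatures(), d, t_exp,
                              diff, des, n_atoms = 10000L, seed) {
  stopifnot(is.numeric(T_list), length(T_list) >= 1L)
  if (is.unsorted(T_list, strictly = TRUE)) {
    stop("`T_list` must be strictly increasing", call. = FALSE)
  }
  seeds <- .sub_seeds(seed, length(T_list))
  rows <- lapply(seq_along(T_list), function(i) {
    cond <- experiment_condition(T_list[i], d, t_exp)
    mc <- simulate_release(cond, diff, des, n_atoms, seeds[i])
    data.frame(temperature_K = T_list[i],
               release_fraction = mc$release_fraction,
               n_evaporated = mc$n_evaporated, n_surface = mc$n_surface,
               n_bulk = mc$n_bulk, seed = mc$seed)
  })
  do.call(rbind, rows)
}

#' Release-versus-thickness sweep
#'
#' Runs one Monte Carlo release simulation per foil thickness at fixed
#' temperature and duration.
#'
#' @param d_list positive thicknesses in cm; default
#'   [default_thicknesses()].
#' @param T temperature, kelvin.
#' @param t_exp heating duration, s.
#' @param diff,des diffusion and desorption laws.
#' @param n_atoms atom histories per thickness.
#' @param seed master integer seed.
#' @return data.frame with columns `thickness_cm`, `release_fraction` and
#'   fate counts.
#' @export
sweep_thickness <- function(d_list = default_thicknesses(), T, t_exp,
                            diff, des, n_atoms = 10000L, seed) {
  stopifnot(is.numeric(d_list), length(d_list) >= 1L)
  if (any(d_list <= 0)) stop("thicknesses must be > 0", call. = FALSE)
  seeds <- .sub_seeds(seed, length(d_list))
  rows <- lapply(seq_along(d_list), function(i) {
    cond <- experiment_condition(T, d_list[i], t_exp)
    mc <- simulate_release(cond, diff, des, n_atoms, seeds[i])
    data.frame(thickness_cm = d_list[i],
               release_fraction = mc$release_fraction,
               n_evaporated = mc$n_evaporated, n_surface = mc$n_surface,
               n_bulk = mc$n_bulk, seed = mc$seed)
  })
  do.call(rbind, rows)
}
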