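## Closed-form physics of the two-step release model:
## slab diffusion to the foil surface (first-term approximation) followed by
## adsorption-desorption from the surface into vacuum.

#' Gas constant used throughout, J/(mol K)
#' @keywords internal
.R_GAS <- 8.314

#' Temperature dependence of the Sc-in-Ti diffusion coefficient
#'
#' The diffusion coefficient of scandium in titanium is modelled as a
#' base-10 exponential in absolute temperature,
#' \deqn{D(T) = 10^{(slope \cdot T + intercept)} \; \mathrm{cm^2/s},}
#' a log-linear fit to the tracer-diffusion measurements of Askill & Gibbs
#' over the 850-1150 degC range relevant to thermal release experiments.
#' Note this is deliberately *not* an Arrhenius law in 1/T; it is used as
#' fitted.
#'
#' @param slope per-kelvin exponent coefficient; must be positive so that
#'   D(T) increases with temperature. Default 0.0039.
#' @param intercept dimensionless log10 offset. Default -13.252.
#' @return An object of class `diffusion_law`.
#' @examples
#' law <- diffusion_law()
#' diffusion_coefficient(law, 1373.15)  # ~1.27e-8 cm^2/s at 1100 degC
#' @export
diffusion_law <- function(slope = 0.0039, intercept = -13.252) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (slope <= 0) {
    stop("`slope` must be > 0: the diffusion coefficient must increase with temperature",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept), class = "diffusion_law")
}

#' Desorption law for an adsorbed atom on a hot surface
#'
#' Holds the parameters of the Frenkel mean adsorption residence time
#' \deqn{\bar\tau_a = \tau_0 \exp(E_{des} / (R T)),}
#' where `tau0` is the period of oscillation of the adsorbed atom
#' perpendicular to the surface (Lindemann estimate, 1.6e-13 s) and
#' `E_des` the positive desorption energy in kJ/mol. The desorption
#' energy is the negative of the (negative) adsorption enthalpy:
#' `E_des = -dH_a`. Storing the positive quantity avoids double-negative
#' sign errors; an adsorption enthalpy of -390 kJ/mol corresponds to
#' `E_des = 390`.
#'
#' @param E_des positive desorption energy in kJ/mol (>= 0).
#' @param tau0 oscillation period in seconds (> 0). Default 1.6e-13.
#' @return An object of class `desorption_law`.
#' @examples
#' des <- desorption_law(E_des = 390)
#' mean_residence_time(des, 1373.15)  # ~110 s at 1100 degC
#' @export
desorption_law <- function(E_des, tau0 = 1.6e-13) {
  stopifnot(is.numeric(E_des), length(E_des) == 1L, is.finite(E_des),
            is.numeric(tau0), length(tau0) == 1L, is.finite(tau0))
  if (tau0 <= 0) stop("`tau0` must be > 0", call. = FALSE)
  if (E_des < 0) {
    stop("`E_des` must be >= 0; pass the positive desorption energy -dH_a",
         call. = FALSE)
  }
  structure(list(E_des = E_des, tau0 = tau0), class = "desorption_law")
}

#' One release-experiment condition
#'
#' Temperature, foil thickness and heating duration of a single thermal
#' release run. Temperatures are stored in kelvin; use `celsius()` for
#' user-facing degC input.
#'
#' @param temperature absolute temperature in kelvin (> 0).
#' @param thickness foil thickness in cm (> 0).
#' @param duration heating time in seconds (>= 0).
#' @return An object of class `experiment_condition`.
#' @examples
#' experiment_condition(celsius(1100), thickness = 0.0025, duration = 7200)
#' @export
experiment_condition <- function(temperature, thickness, duration) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(thickness), length(thickness) == 1L,
            is.numeric(duration), length(duration) == 1L)
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a positive kelvin value", call. = FALSE)
  }
  if (!is.finite(thickness) || thickness <= 0) {
    stop("`thickness` must be > 0 (cm)", call. = FALSE)
  }
  if (!is.finite(duration) || duration < 0) {
    stop("`duration` must be >= 0 (s)", call. = FALSE)
  }
  structure(list(temperature = temperature, thickness = thickness,
                 duration = duration),
            class = "experiment_condition")
}

#' Convert degrees Celsius to kelvin
#' @param t_C temperature(s) in degrees Celsius.
#' @return temperature(s) in kelvin.
#' @export
celsius <- function(t_C) t_C + 273.15

#' Activity triple of one release/recovery experiment
#'
#' The three gamma-counting activities from which the release and recovery
#' ratios are computed: initial activity of the target foil, residual
#' activity after heating, and the activity condensed on the catcher foil.
#'
#' @param C_initial initial target activity, Bq (>= 0).
#' @param C_final residual target activity after heating, Bq; must not
#'   exceed `C_initial`.
#' @param C_catcher activity recovered on the catcher foil, Bq; must not
#'   exceed the released activity `C_initial - C_final`.
#' @param rel_unc optional length-3 vector of relative 1-sigma counting
#'   uncertainties (fractions) for the three activities.
#' @return An object of class `activity_triple`.
#' @export
activity_triple <- function(C_initial, C_final, C_catcher,
                            rel_unc = c(0, 0, 0)) {
  stopifnot(is.numeric(C_initial), is.numeric(C_final), is.numeric(C_catcher),
            is.numeric(rel_unc), length(rel_unc) == 3L, all(rel_unc >= 0))
  if (C_initial < 0 || C_final < 0 || C_catcher < 0) {
    stop("activities must be >= 0 Bq", call. = FALSE)
  }
  if (C_final > C_initial) {
    stop("`C_final` must not exceed `C_initial`", call. = FALSE)
  }
  if (C_catcher > C_initial - C_final) {
    stop("`C_catcher` must not exceed the released activity C_initial - C_final",
         call. = FALSE)
  }
  structure(list(C_initial = C_initial, C_final = C_final,
                 C_catcher = C_catcher, rel_unc = rel_unc),
            class = "activity_triple")
}

#' A measured release observation
#'
#' @param condition an [experiment_condition()].
#' @param release_pct measured release percentage in \[0, 100\].
#' @param sigma_pct 1-sigma uncertainty of `release_pct` in percentage
#'   points (>= 0).
#' @return An object of class `release_observation`.
#' @export
release_observation <- function(condition, release_pct, sigma_pct = 0) {
  stopifnot(inherits(condition, "experiment_condition"),
            is.numeric(release_pct), length(release_pct) == 1L,
            is.numeric(sigma_pct), length(sigma_pct) == 1L)
  if (release_pct < 0 || release_pct > 100) {
    stop("`release_pct` must lie in [0, 100]", call. = FALSE)
  }
  if (sigma_pct < 0) stop("`sigma_pct` must be >= 0", call. = FALSE)
  structure(list(condition = condition, release_pct = release_pct,
                 sigma_pct = sigma_pct),
            class = "release_observation")
}

#' Diffusion coefficient at a given temperature
#'
#' Evaluates \eqn{D(T) = 10^{(slope \cdot T + intercept)}} in cm^2/s.
#'
#' @param law a [diffusion_law()].
#' @param T absolute temperature(s) in kelvin (> 0); vectorised.
#' @return diffusion coefficient(s) in cm^2/s.
#' @export
diffusion_coefficient <- function(law, T) {
  stopifnot(inherits(law, "diffusion_law"), is.numeric(T))
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("`T` must be positive kelvin", call. = FALSE)
  }
  10^(law$slope * T + law$intercept)
}

#' Cumulative probability that a Sc atom has reached the foil surface
#'
#' First-term approximation for release from a plane sheet with uniformly
#' distributed tracer:
#' \deqn{F(t) = 1 - \frac{8}{\pi^2}\exp(-D(T)\,t/d^2).}
#' At t = 0 this equals 1 - 8/pi^2 ~ 0.1894, interpreted as a point mass
#' of immediate surface arrival so that F is a proper CDF. F is
#' non-decreasing in t and T and non-increasing in thickness.
#'
#' @param law a [diffusion_law()].
#' @param condition an [experiment_condition()] supplying T and d.
#' @param t time(s) in seconds (>= 0); vectorised.
#' @return arrival probability(ies) in \[1 - 8/pi^2, 1).
#' @export
arrival_cdf <- function(law, condition, t) {
  stopifnot(inherits(law, "diffusion_law"),
            inherits(condition, "experiment_condition"),
            is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be >= 0 seconds", call. = FALSE)
  }
  D <- diffusion_coefficient(law, condition$temperature)
  1 - (8 / pi^2) * exp(-D * t / condition$thickness^2)
}

#' Mean adsorption residence time
#'
#' Frenkel expression \eqn{\bar\tau_a = \tau_0 \exp(E_{des}/(R T))}, with
#' `E_des` in kJ/mol converted to J/mol internally and R = 8.314 J/(mol K).
#' Individual residence times are exponentially distributed with this mean.
#'
#' @param law a [desorption_law()].
#' @param T absolute temperature(s) in kelvin (> 0); vectorised.
#' @return mean residence time(s) in seconds.
#' @export
mean_residence_time <- function(law, T) {
  stopifnot(inherits(law, "desorption_law"), is.numeric(T))
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("`T` must be positive kelvin", call. = FALSE)
  }
  law$tau0 * exp(law$E_des * 1000 / (.R_GAS * T))
}

#' Relative release ratio from measured activities
#'
#' \deqn{R_{rel} = (C_i - C_f)/C_i \times 100.}
#'
#' @param a an [activity_triple()].
#' @return release percentage in \[0, 100\].
#' @export
release_ratio <- function(a) {
  stopifnot(inherits(a, "activity_triple"))
  if (a$C_initial == 0) {
    stop("release ratio undefined: C_initial is zero", call. = FALSE)
  }
  (a$C_initial - a$C_final) / a$C_initial * 100
}

#' Relative recovery ratio on the catcher foil
#'
#' \deqn{R_{rec} = C_a/(C_i - C_f) \times 100,} the fraction of released
#' activity condensed on the catcher.
#'
#' @param a an [activity_triple()].
#' @return recovery percentage in \[0, 100\].
#' @export
recovery_ratio <- function(a) {
  stopifnot(inherits(a, "activity_triple"))
  released <- a$C_initial - a$C_final
  if (released == 0) {
    stop("recovery ratio undefined: no activity was released (C_initial == C_final)",
         call. = FALSE)
  }
  a$C_catcher / released * 100
}

#' Semi-analytic release probability (quadrature oracle)
#'
#' Deterministic evaluation of the probability that an atom has both
#' reached the surface and desorbed by the end of the experiment, used as
#' a noise-free verification oracle for the Monte Carlo engine:
#' \deqn{P = \int_0^{t_{exp}} p_{arr}(t)\,(1 - e^{-(t_{exp}-t)/\bar\tau})\,dt,}
#' where the arrival distribution comprises a point mass of 1 - 8/pi^2 at
#' t = 0 plus the density (8/pi^2)(1/tau_D) exp(-t/tau_D) with
#' tau_D = d^2/D(T). The continuous part is evaluated with adaptive
#' quadrature to a relative tolerance of 1e-8.
#'
#' @param condition an [experiment_condition()].
#' @param diff a [diffusion_law()].
#' @param des a [desorption_law()].
#' @return release probability in \[0, 1\].
#' @export
semi_analytic_release <- function(condition, diff, des) {
  stopifnot(inherits(condition, "experiment_condition"),
            inherits(diff, "diffusion_law"),
            inherits(des, "desorption_law"))
  t_exp <- condition$duration
  if (t_exp == 0) return(0)
  tau_d <- condition$thickness^2 /
    diffusion_coefficient(diff, condition$temperature)
  tau_a <- mean_residence_time(des, condition$temperature)
  p0 <- 1 - 8 / pi^2

  ## point mass at t = 0: full experiment duration available for desorption
  point <- p0 * (-expm1(-t_exp / tau_a))

  integrand <- function(t) {
    (8 / pi^2) * (1 / tau_d) * exp(-t / tau_d) * (-expm1(-(t_exp - t) / tau_a))
  }
  ## the integrand varies on two scales: the arrival decay tau_d (near t = 0)
  ## and the desorption boundary layer tau_a (near t = t_exp); split there so
  ## the adaptive rule cannot step over either feature
  cuts <- c(30 * tau_d, t_exp - 30 * tau_a)
  ## keep only cuts well inside (0, t_exp): a feature narrower than ~1e-6 of
  ## the experiment contributes below the quadrature tolerance anyway
  cuts <- cuts[is.finite(cuts) & cuts > 1e-6 * t_exp & cuts < (1 - 1e-6) * t_exp]
  breaks <- unique(c(0, sort(cuts), t_exp))
  pieces <- vapply(seq_len(length(breaks) - 1L), function(i) {
    q <- tryCatch(
      stats::integrate(integrand, breaks[i], breaks[i + 1L],
                       rel.tol = 1e-9, abs.tol = 1e-13,
                       subdivisions = 500L),
      error = function(e) {
        stop("quadrature failed for semi_analytic_release (T = ",
             condition$temperature, " K, d = ", condition$thickness,
             " cm, t = ", t_exp, " s): ", conditionMessage(e), call. = FALSE)
      }
    )
    q$value
  }, numeric(1))
  p <- point + sum(pieces)
  ## numerically p can exceed 1 by ~rel.tol only; that would be a bug upstream
  stopifnot(p >= 0, p <= 1 + 1e-7)
  min(p, 1)
}
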