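## Synthetic measurement generator.  Emulates the statistical structure of
## gamma-counting release/recovery measurements: a small counting-statistics
## term (~0.1-0.2% relative) and a larger systematic term (~1-2% relative),
## both modelled as independent multiplicative Gaussian noise, plus
## per-material catcher sticking fractions.

#' Measurement noise model
#'
#' Two independent multiplicative zero-mean Gaussian noise components on a
#' true release fraction: a counting-statistics term and a systematic
#' term. Defaults place the counting term at 0.2% relative and the
#' systematic term at 1.5% relative, the middle of the ranges typical of
#' HPGe gamma-counting release experiments.
#'
#' @param counting_rel_sigma relative 1-sigma of the counting term
#'   (fraction, >= 0). Default 0.002.
#' @param systematic_rel_sigma relative 1-sigma of the systematic term
#'   (fraction, >= 0). Default 0.015.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(counting_rel_sigma = 0.002,
                        systematic_rel_sigma = 0.015) {
  stopifnot(is.numeric(counting_rel_sigma), counting_rel_sigma >= 0,
            is.numeric(systematic_rel_sigma), systematic_rel_sigma >= 0)
  structure(list(counting_rel_sigma = counting_rel_sigma,
                 systematic_rel_sigma = systematic_rel_sigma),
            class = "noise_model")
}

#' Combined relative sigma of a noise model (fraction)
#' @param noise a [noise_model()].
#' @return combined relative standard deviation, sqrt(c^2 + s^2).
#' @export
combined_rel_sigma <- function(noise) {
  stopifnot(inherits(noise, "noise_model"))
  sqrt(noise$counting_rel_sigma^2 + noise$systematic_rel_sigma^2)
}

#' Catcher-foil specification
#'
#' A catcher material and the fraction of released activity that sticks to
#' it. The bundled [default_catchers()] carry sticking fractions on the
#' scale observed for cold-finger catcher foils (Au the best at 0.65, Ti
#' and Ta near 0.3).
#'
#' @param material material label, e.g. `"Au"`.
#' @param recovery_fraction sticking fraction in \[0, 1\].
#' @return An object of class `catcher_spec`.
#' @export
catcher_spec <- function(material, recovery_fraction) {
  stopifnot(is.character(material), length(material) == 1L,
            is.numeric(recovery_fraction), length(recovery_fraction) == 1L)
  if (recovery_fraction < 0 || recovery_fraction > 1) {
    stop("`recovery_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(material = material, recovery_fraction = recovery_fraction),
            class = "catcher_spec")
}

#' Default catcher-foil set
#' @return named list of [catcher_spec()]s for Ti, brass, Au and Ta.
#' @export
default_catchers <- function() {
  list(Ti    = catcher_spec("Ti", 0.30),
       brass = catcher_spec("brass", 0.47),
       Au    = catcher_spec("Au", 0.65),
       Ta    = catcher_spec("Ta", 0.27))
}

#' Reference experimental design
#'
#' The standard two-series release design: a temperature series (900, 950,
#' 1000, 1050, 1100 degC) on 0.025 mm foil, and a thickness series (0.025,
#' 0.05, 0.1, 0.25, 0.5, 1 mm) at 1100 degC, all with a 2 h heating time.
#'
#' @return list of 11 [experiment_condition()]s (5 temperature + 6
#'   thickness entries).
#' @export
reference_conditions <- function() {
  temps <- celsius(c(900, 950, 1000, 1050, 1100))
  thick <- c(0.0025, 0.005, 0.01, 0.025, 0.05, 0.1)  # cm
  c(lapply(temps, experiment_condition, thickness = 0.0025, duration = 7200),
    lapply(thick, function(d)
      experiment_condition(celsius(1100), d, 7200)))
}

#' Generate synthetic release observations
#'
#' For each condition the true release fraction is computed with the
#' noise-free [semi_analytic_release()] oracle, then perturbed
#' multiplicatively: `observed = 100 * true * (1 + e_sys) * (1 + e_cnt)`,
#' with independent zero-mean Gaussian `e`s at the noise model's sigmas.
#' Observations are truncated to \[0, 100\] afterwards (truncation events
#' are counted in the `truncated` attribute). The reported `sigma_pct` is
#' the combined relative sigma times the observed percentage.
#'
#' @param true_des the generating [desorption_law()].
#' @param diff a [diffusion_law()].
#' @param conditions list of [experiment_condition()]s.
#' @param noise a [noise_model()].
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list of [release_observation()]s with a `truncated` attribute.
#' @export
generate_release_observations <- function(true_des, diff, conditions,
                                          noise = noise_model(), seed) {
  stopifnot(inherits(true_des, "desorption_law"),
            inherits(diff, "diffusion_law"),
            is.list(conditions), inherits(noise, "noise_model"))
  n <- length(conditions)
  true_frac <- vapply(conditions, semi_analytic_release, numeric(1),
                      diff = diff, des = true_des)
  eps <- withr::with_seed(as.integer(seed), {
    list(sys = stats::rnorm(n, 0, noise$systematic_rel_sigma),
         cnt = stats::rnorm(n, 0, noise$counting_rel_sigma))
  })
  raw_pct <- 100 * true_frac * (1 + eps$sys) * (1 + eps$cnt)
  pct <- pmin(100, pmax(0, raw_pct))
  n_trunc <- sum(raw_pct != pct)
  sig_pct <- combined_rel_sigma(noise) * pct
  obs <- lapply(seq_len(n), function(i) {
    release_observation(conditions[[i]], pct[i], sig_pct[i])
  })
  attr(obs, "truncated") <- n_trunc
  obs
}

#' Generate a synthetic activity triple
#'
#' Builds the raw gamma-counting activities of one release/recovery
#' experiment from a true release fraction and a catcher sticking
#' fraction: `C_final = C_initial * (1 - release)` and
#' `C_catcher = C_initial * release * recovery`, each perturbed by the
#' counting noise, then truncated so the physical orderings
#' `C_final <= C_initial` and `C_catcher <= C_initial - C_final` hold.
#'
#' @param release_fraction true release fraction in \[0, 1\].
#' @param catcher a [catcher_spec()].
#' @param C_initial initial activity in Bq (> 0).
#' @param noise a [noise_model()]; only the counting term applies to raw
#'   activities.
#' @param seed integer seed.
#' @return an [activity_triple()].
#' @export
generate_activity_triples <- function(release_fraction, catcher, C_initial,
                                      noise = noise_model(), seed) {
  stopifnot(is.numeric(release_fraction), length(release_fraction) == 1L,
            release_fraction >= 0, release_fraction <= 1,
            inherits(catcher, "catcher_spec"),
            is.numeric(C_initial), C_initial > 0,
            inherits(noise, "noise_model"))
  eps <- withr::with_seed(as.integer(seed),
                          stats::rnorm(2, 0, noise$counting_rel_sigma))
  C_f <- C_initial * (1 - release_fraction) * (1 + eps[1])
  C_a <- C_initial * release_fraction * catcher$recovery_fraction * (1 + eps[2])
  C_f <- min(max(C_f, 0), C_initial)
  C_a <- min(max(C_a, 0), C_initial - C_f)
  activity_triple(C_initial, C_f, C_a,
                  rel_unc = rep(noise$counting_rel_sigma, 3))
}

#' Generate a full synthetic dataset
#'
#' Bundles release observations over a condition list with one activity
#' triple per default catcher material, together with the generating truth
#' (desorption energy and recovery fractions) for end-to-end pipeline
#' tests.
#'
#' @param true_E_des generating desorption energy, kJ/mol.
#' @param conditions list of conditions; default [reference_conditions()].
#' @param diff a [diffusion_law()].
#' @param noise a [noise_model()].
#' @param catchers named list of [catcher_spec()]s.
#' @param C_initial initial activity for the catcher experiments, Bq.
#' @param seed integer master seed.
#' @return An object of class `synthetic_dataset`: `observations`,
#'   `activity_triples` (named by material), `true_E_des`,
#'   `true_recovery`, `seed`.
#' @export
generate_dataset <- function(true_E_des = 390,
                             conditions = reference_conditions(),
                             diff = diffusion_law(),
                             noise = noise_model(),
                             catchers = default_catchers(),
                             C_initial = 1e6, seed = 1L) {
  des <- desorption_law(true_E_des)
  sub <- .sub_seeds(seed, 1L + length(catchers))
  obs <- generate_release_observations(des, diff, conditions, noise, sub[1])
  ## catcher experiments run at the optimal release condition
  best <- experiment_condition(celsius(1100), 0.0025, 7200)
  rel <- semi_analytic_release(best, diff, des)
  triples <- lapply(seq_along(catchers), function(i) {
    generate_activity_triples(rel, catchers[[i]], C_initial, noise,
                              sub[1 + i])
  })
  names(triples) <- names(catchers)
  structure(list(observations = obs,
                 activity_triples = triples,
                 true_E_des = true_E_des,
                 true_recovery = vapply(catchers, `[[`, numeric(1),
                                        "recovery_fraction"),
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}
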