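# Independent closed-form oracles, kept free of the package's quadrature and
# sampling code paths.  The release probability has an exact two-exponential
# form: with tau_D = d^2/D(T), tau_a the mean residence time, p0 = 1 - 8/pi^2
# and a = 8/pi^2,
#   P = p0 (1 - e^{-t/tau_a}) + a (1 - e^{-t/tau_D})
#       - (a/tau_D) (e^{-t/tau_D} - e^{-t/tau_a}) / (1/tau_a - 1/tau_D).

oracle_D <- function(T, slope = 0.0039, intercept = -13.252) {
  10^(slope * T + intercept)
}

oracle_tau_a <- function(E_des, T, tau0 = 1.6e-13) {
  tau0 * exp(E_des * 1000 / (8.314 * T))
}

oracle_arrival_cdf <- function(T, d, t) {
  1 - (8 / pi^2) * exp(-oracle_D(T) * t / d^2)
}

closed_form_release <- function(T, d, t, E_des, tau0 = 1.6e-13) {
  if (t == 0) return(0)
  tau_d <- d^2 / oracle_D(T)
  tau_a <- oracle_tau_a(E_des, T, tau0)
  p0 <- 1 - 8 / pi^2
  a <- 8 / pi^2
  r <- 1 / tau_a - 1 / tau_d
  term3 <- if (abs(r) < 1e-300) {
    (a / tau_d) * t * exp(-t / tau_d)
  } else {
    (a / tau_d) * (exp(-t / tau_d) - exp(-t / tau_a)) / r
  }
  p0 * (1 - exp(-t / tau_a)) + a * (1 - exp(-t / tau_d)) - term3
}

# random-but-physical experimental conditions for property loops
random_conditions <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      experiment_condition(
        temperature = runif(1, 1050, 1500),
        thickness = runif(1, 0.002, 0.05),
        duration = runif(1, 600, 14400))
    })
  })
}

temperature_conditions <- function(d = 0.0025, t_exp = 7200,
                                   T_list = default_temperatures()) {
  lapply(T_list, experiment_condition, thickness = d, duration = t_exp)
}
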