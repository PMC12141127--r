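# Monte Carlo atom-history engine: inverse-CDF arrival sampling, per-atom
# fates, aggregated release runs and condition sweeps, all checked against
# the closed-form/quadrature oracles.

test_that("inverse-CDF arrival sampling hits its three branches", {
  diff <- diffusion_law()
  cond <- experiment_condition(1373.15, 0.01, 7200)
  p0 <- 1 - 8 / pi^2
  F_end <- arrival_cdf(diff, cond, 7200)

  expect_identical(sample_arrival_time(0, cond, diff), 0)
  expect_identical(sample_arrival_time(p0 - 1e-9, cond, diff), 0)
  expect_true(is.na(sample_arrival_time((F_end + 1) / 2, cond, diff)))
  expect_true(is.na(sample_arrival_time(0.999999, cond, diff)))

  # interior branch reproduces the analytic quantile and stays in [0, t_exp]
  u <- (p0 + F_end) / 2
  t_u <- sample_arrival_time(u, cond, diff)
  tau_d <- cond$thickness^2 / diffusion_coefficient(diff, 1373.15)
  expect_equal(t_u, -tau_d * log(pi^2 * (1 - u) / 8))
  expect_true(t_u >= 0 && t_u <= 7200)
  expect_equal(arrival_cdf(diff, cond, t_u), u, tolerance = 1e-12)

  expect_error(sample_arrival_time(1, cond, diff), "\\[0, 1\\)")
  expect_error(sample_arrival_time(-0.1, cond, diff), "\\[0, 1\\)")

  # zero-duration experiments give no transport at all
  cond0 <- experiment_condition(1373.15, 0.01, 0)
  expect_true(all(is.na(sample_arrival_time(c(0, 0.1, 0.5), cond0, diff))))
})

test_that("empirical arrival distribution matches the closed CDF (KS band)", {
  diff <- diffusion_law()
  cond <- experiment_condition(1373.15, 0.01, 7200)
  n <- 1e5
  u <- withr::with_seed(101, runif(n))
  t <- sample_arrival_time(u, cond, diff)
  t[is.na(t)] <- Inf # never-arriving atoms sit beyond any finite time
  grid <- seq(0, 7200, length.out = 400)
  emp <- vapply(grid, function(g) mean(t <= g), numeric(1))
  theo <- arrival_cdf(diff, cond, grid)
  ks <- max(abs(emp - theo))
  expect_lt(ks, 1.63 / sqrt(n)) # 99% Kolmogorov band
})

test_that("single-atom histories respect the fate logic", {
  diff <- diffusion_law()
  cond <- experiment_condition(1373.15, 0.005, 7200)
  # zero desorption energy: every atom that arrives evaporates
  withr::with_seed(5, {
    fates <- replicate(200, simulate_atom(cond, diff, desorption_law(0))$category)
  })
  expect_true(all(fates %in% c("retained_in_bulk", "evaporated")))
  expect_true(any(fates == "evaporated"))
  # zero duration: always retained in the bulk
  cond0 <- experiment_condition(1373.15, 0.005, 0)
  withr::with_seed(6, {
    fates0 <- replicate(50, simulate_atom(cond0, diff, desorption_law(390)))
  })
  expect_true(all(vapply(fates0["category", ], identical, logical(1),
                         "retained_in_bulk")))
  expect_true(all(is.na(unlist(fates0["arrival_time", ]))))
})

test_that("release runs conserve atoms and are seed-deterministic", {
  diff <- diffusion_law()
  des <- desorption_law(390)
  for (cond in random_conditions(8, seed = 21)) {
    mc <- simulate_release(cond, diff, des, n_atoms = 2000, seed = 9)
    expect_identical(mc$n_evaporated + mc$n_surface + mc$n_bulk, mc$n_atoms)
    expect_equal(mc$release_fraction, mc$n_evaporated / mc$n_atoms)
  }
  cond <- experiment_condition(1223.15, 0.0025, 7200)  # mid-sigmoid
  a <- simulate_release(cond, diff, des, n_atoms = 5000, seed = 77)
  b <- simulate_release(cond, diff, des, n_atoms = 5000, seed = 77)
  c <- simulate_release(cond, diff, des, n_atoms = 5000, seed = 78)
  expect_identical(a, b)
  expect_false(identical(a$n_evaporated, c$n_evaporated) &&
                 identical(a$n_surface, c$n_surface))
  expect_error(simulate_release(cond, diff, des, n_atoms = 0, seed = 1),
               "n_atoms")
})

test_that("MC release matches the quadrature oracle across a (T, d) grid", {
  diff <- diffusion_law()
  des <- desorption_law(390)
  Ts <- celsius(c(900, 950, 1000, 1050, 1100))
  ds <- c(0.0025, 0.005, 0.01, 0.025, 0.05)
  n <- 10000
  ok <- 0L
  for (T in Ts) {
    for (d in ds) {
      cond <- experiment_condition(T, d, 7200)
      p <- semi_analytic_release(cond, diff, des)
      mc <- simulate_release(cond, diff, des, n, seed = 404)
      se <- sqrt(p * (1 - p) / n)
      ok <- ok + (abs(mc$release_fraction - p) <= 3 * max(se, 1e-12) + 1e-9)
    }
  }
  expect_gte(ok, ceiling(0.95 * length(Ts) * length(ds)))
})

test_that("diffusion-only limit reproduces the arrival CDF; full model sits below it at low T", {
  diff <- diffusion_law()
  n <- 10000
  for (TC in c(900, 1000, 1100)) {
    cond <- experiment_condition(celsius(TC), 0.0025, 7200)
    mc0 <- simulate_release(cond, diff, desorption_law(0), n, seed = 55)
    F_end <- arrival_cdf(diff, cond, 7200)
    se <- sqrt(F_end * (1 - F_end) / n)
    expect_lt(abs(mc0$release_fraction - F_end), 4 * se)
  }
  # with the real desorption barrier the release stays strictly below the
  # diffusion-only curve up to 1050 degC
  des <- desorption_law(390)
  for (TC in seq(850, 1050, by = 50)) {
    cond <- experiment_condition(celsius(TC), 0.0025, 7200)
    mc <- simulate_release(cond, diff, des, n, seed = 56)
    expect_lt(mc$release_fraction, arrival_cdf(diff, cond, 7200))
  }
})

test_that("expected release is monotone in T and t, anti-monotone in d and E", {
  diff <- diffusion_law()
  mean_rel <- function(T, d, t, E) {
    mean(vapply(1:10, function(s)
      simulate_release(experiment_condition(T, d, t), diff,
                       desorption_law(E), 2000, seed = s)$release_fraction,
      numeric(1)))
  }
  byT <- vapply(celsius(c(950, 1025, 1100)), mean_rel, numeric(1),
                d = 0.0025, t = 7200, E = 390)
  expect_true(all(diff(byT) >= 0))
  byt <- vapply(c(1800, 5400, 10800), function(t)
    mean_rel(1348.15, 0.0025, t, 390), numeric(1))
  expect_true(all(diff(byt) >= 0))
  byd <- vapply(c(0.0025, 0.01, 0.05), function(d)
    mean_rel(1373.15, d, 7200, 390), numeric(1))
  expect_true(all(diff(byd) <= 0))
  byE <- vapply(c(380, 390, 400), function(E)
    mean_rel(1348.15, 0.0025, 7200, E), numeric(1))
  expect_true(all(diff(byE) <= 0))
})

test_that("temperature sweep traces the sigmoid between the oracle endpoints", {
  diff <- diffusion_law()
  des <- desorption_law(390)
  sw <- sweep_temperature(d = 0.0025, t_exp = 7200, diff = diff, des = des,
                          n_atoms = 10000, seed = 31)
  expect_identical(nrow(sw), 13L)
  expect_equal(sw$temperature_K, celsius(seq(850, 1150, by = 25)))
  expect_lt(sw$release_fraction[sw$temperature_K == celsius(850)], 0.05)
  expect_gt(sw$release_fraction[sw$temperature_K == celsius(1100)], 0.99)
  # repeatable from the master seed
  expect_identical(sw, sweep_temperature(d = 0.0025, t_exp = 7200,
                                         diff = diff, des = des,
                                         n_atoms = 10000, seed = 31))
  expect_error(sweep_temperature(c(1300, 1200), d = 0.0025, t_exp = 7200,
                                 diff = diff, des = des, seed = 1),
               "increasing")
  one <- sweep_temperature(1373.15, d = 0.0025, t_exp = 7200, diff = diff,
                           des = des, n_atoms = 2000, seed = 4)
  expect_identical(nrow(one), 1L)
})

test_that("diffusion-only sweep equals the arrival CDF at each temperature", {
  diff <- diffusion_law()
  n <- 10000
  sw <- sweep_temperature(d = 0.0025, t_exp = 7200, diff = diff,
                          des = desorption_law(0), n_atoms = n, seed = 8)
  theo <- vapply(sw$temperature_K, function(T)
    arrival_cdf(diff, experiment_condition(T, 0.0025, 7200), 7200),
    numeric(1))
  se <- sqrt(theo * (1 - theo) / n)
  expect_true(all(abs(sw$release_fraction - theo) <= 4 * se))
})

test_that("thickness sweep decreases monotonically and dies at t_exp = 0", {
  diff <- diffusion_law()
  des <- desorption_law(390)
  sw <- sweep_thickness(T = 1373.15, t_exp = 7200, diff = diff, des = des,
                        n_atoms = 10000, seed = 19)
  expect_identical(nrow(sw), 6L)
  expect_true(all(diff(sw$release_fraction) < 0))
  # thick-foil endpoint against the quadrature oracle (~0.196)
  p <- semi_analytic_release(experiment_condition(1373.15, 0.1, 7200),
                             diff, des)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(sw$release_fraction[sw$thickness_cm == 0.1] - p), 3 * se)
  expect_error(sweep_thickness(c(0.0025, -0.01), T = 1373.15, t_exp = 7200,
                               diff = diff, des = des, seed = 1), "> 0")
  sw0 <- sweep_thickness(T = 1373.15, t_exp = 0, diff = diff, des = des,
                         n_atoms = 2000, seed = 2)
  expect_true(all(sw0$release_fraction == 0))
})
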