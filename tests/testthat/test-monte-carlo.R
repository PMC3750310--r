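cfg <- exposure_config()
tab <- shanghai_food_table()

degenerate_model <- function() {
  # all inputs fixed at their survey means; smoking term fixed at the
  # population mean dose of 3.93 ug/day (prevalence 1, constant inputs)
  m <- build_population_model(tab, cfg, stratum = "smokers",
                              tobacco_conc_sd = 0)
  m$foods <- lapply(m$foods, function(f) {
    f$conc <- point_mass(dist_mean(f$conc))
    f$intake <- point_mass(dist_mean(f$intake))
    f
  })
  m$tobacco$cigarettes <- point_mass(3.93 / 1.5)
  m
}

test_that("degenerate inputs propagate to the deterministic total", {
  sim <- simulate_exposure(degenerate_model(), n = 50, seed = 1)
  expect_equal(sim$summary[["std"]], 0)
  expect_equal(sim$summary[["mean"]], 16.73, tolerance = 0.05 / 16.73)
  expect_equal(sim$summary[["min"]], sim$summary[["max"]])
  expect_equal(risk_below(sim, 49.5), 1.0)
})

test_that("a single-lognormal model recovers its analytic mean", {
  # standard lognormal mu = 0, sigma = 1, entered via its moments
  d <- lognormal_from_moments(exp(0.5), exp(0.5) * sqrt(exp(1) - 1))
  expect_equal(d$mu, 0)
  expect_equal(d$sigma, 1)
  sim <- simulate_fitted(d, n = 100000, seed = 11)
  analytic_mean <- exp(0.5)
  analytic_sd <- sqrt((exp(1) - 1) * exp(1))
  se <- analytic_sd / sqrt(100000)
  expect_lt(abs(sim$summary[["mean"]] - analytic_mean), 3 * se)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  model <- build_population_model(tab, cfg)
  a <- simulate_exposure(model, n = 2000, seed = 42)
  b <- simulate_exposure(model, n = 2000, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$input_draws, b$input_draws)
  c <- simulate_exposure(model, n = 2000, seed = 43)
  expect_false(identical(a$draws, c$draws))
  expect_error(simulate_exposure(model, n = 0, seed = 1), "n must be")
})

test_that("draw summaries use n-1 std and interpolated percentiles", {
  s <- summarize_draws(c(1, 2, 3, 4, 5))
  expect_equal(s[["mean"]], 3)
  expect_equal(s[["median"]], 3)
  expect_equal(s[["std"]], sd(1:5))
  d <- lognormal_from_mean_median(23.05, 18.24)
  sim <- simulate_fitted(d, n = 100000, seed = 5)
  expect_equal(sim$summary[["median"]], 18.24, tolerance = 0.3 / 18.24)
  pm <- simulate_fitted(point_mass(7), n = 100, seed = 1)
  expect_equal(pm$summary[["std"]], 0)
  expect_equal(pm$summary[["p5"]], pm$summary[["p95"]])
})

test_that("the simulated total's mean matches the sum of input-term means", {
  model <- build_population_model(tab, cfg)
  n <- 100000
  sim <- simulate_exposure(model, n = n, seed = 2)
  term_means <- sum(vapply(model$foods, function(f) {
    dist_mean(f$conc) * dist_mean(f$intake)
  }, numeric(1))) +
    model$tobacco$prevalence * dist_mean(model$tobacco$cigarettes) *
      dist_mean(model$tobacco$conc) * model$tobacco$cigarette_mass +
    model$water
  mc_se <- sd(sim$draws) / sqrt(n)
  expect_lt(abs(sim$summary[["mean"]] - term_means), 3 * mc_se)
})

test_that("empirical CDFs stay within DKW bounds of the analytic CDF", {
  d <- lognormal_from_mean_median(23.05, 18.24)
  n <- 100000
  sim <- simulate_fitted(d, n = n, seed = 9)
  eps <- sqrt(log(2 / 0.001) / (2 * n))
  grid <- dist_quantile(d, c(0.1, 0.3, 0.5, 0.7, 0.9))
  for (g in grid) {
    expect_lt(abs(mean(sim$draws <= g) - dist_cdf(d, g)), eps)
  }
})

test_that("below-PTDI risk matches the analytic CDF oracle", {
  expect_equal(risk_below(rep(16.73, 100), 49.5), 1.0)
  d <- lognormal_from_mean_median(23.05, 18.24)
  sim <- simulate_fitted(d, n = 100000, seed = 4)
  expect_equal(risk_below(sim, 49.5), dist_cdf(d, 49.5), tolerance = 0.005)
  dw <- lognormal_from_mean_median(14.05, 10.62)
  simw <- simulate_fitted(dw, n = 100000, seed = 4)
  expect_equal(risk_below(simw, 49.5), 0.980, tolerance = 0.003)
  expect_error(risk_below(sim, -1), "positive")
})

test_that("a prevalence-weighted stratum mixture sits between its strata", {
  n <- 20000
  smokers <- simulate_exposure(
    build_population_model(tab, cfg, stratum = "smokers"), n, seed = 21)
  nonsmokers <- simulate_exposure(
    build_population_model(tab, cfg, stratum = "nonsmokers"), n, seed = 22)
  total <- simulate_exposure(
    build_population_model(tab, cfg, stratum = "total"), n, seed = 23)
  r_s <- risk_below(smokers, 49.5)
  r_n <- risk_below(nonsmokers, 49.5)
  r_t <- risk_below(total, 49.5)
  expect_lt(r_s, r_n) # smoking raises exposure
  expect_true(r_t >= r_s - 0.01 && r_t <= r_n + 0.01)
  # exact mixture of the two strata's draws brackets analytically
  p <- cfg$smoking_prevalence$total
  mixed_risk <- p * r_s + (1 - p) * r_n
  expect_true(mixed_risk >= min(r_s, r_n) && mixed_risk <= max(r_s, r_n))
})

test_that("simulation results serialize with seed and risk", {
  model <- build_population_model(tab, cfg)
  sim <- simulate_exposure(model, n = 500, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_result(sim, path, ptdi = 49.5)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(out$seed, 3)
  expect_equal(out$n, 500)
  expect_equal(out$p_below_ptdi, risk_below(sim, 49.5))
})
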