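test_that("NDVI-to-LAI conversion matches the exponential relation", {
  expect_equal(ndvi_to_lai(0), 0.361)
  expect_equal(ndvi_to_lai(0.5), 2.284444, tolerance = 1e-6)
  expect_equal(ndvi_to_lai(-0.2), 0.1725829, tolerance = 1e-6)
  x <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(ndvi_to_lai(x)) > 0))
  expect_true(all(ndvi_to_lai(x) > 0))
  expect_error(ndvi_to_lai(NA_real_), class = "sistr_invalid_input")
})

test_that("the LAI simulator is deterministic with the expected shape", {
  m <- constant_meteo(rs = 15)
  h1 <- simulate_lai(m, 27.7, f = 1)
  h2 <- simulate_lai(m, 27.7, f = 1)
  expect_identical(h1, h2)
  expect_identical(h1$doy, canonical_doys())
  expect_true(all(h1$lai >= 0))

  # healthy profile: rises, peaks in mid-season at a plausible canopy size,
  # then falls
  peak <- which.max(h1$lai)
  expect_gte(h1$doy[peak], 205)
  expect_lte(h1$doy[peak], 225)
  expect_gte(max(h1$lai), 4)
  expect_lte(max(h1$lai), 7)
  expect_true(all(diff(h1$lai[1:peak]) >= 0))
  expect_true(all(diff(h1$lai[peak:20]) <= 0))
})

test_that("stress factor zero kills growth; LAI is monotone in f", {
  m <- constant_meteo()
  s0 <- simulate_lai(m, 27.7, f = 0)
  expect_true(all(diff(s0$lai) <= 0))
  expect_equal(s0$lai[1], crop_params()$lai_init)

  fs <- c(0, 0.25, 0.5, 0.75, 1)
  curves <- lapply(fs, function(f) simulate_lai(m, 27.7, f = f)$lai)
  for (k in seq_len(length(fs) - 1)) {
    expect_true(all(curves[[k + 1]] >= curves[[k]]))
  }
})

test_that("time-varying f and phenology shift behave as documented", {
  m <- constant_meteo()
  fvec <- rep(1, 96)
  fvec[30:50] <- 0.4  # mid-season abrupt window
  dip <- simulate_lai(m, 27.7, f = fvec)
  full <- simulate_lai(m, 27.7, f = 1)
  expect_true(all(dip$lai <= full$lai + 1e-12))
  expect_lt(min(dip$lai / pmax(full$lai, 1e-9)), 0.95)

  shifted <- simulate_lai(m, 27.7, f = 1, phenology_shift = 1L)
  expect_equal(shifted$lai[2:20], full$lai[1:19], tolerance = 1e-12)

  expect_error(simulate_lai(m[-5, ], 27.7, f = 1),
               class = "sistr_missing_forcing")
  expect_error(simulate_lai(m, 27.7, f = 1.5),
               class = "sistr_invalid_input")
})

test_that("the MSE cost matches hand evaluation and matching rules", {
  sim <- tibble::tibble(doy = canonical_doys(), lai = seq(0.5, 10, length = 20))
  obs_same <- tibble::tibble(doy = sim$doy[c(3, 9, 15)],
                             lai = sim$lai[c(3, 9, 15)])
  expect_equal(lai_cost(obs_same, sim), 0)

  obs1 <- tibble::tibble(doy = sim$doy[5], lai = sim$lai[5] + 0.5)
  expect_equal(lai_cost(obs1, sim), 0.25)

  obs3 <- tibble::tibble(doy = sim$doy[c(2, 8, 14)],
                         lai = sim$lai[c(2, 8, 14)] + c(1, -2, 0))
  expect_equal(lai_cost(obs3, sim), 5 / 3)

  # nearest-DOY matching within two days; farther is an error
  obs_near <- tibble::tibble(doy = sim$doy[5] + 2, lai = sim$lai[5])
  expect_equal(lai_cost(obs_near, sim), 0)
  expect_error(lai_cost(tibble::tibble(doy = 300, lai = 2), sim),
               class = "sistr_invalid_input")
  expect_error(lai_cost(obs1[0, ], sim), class = "sistr_invalid_input")
})

test_that("PSO recovers a known stress factor and is reproducible", {
  m <- constant_meteo()
  truth <- simulate_lai(m, 27.7, f = 0.6)
  fit <- calibrate_stress_factor(truth, m, 27.7, pso = pso_config(seed = 7))
  expect_lt(abs(fit$f_hat - 0.6), 0.02)
  expect_equal(fit$cost_hat,
               lai_cost(truth, simulate_lai(m, 27.7, f = fit$f_hat)))

  fit2 <- calibrate_stress_factor(truth, m, 27.7, pso = pso_config(seed = 7))
  expect_identical(fit$f_hat, fit2$f_hat)
  expect_identical(fit$trace, fit2$trace)

  # noiseless recovery is stable across seeds
  fhats <- vapply(1:10, function(s) {
    calibrate_stress_factor(truth, m, 27.7,
                            pso = pso_config(seed = s))$f_hat
  }, numeric(1))
  expect_lt(diff(range(fhats)), 0.05)
})

test_that("PSO degenerate termination returns the best initial particle", {
  m <- constant_meteo()
  truth <- simulate_lai(m, 27.7, f = 0.8)
  fit <- calibrate_stress_factor(
    truth, m, 27.7,
    pso = pso_config(seed = 3, max_iterations = 0, cost_threshold = Inf))
  expect_identical(fit$iterations, 0L)
  expect_equal(fit$cost_hat,
               lai_cost(truth, simulate_lai(m, 27.7, f = fit$f_hat)))
})

test_that("PSO is no worse than a fine grid search", {
  m <- constant_meteo()
  obs <- simulate_lai(m, 27.7, f = 0.45)
  set.seed(42)
  obs$lai <- pmax(obs$lai + rnorm(20, 0, 0.2), 0)
  fit <- calibrate_stress_factor(obs, m, 27.7, pso = pso_config(seed = 5))

  grid <- seq(0, 1, by = 0.01)
  costs <- vapply(grid, function(f) {
    lai_cost(obs, simulate_lai(m, 27.7, f = f))
  }, numeric(1))
  expect_lte(fit$cost_hat, min(costs) + 1e-8)
})

test_that("broom methods summarise a calibration", {
  m <- constant_meteo()
  truth <- simulate_lai(m, 27.7, f = 0.5)
  fit <- calibrate_stress_factor(truth, m, 27.7, pso = pso_config(seed = 1))
  td <- tidy(fit)
  expect_identical(td$term, "f")
  gl <- glance(fit)
  expect_true(all(c("f_hat", "cost", "iterations", "converged") %in%
                    names(gl)))
  expect_true(gl$converged)
})
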