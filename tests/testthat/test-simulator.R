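test_that("pseudo-simulator reduces to the stated response surface", {
  w <- tiny_world()
  p <- w$params

  # null response: zero out all coefficients -> PM2.5 equals baseline
  p0 <- p
  p0$linear_pm_coeff[] <- 0
  p0$nh3_limited_coeff[] <- 0
  f <- simulate_concentrations(c(0.3, 1.2, 0.7, 0.1, 1.4), p0, w$domain)
  expect_equal(f$pm25, pmax(p$baseline_pm, 0))

  # pure-linear params: halving IND changes PM by 0.5 * its coefficient
  pl <- p
  pl$nh3_limited_coeff[] <- 0
  base <- simulate_concentrations(baseline_config(), pl, w$domain)
  half <- simulate_concentrations(c(1, 0.5, 1, 1, 1), pl, w$domain)
  expect_equal(base$pm25 - half$pm25, 0.5 * pl$linear_pm_coeff[, "IND"])

  # f_AGR = 0 kills the ammonia-limited interaction term
  fa0 <- simulate_concentrations(c(1, 1, 1, 0, 1), p, w$domain)
  pl_fa0 <- simulate_concentrations(c(1, 1, 1, 0, 1), pl, w$domain)
  expect_equal(fa0$pm25, pl_fa0$pm25)
})

test_that("simulator validates the design space and is deterministic", {
  w <- tiny_world()
  expect_error(simulate_concentrations(c(1, 1, 1, 1, 1.6), w$params, w$domain),
               "design space")
  expect_error(simulate_concentrations(c(-0.1, 1, 1, 1, 1), w$params, w$domain),
               "design space")
  a <- simulate_concentrations(baseline_config(), w$params, w$domain, noisy = TRUE)
  b <- simulate_concentrations(baseline_config(), w$params, w$domain, noisy = TRUE)
  expect_identical(a, b)
  expect_true(all(a$pm25 >= 0) && all(a$o3 >= 0))
})

test_that("O3 response to TRA is non-monotone where the quadratic dominates", {
  w <- tiny_world()
  p <- w$params
  strong <- which(p$o3_nox_quad_coeff > p$o3_nox_coeff / 3)
  expect_gt(length(strong), 0)
  f_tra <- seq(0, 1.5, by = 0.1)
  o3 <- sapply(f_tra, function(ft)
    simulate_concentrations(c(1, 1, ft, 1, 1), p, w$domain)$o3)
  # finite differences change sign along TRA for the strong-quadratic cells
  for (cell in strong[seq_len(min(5, length(strong)))]) {
    d <- diff(o3[cell, ])
    expect_true(any(d < 0) && any(d > 0))
  }
})

test_that("hourly ozone generator produces seeded diurnal series", {
  s <- generate_hourly_ozone(3, mean_level = 40, amplitude = 0, noise_sd = 0)
  expect_length(s, 72)
  expect_equal(s, rep(40, 72))
  a <- generate_hourly_ozone(10, seed = 5)
  b <- generate_hourly_ozone(10, seed = 5)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_error(generate_hourly_ozone(0), "n_days")
})

test_that("noiseless station observations equal the simulator at paired cells", {
  w <- tiny_world()
  traj <- true_trajectory()
  obs <- synth_observations(traj, w$params, w$domain, w$stations,
                            seed = 1, relative_noise = 0)
  for (yr in c(2015, 2018, 2020)) {
    fld <- simulate_concentrations(traj[as.character(yr), ], w$params, w$domain)
    sub <- obs[obs$year == yr & obs$pollutant == "PM25", ]
    expect_equal(sub$value, fld$pm25[w$stations$paired_cell])
    sub_o3 <- obs[obs$year == yr & obs$pollutant == "O3", ]
    expect_equal(sub_o3$value, fld$o3[w$stations$paired_cell])
  }
})

test_that("observation noise has the requested standard deviation", {
  w <- tiny_world()
  traj <- true_trajectory(years = 2015, configs = matrix(rep(1, 5), 1))
  p <- w$params
  p$noise_sd_pm <- 1
  reps <- sapply(1:1000, function(i)
    synth_observations(traj, p, w$domain, w$stations, seed = i)$value[1])
  expect_equal(sd(reps), 1, tolerance = 0.1)
})

test_that("true trajectory pins 2015 at baseline and stays in bounds", {
  traj <- true_trajectory()
  expect_equal(unname(traj["2015", ]), rep(1, 5))
  expect_true(all(traj >= 0 & traj <= 1.5))
  expect_error(true_trajectory(years = 2015,
                               configs = matrix(c(1, 1, 1, 1, 0.8), 1)),
               "baseline")
})
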