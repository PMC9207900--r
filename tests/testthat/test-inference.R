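test_that("station deltas are target minus base with dropped-station bookkeeping", {
  rec <- data.frame(
    station_id = c("A", "A", "B", "B", "C"),
    year = c(2015, 2020, 2015, 2020, 2015),
    pollutant = "PM25",
    value = c(40, 28, 50, 50, 33))
  d <- station_deltas(rec, target_year = 2020)
  expect_equal(d$delta[d$station_id == "A"], -12)
  expect_equal(d$delta[d$station_id == "B"], 0)
  expect_equal(attr(d, "n_dropped"), 1)  # C lacks 2020
  expect_false("C" %in% d$station_id)

  same <- station_deltas(rec, target_year = 2015)
  expect_true(all(same$delta == 0))
  expect_error(station_deltas(rec[rec$station_id == "C", ], target_year = 2020),
               "no station")
})

test_that("all-zero observed deltas match the baseline configuration everywhere", {
  w <- study_world()
  bank <- study_bank_calibrated()
  zero_deltas <- data.frame(
    station_id = w$stations$station_id, pollutant = "PM25",
    base_year = 2015L, target_year = 2020L, delta = 0)
  m <- match_configs(zero_deltas, bank, w$stations)
  base_row <- which(apply(as.data.frame(m)[, 1:5], 1, function(r) all(r == 1)))
  expect_equal(m$count[base_row], nrow(w$stations))
})

test_that("the retained set shrinks as the tolerance shrinks", {
  w <- study_world()
  bank <- study_bank_calibrated()
  obs <- synth_observations(true_trajectory(), w$params, w$domain, w$stations,
                            seed = 5, relative_noise = 0.02)
  deltas <- station_deltas(obs, target_year = 2020)
  m_small <- match_configs(deltas, bank, w$stations, tol = 0.005)
  m_mid <- match_configs(deltas, bank, w$stations, tol = 0.01)
  m_big <- match_configs(deltas, bank, w$stations, tol = 0.05)
  expect_true(all(m_small$count <= m_mid$count))
  expect_true(all(m_mid$count <= m_big$count))
  # counting is station-order invariant
  perm <- sample(nrow(deltas))
  m_perm <- match_configs(deltas[perm, ], bank, w$stations, tol = 0.01)
  expect_equal(m_perm$count, m_mid$count)
})

test_that("informed estimate summarizes the top configurations correctly", {
  grid <- interior_configuration_grid()
  m <- as.data.frame(grid)
  m$count <- 0L
  # single matching configuration -> the estimate is exactly that row
  i <- which(apply(m[, 1:5], 1, function(r)
    all(abs(r - c(0.4, 0.8, 1.0, 0.6, 1.2)) < 1e-9)))
  m$count[i] <- 5L
  attr(m, "baseline") <- baseline_config()
  class(m) <- c("match_result", "data.frame")
  est <- informed_estimate(m, K = 1000)
  expect_equal(unname(est$mean), c(0.4, 0.8, 1.0, 0.6, 1.2), tolerance = 1e-9)
  expect_equal(est$K_used, 1)
  expect_true(all(diff(est$percentiles[, "res"]) >= 0))

  # two equal-count configurations symmetric about baseline -> mean = baseline
  m$count[] <- 0L
  lo <- which(apply(m[, 1:5], 1, function(r) all(abs(r - 0.8) < 1e-9)))
  hi <- which(apply(m[, 1:5], 1, function(r) all(abs(r - 1.2) < 1e-9)))
  m$count[c(lo, hi)] <- 3L
  est2 <- informed_estimate(m, K = 1000)
  expect_equal(unname(est2$mean), rep(1, 5), tolerance = 1e-9)

  m$count[] <- 0L
  expect_error(informed_estimate(m), "larger tol")
})

test_that("species averaging is the unweighted mean over species", {
  ch <- matrix(1.0, nrow = 9, ncol = 5)
  expect_equal(unname(average_species_changes(ch)), rep(1, 5))
  ch2 <- rbind(rep(0.8, 5), rep(1.2, 5))
  expect_equal(unname(average_species_changes(ch2)), rep(1, 5))
  set.seed(1)
  ch3 <- matrix(runif(45, 0.5, 1.5), nrow = 9)
  expect_equal(average_species_changes(ch3[sample(9), ]),
               average_species_changes(ch3))
  expect_error(average_species_changes(ch3[0, ]), "at least one species")
})

test_that("noiseless grid-truth observations are recovered exactly at the top", {
  w <- study_world()
  bank <- study_bank_calibrated()
  # truth: a single on-grid configuration in 2020
  truth <- c(0.6, 0.8, 1.0, 0.8, 0.6)
  traj <- true_trajectory(years = c(2015, 2020),
                          configs = rbind(rep(1, 5), truth))
  obs <- synth_observations(traj, w$params, w$domain, w$stations,
                            seed = 2, relative_noise = 0)
  deltas <- station_deltas(obs, target_year = 2020)
  m <- match_configs(deltas, bank, w$stations)
  truth_row <- which(apply(as.data.frame(m)[, 1:5], 1,
                           function(r) all(abs(r - truth) < 1e-9)))
  expect_equal(m$count[truth_row], max(m$count))
})
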