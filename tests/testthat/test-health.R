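test_that("GEMM relative risk matches the published functional form", {
  g <- gemm_params()
  expect_equal(g$counterfactual, 2.4)
  # at and below the counterfactual there is no excess risk
  expect_equal(gemm_rr(2.4, g), 1)
  expect_equal(gemm_rr(0, g), 1)
  # hand evaluation with all-age constants (theta 0.1430, alpha 1.6,
  # mu 15.5, nu 36.8) at 52.8 ug/m3
  z <- 52.8 - 2.4
  by_hand <- exp(0.1430 * log(1 + z / 1.6) / (1 + exp(-(z - 15.5) / 36.8)))
  expect_equal(gemm_rr(52.8, g), by_hand, tolerance = 1e-12)
  expect_equal(by_hand, 1.43, tolerance = 0.005)
  # continuous and non-decreasing in concentration
  cc <- seq(0, 300, by = 0.5)
  rr <- gemm_rr(cc, g)
  expect_true(all(diff(rr) >= -1e-12))
  expect_true(all(rr >= 1))
  # age-specific thetas load and order risk sensibly
  expect_gt(gemm_rr(50, g, age_group = "25-29"), gemm_rr(50, g, age_group = "80+"))
})

test_that("O3 relative risk is log-linear above 35.7 ppb", {
  p <- o3_rr_params(rr_per_10ppb = 1.063)
  expect_equal(o3_rr(35.7, p), 1)
  expect_equal(o3_rr(10, p), 1)
  expect_equal(o3_rr(45.7, p), 1.063, tolerance = 1e-12)
  expect_equal(o3_rr(55.7, p), 1.063^2, tolerance = 1e-12)
  expect_error(o3_rr(40, o3_rr_params(rr_per_10ppb = 1.05), rr_per_10ppb = 0.9),
               ">= 1")
})

test_that("PAF is the attributable share and stays in [0, 1)", {
  expect_equal(paf(1), 0)
  expect_equal(paf(2), 0.5)
  rr <- seq(1, 100, by = 0.01)
  p <- paf(rr)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
  expect_error(paf(0.99), ">= 1")
})

test_that("mortality burden reproduces hand arithmetic", {
  # single cell, one age group, pop 10,000, rate 0.01, RR = 2 -> 50 deaths
  demo <- flat_demographics(1, outcome = "COPD")
  o3p <- o3_rr_params(rr_per_10ppb = 2, lower95 = 2, upper95 = 2)
  res <- mortality_burden(45.7, demo, 2015, outcome = "COPD", o3p = o3p)
  expect_equal(res$central, 10000 * 0.01 * 0.5, tolerance = 1e-12)

  # below the counterfactual -> zero burden
  res0 <- mortality_burden(2.0, flat_demographics(3), 2015, outcome = "NCD")
  expect_equal(res0$central, 0)

  # linear in population
  demo2 <- flat_demographics(1, pop = 2e4, outcome = "COPD")
  res2 <- mortality_burden(45.7, demo2, 2015, outcome = "COPD", o3p = o3p)
  expect_equal(res2$central, 2 * res$central)

  expect_error(mortality_burden(45.7, demo, 2015, outcome = "NCD+LRI"),
               "missing baseline rates")
})

test_that("burden is monotone in the concentration field", {
  w <- tiny_world()
  fld <- simulate_concentrations(baseline_config(), w$params, w$domain)
  b1 <- mortality_burden(fld$pm25, w$demo, 2015)$central
  b2 <- mortality_burden(fld$pm25 * 1.2, w$demo, 2015)$central
  expect_gt(b2, b1)
  expect_gte(b1, 0)
})

test_that("attribution shares are additive to the total burden", {
  w <- tiny_world()
  bank <- tiny_bank()
  res <- attribute_sectors(bank, baseline_config(), w$demo, 2015)
  total <- res$central[res$method == "total"]
  parts <- sum(res$central[res$method == "attribution"])
  expect_equal(parts, total, tolerance = 1e-9)
  expect_true(all(res$central >= -1e-9))
})

test_that("a single-sector world attributes everything to that sector", {
  d <- make_domain(3, 3, 2, seed = 5)
  p <- pseudo_simulator_params(d, seed = 6)
  p$baseline_pm[] <- 0
  p$nh3_limited_coeff[] <- 0
  p$linear_pm_coeff[, c("RES", "TRA", "AGR", "ENE")] <- 0
  design <- latin_hypercube_maximin(15, seed = 7, n_candidates = 10)
  fields <- run_simulator(design, p, d)
  bank <- train_emulator_bank(design, fields, emulator_spec(seed = 8, restarts = 1),
                              domain = d)
  demo <- make_demographics(d, seed = 9)
  res <- attribute_sectors(bank, baseline_config(), demo, 2015)
  ind <- res$central[res$sector == "IND"]
  total <- res$central[res$method == "total"]
  expect_equal(ind / total, 1, tolerance = 0.01)
  others <- res$central[res$method == "attribution" & res$sector != "IND"]
  expect_true(all(abs(others) / total < 0.01))
})

test_that("subtraction-method benefits are below attribution at high exposure", {
  w <- tiny_world()
  bank <- tiny_bank()
  att <- attribute_sectors(bank, baseline_config(), w$demo, 2015)
  for (s in c("RES", "IND")) {   # the two large sectors
    sub <- subtract_sector(bank, baseline_config(), s, w$demo, 2015)
    att_s <- att$central[att$sector == s & att$method == "attribution"]
    expect_lte(sub$central, att_s * (1 + 1e-6))
    expect_gt(sub$central, 0)
  }
})

test_that("subtraction and attribution agree in the linear low-exposure regime", {
  # tiny concentrations with a zero counterfactual: attributable risk is
  # linear through the origin, so zero-out shares and burden differences
  # coincide to ~1%
  d <- make_domain(2, 2, 1, seed = 3)
  p <- pseudo_simulator_params(d, seed = 4,
                               mean_linear_pm = c(RES = 0.004, IND = 0.006,
                                                  TRA = 0.001, AGR = 0.001,
                                                  ENE = 0.001))
  p$baseline_pm[] <- 0
  p$nh3_limited_coeff[] <- 0
  design <- latin_hypercube_maximin(15, seed = 5, n_candidates = 10)
  fields <- run_simulator(design, p, d)
  bank <- train_emulator_bank(design, fields, emulator_spec(seed = 6, restarts = 1),
                              domain = d)
  demo <- make_demographics(d, seed = 7)
  g0 <- gemm_params()
  g0$counterfactual <- 0
  att <- attribute_sectors(bank, baseline_config(), demo, 2015, gemm = g0)
  for (s in c("RES", "IND")) {
    sub <- subtract_sector(bank, baseline_config(), s, demo, 2015,
                           gemm = g0)$central
    att_s <- att$central[att$sector == s & att$method == "attribution"]
    expect_equal(sub, att_s, tolerance = 0.02)
  }
})

test_that("counterfactual demographics reduce to the standard burden", {
  w <- tiny_world()
  fld <- simulate_concentrations(baseline_config(), w$params, w$domain)
  std <- mortality_burden(fld$pm25, w$demo, 2015)
  cf <- counterfactual_demographics(fld$pm25, w$demo, 2015, 2015)
  expect_equal(cf$central, std$central)
  # older demographics at equal exposure carry a larger burden
  cf2020 <- counterfactual_demographics(fld$pm25, w$demo, 2015, 2020)
  expect_gt(cf2020$central, std$central)
})

test_that("burden uncertainty is seeded and collapses without uncertainty", {
  demo <- flat_demographics(2, outcome = "COPD")
  o3p <- o3_rr_params(rr_per_10ppb = 2, lower95 = 2, upper95 = 2)
  res <- burden_uncertainty(c(45.7, 50), demo, 2015, outcome = "COPD",
                            n_draws = 200, seed = 1, age_frac_rel = 0,
                            o3p = o3p)
  expect_equal(res$lower95, res$central, tolerance = 1e-9)
  expect_equal(res$upper95, res$central, tolerance = 1e-9)

  w <- tiny_world()
  fld <- simulate_concentrations(baseline_config(), w$params, w$domain)
  a <- burden_uncertainty(fld$pm25, w$demo, 2015, n_draws = 150, seed = 4)
  b <- burden_uncertainty(fld$pm25, w$demo, 2015, n_draws = 150, seed = 4)
  expect_identical(a, b)
  expect_lte(a$lower95, a$central)
  expect_gte(a$upper95, a$central)
  expect_error(burden_uncertainty(fld$pm25, w$demo, 2015, n_draws = 50), "100")
})

test_that("uncertainty width grows with the exposure-response SE", {
  demo <- flat_demographics(2, outcome = "NCD")
  g <- gemm_params()
  widths <- vapply(c(0.005, 0.02, 0.06), function(se) {
    g$all_age$theta_se <- se
    r <- burden_uncertainty(c(40, 60), demo, 2015, outcome = "NCD",
                            n_draws = 400, seed = 2, age_frac_rel = 0, gemm = g)
    r$upper95 - r$lower95
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
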