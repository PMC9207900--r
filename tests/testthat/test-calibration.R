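test_that("factor metrics reproduce hand-evaluated values", {
  obs <- c(10, 20, 30, 40)
  expect_equal(nmbf(obs, obs), 0)
  expect_equal(nmaef(obs, obs), 0)
  expect_equal(nmbf(2 * obs, obs), 1)     # factor-of-2 overestimate
  expect_equal(nmbf(obs / 2, obs), -1)    # symmetric underestimate
  expect_equal(nmaef(2 * obs, obs), 1)
  model <- c(12, 18, 33, 41)
  expect_equal(nmbf(model, obs), oracle_nmbf(model, obs))
  expect_equal(nmaef(model, obs), oracle_nmaef(model, obs))
})

test_that("factor metrics satisfy their invariants on random pairs", {
  set.seed(77)
  for (i in 1:1000) {
    m <- runif(8, 0.1, 50)
    o <- runif(8, 0.1, 50)
    expect_gte(nmaef(m, o), abs(nmbf(m, o)) - 1e-12)
  }
  set.seed(78)
  for (i in 1:50) {
    m <- runif(6, 0.1, 50); o <- runif(6, 0.1, 50); k <- runif(1, 0.1, 10)
    expect_equal(nmbf(m, o), -nmbf(o, m), tolerance = 1e-12)   # antisymmetry
    expect_equal(nmbf(k * m, k * o), nmbf(m, o), tolerance = 1e-12) # scale-free
  }
  expect_error(nmbf(c(0, 0), c(1, 2)), "zero")
})

test_that("derived scalings match control to observations by region", {
  w <- tiny_world()
  control <- simulate_concentrations(baseline_config(), w$params, w$domain)
  st <- w$stations
  # observations exactly equal to control -> all factors 1
  obs_eq <- data.frame(station_id = rep(st$station_id, 2),
                       pollutant = rep(c("PM25", "O3"), each = nrow(st)),
                       value = c(control$pm25[st$paired_cell],
                                 control$o3[st$paired_cell]))
  tab <- derive_scaling(control, obs_eq, st, w$domain)
  expect_equal(tab$factor, rep(1, nrow(tab)), tolerance = 1e-12)

  # control = obs/2 at every station -> all factors 2
  obs_double <- obs_eq
  obs_double$value <- obs_double$value * 2
  tab2 <- derive_scaling(control, obs_double, st, w$domain)
  expect_equal(tab2$factor, rep(2, nrow(tab2)), tolerance = 1e-12)
})

test_that("prefectures without stations inherit province then domain factors", {
  d <- make_domain(6, 6, 4, seed = 11)
  # stations only in region 1's cells
  cells_r1 <- which(d$region_id == 1)
  st <- data.frame(station_id = c("A", "B"),
                   x = d$centroids[cells_r1[1:2], 1],
                   y = d$centroids[cells_r1[1:2], 2],
                   paired_cell = cells_r1[1:2])
  class(st) <- c("station_set", "data.frame")
  control <- conc_fields(rep(10, d$n_cells), rep(40, d$n_cells))
  obs <- data.frame(station_id = rep(st$station_id, 2),
                    pollutant = rep(c("PM25", "O3"), each = 2),
                    value = c(15, 15, 60, 60))
  tab <- derive_scaling(control, obs, st, d)
  pm <- tab[tab$pollutant == "PM25", ]
  expect_equal(pm$factor[pm$region_id == 1], 1.5)
  expect_equal(pm$provenance[pm$region_id == 1], "prefecture")
  same_prov <- setdiff(which(d$region_parent == d$region_parent[1]), 1)
  if (length(same_prov))
    expect_true(all(pm$provenance[pm$region_id %in% same_prov] == "province"))
  other_prov <- which(d$region_parent != d$region_parent[1])
  expect_true(all(pm$provenance[pm$region_id %in% other_prov] == "domain"))
  # all factors resolve and equal 1.5 here (uniform bias)
  expect_equal(pm$factor, rep(1.5, nrow(pm)))
})

test_that("applying a scaling rescales cells and composes onto predictions", {
  w <- tiny_world()
  bank <- tiny_bank()
  control <- simulate_concentrations(baseline_config(), w$params, w$domain)
  st <- w$stations
  obs <- data.frame(station_id = rep(st$station_id, 2),
                    pollutant = rep(c("PM25", "O3"), each = nrow(st)),
                    value = c(1.3 * control$pm25[st$paired_cell],
                              0.8 * control$o3[st$paired_cell]))
  tab <- derive_scaling(control, obs, st, w$domain)

  scaled <- apply_scaling(control, tab, w$domain)
  expect_true(all(scaled$pm25 >= 0) && all(scaled$o3 >= 0))
  # region-constant bias is removed exactly at the stations
  expect_lt(abs(nmbf(scaled$pm25[st$paired_cell],
                     obs$value[obs$pollutant == "PM25"])), 1e-9)

  # scaling-then-predicting equals predicting-then-scaling (multiplicative)
  cfg <- c(0.6, 1.1, 0.9, 0.7, 1.2)
  sbank <- apply_scaling(bank, tab, w$domain)
  p_scaled <- predict(sbank, cfg)
  p_raw <- predict(bank, cfg)
  fac_pm <- tab$factor[tab$pollutant == "PM25"][match(w$domain$region_id,
            tab$region_id[tab$pollutant == "PM25"])]
  expect_equal(as.vector(p_scaled$pm25), as.vector(p_raw$pm25) * fac_pm,
               tolerance = 1e-12)
  # identity table leaves predictions unchanged
  id_tab <- tab
  id_tab$factor <- 1
  expect_equal(predict(apply_scaling(bank, id_tab, w$domain), cfg), p_raw)
})

test_that("scaling tables round-trip through CSV", {
  w <- tiny_world()
  control <- simulate_concentrations(baseline_config(), w$params, w$domain)
  st <- w$stations
  obs <- data.frame(station_id = rep(st$station_id, 2),
                    pollutant = rep(c("PM25", "O3"), each = nrow(st)),
                    value = c(1.2 * control$pm25[st$paired_cell],
                              0.9 * control$o3[st$paired_cell]))
  tab <- derive_scaling(control, obs, st, w$domain)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scaling_csv(tab, path)
  expect_equal(as.data.frame(read_scaling_csv(path)), as.data.frame(tab),
               tolerance = 1e-12)
})
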