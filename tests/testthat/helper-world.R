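# Shared synthetic-world fixtures. Heavy objects (trained emulator banks)
# are built lazily once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small world for unit tests: 6x6 grid, 4 prefectures, 12 stations
tiny_world <- function() {
  fixture("tiny_world", function() {
    domain <- make_domain(6, 6, 4, seed = 11)
    list(
      domain = domain,
      params = pseudo_simulator_params(domain, seed = 12),
      stations = make_stations(domain, 12, seed = 13),
      demo = make_demographics(domain, seed = 14)
    )
  })
}

# trained (uncalibrated) bank on the tiny world: 20-run design, light restarts
tiny_bank <- function() {
  fixture("tiny_bank", function() {
    w <- tiny_world()
    design <- latin_hypercube_maximin(20, seed = 21, n_candidates = 30)
    fields <- run_simulator(design, w$params, w$domain)
    train_emulator_bank(design, fields, emulator_spec(seed = 22, restarts = 2),
                        domain = w$domain)
  })
}

# desk-scale study world: 10x10 grid, 8 prefectures / 3 provinces, 25 stations,
# 50-run maximin training design + 5-run test design (the default conditions)
study_world <- function() {
  fixture("study_world", function() {
    domain <- make_domain(10, 10, 8, seed = 101)
    params <- pseudo_simulator_params(domain, seed = 102)
    list(
      domain = domain, params = params,
      stations = make_stations(domain, 25, seed = 103),
      demo = make_demographics(domain, seed = 104),
      train = latin_hypercube_maximin(50, seed = 105, role = "train"),
      test = latin_hypercube_maximin(5, seed = 106, role = "test")
    )
  })
}

study_bank <- function() {
  fixture("study_bank", function() {
    w <- study_world()
    fields <- run_simulator(w$train, w$params, w$domain)
    train_emulator_bank(w$train, fields, emulator_spec(seed = 107),
                        domain = w$domain)
  })
}

# study bank with observation scaling derived from noiseless 2015 records
study_bank_calibrated <- function() {
  fixture("study_bank_cal", function() {
    w <- study_world()
    control <- simulate_concentrations(baseline_config(), w$params, w$domain)
    obs15 <- data.frame(
      station_id = rep(w$stations$station_id, 2),
      pollutant = rep(c("PM25", "O3"), each = nrow(w$stations)),
      value = c(control$pm25[w$stations$paired_cell],
                control$o3[w$stations$paired_cell]))
    scaling <- derive_scaling(control, obs15, w$stations, w$domain)
    apply_scaling(study_bank(), scaling, w$domain)
  })
}

run_simulator <- function(design, params, domain) {
  lapply(seq_len(nrow(design)), function(i)
    simulate_concentrations(as.numeric(design[i, 1:5]), params, domain))
}

# minimal hand-constructed demographics: one year, uniform rates, for burden
# arithmetic tests
flat_demographics <- function(n_cells, year = 2015, pop = 1e4, rate = 0.01,
                              age_group = "60-64", outcome = "NCD") {
  population <- matrix(pop, nrow = n_cells, ncol = 1,
                       dimnames = list(NULL, year))
  age_structure <- matrix(0, nrow = 1, ncol = 12,
                          dimnames = list(year, age_groups()))
  age_structure[1, age_group] <- 1
  rates <- data.frame(year = year, outcome = outcome, age_group = age_groups(),
                      central = 0, lower95 = 0, upper95 = 0,
                      stringsAsFactors = FALSE)
  rates$central[rates$age_group == age_group] <- rate
  rates$lower95 <- rates$central
  rates$upper95 <- rates$central
  structure(list(population = population, age_structure = age_structure,
                 rates = rates, years = year, age_groups = age_groups()),
            class = "demographics")
}
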