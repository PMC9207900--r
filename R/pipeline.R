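#' Bottom-up exposure and burden time series
#'
#' Drives the calibrated emulators with a per-year emission trajectory
#' (e.g. inventory-derived sector fractions) and returns, for every
#' year, national population-weighted exposures, the total PM2.5 and O3
#' burdens, and the attribution-method sector breakdown.
#'
#' @param trajectory A `true_trajectory` (or matrix with year rownames,
#'   sector columns).
#' @param bank Calibrated `emulator_bank`.
#' @param demographics A `demographics` object covering the years.
#' @param domain The `aq_domain` (default: the bank's).
#' @param gemm,o3p Exposure-response parameters.
#' @return List of data.frames: `exposures` (year, pollutant, exposure),
#'   `burdens` (stacked `burden_result` rows: totals for PM2.5 NCD+LRI
#'   and O3 COPD), `sector_burdens` (attribution rows per year).
#' @export
bottom_up_timeseries <- function(trajectory, bank, demographics,
                                 domain = bank$domain,
                                 gemm = gemm_params(), o3p = o3_rr_params()) {
  stopifnot(inherits(domain, "aq_domain"))
  years <- as.integer(rownames(trajectory))
  if (!all(years %in% demographics$years))
    stop("demographics do not cover years: ",
         paste(setdiff(years, demographics$years), collapse = ", "))
  preds <- predict(bank, config_matrix(trajectory))

  exposures <- do.call(rbind, lapply(seq_along(years), function(i) {
    pop <- demographics$population[, as.character(years[i])]
    data.frame(year = years[i],
               pollutant = c("PM25", "O3"),
               exposure = c(population_weighted(preds$pm25[i, ], pop),
                            population_weighted(preds$o3[i, ], pop)),
               stringsAsFactors = FALSE)
  }))

  burdens <- do.call(rbind, lapply(seq_along(years), function(i) {
    rbind(mortality_burden(preds$pm25[i, ], demographics, years[i],
                           c("NCD", "LRI"), gemm, o3p),
          mortality_burden(preds$o3[i, ], demographics, years[i],
                           "COPD", gemm, o3p))
  }))

  sector_burdens <- do.call(rbind, lapply(seq_along(years), function(i)
    attribute_sectors(bank, trajectory[i, ], demographics, years[i],
                      c("NCD", "LRI"), gemm, o3p)))

  list(exposures = exposures, burdens = burdens,
       sector_burdens = sector_burdens)
}

#' Search emission scenarios meeting an exposure target
#'
#' Exhaustively evaluates a lattice of reductions in the free sectors
#' (others held at `fixed_config`), keeps the configurations whose
#' national population-weighted PM2.5 exposure meets the target, and
#' reports the Pareto-minimal reductions together with the avoided
#' mortality (subtraction method: burden at `fixed_config` minus burden
#' at the scenario).
#'
#' @param bank Calibrated `emulator_bank`.
#' @param demographics A `demographics` object.
#' @param target Target national PM2.5 exposure (ug/m3), > 0.
#' @param year Year for population weighting and burden.
#' @param free_sectors Sector codes allowed to vary (default RES, IND).
#' @param fixed_config Configuration holding the non-free sectors (and
#'   the reference for reductions; default the baseline).
#' @param grid_step Lattice step for the free sectors (default 0.1).
#' @param domain The `aq_domain` (default: the bank's).
#' @param gemm,o3p Exposure-response parameters.
#' @return A `scenario_result` list: `feasible`, `admissible`
#'   (data.frame of configurations with exposure), `frontier`
#'   (Pareto-minimal reductions with avoided deaths), `reference`
#'   (exposure and burden at `fixed_config`), `target`.
#' @export
scenario_search <- function(bank, demographics, target, year = 2020,
                            free_sectors = c("RES", "IND"),
                            fixed_config = baseline_config(),
                            grid_step = 0.1, domain = bank$domain,
                            gemm = gemm_params(), o3p = o3_rr_params()) {
  stopifnot(inherits(domain, "aq_domain"))
  if (target <= 0) stop("target must be > 0")
  fixed_config <- as_config(fixed_config)
  ki <- match(free_sectors, sectors())
  if (anyNA(ki)) stop("unknown sector in free_sectors")
  pop <- demographics$population[, as.character(year)]

  levels <- lapply(ki, function(k) seq(0, fixed_config[k], by = grid_step))
  lattice <- as.matrix(expand.grid(levels, KEEP.OUT.ATTRS = FALSE))
  configs <- matrix(rep(fixed_config, each = nrow(lattice)), ncol = 5,
                    dimnames = list(NULL, sectors()))
  configs[, ki] <- lattice

  preds <- predict(bank, configs)
  expo <- apply(preds$pm25, 1, population_weighted, pop = pop)
  adm <- which(expo <= target)

  ref_pred <- predict(bank, fixed_config)
  ref_expo <- population_weighted(ref_pred$pm25[1, ], pop)
  ref_burden <- mortality_burden(ref_pred$pm25[1, ], demographics, year,
                                 c("NCD", "LRI"), gemm, o3p)$central

  admissible <- data.frame(configs[adm, , drop = FALSE],
                           exposure = expo[adm], check.names = FALSE)
  names(admissible)[1:5] <- tolower(sectors())

  frontier <- integer(0)
  if (length(adm)) {
    # Pareto-minimal reductions: no other admissible point with all free-sector
    # fractions >= (less reduction) and one strictly greater
    lat_adm <- lattice[adm, , drop = FALSE]
    dominated <- vapply(seq_len(nrow(lat_adm)), function(i) {
      any(vapply(seq_len(nrow(lat_adm)), function(j) {
        j != i && all(lat_adm[j, ] >= lat_adm[i, ]) && any(lat_adm[j, ] > lat_adm[i, ])
      }, logical(1)))
    }, logical(1))
    frontier <- which(!dominated)
  }
  frontier_df <- admissible[frontier, , drop = FALSE]
  if (nrow(frontier_df)) {
    frontier_df$avoided_deaths <- vapply(frontier, function(i) {
      b <- mortality_burden(preds$pm25[adm[i], ], demographics, year,
                            c("NCD", "LRI"), gemm, o3p)$central
      ref_burden - b
    }, numeric(1))
  }

  structure(list(
    feasible = length(adm) > 0,
    admissible = admissible,
    frontier = frontier_df,
    reference = list(exposure = ref_expo, burden = ref_burden,
                     config = fixed_config),
    target = target, year = year, free_sectors = free_sectors
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> target %.1f ug/m3 (%d): %s; %d admissible, %d on frontier\n",
              x$target, x$year,
              if (x$feasible) "feasible" else "infeasible",
              nrow(x$admissible), nrow(x$frontier)))
  invisible(x)
}

#' Run the full synthetic-world analysis pipeline
#'
#' End-to-end orchestration: build the synthetic world, draw the maximin
#' training/test designs, run the pseudo-simulator, train the per-cell
#' emulator bank, evaluate it on the held-out runs, calibrate to the
#' 2015 station observations, infer measurement-informed emission
#' changes from the 2015-2020 observed trends, and compute exposures and
#' burdens. Every stage seed derives from the single `seed` by a fixed
#' offset, so a run is reproducible end to end.
#'
#' @param seed Global integer seed.
#' @param n_x,n_y,n_regions,n_stations World size (defaults: 10 x 10
#'   grid, 8 prefectures in 3 provinces, 25 stations).
#' @param n_train,n_test Design sizes (defaults 50 and 5).
#' @param target_years Years of observed trends matched in the emission
#'   inference (default 2016:2020).
#' @param relative_noise Station observation noise as a fraction of the
#'   record value (default 0.02).
#' @param tol Relative match tolerance for the emission inference
#'   (default 0.01, i.e. within 1%).
#' @param top_k Top configurations summarized (default 1000).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as CSV/YAML/JSON.
#' @param quiet Suppress stage messages?
#' @return A list bundle with the world, designs, bank, evaluation
#'   report, calibration table and metrics, informed estimate, and
#'   per-year summaries.
#' @export
run_pipeline <- function(seed = 1L, n_x = 10L, n_y = 10L, n_regions = 8L,
                         n_stations = 25L, n_train = 50L, n_test = 5L,
                         target_years = 2016:2020, relative_noise = 0.02,
                         tol = 0.01, top_k = 1000L, out_dir = NULL,
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  seed <- as.integer(seed)
  stage_seed <- function(k) (seed + 1000L * k) %% .Machine$integer.max

  say("stage world: %d x %d grid, %d regions, %d stations", n_x, n_y, n_regions, n_stations)
  domain <- make_domain(n_x, n_y, n_regions, seed = stage_seed(1))
  params <- pseudo_simulator_params(domain, seed = stage_seed(2))
  stations <- make_stations(domain, n_stations, seed = stage_seed(3))
  demo <- make_demographics(domain, seed = stage_seed(4))
  traj <- true_trajectory()

  say("stage design: %d train + %d test maximin LHS", n_train, n_test)
  train <- latin_hypercube_maximin(n_train, seed = stage_seed(5), role = "train")
  test <- latin_hypercube_maximin(n_test, seed = stage_seed(6), role = "test")

  say("stage simulate: %d runs", n_train + n_test)
  sim <- function(design) lapply(seq_len(nrow(design)), function(i)
    simulate_concentrations(as.numeric(design[i, 1:5]), params, domain))
  train_fields <- sim(train)
  test_fields <- sim(test)

  say("stage train: %d emulators", 2L * domain$n_cells)
  bank <- train_emulator_bank(train, train_fields,
                              emulator_spec(seed = stage_seed(7)),
                              domain = domain)
  eval_report <- evaluate_bank(bank, test, test_fields)
  say("stage evaluate: R2 PM2.5 %.4f, O3 %.4f", eval_report$r2[1], eval_report$r2[2])

  say("stage calibrate")
  obs <- synth_observations(traj, params, domain, stations,
                            seed = stage_seed(8),
                            relative_noise = relative_noise)
  control <- simulate_concentrations(baseline_config(), params, domain)
  obs15 <- obs[obs$year == 2015, c("station_id", "pollutant", "value")]
  scaling <- derive_scaling(control, obs15, stations, domain)
  bank <- apply_scaling(bank, scaling, domain)
  scaled_control <- apply_scaling(control, scaling, domain)
  metrics <- list(
    pm25 = list(
      before = list(nmbf = nmbf(control$pm25[stations$paired_cell],
                                obs15$value[obs15$pollutant == "PM25"]),
                    nmaef = nmaef(control$pm25[stations$paired_cell],
                                  obs15$value[obs15$pollutant == "PM25"])),
      after = list(nmbf = nmbf(scaled_control$pm25[stations$paired_cell],
                               obs15$value[obs15$pollutant == "PM25"]),
                   nmaef = nmaef(scaled_control$pm25[stations$paired_cell],
                                 obs15$value[obs15$pollutant == "PM25"]))),
    o3 = list(
      before = list(nmbf = nmbf(control$o3[stations$paired_cell],
                                obs15$value[obs15$pollutant == "O3"]),
                    nmaef = nmaef(control$o3[stations$paired_cell],
                                  obs15$value[obs15$pollutant == "O3"])),
      after = list(nmbf = nmbf(scaled_control$o3[stations$paired_cell],
                               obs15$value[obs15$pollutant == "O3"]),
                   nmaef = nmaef(scaled_control$o3[stations$paired_cell],
                                 obs15$value[obs15$pollutant == "O3"]))))

  say("stage infer-emissions: %d target years over %d configurations",
      length(target_years), nrow(interior_configuration_grid()))
  deltas <- lapply(target_years, function(yr)
    station_deltas(obs, target_year = yr, pollutant = "PM25"))
  match <- match_configs(deltas, bank, stations, tol = tol)
  estimate <- informed_estimate(match, K = top_k)

  say("stage burden")
  summary_tbl <- bottom_up_timeseries(traj, bank, demo)

  bundle <- list(
    domain = domain, params = params, stations = stations,
    demographics = demo, trajectory = traj,
    train_design = train, test_design = test,
    bank = bank, eval_report = eval_report,
    scaling = scaling, calibration_metrics = metrics,
    observations = obs, match = match, estimate = estimate,
    summary = summary_tbl,
    seed = seed, elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  say("done in %.1f s", bundle$elapsed_s)
  bundle
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(bundle$train_design, file.path(out_dir, "design_train.csv"))
  write_design_csv(bundle$test_design, file.path(out_dir, "design_test.csv"))
  write_scaling_csv(bundle$scaling, file.path(out_dir, "scaling.csv"))
  utils::write.csv(as.data.frame(bundle$eval_report),
                   file.path(out_dir, "eval_report.csv"), row.names = FALSE)
  utils::write.csv(bundle$observations,
                   file.path(out_dir, "station_observations.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$match),
                   file.path(out_dir, "match_counts.csv"), row.names = FALSE)
  utils::write.csv(bundle$summary$exposures,
                   file.path(out_dir, "exposures.csv"), row.names = FALSE)
  write_burden_csv(bundle$summary$burdens, file.path(out_dir, "burdens.csv"))
  write_burden_csv(bundle$summary$sector_burdens,
                   file.path(out_dir, "sector_burdens.csv"))
  grid_df <- data.frame(cell = seq_len(bundle$domain$n_cells),
                        region_id = bundle$domain$region_id,
                        parent_region_id = bundle$domain$parent_region_id,
                        x = bundle$domain$centroids[, 1],
                        y = bundle$domain$centroids[, 2])
  utils::write.csv(grid_df, file.path(out_dir, "domain.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(calibration = bundle$calibration_metrics,
         informed_estimate = list(mean = as.list(bundle$estimate$mean),
                                  K_used = bundle$estimate$K_used),
         elapsed_s = bundle$elapsed_s, seed = bundle$seed),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(
    list(n_cells = bundle$domain$n_cells, seed = bundle$seed,
         sectors = sectors(),
         years = as.integer(rownames(bundle$trajectory))),
    file.path(out_dir, "world.yaml"))
  invisible(out_dir)
}
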