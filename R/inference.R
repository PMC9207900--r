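#' Observed station changes relative to a base year
#'
#' Computes per-station changes in an annual metric between a base year
#' (the calibration baseline, 2015) and a target year. Stations missing
#' either year are dropped and counted.
#'
#' @param records Data.frame `station_id, year, pollutant, value` (e.g.
#'   from [synth_observations()] or real monitor annual metrics).
#' @param target_year Year the change is measured to.
#' @param base_year Base year (default 2015).
#' @param pollutant `"PM25"` or `"O3"`.
#' @return Data.frame `station_id, pollutant, base_year, target_year,
#'   delta` with attribute `n_dropped`.
#' @export
station_deltas <- function(records, target_year, base_year = 2015,
                           pollutant = "PM25") {
  r <- records[records$pollutant == pollutant, , drop = FALSE]
  base <- r[r$year == base_year, c("station_id", "value")]
  targ <- r[r$year == target_year, c("station_id", "value")]
  merged <- merge(base, targ, by = "station_id", suffixes = c("_base", "_target"))
  n_dropped <- length(unique(r$station_id)) - nrow(merged)
  if (nrow(merged) == 0)
    stop("no station has records for both ", base_year, " and ", target_year)
  out <- data.frame(
    station_id = merged$station_id, pollutant = pollutant,
    base_year = as.integer(base_year), target_year = as.integer(target_year),
    delta = merged$value_target - merged$value_base,
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Rejection-match emission configurations to observed changes
#'
#' For every configuration in the grid, the predicted concentration
#' change at each station's paired cell (prediction at the configuration
#' minus prediction at the baseline configuration) is compared to that
#' station's observed change; predictions matching within the tolerance
#' are retained and the configuration's count is incremented once per
#' matching (station, target year) pair. The tolerance is relative with
#' an absolute floor: a match requires
#' `|pred - obs| <= tol * max(|obs|, floor)`.
#'
#' @param deltas One `station_deltas` result, or a list of them (e.g.
#'   one per target year and pollutant; counts are pooled).
#' @param bank Calibrated `emulator_bank`.
#' @param stations The `station_set` the deltas refer to.
#' @param grid `config_grid` to search (default
#'   [interior_configuration_grid()]).
#' @param baseline Baseline configuration (default all 1.0).
#' @param tol Relative tolerance (default 0.01, i.e. within 1%).
#' @param floor Absolute floor on the tolerance denominator
#'   (concentration units, default 1.0).
#' @param mode Pollutant-matching mode: `"PM25_only"` (default),
#'   `"O3_only"`, `"both"` (a station-year counts only if both
#'   pollutants match), or `"either"`.
#' @return A `match_result`: the grid with a `count` column, plus
#'   attributes `tol`, `mode`, `n_tuples`.
#' @export
match_configs <- function(deltas, bank, stations,
                          grid = interior_configuration_grid(),
                          baseline = baseline_config(),
                          tol = 0.01, floor = 1.0,
                          mode = c("PM25_only", "O3_only", "both", "either")) {
  mode <- match.arg(mode)
  if (is.data.frame(deltas)) deltas <- list(deltas)
  if (nrow(grid) < 1) stop("empty configuration grid")
  baseline <- as_config(baseline)

  used_pols <- switch(mode, PM25_only = "PM25", O3_only = "O3",
                      both = c("PM25", "O3"), either = c("PM25", "O3"))
  # predicted deltas per config at every paired cell, one matrix per pollutant
  cells <- stations$paired_cell
  X <- rbind(config_matrix(grid), matrix(baseline, nrow = 1))
  pred <- predict(bank, X, cells = cells)
  pred_delta <- list(
    PM25 = sweep(pred$pm25[-nrow(X), , drop = FALSE], 2, pred$pm25[nrow(X), ]),
    O3   = sweep(pred$o3[-nrow(X), , drop = FALSE], 2, pred$o3[nrow(X), ])
  )

  counts <- integer(nrow(grid))
  n_tuples <- 0L
  # group the delta tables by target year so "both"/"either" can pair them
  key <- vapply(deltas, function(d) paste(d$target_year[1]), character(1))
  for (yr in unique(key)) {
    dlist <- deltas[key == yr]
    pol_match <- list()
    for (pol in used_pols) {
      d <- Filter(function(x) x$pollutant[1] == pol, dlist)
      if (length(d) == 0) {
        if (mode %in% c("PM25_only", "O3_only"))
          stop("no ", pol, " deltas supplied for mode ", mode)
        next
      }
      d <- d[[1]]
      sidx <- match(d$station_id, stations$station_id)
      if (anyNA(sidx)) stop("delta for unknown station")
      thr <- tol * pmax(abs(d$delta), floor)
      # n_configs x n_stations logical
      pm <- abs(sweep(pred_delta[[pol]][, sidx, drop = FALSE], 2, d$delta)) <=
        matrix(thr, nrow = nrow(grid), ncol = length(sidx), byrow = TRUE)
      pol_match[[pol]] <- pm
    }
    m <- switch(mode,
      PM25_only = pol_match$PM25,
      O3_only = pol_match$O3,
      both = if (length(pol_match) == 2) pol_match[[1]] & pol_match[[2]]
             else stop("mode 'both' needs deltas for both pollutants"),
      either = if (length(pol_match) == 2) pol_match[[1]] | pol_match[[2]]
               else pol_match[[1]]
    )
    counts <- counts + rowSums(m)
    n_tuples <- n_tuples + ncol(m)
  }

  out <- as.data.frame(grid)
  out$count <- as.integer(counts)
  attr(out, "tol") <- tol
  attr(out, "mode") <- mode
  attr(out, "n_tuples") <- n_tuples
  attr(out, "baseline") <- baseline
  class(out) <- c("match_result", "data.frame")
  out
}

#' Measurement-informed emission estimate from matched configurations
#'
#' Ranks configurations by match count (ties broken by smaller Euclidean
#' distance to the baseline configuration, then lexicographically) and
#' summarizes the top `K` (default 1,000) by per-sector mean and the
#' 5th/25th/50th/75th/95th percentiles.
#'
#' @param match A `match_result`.
#' @param K Number of top configurations summarized (default 1000; all
#'   matched configurations if fewer have nonzero counts).
#' @return An `informed_estimate` list: `mean` (named per-sector),
#'   `percentiles` (5 x 5 matrix), `K_used`, `top` (the ranked subset).
#' @export
informed_estimate <- function(match, K = 1000L) {
  m <- match[match$count > 0, , drop = FALSE]
  if (nrow(m) == 0)
    stop("no configuration matched any observation; consider a larger tol")
  base <- attr(match, "baseline")
  cm <- config_matrix(m)
  dist_base <- sqrt(rowSums(sweep(cm, 2, base)^2))
  ord <- order(-m$count, dist_base, cm[, 1], cm[, 2], cm[, 3], cm[, 4], cm[, 5])
  top <- m[ord[seq_len(min(K, nrow(m)))], , drop = FALSE]
  tm <- config_matrix(top)
  colnames(tm) <- tolower(sectors())
  pct <- apply(tm, 2, stats::quantile, probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  est <- colMeans(tm)
  names(est) <- sectors()
  structure(list(mean = est, percentiles = pct, K_used = nrow(tm), top = top),
            class = "informed_estimate")
}

#' @export
print.informed_estimate <- function(x, ...) {
  cat(sprintf("<informed_estimate> top %d configurations; per-sector mean:\n",
              x$K_used))
  print(round(x$mean, 3))
  invisible(x)
}

#' Average per-sector emission changes over species
#'
#' Inventory emission changes are reported per chemical species (CO, NOx,
#' SO2, NH3, BC, OC, PM2.5, coarse PM, VOC); the emulator input is the
#' unweighted mean fractional change across species for each sector.
#'
#' @param species_changes Matrix or data.frame (species x sectors) of
#'   fractional changes; columns in [sectors()] order.
#' @return Named per-sector mean fractions.
#' @export
average_species_changes <- function(species_changes) {
  m <- as.matrix(species_changes)
  if (nrow(m) < 1) stop("need at least one species")
  out <- colMeans(m)
  names(out) <- sectors()[seq_len(ncol(m))]
  out
}

#' Parameter-recovery experiment for the emission inference
#'
#' Validation experiment: synthetic station observations are generated
#' from a known on-grid emission configuration (baseline in 2015, the
#' truth in every later target year) with multiplicative observation
#' noise, the rejection-matching inference is run, and the top-K
#' per-sector mean is compared to the truth. Repeated over seeded
#' replicates; a replicate succeeds when every sector's estimate is
#' within `tol_frac` (default one 0.2 grid increment) of the truth.
#'
#' @param bank Calibrated `emulator_bank`.
#' @param params `pseudo_sim_params` of the generating world.
#' @param domain The `aq_domain`.
#' @param stations The `station_set`.
#' @param truth On-grid emission configuration acting as ground truth
#'   (default: the default trajectory's 2020 configuration).
#' @param target_years Years observed after the 2015 baseline.
#' @param n_reps Number of seeded replicates (default 20).
#' @param noise Relative observation noise (default 0.05, i.e. 5%).
#' @param tol_frac Per-sector success tolerance (default 0.2).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param K Top configurations summarized (default 1000).
#' @return List: `success` (logical per replicate), `estimates`
#'   (n_reps x 5), `truth`, `rate` (fraction of successes).
#' @export
recovery_experiment <- function(bank, params, domain, stations,
                                truth = c(0.6, 0.6, 0.8, 0.6, 0.6),
                                target_years = 2016:2020, n_reps = 20L,
                                noise = 0.05, tol_frac = 0.2, seed = 1L,
                                K = 1000L) {
  truth <- as_config(truth)
  years <- c(2015, target_years)
  traj <- true_trajectory(years = years,
                          configs = rbind(rep(1, 5),
                                          matrix(rep(truth, length(target_years)),
                                                 ncol = 5, byrow = TRUE)))
  estimates <- matrix(NA_real_, n_reps, 5, dimnames = list(NULL, sectors()))
  for (r in seq_len(n_reps)) {
    obs <- synth_observations(traj, params, domain, stations,
                              seed = seed + r, relative_noise = noise)
    deltas <- lapply(target_years, function(yr)
      station_deltas(obs, target_year = yr, pollutant = "PM25"))
    m <- match_configs(deltas, bank, stations)
    estimates[r, ] <- informed_estimate(m, K = K)$mean
  }
  success <- apply(abs(sweep(estimates, 2, truth)) <= tol_frac + 1e-9, 1, all)
  list(success = success, estimates = estimates, truth = truth,
       rate = mean(success))
}
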