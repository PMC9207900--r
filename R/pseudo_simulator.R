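#' Parameters of the pseudo chemistry-transport simulator
#'
#' Draws per-cell response coefficients for a smooth, sector-separable
#' surrogate of a chemistry-transport model. PM2.5 responds linearly to
#' each sector plus one ammonia-limited interaction term,
#' `min(f_AGR, (f_IND + f_ENE)/2)`, standing in for NH3-limited secondary
#' inorganic aerosol formation. O3 has a VOC-driven industrial term and a
#' non-monotone NOx response to land transport (linear minus quadratic),
#' standing in for titration chemistry. Coefficient magnitudes default to
#' a high-exposure regime: at the baseline configuration (all sectors at
#' 1.0) the domain-mean PM2.5 is roughly 50 ug/m3 with sector shares of
#' about 31% industry, 22% residential, and a few percent each for the
#' remaining sectors, and O3 sits near 45 ppb.
#'
#' @param domain An `aq_domain`.
#' @param seed Integer seed; identical seed gives identical coefficients.
#' @param noise_sd_pm,noise_sd_o3 Observation noise SDs (ug/m3, ppb) used
#'   when concentrations are simulated with `noisy = TRUE` or when
#'   synthetic station records are generated.
#' @param mean_linear_pm Named numeric: mean per-sector linear PM2.5
#'   coefficient (ug/m3 per unit scaling), in [sectors()] order.
#' @return A `pseudo_sim_params` list of per-cell coefficient vectors.
#' @export
pseudo_simulator_params <- function(domain, seed,
                                    noise_sd_pm = 1.0, noise_sd_o3 = 0.5,
                                    mean_linear_pm = c(RES = 11, IND = 16,
                                                       TRA = 2.5, AGR = 1.5,
                                                       ENE = 1.0)) {
  stopifnot(inherits(domain, "aq_domain"))
  stopifnot(identical(names(mean_linear_pm), sectors()))
  n <- domain$n_cells
  rng <- local_seed(seed)
  lin <- sapply(mean_linear_pm, function(m) stats::runif(n, 0.5 * m, 1.5 * m))
  lin <- matrix(lin, nrow = n, dimnames = list(NULL, sectors()))
  p <- list(
    baseline_pm = stats::runif(n, 12, 25),      # non-sector "other sources"
    linear_pm_coeff = lin,
    nh3_limited_coeff = stats::runif(n, 1, 3),  # AGR x (IND+ENE) interaction
    o3_background = stats::runif(n, 35, 48),
    o3_voc_coeff = stats::runif(n, 2, 6),
    o3_nox_coeff = stats::runif(n, 1, 4),
    o3_nox_quad_coeff = stats::runif(n, 0.5, 2.5),
    noise_sd_pm = noise_sd_pm,
    noise_sd_o3 = noise_sd_o3,
    seed = as.integer(seed)
  )
  restore_seed(rng)
  structure(p, class = "pseudo_sim_params")
}

#' Check an emission configuration vector
#'
#' An emission configuration is a vector of five per-sector scaling
#' fractions of 2015 baseline emissions (1.0 = baseline), in [sectors()]
#' order, each within the design space [0, 1.5].
#'
#' @param config Numeric vector of length 5 (named or unnamed, RES, IND,
#'   TRA, AGR, ENE order).
#' @return The validated, named configuration (invisibly usable).
#' @export
as_config <- function(config) {
  config <- as.numeric(config)
  if (length(config) != 5L || anyNA(config) || !all(is.finite(config)))
    stop("an emission configuration needs 5 finite per-sector fractions")
  if (any(config < 0 | config > 1.5))
    stop("emission scaling fractions outside the design space [0, 1.5]")
  names(config) <- sectors()
  config
}

#' Baseline emission configuration (all sectors at 1.0)
#' @export
baseline_config <- function() as_config(rep(1, 5))

#' Run the pseudo chemistry-transport simulator
#'
#' Evaluates the surrogate response surface for one emission configuration:
#' \deqn{PM_{2.5,c} = \max(0,\; b_c + \sum_s \beta_{s,c} f_s +
#'   \gamma_c \min(f_{AGR}, (f_{IND}+f_{ENE})/2))}
#' \deqn{O_{3,c} = \max(0,\; o_c + v_c f_{IND} - n_c f_{TRA} + q_c f_{TRA}^2)}
#' With `noisy = TRUE`, seeded Gaussian noise (`noise_sd_pm`,
#' `noise_sd_o3`) is added before clipping at zero.
#'
#' @param config Emission configuration (see [as_config()]).
#' @param params A `pseudo_sim_params`.
#' @param domain The `aq_domain` the parameters were drawn for.
#' @param noisy Add observation noise? Default `FALSE` (the deterministic
#'   simulator output used as emulator training data).
#' @param noise_seed Seed for the noise draw (defaults to `params$seed`).
#' @return A `conc_fields` list: numeric vectors `pm25` (ug/m3) and `o3`
#'   (ppb), one value per grid cell.
#' @export
simulate_concentrations <- function(config, params, domain, noisy = FALSE,
                                    noise_seed = params$seed) {
  stopifnot(inherits(params, "pseudo_sim_params"), inherits(domain, "aq_domain"))
  f <- as_config(config)
  pm <- params$baseline_pm +
    as.vector(params$linear_pm_coeff %*% f) +
    params$nh3_limited_coeff * min(f[["AGR"]], (f[["IND"]] + f[["ENE"]]) / 2)
  o3 <- params$o3_background +
    params$o3_voc_coeff * f[["IND"]] -
    params$o3_nox_coeff * f[["TRA"]] +
    params$o3_nox_quad_coeff * f[["TRA"]]^2
  if (noisy) {
    rng <- local_seed(noise_seed)
    pm <- pm + stats::rnorm(length(pm), 0, params$noise_sd_pm)
    o3 <- o3 + stats::rnorm(length(o3), 0, params$noise_sd_o3)
    restore_seed(rng)
  }
  conc_fields(pmax(pm, 0), pmax(o3, 0))
}

#' Construct a concentration-fields container
#' @param pm25 Per-cell annual-mean PM2.5 (ug/m3).
#' @param o3 Per-cell 6mDM8h O3 (ppb).
#' @return A `conc_fields` list.
#' @export
conc_fields <- function(pm25, o3) {
  stopifnot(length(pm25) == length(o3), all(is.finite(pm25)), all(is.finite(o3)))
  structure(list(pm25 = as.numeric(pm25), o3 = as.numeric(o3)),
            class = "conc_fields")
}

#' A known "true" emission trajectory for the synthetic world
#'
#' Year-by-year emission configurations 2010-2020 used as the generator's
#' ground truth; 2015 is pinned at the baseline (all 1.0). The default
#' shape mirrors the broad national picture: power generation declining
#' early, industry and residential declining after 2013, transport and
#' agriculture declining after 2015, with all 2016-2020 values on the 0.2
#' lattice so grid-based inference can recover them exactly.
#'
#' @param years Integer years covered (default 2010:2020).
#' @param configs Optional matrix (length(years) x 5) of per-year
#'   configurations overriding the default shape.
#' @return A `true_trajectory`: matrix with one row per year, columns in
#'   [sectors()] order, rownames the years.
#' @export
true_trajectory <- function(years = 2010:2020, configs = NULL) {
  if (is.null(configs)) {
    full <- rbind(
      `2010` = c(1.2, 1.2, 1.0, 1.0, 1.4),
      `2011` = c(1.2, 1.2, 1.0, 1.0, 1.3),
      `2012` = c(1.1, 1.2, 1.0, 1.0, 1.2),
      `2013` = c(1.1, 1.1, 1.0, 1.0, 1.2),
      `2014` = c(1.0, 1.1, 1.0, 1.0, 1.1),
      `2015` = c(1.0, 1.0, 1.0, 1.0, 1.0),
      `2016` = c(1.0, 1.0, 1.0, 1.0, 0.8),
      `2017` = c(0.8, 0.8, 0.8, 0.8, 0.8),
      `2018` = c(0.8, 0.8, 0.8, 0.8, 0.6),
      `2019` = c(0.6, 0.8, 0.8, 0.6, 0.6),
      `2020` = c(0.6, 0.6, 0.8, 0.6, 0.6)
    )
    missing_years <- setdiff(as.character(years), rownames(full))
    if (length(missing_years))
      stop("no default configuration for years: ", paste(missing_years, collapse = ", "))
    configs <- full[as.character(years), , drop = FALSE]
  }
  configs <- as.matrix(configs)
  stopifnot(nrow(configs) == length(years), ncol(configs) == 5L)
  if (any(configs < 0 | configs > 1.5))
    stop("trajectory fractions outside [0, 1.5]")
  if (2015 %in% years && !all(configs[as.character(2015) == as.character(years), ] == 1))
    stop("year 2015 must be the baseline configuration (all 1.0)")
  dimnames(configs) <- list(as.character(years), sectors())
  structure(configs, class = c("true_trajectory", "matrix"))
}

#' Synthetic hourly ozone series with a diurnal cycle
#'
#' Generates `24 * n_days` consecutive non-negative hourly O3 values:
#' a mean level plus a sinusoidal diurnal cycle peaking mid-afternoon,
#' plus seeded Gaussian noise, clipped at zero. A fixture generator for
#' exercising the 6mDM8h chronic exposure metric.
#'
#' @param n_days Number of days (>= 1).
#' @param mean_level Mean mixing ratio (ppb).
#' @param amplitude Diurnal half-range (ppb).
#' @param noise_sd Hourly noise SD (ppb); 0 gives a deterministic cycle.
#' @param seed Integer seed.
#' @return Numeric vector of length `24 * n_days`.
#' @export
generate_hourly_ozone <- function(n_days, mean_level = 40, amplitude = 15,
                                  noise_sd = 3, seed = 1) {
  if (n_days < 1) stop("n_days must be >= 1")
  hours <- seq_len(24 * n_days) - 1
  hod <- hours %% 24
  base <- mean_level + amplitude * sin(2 * pi * (hod - 9) / 24)
  rng <- local_seed(seed)
  x <- base + stats::rnorm(length(base), 0, noise_sd)
  restore_seed(rng)
  pmax(x, 0)
}

#' Synthetic station observations of annual metrics
#'
#' Generates per-station annual-metric records (annual-mean PM2.5 and
#' 6mDM8h O3) for each year of a true trajectory: the pseudo-simulator is
#' evaluated at that year's configuration, read off at each station's
#' paired cell, and seeded Gaussian noise is added. With
#' `relative_noise = TRUE` the noise SD is the given fraction of each
#' record's noiseless value instead of the absolute `noise_sd_*` in
#' `params`.
#'
#' @param trajectory A `true_trajectory` covering `years`.
#' @param params A `pseudo_sim_params`.
#' @param domain The `aq_domain`.
#' @param stations A `station_set`.
#' @param years Years to generate (default all trajectory years).
#' @param seed Integer seed for the noise.
#' @param relative_noise If not `NULL`, a fraction: noise SD =
#'   `relative_noise * value` per record (e.g. 0.05 for 5% noise).
#' @return Data.frame `station_id, year, pollutant, value` with pollutant
#'   in `c("PM25", "O3")`.
#' @export
synth_observations <- function(trajectory, params, domain, stations,
                               years = rownames(trajectory), seed = 1,
                               relative_noise = NULL) {
  stopifnot(inherits(trajectory, "true_trajectory"))
  years <- as.character(years)
  if (!all(years %in% rownames(trajectory)))
    stop("trajectory does not cover all requested years")
  if (any(stations$paired_cell < 1 | stations$paired_cell > domain$n_cells))
    stop("station paired to a cell outside the domain")
  recs <- lapply(years, function(yr) {
    fld <- simulate_concentrations(trajectory[yr, ], params, domain, noisy = FALSE)
    data.frame(
      station_id = rep(stations$station_id, 2L),
      year = as.integer(yr),
      pollutant = rep(c("PM25", "O3"), each = nrow(stations)),
      value = c(fld$pm25[stations$paired_cell], fld$o3[stations$paired_cell]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rng <- local_seed(seed)
  sd_vec <- if (is.null(relative_noise)) {
    ifelse(out$pollutant == "PM25", params$noise_sd_pm, params$noise_sd_o3)
  } else {
    relative_noise * out$value
  }
  out$value <- pmax(out$value + stats::rnorm(nrow(out), 0, sd_vec), 0)
  restore_seed(rng)
  out
}
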