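#' Load GEMM exposure-response parameters
#'
#' Reads the GEMM (Global Exposure Mortality Model) NCD+LRI parameters
#' from a YAML config. The package ships a fixture with published
#' Burnett-style values (`inst/extdata/gemm_ncd_lri.yaml`); pass `path`
#' to override.
#'
#' @param path YAML file path (default: the shipped fixture).
#' @return A `gemm_params` list: `counterfactual`, `alpha`, `mu`, `nu`,
#'   `all_age` (theta, theta_se), `age_specific` (named list per age
#'   group).
#' @export
gemm_params <- function(path = system.file("extdata", "gemm_ncd_lri.yaml",
                                           package = "aqemu")) {
  p <- yaml::read_yaml(path)
  stopifnot(p$alpha > 0, p$nu > 0, p$counterfactual >= 0)
  structure(p, class = "gemm_params")
}

#' O3 exposure-response parameters
#'
#' Log-linear relative risk per 10 ppb of chronic 6mDM8h O3 above the
#' counterfactual, for COPD mortality (GBD2017-style).
#'
#' @param rr_per_10ppb Central RR per 10 ppb (>= 1).
#' @param lower95,upper95 95% uncertainty interval of `rr_per_10ppb`.
#' @param counterfactual Minimum exposure of no excess risk (ppb).
#' @return An `o3_rr_params` list.
#' @export
o3_rr_params <- function(rr_per_10ppb = 1.063, lower95 = 1.029,
                         upper95 = 1.098, counterfactual = 35.7) {
  if (rr_per_10ppb < 1) stop("rr_per_10ppb must be >= 1")
  structure(list(rr_per_10ppb = rr_per_10ppb, lower95 = lower95,
                 upper95 = upper95, counterfactual = counterfactual),
            class = "o3_rr_params")
}

#' GEMM relative risk for PM2.5
#'
#' \deqn{RR(C) = \exp\left(\theta \,\frac{\ln(1 + z/\alpha)}{1 +
#'   e^{-(z-\mu)/\nu}}\right), \quad z = \max(0, C - C_{cf})}
#' with counterfactual \eqn{C_{cf} = 2.4} ug/m3 by default. Vectorized
#' over concentrations.
#'
#' @param conc Ambient annual-mean PM2.5 (ug/m3), >= 0.
#' @param params A `gemm_params`.
#' @param age_group Age group name (e.g. "60-64") or `"all_age"`.
#' @param theta Optional explicit theta overriding the config (used for
#'   uncertainty draws).
#' @return Relative risk(s), >= 1.
#' @export
gemm_rr <- function(conc, params = gemm_params(), age_group = "all_age",
                    theta = NULL) {
  if (any(!is.finite(conc))) stop("non-finite concentration")
  if (is.null(theta)) {
    theta <- if (identical(age_group, "all_age")) params$all_age$theta
             else params$age_specific[[age_group]]$theta
    if (is.null(theta)) stop("no GEMM parameters for age group ", age_group)
  }
  z <- pmax(0, conc - params$counterfactual)
  exp(theta * log(1 + z / params$alpha) / (1 + exp(-(z - params$mu) / params$nu)))
}

#' Log-linear O3 relative risk
#'
#' \deqn{RR(C) = \exp\left(\frac{\ln(RR_{10})}{10}\max(0, C - C_{cf})\right)}
#' with counterfactual 35.7 ppb by default.
#'
#' @param conc 6mDM8h O3 (ppb), >= 0.
#' @param params An `o3_rr_params`.
#' @param rr_per_10ppb Optional explicit RR per 10 ppb overriding the
#'   central value (used for uncertainty draws).
#' @return Relative risk(s), >= 1.
#' @export
o3_rr <- function(conc, params = o3_rr_params(), rr_per_10ppb = NULL) {
  if (any(!is.finite(conc))) stop("non-finite concentration")
  rr10 <- if (is.null(rr_per_10ppb)) params$rr_per_10ppb else rr_per_10ppb
  if (rr10 < 1) stop("rr_per_10ppb must be >= 1")
  exp(log(rr10) / 10 * pmax(0, conc - params$counterfactual))
}

#' Population attributable fraction
#'
#' `PAF = (RR - 1)/RR`, the share of an outcome attributable to the
#' exposure; lies in [0, 1).
#'
#' @param rr Relative risk(s), >= 1.
#' @return Attributable fraction(s).
#' @export
paf <- function(rr) {
  if (any(rr < 1)) stop("relative risk must be >= 1")
  (rr - 1) / rr
}

# per-cell attributable deaths for one outcome/year; pm_conc or o3_conc
# depending on outcome. Returns vector over cells.
cell_mortality <- function(conc, demographics, year, outcome,
                           gemm = gemm_params(), o3p = o3_rr_params(),
                           theta_shift = 0, rate_draw = NULL,
                           age_frac_mult = NULL) {
  yr <- as.character(year)
  if (!yr %in% colnames(demographics$population))
    stop("no population data for year ", year)
  pop <- demographics$population[, yr]
  af <- demographics$age_structure[yr, ]
  if (!is.null(age_frac_mult)) af <- af * age_frac_mult
  rates <- demographics$rates
  rates <- rates[rates$year == year & rates$outcome == outcome, , drop = FALSE]
  if (nrow(rates) == 0)
    stop(sprintf("missing baseline rates for (%s, year %s)", outcome, yr))

  total <- numeric(length(pop))
  for (g in demographics$age_groups) {
    rate <- rates$central[rates$age_group == g]
    if (length(rate) != 1)
      stop(sprintf("missing baseline rate for (%s, %s, year %s)", outcome, g, yr))
    if (!is.null(rate_draw)) rate <- rate_draw[[paste(outcome, g)]]
    rr <- if (outcome == "COPD") {
      o3_rr(conc, o3p, rr_per_10ppb = max(1, o3p$rr_per_10ppb + theta_shift))
    } else {
      th <- if (identical(g, "all_age")) gemm$all_age$theta
            else gemm$age_specific[[g]]$theta
      gemm_rr(conc, gemm, theta = max(0, th + theta_shift))
    }
    total <- total + pop * af[[g]] * rate * paf(rr)
  }
  total
}

#' Attributable premature mortality burden
#'
#' Total premature deaths per year attributable to exposure above the
#' counterfactual: the sum over grid cells and adult age groups (25+) of
#' population x age fraction x baseline rate x PAF(RR(C)). PM2.5 burden
#' (outcomes NCD, LRI, or the combined "NCD+LRI" rates summed) uses the
#' GEMM; the O3 burden (outcome COPD) uses the log-linear RR.
#'
#' @param conc Per-cell concentration field (PM2.5 ug/m3, or 6mDM8h ppb
#'   for COPD).
#' @param demographics A `demographics` object.
#' @param year Year of both exposure and demographics.
#' @param outcome One of `"NCD"`, `"LRI"`, `"COPD"` (or `c("NCD","LRI")`
#'   summed).
#' @param gemm,o3p Exposure-response parameter objects.
#' @return A `burden_result` data.frame row: `outcome, year, method,
#'   sector, central, lower95, upper95` (UI columns `NA` until
#'   [burden_uncertainty()] fills them).
#' @export
mortality_burden <- function(conc, demographics, year, outcome = c("NCD", "LRI"),
                             gemm = gemm_params(), o3p = o3_rr_params()) {
  total <- sum(vapply(outcome, function(oc)
    sum(cell_mortality(conc, demographics, year, oc, gemm, o3p)), numeric(1)))
  burden_row(outcome = paste(outcome, collapse = "+"), year = year,
             method = "total", sector = "all", central = total)
}

burden_row <- function(outcome, year, method, sector, central,
                       lower95 = NA_real_, upper95 = NA_real_) {
  out <- data.frame(outcome = outcome, year = as.integer(year),
                    method = method, sector = sector,
                    central = central, lower95 = lower95, upper95 = upper95,
                    stringsAsFactors = FALSE)
  class(out) <- c("burden_result", "data.frame")
  out
}

#' Sector attribution of the PM2.5 burden (attribution method)
#'
#' Apportions each cell's attributable mortality to sectors by zero-out
#' concentration shares: for sector k, share_k = (C(config) - C(config
#' with sector k zeroed)) / C(config), clipped to [0, 1]; if shares sum
#' above 1 they are renormalized to sum 1 (nonlinear overlap), otherwise
#' the residual share is "other sources". Sector burden is the cell
#' total burden times the cell share, summed over cells.
#'
#' @param bank Calibrated `emulator_bank`.
#' @param config Emission configuration at which to attribute.
#' @param demographics A `demographics` object.
#' @param year Year for demographics.
#' @param outcome Outcomes summed for the burden (default NCD+LRI on
#'   PM2.5).
#' @param gemm,o3p Exposure-response parameters.
#' @return A `burden_result` data.frame: one `attribution` row per
#'   sector, one for `other`, and the `total` row. Sector + other rows
#'   sum to the total.
#' @export
attribute_sectors <- function(bank, config, demographics, year,
                              outcome = c("NCD", "LRI"),
                              gemm = gemm_params(), o3p = o3_rr_params()) {
  config <- as_config(config)
  zeroed <- t(vapply(seq_len(5), function(k) {
    cfg <- config; cfg[k] <- 0; cfg
  }, numeric(5)))
  preds <- predict(bank, rbind(config, zeroed))
  conc <- preds$pm25[1, ]
  shares <- matrix(0, nrow = 5, ncol = bank$n_cells,
                   dimnames = list(sectors(), NULL))
  ok <- conc > 0
  for (k in seq_len(5))
    shares[k, ok] <- pmin(pmax((conc[ok] - preds$pm25[k + 1, ok]) / conc[ok], 0), 1)
  if (any(!ok))
    warning("attribution undefined for ", sum(!ok),
            " cell(s) with zero total concentration; skipped")
  ssum <- colSums(shares)
  over <- ssum > 1
  if (any(over))
    shares[, over] <- sweep(shares[, over, drop = FALSE], 2, ssum[over], `/`)
  other <- pmax(1 - colSums(shares), 0)
  other[!ok] <- 0

  cell_tot <- Reduce(`+`, lapply(outcome, function(oc)
    cell_mortality(conc, demographics, year, oc, gemm, o3p)))
  oc_lab <- paste(outcome, collapse = "+")
  rows <- lapply(seq_len(5), function(k)
    burden_row(oc_lab, year, "attribution", sectors()[k],
               sum(cell_tot * shares[k, ])))
  rows[[6]] <- burden_row(oc_lab, year, "attribution", "other",
                          sum(cell_tot * other))
  rows[[7]] <- burden_row(oc_lab, year, "total", "all", sum(cell_tot))
  do.call(rbind, rows)
}

#' Sector burden change by the subtraction method
#'
#' The change in attributable mortality from removing one sector's
#' emissions entirely: MORT(config) - MORT(config with the sector
#' zeroed). Under the concave GEMM response at high exposure this is
#' smaller than the attribution-method estimate for the same sector.
#'
#' @inheritParams attribute_sectors
#' @param sector Sector code (one of [sectors()]).
#' @return A `burden_result` row with method `"subtraction"`.
#' @export
subtract_sector <- function(bank, config, sector, demographics, year,
                            outcome = c("NCD", "LRI"),
                            gemm = gemm_params(), o3p = o3_rr_params()) {
  config <- as_config(config)
  k <- match(sector, sectors())
  if (is.na(k)) stop("unknown sector ", sector)
  cfg0 <- config; cfg0[k] <- 0
  preds <- predict(bank, rbind(config, cfg0))
  tot <- function(conc) sum(Reduce(`+`, lapply(outcome, function(oc)
    cell_mortality(conc, demographics, year, oc, gemm, o3p))))
  burden_row(paste(outcome, collapse = "+"), year, "subtraction", sector,
             tot(preds$pm25[1, ]) - tot(preds$pm25[2, ]))
}

#' Burden with counterfactual demographics
#'
#' Computes the burden with one year's exposure and another year's
#' population count, age structure, and baseline rates — e.g. the 2020
#' burden had demographics stayed at 2012 levels, isolating the effect
#' of population aging and growth.
#'
#' @param conc Per-cell concentration field for the exposure year.
#' @param demographics A `demographics` object.
#' @param exposure_year Year the concentrations refer to (label only).
#' @param demo_year Year whose demographics are used.
#' @param outcome Outcomes summed.
#' @param gemm,o3p Exposure-response parameters.
#' @return A `burden_result` row labelled with the exposure year.
#' @export
counterfactual_demographics <- function(conc, demographics, exposure_year,
                                        demo_year, outcome = c("NCD", "LRI"),
                                        gemm = gemm_params(),
                                        o3p = o3_rr_params()) {
  res <- mortality_burden(conc, demographics, demo_year, outcome, gemm, o3p)
  res$year <- as.integer(exposure_year)
  res$method <- "counterfactual_demographics"
  res
}

#' Monte-Carlo 95% uncertainty interval for a burden
#'
#' Propagates the stated uncertainty sources jointly by seeded Monte
#' Carlo: the exposure-response coefficient (theta ~ Normal(theta,
#' theta_se) for GEMM; RR per 10 ppb ~ Normal within its 95UI for O3),
#' baseline rates (triangular on lower95/central/upper95 per outcome and
#' age group), and age fractions (uniform multiplicative perturbation of
#' +/- `age_frac_rel`, renormalized to the year's adult total). Reports
#' the 2.5th/97.5th percentiles of the resulting total mortality.
#'
#' @param conc Per-cell concentration field.
#' @param demographics A `demographics` object.
#' @param year Year.
#' @param outcome Outcomes summed.
#' @param n_draws Monte-Carlo draws (>= 100).
#' @param seed Integer seed.
#' @param age_frac_rel Relative half-width of the age-fraction
#'   perturbation (default 0.05).
#' @param gemm,o3p Exposure-response parameters.
#' @return A `burden_result` row with `central`, `lower95`, `upper95`.
#' @export
burden_uncertainty <- function(conc, demographics, year,
                               outcome = c("NCD", "LRI"),
                               n_draws = 1000L, seed = 1L,
                               age_frac_rel = 0.05,
                               gemm = gemm_params(), o3p = o3_rr_params()) {
  if (n_draws < 100) stop("n_draws must be >= 100")
  central <- mortality_burden(conc, demographics, year, outcome, gemm, o3p)$central

  rates <- demographics$rates
  yr <- as.integer(year)
  rng <- local_seed(seed)
  draws <- vapply(seq_len(n_draws), function(i) {
    # joint draw: one theta shift per ER function, triangular rates, age wiggle
    th_shift <- if (identical(outcome, "COPD") || "COPD" %in% outcome) {
      se <- (o3p$upper95 - o3p$lower95) / (2 * 1.96)
      stats::rnorm(1, 0, se)
    } else {
      stats::rnorm(1, 0, gemm$all_age$theta_se)
    }
    rate_draw <- list()
    for (oc in outcome) {
      sub <- rates[rates$year == yr & rates$outcome == oc, , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        rate_draw[[paste(oc, sub$age_group[j])]] <-
          rtriangular(1, sub$lower95[j], sub$central[j], sub$upper95[j])
      }
    }
    mult <- stats::runif(length(demographics$age_groups),
                         1 - age_frac_rel, 1 + age_frac_rel)
    af <- demographics$age_structure[as.character(yr), ]
    mult <- mult * sum(af) / sum(af * mult)  # preserve the adult total
    sum(vapply(outcome, function(oc)
      sum(cell_mortality(conc, demographics, yr, oc, gemm, o3p,
                         theta_shift = th_shift, rate_draw = rate_draw,
                         age_frac_mult = mult)), numeric(1)))
  }, numeric(1))
  restore_seed(rng)

  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  burden_row(paste(outcome, collapse = "+"), year, "total", "all",
             central, min(qs[1], central), max(qs[2], central))
}

# triangular(lower, mode, upper) sampler by inverse CDF; degenerates to the
# mode when the interval collapses
rtriangular <- function(n, lower, mode, upper) {
  if (upper - lower <= 0) return(rep(mode, n))
  u <- stats::runif(n)
  fc <- (mode - lower) / (upper - lower)
  ifelse(u < fc,
         lower + sqrt(u * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - u) * (upper - lower) * (upper - mode)))
}

#' Write burdens as CSV
#' @param burdens A `burden_result` data.frame (rows may be stacked).
#' @param path CSV file path.
#' @export
write_burden_csv <- function(burdens, path) {
  utils::write.csv(as.data.frame(burdens), path, row.names = FALSE)
  invisible(path)
}
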