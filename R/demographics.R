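#' Synthetic gridded population, age structure, and baseline health rates
#'
#' Generates the demographic inputs of the health impact assessment for a
#' synthetic domain, 2010-2020:
#' \itemize{
#' \item \strong{Population}: per-cell counts anchored at 2010, 2015 and
#'   2020 and linearly interpolated in between, the treatment used for
#'   gridded census-year population products. Spatial pattern is
#'   log-normal (a few dense cells, many sparse ones); national growth
#'   over 2010-2020 defaults to 5%.
#' \item \strong{Age structure}: yearly fractions of total population in
#'   the 12 adult groups 25-29 ... 75-79, 80+. With `aging > 0` mass
#'   shifts from the younger to the older half of the groups linearly in
#'   time (population aging).
#' \item \strong{Baseline mortality rates}: per (year 2010-2019, outcome
#'   in NCD/LRI/COPD, age group) central rates with 95% uncertainty
#'   intervals, rising steeply with age, with a mild declining time
#'   trend; 2020 is a linear continuation of each (outcome, age) series,
#'   floored at zero.
#' }
#'
#' @param domain An `aq_domain`.
#' @param seed Integer seed.
#' @param years Years covered (must contain anchors 2010, 2015, 2020).
#' @param growth_2015,growth_2020 National population growth factors
#'   relative to 2010 at the 2015 and 2020 anchors.
#' @param aging Per-year fraction of age mass moved from the younger six
#'   to the older six groups (0 disables aging).
#' @param rate_trend Multiplicative per-year change in baseline rates
#'   over 2010-2019 (e.g. -0.005 for a 0.5%/yr decline).
#' @param rate_ui_rel Half-width of the 95% interval, as a fraction of
#'   the central rate.
#' @return A `demographics` list: `population` (n_cells x years matrix),
#'   `age_structure` (years x 12 matrix of fractions), `rates`
#'   (data.frame `year, outcome, age_group, central, lower95, upper95`),
#'   `years`, `age_groups`.
#' @export
make_demographics <- function(domain, seed, years = 2010:2020,
                              growth_2015 = 1.025, growth_2020 = 1.05,
                              aging = 0.004, rate_trend = -0.005,
                              rate_ui_rel = 0.2) {
  stopifnot(inherits(domain, "aq_domain"))
  anchors <- c(2010, 2015, 2020)
  if (!all(anchors %in% years)) stop("years must include the anchors 2010, 2015, 2020")
  years <- sort(as.integer(years))
  groups <- age_groups()

  rng <- local_seed(seed)
  base_pop <- stats::rlnorm(domain$n_cells, meanlog = log(8e4), sdlog = 0.8)
  restore_seed(rng)

  anchor_pop <- cbind(`2010` = base_pop,
                      `2015` = base_pop * growth_2015,
                      `2020` = base_pop * growth_2020)
  population <- sapply(years, function(yr) {
    if (yr <= 2015) {
      w <- (yr - 2010) / 5
      (1 - w) * anchor_pop[, "2010"] + w * anchor_pop[, "2015"]
    } else {
      w <- (yr - 2015) / 5
      (1 - w) * anchor_pop[, "2015"] + w * anchor_pop[, "2020"]
    }
  })
  colnames(population) <- years

  # adult age fractions: geometric decay over 5-year bands, ~55% adults total
  base_frac <- 0.105 * 0.93^(0:10)
  base_frac <- c(base_frac, 0.6 * base_frac[11])  # 80+ thinner than 75-79
  base_frac <- base_frac / sum(base_frac) * 0.55
  age_structure <- t(sapply(years, function(yr) {
    dt <- yr - min(years)
    shift <- aging * dt
    f <- base_frac
    move <- f[1:6] * shift          # drain younger groups proportionally
    f[1:6] <- f[1:6] - move
    f[7:12] <- f[7:12] + sum(move) * f[7:12] / sum(f[7:12])
    f
  }))
  dimnames(age_structure) <- list(years, groups)

  # baseline rates per person-year, rising with age; COPD/LRI much rarer than NCD
  scale <- c(NCD = 1.0, LRI = 0.02, COPD = 0.08)
  age_mult <- exp(seq(log(0.002), log(0.15), length.out = 12))
  rate_years <- 2010:2019
  rates <- do.call(rbind, lapply(names(scale), function(oc) {
    do.call(rbind, lapply(rate_years, function(yr) {
      central <- scale[[oc]] * age_mult * (1 + rate_trend)^(yr - 2010)
      data.frame(year = yr, outcome = oc, age_group = groups,
                 central = central,
                 lower95 = central * (1 - rate_ui_rel),
                 upper95 = central * (1 + rate_ui_rel),
                 stringsAsFactors = FALSE)
    }))
  }))
  rates <- rbind(rates, extrapolate_rates_2020(rates))
  rates <- rates[rates$year %in% years, , drop = FALSE]
  rownames(rates) <- NULL

  structure(list(population = population, age_structure = age_structure,
                 rates = rates, years = years, age_groups = groups),
            class = "demographics")
}

#' The 12 adult age groups used in the health impact assessment
#' @return Character vector: "25-29" ... "75-79", "80+".
#' @export
age_groups <- function() {
  c(paste(seq(25, 75, 5), seq(29, 79, 5), sep = "-"), "80+")
}

# linear continuation of each (outcome, age_group) 2010-2019 series, floored at 0
extrapolate_rates_2020 <- function(rates) {
  pieces <- split(rates, list(rates$outcome, rates$age_group), drop = TRUE)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$year), ]
    new <- d[nrow(d), , drop = FALSE]
    new$year <- 2020L
    for (col in c("central", "lower95", "upper95")) {
      fit <- stats::lm.fit(cbind(1, d$year), d[[col]])
      new[[col]] <- max(0, sum(fit$coefficients * c(1, 2020)))
    }
    new
  })
  out <- do.call(rbind, out)
  out$upper95 <- pmax(out$upper95, out$central)
  out$lower95 <- pmin(out$lower95, out$central)
  rownames(out) <- NULL
  out
}

#' @export
print.demographics <- function(x, ...) {
  cat(sprintf("<demographics> %d cells, years %d-%d, total 2010 population %.3g\n",
              nrow(x$population), min(x$years), max(x$years),
              sum(x$population[, 1])))
  invisible(x)
}
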