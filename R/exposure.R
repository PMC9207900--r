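#' Maximum 6-monthly-mean daily-maximum 8-hour ozone (6mDM8h)
#'
#' The chronic O3 exposure metric: for each day, 24 rolling 8-hour mean
#' mixing ratios are formed (one starting at each hour of the day;
#' windows may run into the next day, and windows truncated by the end
#' of the series need at least 6 of their 8 hours to count); the daily
#' maximum of these is the DM8h. Twelve 6-month seasonal means of the
#' DM8h are then formed, one starting at each calendar month (a fixed
#' 365-day no-leap calendar; the windows that run past December wrap to
#' the start of the same data year), and the largest of the twelve is
#' returned.
#'
#' @param series Numeric vector of consecutive hourly O3 values (ppb),
#'   length a multiple of 24 covering >= 365 days.
#' @return The 6mDM8h metric (ppb).
#' @export
six_month_dm8h <- function(series) {
  if (length(series) %% 24 != 0) stop("series length must be a multiple of 24")
  n_days <- length(series) / 24
  if (n_days < 365) stop("need at least one 365-day year of hourly data")
  if (any(!is.finite(series)) || any(series < 0))
    stop("series must be finite and non-negative")

  dm8h <- daily_max_8h(series, n_days)
  month_len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month_of_day <- rep(seq_len(12), times = month_len)  # day 1..365 -> month

  # mean DM8h over 6 consecutive calendar months starting at each month,
  # wrapping within the same 365-day year
  dm8h_year <- dm8h[seq_len(365)]
  seasonal <- vapply(seq_len(12), function(m0) {
    months <- ((m0 - 1) + 0:5) %% 12 + 1
    mean(dm8h_year[month_of_day %in% months])
  }, numeric(1))
  max(seasonal)
}

# daily maximum of 24 rolling 8-hour means; windows start each hour of the
# day and may extend into the next day; truncated trailing windows need >= 6 h
daily_max_8h <- function(series, n_days) {
  n <- length(series)
  cs <- c(0, cumsum(series))
  starts <- seq_len(n)
  len <- pmin(8L, n - starts + 1L)
  means <- (cs[pmin(starts + 8L, n + 1L)] - cs[starts]) / len
  means[len < 6L] <- -Inf
  day_of_start <- (starts - 1L) %/% 24L + 1L
  vapply(seq_len(n_days), function(d) max(means[day_of_start == d]), numeric(1))
}

#' Population-weighted exposure
#'
#' Concentration field averaged with per-cell population counts as
#' weights, over an optional scope mask (e.g. a region's cells).
#'
#' @param field Per-cell concentration vector.
#' @param pop Per-cell population counts (same length).
#' @param scope Optional logical mask or integer cell indices restricting
#'   the aggregation (default: all cells).
#' @return The population-weighted mean concentration.
#' @export
population_weighted <- function(field, pop, scope = NULL) {
  stopifnot(length(field) == length(pop))
  if (is.null(scope)) scope <- seq_along(field)
  f <- field[scope]; p <- pop[scope]
  if (any(p < 0)) stop("negative population weights")
  tot <- sum(p)
  if (tot <= 0) stop("undefined exposure: zero total population in scope")
  sum(f * p) / tot
}

#' Annual mean of a concentration series
#'
#' @param x Non-empty numeric vector of per-period values (e.g. hourly or
#'   daily concentrations over a year).
#' @return Arithmetic mean.
#' @export
annual_mean <- function(x) {
  if (length(x) < 1) stop("empty input")
  mean(x)
}

#' Exposure summaries by scope
#'
#' Population-weighted exposures for the national domain and each region.
#'
#' @param field Per-cell concentration vector.
#' @param pop Per-cell population counts.
#' @param domain The `aq_domain`.
#' @param pollutant Label for the output.
#' @param year Year label for the output.
#' @return Data.frame `scope, pollutant, year, exposure`.
#' @export
exposure_summary <- function(field, pop, domain, pollutant, year = NA_integer_) {
  scopes <- c(list(national = seq_len(domain$n_cells)),
              split(seq_len(domain$n_cells), domain$region_id))
  data.frame(
    scope = names(scopes),
    pollutant = pollutant,
    year = year,
    exposure = vapply(scopes, function(idx)
      population_weighted(field, pop, idx), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
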