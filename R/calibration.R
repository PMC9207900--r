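#' Normalized mean bias factor
#'
#' Symmetric factor-style bias metric for paired model/observation
#' values: for model mean M and observed mean O,
#' `NMBF = M/O - 1` when `M >= O` and `NMBF = 1 - O/M` when `M < O`.
#' A model overestimating by a factor of 2 gives +1; underestimating by a
#' factor of 2 gives -1.
#'
#' @param model,obs Equal-length numeric vectors of paired values.
#' @return A single unitless factor.
#' @export
nmbf <- function(model, obs) {
  check_pairs(model, obs)
  M <- mean(model); O <- mean(obs)
  if (M >= O) {
    if (O == 0) stop("undefined metric: observed mean is zero")
    M / O - 1
  } else {
    if (M == 0) stop("undefined metric: model mean is zero")
    1 - O / M
  }
}

#' Normalized mean absolute error factor
#'
#' Companion error metric to [nmbf()]: `sum(|M_i - O_i|)` normalized by
#' `sum(O_i)` when the model mean is >= the observed mean, otherwise by
#' `sum(M_i)`. Always >= |NMBF|.
#'
#' @inheritParams nmbf
#' @return A single unitless factor (>= 0).
#' @export
nmaef <- function(model, obs) {
  check_pairs(model, obs)
  M <- mean(model); O <- mean(obs)
  sae <- sum(abs(model - obs))
  if (M >= O) {
    if (O == 0) stop("undefined metric: observed mean is zero")
    sae / sum(obs)
  } else {
    if (M == 0) stop("undefined metric: model mean is zero")
    sae / sum(model)
  }
}

check_pairs <- function(model, obs) {
  if (length(model) != length(obs) || length(model) < 1)
    stop("model and obs must be equal-length, non-empty")
  if (!all(is.finite(model)) || !all(is.finite(obs)))
    stop("non-finite values in model/obs pairs")
  invisible(NULL)
}

#' Derive per-region observation scaling factors
#'
#' Computes multiplicative factors matching a control concentration field
#' to station observations, per pollutant: for each prefecture with at
#' least one station, factor = mean(observed at its stations) /
#' mean(control at the paired cells); prefectures without stations
#' inherit the factor of their province (computed from all stations in
#' the province); provinces without any station fall back to the
#' domain-wide factor. Ratio-of-means is used for robustness to
#' near-zero station values.
#'
#' @param control_field `conc_fields` from the control (baseline) run.
#' @param station_obs Data.frame `station_id, pollutant, value` of
#'   observed annual metrics for the calibration year.
#' @param stations A `station_set`.
#' @param domain The `aq_domain`.
#' @return A `scaling_table` data.frame `region_id, pollutant, factor,
#'   provenance` with provenance in `c("prefecture", "province",
#'   "domain")`, one row per (region, pollutant).
#' @export
derive_scaling <- function(control_field, station_obs, stations, domain) {
  stopifnot(inherits(domain, "aq_domain"))
  if (nrow(stations) < 1) stop("need at least one station")
  regions <- sort(unique(domain$region_id))
  st_region <- domain$region_id[stations$paired_cell]
  st_province <- domain$parent_region_id[stations$paired_cell]

  rows <- list()
  for (pol in c("PM25", "O3")) {
    fld <- if (pol == "PM25") control_field$pm25 else control_field$o3
    obs <- station_obs[station_obs$pollutant == pol, , drop = FALSE]
    obs_val <- obs$value[match(stations$station_id, obs$station_id)]
    if (anyNA(obs_val)) stop("missing ", pol, " observation for some stations")
    mod_val <- fld[stations$paired_cell]

    ratio <- function(idx, label) {
      m <- mean(mod_val[idx])
      if (m == 0) stop("undefined scaling: zero model mean in ", label)
      mean(obs_val[idx]) / m
    }
    dom_factor <- ratio(seq_along(mod_val), "domain")

    for (r in regions) {
      in_pref <- which(st_region == r)
      prov <- domain$region_parent[r]
      if (length(in_pref) >= 1) {
        f <- ratio(in_pref, paste("prefecture", r)); prov_flag <- "prefecture"
      } else {
        in_prov <- which(st_province == prov)
        if (length(in_prov) >= 1) {
          f <- ratio(in_prov, paste("province", prov)); prov_flag <- "province"
        } else {
          f <- dom_factor; prov_flag <- "domain"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = r, pollutant = pol, factor = f, provenance = prov_flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$factor <= 0)) stop("derived scaling factor <= 0")
  class(out) <- c("scaling_table", "data.frame")
  out
}

# per-cell factor vector for one pollutant
cell_factors <- function(table, domain, pollutant) {
  t_pol <- table[table$pollutant == pollutant, , drop = FALSE]
  idx <- match(domain$region_id, t_pol$region_id)
  if (anyNA(idx))
    stop("scaling table does not resolve every cell for ", pollutant)
  t_pol$factor[idx]
}

#' Apply a scaling table to fields or an emulator bank
#'
#' Multiplies each cell's concentration by its region's factor. For an
#' `emulator_bank`, the factors are stored and compose onto every later
#' prediction (post-multiplication); the training data are untouched.
#'
#' @param x A `conc_fields` or an `emulator_bank`.
#' @param table A `scaling_table` from [derive_scaling()].
#' @param domain The `aq_domain` (taken from the bank if absent there).
#' @return An object of the same class as `x`, scaled.
#' @export
apply_scaling <- function(x, table, domain = NULL) {
  UseMethod("apply_scaling")
}

#' @export
apply_scaling.conc_fields <- function(x, table, domain = NULL) {
  stopifnot(inherits(domain, "aq_domain"))
  conc_fields(x$pm25 * cell_factors(table, domain, "PM25"),
              x$o3 * cell_factors(table, domain, "O3"))
}

#' @export
apply_scaling.emulator_bank <- function(x, table, domain = NULL) {
  if (is.null(domain)) domain <- x$domain
  stopifnot(inherits(domain, "aq_domain"))
  x$scale_factors <- list(
    PM25 = x$scale_factors$PM25 * cell_factors(table, domain, "PM25"),
    O3 = x$scale_factors$O3 * cell_factors(table, domain, "O3")
  )
  x
}

#' Write/read a scaling table as CSV
#' @param table A `scaling_table`.
#' @param path CSV file path.
#' @export
write_scaling_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaling_csv
#' @export
read_scaling_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("scaling_table", "data.frame")
  out
}
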