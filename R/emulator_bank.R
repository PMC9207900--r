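#' Emulator specification
#'
#' Collects the Gaussian-process fitting choices shared by every per-cell
#' emulator in a bank.
#'
#' @param nugget Correlation-diagonal jitter (> 0, standardized scale).
#' @param restarts Hyperparameter-optimization restarts (>= 0).
#' @param seed Integer base seed; each (pollutant, cell) emulator gets a
#'   distinct seed derived from it so training is reproducible and
#'   order-independent.
#' @param bounds Input design-space bounds (length-2, per sector).
#' @return An `emulator_spec` list.
#' @export
emulator_spec <- function(nugget = 1e-6, restarts = 5L, seed = 1L,
                          bounds = c(0, 1.5)) {
  stopifnot(nugget > 0, restarts >= 0)
  structure(list(nugget = nugget, restarts = as.integer(restarts),
                 seed = as.integer(seed), bounds = bounds),
            class = "emulator_spec")
}

#' Train one Gaussian-process emulator per grid cell per pollutant
#'
#' Fits an independent [gp_fit()] emulator for every (cell, pollutant)
#' pair, mapping the five-sector emission configuration to that cell's
#' annual-mean PM2.5 or 6mDM8h O3 — the per-grid-cell emulation strategy
#' used to replace expensive chemistry-transport simulations.
#'
#' @param design A `scaling_design` (>= 10 rows) of training
#'   configurations.
#' @param sim_fields List of `conc_fields`, one per design row, from the
#'   simulator.
#' @param spec An [emulator_spec()].
#' @param domain Optional `aq_domain` carried along for downstream
#'   region-aware operations.
#' @return An `emulator_bank`: per-pollutant lists of `gp_emulator`
#'   objects (length n_cells), the training design, spec, optional
#'   domain, and per-cell multiplicative calibration factors (identity
#'   until [apply_scaling()] is used).
#' @export
train_emulator_bank <- function(design, sim_fields, spec = emulator_spec(),
                                domain = NULL) {
  Xd <- config_matrix(design)
  if (nrow(Xd) < 10) stop("need at least 10 training runs")
  if (length(sim_fields) != nrow(Xd))
    stop("need exactly one simulated field per design row")
  Y <- list(
    PM25 = t(vapply(sim_fields, function(f) f$pm25, numeric(length(sim_fields[[1]]$pm25)))),
    O3   = t(vapply(sim_fields, function(f) f$o3,   numeric(length(sim_fields[[1]]$o3))))
  )
  if (!all(vapply(Y, function(m) all(is.finite(m)), logical(1))))
    stop("non-finite training values in simulated fields")
  n_cells <- ncol(Y$PM25)

  models <- lapply(names(Y), function(pol) {
    lapply(seq_len(n_cells), function(cell) {
      cell_seed <- (spec$seed + 7919L * match(pol, names(Y)) + cell) %% .Machine$integer.max
      tryCatch(
        gp_fit(Xd, Y[[pol]][, cell], bounds = spec$bounds,
               nugget = spec$nugget, restarts = spec$restarts,
               seed = cell_seed),
        error = function(e)
          stop(sprintf("emulator training failed for %s cell %d: %s",
                       pol, cell, conditionMessage(e)))
      )
    })
  })
  names(models) <- names(Y)

  structure(list(
    models = models, design = Xd, spec = spec, domain = domain,
    n_cells = n_cells,
    scale_factors = list(PM25 = rep(1, n_cells), O3 = rep(1, n_cells))
  ), class = "emulator_bank")
}

#' Predict concentration fields for emission configurations
#'
#' Evaluates every per-cell emulator at each configuration; any
#' calibration factors attached by [apply_scaling()] post-multiply the
#' predictions (training data are untouched).
#'
#' @param object An `emulator_bank`.
#' @param configs Configurations: a `config_grid`, `scaling_design`,
#'   matrix, or single length-5 vector.
#' @param cells Optional integer subset of cells to predict (default all).
#' @param se Also return posterior predictive SDs?
#' @param ... Unused.
#' @return List with matrices `pm25`, `o3` (n_configs x n_cells_predicted);
#'   with `se = TRUE`, also `pm25_sd`, `o3_sd`. SDs are scaled by the same
#'   calibration factors.
#' @export
predict.emulator_bank <- function(object, configs, cells = NULL, se = FALSE, ...) {
  Xn <- config_matrix(configs)
  lo <- object$spec$bounds[1]; hi <- object$spec$bounds[2]
  if (any(Xn < lo - 1e-12 | Xn > hi + 1e-12))
    stop("configuration outside the emulator design space [", lo, ", ", hi, "]")
  if (is.null(cells)) cells <- seq_len(object$n_cells)
  out <- list()
  for (pol in c("PM25", "O3")) {
    fac <- object$scale_factors[[pol]][cells]
    preds <- lapply(seq_along(cells), function(i) {
      p <- predict(object$models[[pol]][[cells[i]]], Xn, se = se)
      if (se) list(mean = p$mean * fac[i], sd = p$sd * fac[i])
      else p * fac[i]
    })
    key <- if (pol == "PM25") "pm25" else "o3"
    if (se) {
      out[[key]] <- do.call(cbind, lapply(preds, `[[`, "mean"))
      out[[paste0(key, "_sd")]] <- do.call(cbind, lapply(preds, `[[`, "sd"))
    } else {
      out[[key]] <- do.call(cbind, preds)
    }
  }
  out
}

#' Evaluate an emulator bank on held-out test runs
#'
#' Pools predictions over all (cell, test-run) pairs per pollutant and
#' reports the coefficient of determination R^2 and RMSE, plus a per-cell
#' breakdown.
#'
#' @param bank An `emulator_bank`.
#' @param test_design `scaling_design` of unseen configurations.
#' @param test_fields List of `conc_fields`, one per test row.
#' @return An `eval_report`: data.frame `pollutant, r2, rmse, n` plus a
#'   `per_cell` attribute.
#' @export
evaluate_bank <- function(bank, test_design, test_fields) {
  Xt <- config_matrix(test_design)
  stopifnot(length(test_fields) == nrow(Xt))
  pred <- predict(bank, Xt)
  truth <- list(
    pm25 = t(vapply(test_fields, function(f) f$pm25, numeric(bank$n_cells))),
    o3   = t(vapply(test_fields, function(f) f$o3,   numeric(bank$n_cells)))
  )
  rows <- lapply(c("pm25", "o3"), function(key) {
    tr <- as.vector(truth[[key]]); pr <- as.vector(pred[[key]])
    sst <- sum((tr - mean(tr))^2)
    r2 <- if (sst == 0) {
      warning("zero-variance truth for ", key, "; R^2 undefined")
      NA_real_
    } else 1 - sum((pr - tr)^2) / sst
    per_cell_rmse <- sqrt(colMeans((pred[[key]] - truth[[key]])^2))
    data.frame(pollutant = toupper(sub("pm25", "PM25", key)),
               r2 = r2, rmse = sqrt(mean((pr - tr)^2)), n = length(tr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pollutant <- c("PM25", "O3")
  attr(out, "per_cell") <- list(
    pm25_rmse = sqrt(colMeans((pred$pm25 - truth$pm25)^2)),
    o3_rmse = sqrt(colMeans((pred$o3 - truth$o3)^2))
  )
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.emulator_bank <- function(x, ...) {
  cat(sprintf("<emulator_bank> %d cells x 2 pollutants (%d emulators), %d training runs\n",
              x$n_cells, 2L * x$n_cells, nrow(x$design)))
  if (any(x$scale_factors$PM25 != 1) || any(x$scale_factors$O3 != 1))
    cat("  observation scaling applied\n")
  invisible(x)
}

#' @export
summary.emulator_bank <- function(object, ...) {
  ell <- t(vapply(object$models$PM25,
                  function(m) if (is.null(m$ell)) rep(NA_real_, 5) else m$ell,
                  numeric(5)))
  cat(sprintf("<emulator_bank> %d emulators; median PM2.5 length-scales: %s\n",
              2L * object$n_cells,
              paste(signif(apply(ell, 2, stats::median, na.rm = TRUE), 3),
                    collapse = ", ")))
  invisible(object)
}
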