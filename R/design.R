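#' Maximin Latin hypercube design of emission configurations
#'
#' Draws `n_candidates` random Latin hypercube samples (one point per
#' equal-width stratum in every dimension) and returns the candidate that
#' maximizes the minimum pairwise Euclidean distance — the maximin
#' space-filling criterion used to design computer experiments for
#' emulator training.
#'
#' @param n_runs Number of design points (>= 2).
#' @param bounds Length-2 numeric `c(lo, hi)` applied to every dimension,
#'   or a 2 x n_dims matrix of per-dimension bounds.
#' @param n_dims Number of input dimensions (default 5, the sectors).
#' @param n_candidates Candidate LHS draws scored by the maximin
#'   criterion (default 200).
#' @param seed Integer seed; the winning design is deterministic given it.
#' @param role Design role label, `"train"` or `"test"`.
#' @return A `scaling_design` data.frame with one column per sector
#'   (lower-case) and attributes `role` and `min_distance`.
#' @export
latin_hypercube_maximin <- function(n_runs, bounds = c(0, 1.5), n_dims = 5L,
                                    n_candidates = 200L, seed = 1L,
                                    role = c("train", "test")) {
  role <- match.arg(role)
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (n_candidates < 1) stop("n_candidates must be >= 1")
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == 2L, ncol(bounds) == n_dims)
  } else {
    stopifnot(length(bounds) == 2L)
    bounds <- matrix(rep(bounds, n_dims), nrow = 2L)
  }
  if (any(bounds[1, ] >= bounds[2, ])) stop("degenerate bounds: lo >= hi")

  rng <- local_seed(seed)
  best <- NULL
  best_d <- -Inf
  for (i in seq_len(n_candidates)) {
    u <- lhs::randomLHS(n_runs, n_dims)
    d <- min(stats::dist(u))
    if (d > best_d) {
      best <- u
      best_d <- d
    }
  }
  restore_seed(rng)

  x <- sweep(sweep(best, 2, bounds[2, ] - bounds[1, ], `*`), 2, bounds[1, ], `+`)
  out <- as.data.frame(x)
  names(out) <- tolower(sectors())[seq_len(n_dims)]
  attr(out, "role") <- role
  attr(out, "min_distance") <- best_d
  class(out) <- c("scaling_design", "data.frame")
  out
}

#' Full emission-configuration grid
#'
#' The exhaustive Cartesian lattice of per-sector emission scaling
#' fractions: by default 8 levels per sector at 20% increments from 0% to
#' 140%, i.e. 8^5 = 32,768 configurations.
#'
#' @param increment Fraction step between levels (default 0.2).
#' @param lower Lowest level (default 0).
#' @param upper Highest level (default 1.4).
#' @return A `config_grid` data.frame with columns `res, ind, tra, agr,
#'   ene`.
#' @export
full_configuration_grid <- function(increment = 0.2, lower = 0, upper = 1.4) {
  if (increment <= 0) stop("increment must be > 0")
  levels <- seq(lower, upper, by = increment)
  grid <- expand.grid(rep(list(levels), 5), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- tolower(sectors())
  attr(grid, "levels") <- levels
  class(grid) <- c("config_grid", "data.frame")
  grid
}

#' Interior emission-configuration grid
#'
#' The full 20%-increment grid with the edges of the parameter space (0%
#' and 140%) removed: 6 levels (20%..120%) per sector, 6^5 = 7,776
#' configurations. This is the search space of the measurement-informed
#' emission inference, where edge levels are excluded as implausible.
#'
#' @return A `config_grid` data.frame (7,776 rows).
#' @export
interior_configuration_grid <- function() {
  full_configuration_grid(increment = 0.2, lower = 0.2, upper = 1.2)
}

#' Write/read designs and grids as CSV
#'
#' Round-trip serialization: sector columns plus an optional
#' `design_role` column.
#'
#' @param design A `scaling_design` or `config_grid`.
#' @param path CSV file path.
#' @export
write_design_csv <- function(design, path) {
  out <- as.data.frame(design)
  role <- attr(design, "role")
  if (!is.null(role)) out$design_role <- role
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  role <- if ("design_role" %in% names(d)) d$design_role[1] else NULL
  d$design_role <- NULL
  if (!is.null(role)) {
    attr(d, "role") <- role
    class(d) <- c("scaling_design", "data.frame")
  } else {
    class(d) <- c("config_grid", "data.frame")
  }
  d
}

# config_grid/scaling_design rows as a plain numeric matrix in sector order
config_matrix <- function(configs) {
  if (is.null(dim(configs))) configs <- matrix(as.numeric(configs), nrow = 1L)
  m <- as.matrix(as.data.frame(configs))
  cols <- tolower(sectors())
  if (all(cols %in% colnames(m))) m <- m[, cols, drop = FALSE]
  if (ncol(m) != 5L) stop("configurations need 5 sector columns")
  storage.mode(m) <- "double"
  unname(m)
}
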