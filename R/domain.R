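#' Sector labels in canonical order
#'
#' The five anthropogenic emission sectors, in the order used by every
#' design matrix and emission-configuration vector in the package:
#' residential (RES), industrial (IND), land transport (TRA), agricultural
#' (AGR), and power generation (ENE).
#'
#' @return Character vector of length 5.
#' @export
sectors <- function() c("RES", "IND", "TRA", "AGR", "ENE")

#' Build a rectangular model domain with nested regions
#'
#' Creates an `n_x` by `n_y` grid of cells, partitions the cells into
#' `n_regions` contiguous-ish "prefecture" regions (Voronoi assignment to
#' randomly placed region seeds), and groups those regions into
#' `n_parents` "province" parent regions the same way. Stands in for a
#' national chemistry-transport model grid with its administrative
#' aggregation levels.
#'
#' @param n_x,n_y Integer grid dimensions (cells).
#' @param n_regions Number of prefecture-level regions (1..n_x*n_y).
#' @param seed Integer seed; the partition is deterministic given it.
#' @param n_parents Number of province-level parent regions
#'   (default `min(3, n_regions)`).
#' @return An object of class `aq_domain`: a list with `n_x`, `n_y`,
#'   `n_cells`, `centroids` (n_cells x 2 matrix, planar units),
#'   `region_id` and `parent_region_id` (integer per cell), and
#'   `region_parent` (parent id per region).
#' @export
make_domain <- function(n_x, n_y, n_regions, seed, n_parents = min(3L, n_regions)) {
  if (length(n_x) != 1L || length(n_y) != 1L || n_x < 1 || n_y < 1)
    stop("n_x and n_y must be positive integers")
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  n_cells <- n_x * n_y
  if (n_regions < 1 || n_regions > n_cells)
    stop("n_regions must be in 1..n_x*n_y")
  if (n_parents < 1 || n_parents > n_regions)
    stop("n_parents must be in 1..n_regions")

  # cell centroids on the unit lattice, cell index runs column-major in x
  centroids <- cbind(
    x = rep(seq_len(n_x), times = n_y) - 0.5,
    y = rep(seq_len(n_y), each = n_x) - 0.5
  )

  rng <- local_seed(seed)
  seed_cells <- sample.int(n_cells, n_regions)
  region_id <- nearest_index(centroids, centroids[seed_cells, , drop = FALSE])

  # group prefectures into provinces by the same Voronoi rule on region seeds
  parent_seeds <- sample.int(n_regions, n_parents)
  region_parent <- nearest_index(
    centroids[seed_cells, , drop = FALSE],
    centroids[seed_cells[parent_seeds], , drop = FALSE]
  )
  restore_seed(rng)

  structure(list(
    n_x = n_x, n_y = n_y, n_cells = n_cells,
    centroids = centroids,
    region_id = region_id,
    parent_region_id = region_parent[region_id],
    region_parent = region_parent
  ), class = "aq_domain")
}

#' @export
print.aq_domain <- function(x, ...) {
  cat(sprintf("<aq_domain> %d x %d grid (%d cells), %d regions in %d parent regions\n",
              x$n_x, x$n_y, x$n_cells,
              length(unique(x$region_id)), length(unique(x$parent_region_id))))
  invisible(x)
}

#' Place monitoring stations and pair them to grid cells
#'
#' Scatters `n_stations` stations uniformly over the domain and pairs each
#' to the grid cell whose centroid is nearest, mirroring how surface
#' air-quality monitors are paired to the nearest model grid cell.
#'
#' @param domain An `aq_domain`.
#' @param n_stations Number of stations.
#' @param seed Integer seed.
#' @return A `station_set` data.frame with columns `station_id`, `x`, `y`,
#'   `paired_cell`.
#' @export
make_stations <- function(domain, n_stations, seed) {
  stopifnot(inherits(domain, "aq_domain"), n_stations >= 1)
  rng <- local_seed(seed)
  xy <- cbind(
    x = stats::runif(n_stations, 0, domain$n_x),
    y = stats::runif(n_stations, 0, domain$n_y)
  )
  restore_seed(rng)
  paired <- nearest_index(xy, domain$centroids)
  out <- data.frame(
    station_id = sprintf("S%03d", seq_len(n_stations)),
    x = xy[, 1], y = xy[, 2],
    paired_cell = paired,
    stringsAsFactors = FALSE
  )
  class(out) <- c("station_set", "data.frame")
  out
}

# index of the nearest row of `ref` for every row of `pts` (ties -> lowest index)
nearest_index <- function(pts, ref) {
  d2 <- outer(rowSums(pts^2), rep(1, nrow(ref))) +
    outer(rep(1, nrow(pts)), rowSums(ref^2)) - 2 * pts %*% t(ref)
  max.col(-d2, ties.method = "first")
}

# seed handling: set a seed locally, restore global RNG state afterwards
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
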