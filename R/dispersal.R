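#' Regular analysis grid
#'
#' Half-open 1 km cells are the standard resolution for dispersal heatmaps;
#' cell `(i, j)` covers `[origin + (i-1) * cell, origin + i * cell)` on each
#' axis.
#'
#' @param origin_x,origin_y Lower-left corner in metres.
#' @param cell_size Cell edge in metres (default 1000).
#' @param n_x,n_y Cell counts.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, n_x, n_y, cell_size = 1000) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (n_x < 1L || n_y < 1L) stop("grid must have at least one cell per axis")
  structure(list(origin_x = as.double(origin_x),
                 origin_y = as.double(origin_y),
                 cell_size = as.double(cell_size),
                 n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "grid_spec")
}

as_traj_list <- function(traj_sets) {
  if (inherits(traj_sets, "trajectory_set")) traj_sets <- list(traj_sets)
  if (!length(traj_sets) || !all(vapply(traj_sets, inherits, TRUE,
                                        "trajectory_set")))
    stop("need one or more trajectory_set objects")
  traj_sets
}

pooled_xy <- function(traj_sets) {
  list(x = unlist(lapply(traj_sets, function(t) as.vector(t$x)),
                  use.names = FALSE),
       y = unlist(lapply(traj_sets, function(t) as.vector(t$y)),
                  use.names = FALSE))
}

# expand a grid_spec (preserving cell anchoring) until it covers all points
cover_grid <- function(grid, x, y) {
  c_ <- grid$cell_size
  lo_i <- floor((min(x) - grid$origin_x) / c_)
  lo_j <- floor((min(y) - grid$origin_y) / c_)
  hi_i <- floor((max(x) - grid$origin_x) / c_)
  hi_j <- floor((max(y) - grid$origin_y) / c_)
  grid_spec(origin_x = grid$origin_x + min(lo_i, 0) * c_,
            origin_y = grid$origin_y + min(lo_j, 0) * c_,
            n_x = max(hi_i + 1L, grid$n_x) - min(lo_i, 0),
            n_y = max(hi_j + 1L, grid$n_y) - min(lo_j, 0),
            cell_size = c_)
}

cell_index <- function(grid, x, y) {
  i <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  j <- floor((y - grid$origin_y) / grid$cell_size) + 1L
  if (any(i < 1L | i > grid$n_x | j < 1L | j > grid$n_y))
    stop("positions fall outside the analysis grid")
  (j - 1L) * grid$n_x + i                # linear cell id, row-major by y
}

#' Particle density heatmap on a regular grid
#'
#' Counts every recorded particle position (all particles at every recording
#' timestep, frozen beached/out-of-domain records included) into the grid
#' cells and converts counts to percent of the total number of
#' particle-records, so the whole heatmap sums to exactly 100. This is the
#' standard presentation of total backtracked dispersal averaged over
#' releases.
#'
#' @param traj_sets A `trajectory_set` or list of them.
#' @param grid A [grid_spec()], or `NULL` to derive a covering 1 km grid
#'   anchored at the domain lower-left. A given grid is auto-expanded to
#'   cover all positions.
#' @param cell_size Cell edge (m) when `grid` is `NULL`.
#' @return An object of class `density_grid`: the `grid_spec`, a
#'   `n_y x n_x` matrix `density` of percentages, and `n_contributions`.
#' @export
density_heatmap <- function(traj_sets, grid = NULL, cell_size = 1000) {
  traj_sets <- as_traj_list(traj_sets)
  p <- pooled_xy(traj_sets)
  if (is.null(grid))
    grid <- grid_spec(origin_x = floor(min(p$x) / cell_size) * cell_size,
                      origin_y = floor(min(p$y) / cell_size) * cell_size,
                      n_x = 1L, n_y = 1L, cell_size = cell_size)
  grid <- cover_grid(grid, p$x, p$y)
  ids <- cell_index(grid, p$x, p$y)
  counts <- tabulate(ids, nbins = grid$n_x * grid$n_y)
  n <- length(ids)
  structure(list(grid = grid,
                 density = matrix(counts / n * 100, grid$n_y, grid$n_x,
                                  byrow = TRUE),
                 n_contributions = n),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "density_grid: %d x %d cells of %g m, %d particle-records\n  occupied cells: %d, total density: %.6f%%\n",
    x$grid$n_x, x$grid$n_y, x$grid$cell_size, x$n_contributions,
    sum(x$density > 0), sum(x$density)))
  invisible(x)
}

#' Plot a density heatmap
#'
#' @param x A `density_grid`.
#' @param stations Optional station data frame (columns `x`, `y`,
#'   `station_id`) overplotted as points.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.density_grid <- function(x, stations = NULL, ...) {
  g <- x$grid
  xs <- g$origin_x + (seq_len(g$n_x) - 0.5) * g$cell_size
  ys <- g$origin_y + (seq_len(g$n_y) - 0.5) * g$cell_size
  z <- t(x$density)                       # image() wants (x, y)
  z[z == 0] <- NA
  graphics::image(xs / 1000, ys / 1000, log10(z),
                  xlab = "Easting (km)", ylab = "Northing (km)",
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  useRaster = TRUE, ...)
  if (!is.null(stations)) {
    graphics::points(stations$x / 1000, stations$y / 1000, pch = 19)
    graphics::text(stations$x / 1000, stations$y / 1000,
                   labels = stations$station_id, pos = 3, cex = 0.7)
  }
  invisible(x)
}

#' Maximum straight-line distance of a backtracked release
#'
#' The maximum over all particles and recording timesteps of the Euclidean
#' distance from the station position, in kilometres: how far the detected
#' eDNA could have travelled to reach the sampling station within the
#' tracking window.
#'
#' @param traj A `trajectory_set`.
#' @return Distance in km.
#' @export
max_straight_line_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  dx <- traj$x - traj$station_x
  dy <- traj$y - traj$station_y
  sqrt(max(dx * dx + dy * dy)) / 1000
}

#' Areal extent of backtracked particle dispersal
#'
#' The number of distinct grid cells occupied by at least one
#' particle-record at any time, times the cell area: the surface area over
#' which the detected eDNA could have been shed.
#'
#' @inheritParams density_heatmap
#' @return Area in square kilometres.
#' @export
areal_extent <- function(traj_sets, grid = NULL, cell_size = 1000) {
  dg <- density_heatmap(traj_sets, grid = grid, cell_size = cell_size)
  sum(dg$density > 0) * (dg$grid$cell_size / 1000)^2
}

#' Aggregate per-release dispersal statistics over detections
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' per-release statistic (maximum distance, areal extent, ...) over the
#' releases selected by a detection filter. With a single selected release
#' the sd is undefined and reported as `NA`.
#'
#' @param values Numeric per-release values.
#' @param select Logical or integer index of releases that coincide with
#'   eDNA detections; `NULL` selects all.
#' @return A list with `mean`, `sd`, `n` and the selected `values`.
#' @export
aggregate_dispersal <- function(values, select = NULL) {
  v <- if (is.null(select)) as.double(values) else as.double(values[select])
  if (!length(v)) stop("detection filter selected no releases")
  if (any(!is.finite(v))) stop("non-finite per-release values")
  list(mean = mean(v),
       sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
       n = length(v), values = v)
}

#' Inter-station connectivity from backtracked trajectories
#'
#' `fraction[i, j]` is the share of particles backtracked from station `i`
#' whose trajectory ever comes within `radius` of station `j` during the
#' tracking window: an estimate of whether the same water (and hence the
#' same eDNA) could have flowed through more than one station, i.e. whether
#' detections at the two stations are independent. The diagonal is 1 by
#' construction whenever the release radius does not exceed `radius`.
#'
#' @param traj_by_station Named list of `trajectory_set`, one per station.
#' @param stations Data frame with `station_id`, `x`, `y` for every name in
#'   `traj_by_station`.
#' @param radius Encounter radius in metres (default 1000, the heatmap cell
#'   scale).
#' @return A square matrix of fractions with station ids as dimnames and
#'   attribute `radius`; `fraction > 0` is the "potentially connected" view.
#' @export
connectivity <- function(traj_by_station, stations, radius = 1000) {
  ids <- names(traj_by_station)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("traj_by_station must be a named list keyed by station id")
  missing <- setdiff(ids, stations$station_id)
  if (length(missing))
    stop("no station metadata for: ", paste(missing, collapse = ", "))
  n <- length(ids)
  fr <- matrix(0, n, n, dimnames = list(from = ids, to = ids))
  r2 <- radius^2
  for (i in seq_len(n)) {
    tr <- traj_by_station[[i]]
    for (j in seq_len(n)) {
      sj <- stations[stations$station_id == ids[j], ]
      dx <- tr$x - sj$x; dy <- tr$y - sj$y
      hit <- rowSums(dx * dx + dy * dy <= r2) > 0
      fr[i, j] <- mean(hit)
    }
  }
  attr(fr, "radius") <- radius
  fr
}
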