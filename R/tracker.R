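#' Define a sampling station
#'
#' @param id Short station code (e.g. `"PO"`).
#' @param x,y Station position in metres, inside the flow-field domain.
#' @param sampling_times Optional strictly increasing vector of water-sample
#'   collection times (seconds since the flow-field epoch).
#' @return An object of class `station`.
#' @export
station <- function(id, x, y, sampling_times = numeric()) {
  sampling_times <- as.double(sampling_times)
  if (length(sampling_times) > 1 && any(diff(sampling_times) <= 0))
    stop("sampling_times must be strictly increasing")
  structure(list(id = as.character(id), x = as.double(x), y = as.double(y),
                 sampling_times = sampling_times),
            class = "station")
}

#' Release protocol for a backtracking run
#'
#' Defaults follow the standard protocol for eDNA source-area backtracking:
#' 1000 particles released within a 200 m radius of the station at the exact
#' sampling time, tracked for 3 days (a proxy for eDNA degradation) with
#' positions recorded every 5 minutes.
#'
#' @param n_particles Particles per release (default 1000).
#' @param radius Release disc radius in metres (default 200), accounting for
#'   variability in sample location and model resolution.
#' @param duration Tracking window in seconds (default 259200 = 3 days).
#' @param record_interval Recording cadence in seconds (default 300 = 5 min).
#' @param dt Integration step in seconds (default 60); must divide
#'   `record_interval`, which must divide `duration`.
#' @param seed RNG seed controlling the release positions.
#' @return An object of class `release_spec`.
#' @export
release_spec <- function(n_particles = 1000L, radius = 200,
                         duration = 259200, record_interval = 300,
                         dt = 60, seed = 1L) {
  spec <- structure(list(n_particles = as.integer(n_particles),
                         radius = as.double(radius),
                         duration = as.double(duration),
                         record_interval = as.double(record_interval),
                         dt = as.double(dt), seed = as.integer(seed)),
                    class = "release_spec")
  if (spec$n_particles < 1L) stop("n_particles must be >= 1")
  if (spec$radius < 0) stop("radius must be >= 0")
  if (spec$dt <= 0) stop("dt must be positive")
  if (abs(spec$record_interval / spec$dt -
          round(spec$record_interval / spec$dt)) > 1e-9)
    stop("dt must divide record_interval")
  if (abs(spec$duration / spec$record_interval -
          round(spec$duration / spec$record_interval)) > 1e-9)
    stop("record_interval must divide duration")
  spec
}

# run fn with a private, restored RNG state
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Draw particle release positions around a station
#'
#' Positions are uniform over the release disc: radius `radius * sqrt(U)`
#' and angle `2 * pi * U'`, the standard square-root transform for uniform
#' areal density. Deterministic given `spec$seed`.
#'
#' @param station A [station()].
#' @param spec A [release_spec()].
#' @return `n_particles x 2` matrix of easting/northing metres.
#' @export
release_positions <- function(station, spec = release_spec()) {
  stopifnot(inherits(station, "station"), inherits(spec, "release_spec"))
  with_seed(spec$seed, function() {
    r <- spec$radius * sqrt(stats::runif(spec$n_particles))
    th <- 2 * pi * stats::runif(spec$n_particles)
    cbind(x = station$x + r * cos(th), y = station$y + r * sin(th))
  })
}

status_levels <- c("active", "beached", "out_of_domain")

#' Advect particles passively through a flow field
#'
#' Fixed-step fourth-order Runge-Kutta integration driven by
#' [sample_velocity()]; transport is purely advective (no added sub-grid
#' diffusion). A particle stepping onto a dry cell is flagged `beached`, one
#' leaving the grid bounding box `out_of_domain`; either way it is frozen at
#' its last valid position for the remainder of the run (frozen records
#' still count in density and connectivity tallies).
#'
#' @param field A [flow_field()].
#' @param positions `n x 2` matrix of start positions (metres).
#' @param t_start Start time (seconds, field epoch).
#' @param spec A [release_spec()]; `duration`, `record_interval` and `dt`
#'   control the integration.
#' @param station_id,sample_time Optional labels carried into the result.
#' @param station_xy Optional length-2 reference position; defaults to the
#'   mean release position.
#' @return An object of class `trajectory_set` with elements `elapsed`
#'   (recording offsets in seconds), matrices `x`, `y`
#'   (`n_particles x n_records`), integer `status` matrix (0 = active,
#'   1 = beached, 2 = out of domain), and the release positions.
#' @export
advect <- function(field, positions, t_start, spec = release_spec(),
                   station_id = NA_character_, sample_time = NA_real_,
                   station_xy = NULL) {
  stopifnot(inherits(field, "flow_field"), is.matrix(positions),
            ncol(positions) == 2L)
  nt <- length(field$times)
  if (t_start < field$times[1] - 1e-9 ||
      t_start + spec$duration > field$times[nt] + 1e-9)
    stop("configuration error: flow-field time span does not cover the ",
         "tracking window [", t_start, ", ", t_start + spec$duration, "] s")

  n <- nrow(positions)
  n_steps <- round(spec$duration / spec$dt)
  rec_every <- round(spec$record_interval / spec$dt)
  n_rec <- round(spec$duration / spec$record_interval) + 1L

  px <- as.double(positions[, 1]); py <- as.double(positions[, 2])
  status <- integer(n)
  X <- matrix(NA_real_, n, n_rec); Y <- matrix(NA_real_, n, n_rec)
  S <- matrix(0L, n, n_rec)
  X[, 1L] <- px; Y[, 1L] <- py
  xmin <- field$x[1]; xmax <- field$x[length(field$x)]
  ymin <- field$y[1]; ymax <- field$y[length(field$y)]

  t <- t_start
  h <- spec$dt
  for (s in seq_len(n_steps)) {
    idx <- which(status == 0L)
    if (length(idx)) {
      x0 <- px[idx]; y0 <- py[idx]
      k1 <- vel_at(field, x0, y0, t)
      k2 <- vel_at(field, x0 + h / 2 * k1[, 1], y0 + h / 2 * k1[, 2], t + h / 2)
      k3 <- vel_at(field, x0 + h / 2 * k2[, 1], y0 + h / 2 * k2[, 2], t + h / 2)
      k4 <- vel_at(field, x0 + h * k3[, 1], y0 + h * k3[, 2], t + h)
      x1 <- x0 + h / 6 * (k1[, 1] + 2 * k2[, 1] + 2 * k3[, 1] + k4[, 1])
      y1 <- y0 + h / 6 * (k1[, 2] + 2 * k2[, 2] + 2 * k3[, 2] + k4[, 2])
      oob <- x1 < xmin | x1 > xmax | y1 < ymin | y1 > ymax
      dry <- !oob & !is_wet(field, x1, y1)
      ok <- !oob & !dry
      px[idx[ok]] <- x1[ok]; py[idx[ok]] <- y1[ok]
      status[idx[oob]] <- 2L
      status[idx[dry]] <- 1L
    }
    t <- t_start + s * h
    if (s %% rec_every == 0L) {
      r <- s %/% rec_every + 1L
      X[, r] <- px; Y[, r] <- py; S[, r] <- status
    }
  }

  if (is.null(station_xy)) station_xy <- c(mean(positions[, 1]),
                                           mean(positions[, 2]))
  structure(list(station_id = station_id, sample_time = sample_time,
                 elapsed = seq(0, spec$duration, by = spec$record_interval),
                 x = X, y = Y, status = S,
                 release = positions,
                 station_x = station_xy[1], station_y = station_xy[2],
                 spec = spec),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "trajectory_set: station %s, %d particles x %d records (%.2f days)\n  final status: %s\n",
    x$station_id, nrow(x$x), ncol(x$x),
    x$elapsed[length(x$elapsed)] / 86400,
    paste(sprintf("%s=%d", status_levels,
                  tabulate(x$status[, ncol(x$status)] + 1L, 3L)),
          collapse = " ")))
  invisible(x)
}

#' Backtrack particles from a station to potential eDNA source areas
#'
#' Releases particles in a disc around the station at the water-sampling
#' time and integrates them backwards through the currents for the tracking
#' window (default 3 days, the decay proxy), by forward integration through
#' [reverse_field()]. The `elapsed` axis of the result is seconds *before*
#' sampling: the record at elapsed 0 is the arrival constraint (particles at
#' the station at the precise sampling time).
#'
#' @param field A [flow_field()] of forward (real) currents.
#' @param station A [station()].
#' @param sample_time Water-sample collection time (seconds, field epoch);
#'   `[sample_time - duration, sample_time]` must lie inside the field span.
#' @param spec A [release_spec()].
#' @return A `trajectory_set`; see [advect()].
#' @export
backtrack <- function(field, station, sample_time, spec = release_spec()) {
  stopifnot(inherits(field, "flow_field"), inherits(station, "station"))
  nt <- length(field$times)
  if (sample_time - spec$duration < field$times[1] - 1e-9 ||
      sample_time > field$times[nt] + 1e-9)
    stop("configuration error: flow field does not cover [sample_time - ",
         "duration, sample_time] for station ", station$id)
  pos <- release_positions(station, spec)
  rf <- reverse_field(field)
  advect(rf, pos, t_start = field$times[nt] - sample_time, spec = spec,
         station_id = station$id, sample_time = sample_time,
         station_xy = c(station$x, station$y))
}

#' Write a trajectory set to HDF5
#'
#' Datasets `x`, `y` \[m\] and `status` over (particle, record), `elapsed`
#' \[s\], `release` positions, and scalar metadata.
#'
#' @param traj A `trajectory_set`.
#' @param path Output path; overwritten if present.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(traj$x, path, "x")
  rhdf5::h5write(traj$y, path, "y")
  rhdf5::h5write(traj$status, path, "status")
  rhdf5::h5write(traj$elapsed, path, "elapsed")
  rhdf5::h5write(traj$release, path, "release")
  rhdf5::h5write(as.character(traj$station_id), path, "station_id")
  rhdf5::h5write(as.double(traj$sample_time), path, "sample_time")
  rhdf5::h5write(c(traj$station_x, traj$station_y), path, "station_xy")
  invisible(path)
}

#' Read a trajectory set written by [write_trajectories()]
#'
#' @param path HDF5 file path.
#' @return A `trajectory_set`.
#' @export
read_trajectories <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  g <- function(nm) rhdf5::h5read(path, nm)
  sxy <- as.double(g("station_xy"))
  structure(list(station_id = as.character(g("station_id")),
                 sample_time = as.double(g("sample_time")),
                 elapsed = as.double(g("elapsed")),
                 x = g("x"), y = g("y"),
                 status = matrix(as.integer(g("status")), nrow(g("x"))),
                 release = g("release"),
                 station_x = sxy[1], station_y = sxy[2],
                 spec = NULL),
            class = "trajectory_set")
}
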