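#' Construct a depth-averaged flow field
#'
#' A `flow_field` holds time-varying 2-D depth-averaged currents on a regular
#' grid in local projected metres, together with a wet/dry mask marking water
#' cells. Velocities are node values; [sample_velocity()] interpolates
#' bilinearly in space and linearly in time, renormalising interpolation
#' weights over wet nodes so land never contributes spurious momentum.
#'
#' @param x,y Strictly increasing node coordinates in metres (easting,
#'   northing).
#' @param times Strictly increasing, uniformly spaced times in seconds since
#'   the simulation epoch.
#' @param u,v Eastward / northward velocity in m/s, arrays with
#'   `dim = c(length(times), length(y), length(x))`.
#' @param wet Logical matrix `length(y) x length(x)`; `TRUE` marks water.
#'   Defaults to all wet.
#' @return An object of class `flow_field`.
#' @seealso [sample_velocity()], [reverse_field()], [is_wet()],
#'   [write_flowfield()]
#' @export
flow_field <- function(x, y, times, u, v, wet = NULL) {
  x <- as.double(x); y <- as.double(y); times <- as.double(times)
  if (is.null(wet)) wet <- matrix(TRUE, length(y), length(x))
  wet <- matrix(as.logical(wet), length(y), length(x))
  f <- structure(
    list(x = x, y = y, times = times,
         u = u, v = v, wet = wet),
    class = "flow_field")
  validate_flow_field(f)
  # zero out dry-node velocities so interpolation can use plain products
  # (dry nodes carry zero weight anyway; their stored values are never used)
  if (!all(wet)) {
    dry <- which(!as.vector(wet))
    nt <- length(times)
    um <- matrix(f$u, nt); um[, dry] <- 0
    vm <- matrix(f$v, nt); vm[, dry] <- 0
    f$u <- array(um, dim(f$u)); f$v <- array(vm, dim(f$v))
  }
  f
}

validate_flow_field <- function(f) {
  nx <- length(f$x); ny <- length(f$y); nt <- length(f$times)
  if (nx < 2L || ny < 2L) stop("flow_field needs at least 2 nodes per spatial axis")
  if (any(diff(f$x) <= 0)) stop("x coordinates must be strictly increasing")
  if (any(diff(f$y) <= 0)) stop("y coordinates must be strictly increasing")
  if (nt < 1L) stop("flow_field needs at least one time step")
  if (nt > 1L) {
    dt <- diff(f$times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if ((max(dt) - min(dt)) > 1e-6 * mean(dt))
      stop("time spacing must be uniform (1e-6 relative tolerance)")
  }
  expect_dim <- c(nt, ny, nx)
  for (nm in c("u", "v")) {
    d <- dim(f[[nm]])
    if (is.null(d) || length(d) != 3L || any(d != expect_dim))
      stop(sprintf("%s must have dim (time=%d, y=%d, x=%d)", nm, nt, ny, nx))
  }
  if (!all(dim(f$wet) == c(ny, nx)))
    stop("wet mask must have dim (y, x) matching the coordinates")
  # finiteness is only required over water
  wet_idx <- which(f$wet)
  if (length(wet_idx)) {
    for (nm in c("u", "v")) {
      m <- matrix(f[[nm]], nt, ny * nx)
      if (!all(is.finite(m[, wet_idx])))
        stop(sprintf("%s must be finite at all wet cells for all times", nm))
    }
  }
  invisible(f)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "flow_field: %d x %d nodes, %d time steps\n  x: [%g, %g] m  y: [%g, %g] m\n  t: [%g, %g] s (dt = %g s)\n  wet fraction: %.2f\n",
    length(x$x), length(x$y), length(x$times),
    min(x$x), max(x$x), min(x$y), max(x$y),
    x$times[1], x$times[length(x$times)],
    if (length(x$times) > 1) x$times[2] - x$times[1] else NA_real_,
    mean(x$wet)))
  invisible(x)
}

# Vectorised interior sampler used by the integrator: x, y vectors, t scalar.
# Out-of-bounds positions yield (0, 0) rather than an error so that RK4
# sub-steps straddling the boundary stay defined; the tracker itself freezes
# particles that leave the domain.
vel_at <- function(field, x, y, t, clip = TRUE) {
  nx <- length(field$x); ny <- length(field$y); nt <- length(field$times)
  n <- length(x)
  u_out <- numeric(n); v_out <- numeric(n)

  inside <- x >= field$x[1] & x <= field$x[nx] &
            y >= field$y[1] & y <= field$y[ny]
  if (!clip && !all(inside)) {
    ax <- if (any(x < field$x[1] | x > field$x[nx])) "x" else "y"
    stop(sprintf("position outside flow-field domain on the %s axis", ax))
  }
  if (t < field$times[1] || t > field$times[nt]) {
    if (!clip) stop("time outside flow-field span on the time axis")
    t <- min(max(t, field$times[1]), field$times[nt])
  }
  if (!any(inside)) return(cbind(u = u_out, v = v_out))

  xi <- x[inside]; yi <- y[inside]
  ix <- findInterval(xi, field$x, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L)
  iy <- findInterval(yi, field$y, rightmost.closed = TRUE)
  iy <- pmin(pmax(iy, 1L), ny - 1L)
  fx <- (xi - field$x[ix]) / (field$x[ix + 1L] - field$x[ix])
  fy <- (yi - field$y[iy]) / (field$y[iy + 1L] - field$y[iy])

  if (nt == 1L) {
    kt <- 1L; wt <- 0
  } else {
    kt <- findInterval(t, field$times, rightmost.closed = TRUE)
    kt <- min(max(kt, 1L), nt - 1L)
    wt <- (t - field$times[kt]) / (field$times[kt + 1L] - field$times[kt])
  }

  i00 <- (ix - 1L) * ny + iy             # linear index of node [iy, ix]
  i01 <- i00 + ny; i10 <- i00 + 1L; i11 <- i00 + ny + 1L
  w <- field$wet
  a00 <- (1 - fx) * (1 - fy) * w[i00]
  a01 <- fx       * (1 - fy) * w[i01]
  a10 <- (1 - fx) * fy       * w[i10]
  a11 <- fx       * fy       * w[i11]
  wsum <- a00 + a01 + a10 + a11
  # renormalise over wet corners; all-dry neighbourhood samples to zero
  scl <- numeric(length(wsum))
  ok <- wsum > 0
  scl[ok] <- 1 / wsum[ok]

  interp_slice <- function(arr, k) {
    m <- arr[k, , ]                      # (ny x nx) matrix
    # dry-node values are zeroed at construction; weights handle the rest
    (a00 * m[i00] + a01 * m[i01] + a10 * m[i10] + a11 * m[i11]) * scl
  }

  u1 <- interp_slice(field$u, kt); v1 <- interp_slice(field$v, kt)
  if (wt > 0) {
    u2 <- interp_slice(field$u, kt + 1L); v2 <- interp_slice(field$v, kt + 1L)
    u1 <- (1 - wt) * u1 + wt * u2
    v1 <- (1 - wt) * v1 + wt * v2
  }
  u_out[inside] <- u1; v_out[inside] <- v1
  cbind(u = u_out, v = v_out)
}

#' Sample the velocity field at a point in space and time
#'
#' Bilinear interpolation in space and linear interpolation in time. Dry
#' (land) nodes contribute zero with the remaining weights renormalised over
#' wet nodes; if all four surrounding nodes are dry the velocity is `(0, 0)`.
#'
#' @param field A [flow_field()].
#' @param x,y Position in metres (vectors of equal length allowed).
#' @param t Time in seconds since the field epoch (scalar).
#' @return A two-column matrix with columns `u`, `v` (m/s); a single row for
#'   scalar input.
#' @export
sample_velocity <- function(field, x, y, t) {
  stopifnot(inherits(field, "flow_field"), length(t) == 1L)
  vel_at(field, as.double(x), as.double(y), as.double(t), clip = FALSE)
}

#' Reverse a flow field in time for backtracking
#'
#' Negates both velocity components and reverses the time axis, re-anchoring
#' the reversed times at zero. Integrating forwards through the reversed
#' field is equivalent to integrating backwards through the original, which
#' is how backtracked trajectories are computed.
#'
#' @param field A [flow_field()].
#' @return A [flow_field()] with `times' = max(times) - rev(times)`,
#'   `u' = -u` and `v' = -v` reversed along time, and the wet mask unchanged.
#' @export
reverse_field <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  nt <- length(field$times)
  ord <- nt:1L
  flow_field(
    x = field$x, y = field$y,
    times = field$times[nt] - field$times[ord],
    u = -field$u[ord, , , drop = FALSE],
    v = -field$v[ord, , , drop = FALSE],
    wet = field$wet)
}

#' Is a position over water?
#'
#' Positions are assigned to the grid cell of the nearest node; positions
#' outside the grid (beyond half a cell from the outermost nodes) are dry by
#' definition.
#'
#' @param field A [flow_field()].
#' @param x,y Position(s) in metres.
#' @return Logical vector.
#' @export
is_wet <- function(field, x, y) {
  nx <- length(field$x); ny <- length(field$y)
  dx <- field$x[2] - field$x[1]; dy <- field$y[2] - field$y[1]
  ix <- round((x - field$x[1]) / dx) + 1
  iy <- round((y - field$y[1]) / dy) + 1
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & is.finite(x) & is.finite(y)
  out <- logical(length(x))
  if (any(ok)) out[ok] <- field$wet[cbind(iy[ok], ix[ok])]
  out
}

#' Project geographic coordinates to local metres
#'
#' Equirectangular projection about a reference latitude: adequate for
#' domains tens of kilometres across, where it keeps distances and areas
#' metric without a full map projection.
#'
#' @param lon,lat Geographic coordinates in decimal degrees.
#' @param lon0,lat0 Reference point mapped to the local origin.
#' @return A two-column matrix `x`, `y` in metres.
#' @export
lonlat_to_metres <- function(lon, lat, lon0, lat0) {
  R <- 6371000
  x <- (lon - lon0) * pi / 180 * R * cos(lat0 * pi / 180)
  y <- (lat - lat0) * pi / 180 * R
  cbind(x = x, y = y)
}
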