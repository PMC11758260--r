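#' Write a flow field to an HDF5 file
#'
#' The on-disk layout follows CF-style naming: datasets `x` \[m\], `y` \[m\],
#' `time` \[s since the field epoch\], `u(time,y,x)` and `v(time,y,x)`
#' \[m s-1\] and `wet_mask(y,x)` \[0/1\]. Coordinates are stored in double
#' precision (bit-exact round trip); velocities in 32-bit floats, the usual
#' storage precision for hydrodynamic hindcast output.
#'
#' @param field A [flow_field()].
#' @param path Output file path; overwritten if present.
#' @return `path`, invisibly.
#' @export
write_flowfield <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(field$x, path, "x")
  rhdf5::h5write(field$y, path, "y")
  rhdf5::h5write(field$times, path, "time")
  for (nm in c("u", "v")) {
    rhdf5::h5createDataset(path, nm, dims = dim(field[[nm]]),
                           H5type = "H5T_IEEE_F32LE", level = 0,
                           chunk = NULL)
    rhdf5::h5write(field[[nm]], path, nm)
  }
  rhdf5::h5write(matrix(as.integer(field$wet), nrow(field$wet)), path,
                 "wet_mask")
  invisible(path)
}

#' Read a flow field from an HDF5 file
#'
#' Counterpart of [write_flowfield()]. Validates the layout and the
#' [flow_field()] invariants; a missing dataset or an inconsistent shape
#' raises a format error naming the violation.
#'
#' @param path File written by [write_flowfield()].
#' @return A [flow_field()].
#' @export
read_flowfield <- function(path) {
  if (!file.exists(path)) stop("flow-field file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  have <- rhdf5::h5ls(path)$name
  need <- c("x", "y", "time", "u", "v", "wet_mask")
  missing <- setdiff(need, have)
  if (length(missing))
    stop("flow-field format error: missing variable(s) ",
         paste(sQuote(missing), collapse = ", "))
  g <- function(nm) rhdf5::h5read(path, nm)
  f <- try(flow_field(x = as.double(g("x")), y = as.double(g("y")),
                      times = as.double(g("time")),
                      u = g("u"), v = g("v"),
                      wet = g("wet_mask") != 0), silent = TRUE)
  if (inherits(f, "try-error"))
    stop("flow-field format error: ", attr(f, "condition")$message)
  f
}

#' Read station metadata
#'
#' Stations CSV columns: `station_id,name,x_m,y_m`. Sampling-times CSV
#' columns: `station_id,sample_time_s` (seconds since the flow-field epoch).
#'
#' @param stations_path Stations CSV.
#' @param times_path Optional sampling-times CSV; when given, each station's
#'   `sampling_times` are attached (sorted, strictly increasing).
#' @return A data frame with columns `station_id`, `name`, `x`, `y` and, if
#'   `times_path` was given, a list column `sampling_times`.
#' @export
read_stations <- function(stations_path, times_path = NULL) {
  st <- utils::read.csv(stations_path, stringsAsFactors = FALSE)
  need <- c("station_id", "name", "x_m", "y_m")
  missing <- setdiff(need, names(st))
  if (length(missing))
    stop("stations format error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "))
  out <- data.frame(station_id = as.character(st$station_id),
                    name = as.character(st$name),
                    x = as.double(st$x_m), y = as.double(st$y_m),
                    stringsAsFactors = FALSE)
  if (!is.null(times_path)) {
    tt <- utils::read.csv(times_path, stringsAsFactors = FALSE)
    if (!all(c("station_id", "sample_time_s") %in% names(tt)))
      stop("sampling-times format error: need columns station_id, sample_time_s")
    out$sampling_times <- lapply(out$station_id, function(id) {
      ts <- sort(as.double(tt$sample_time_s[tt$station_id == id]))
      if (anyDuplicated(ts)) stop("duplicated sampling time for station ", id)
      ts
    })
  }
  out
}
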