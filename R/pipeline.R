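#' Read a run configuration
#'
#' A YAML file (or list) describing an end-to-end run: input paths or
#' in-memory objects, release-protocol overrides, analysis grid, and seed.
#' Recognised fields: `flowfield`, `stations`, `sampling_times`,
#' `asv_table`, `sample_metadata`, `release` (list of [release_spec()]
#' overrides), `cell_size`, `connectivity_radius`, `target_class`,
#' `min_confidence`, `contaminants`, `out_dir`, `seed`.
#'
#' @param x Path to a YAML file, or a list.
#' @return A `run_config` list with defaults filled in.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(release = list(), cell_size = 1000,
                   connectivity_radius = 1000,
                   target_class = "Elasmobranchii", min_confidence = 40,
                   contaminants = character(), out_dir = NULL, seed = 1L)
  cfg <- utils::modifyList(defaults, x)
  for (nm in c("flowfield", "stations", "sampling_times", "asv_table",
               "sample_metadata")) {
    if (is.character(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("configuration error: file not found for ", nm, ": ", cfg[[nm]])
  }
  structure(cfg, class = "run_config")
}

resolve_field <- function(cfg) {
  f <- cfg$flowfield
  if (is.character(f)) f <- read_flowfield(f)
  stopifnot(inherits(f, "flow_field"))
  f
}

resolve_stations <- function(cfg) {
  st <- cfg$stations
  if (is.character(st)) st <- read_stations(st)
  stopifnot(is.data.frame(st), all(c("station_id", "x", "y") %in% names(st)))
  st
}

resolve_sampling_times <- function(cfg) {
  tt <- cfg$sampling_times
  if (is.character(tt)) tt <- utils::read.csv(tt, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(tt),
            all(c("station_id", "sample_time_s") %in% names(tt)))
  if (is.null(tt$month)) tt$month <- as.character(seq_len(nrow(tt)))
  tt
}

#' Run backtracking for every station and sampling time
#'
#' Releases and backtracks one particle set per station per sampling time
#' (the monthly campaign structure), then aggregates the dispersal
#' products: per-release maximum straight-line distances and areal
#' extents, the pooled density heatmap, per-campaign and overall
#' inter-station connectivity, and a machine-readable manifest of counts.
#' A release whose sampling window is not covered by the flow field is
#' recorded as a per-release error and the run continues.
#'
#' @param cfg A [run_config()].
#' @return A list of class `backtrack_run`: `releases` (per-release data
#'   frame), `trajectories` (list keyed `station_id.month`), `heatmap`
#'   (pooled [density_heatmap()]), `connectivity` (list with `per_campaign`
#'   and element-wise max `overall`), `manifest`, `errors`.
#' @export
run_backtrack <- function(cfg) {
  cfg <- if (inherits(cfg, "run_config")) cfg else run_config(cfg)
  field <- resolve_field(cfg)
  stations <- resolve_stations(cfg)
  stimes <- resolve_sampling_times(cfg)

  base <- list(seed = cfg$seed)
  spec_args <- utils::modifyList(base, cfg$release)
  trajs <- list(); rel <- list(); errs <- list()
  idx <- 0L
  for (k in seq_len(nrow(stimes))) {
    sid <- stimes$station_id[k]
    srow <- stations[stations$station_id == sid, ]
    if (!nrow(srow)) {
      errs[[length(errs) + 1L]] <- data.frame(
        station_id = sid, month = stimes$month[k],
        error = "unknown station", stringsAsFactors = FALSE)
      next
    }
    idx <- idx + 1L
    spec_k <- spec_args
    spec_k$seed <- as.integer(spec_args$seed + idx)  # one draw per release
    spec <- do.call(release_spec, spec_k)
    st <- station(sid, srow$x, srow$y)
    tr <- tryCatch(backtrack(field, st, stimes$sample_time_s[k], spec),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        station_id = sid, month = stimes$month[k],
        error = conditionMessage(tr), stringsAsFactors = FALSE)
      next
    }
    key <- paste(sid, stimes$month[k], sep = ".")
    trajs[[key]] <- tr
    rel[[key]] <- data.frame(
      station_id = sid, month = stimes$month[k],
      sample_time = stimes$sample_time_s[k],
      n_particles = nrow(tr$x),
      max_distance_km = max_straight_line_distance(tr),
      areal_extent_km2 = areal_extent(tr, cell_size = cfg$cell_size),
      stringsAsFactors = FALSE)
  }
  if (!length(trajs)) stop("no release succeeded")
  releases <- do.call(rbind, rel); rownames(releases) <- NULL
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(station_id = character(), month = character(),
               error = character(), stringsAsFactors = FALSE)

  heatmap <- density_heatmap(trajs, cell_size = cfg$cell_size)

  per_campaign <- list()
  for (mo in unique(releases$month)) {
    sel <- releases$month == mo
    if (sum(sel) < 2) next
    tl <- trajs[paste(releases$station_id[sel], mo, sep = ".")]
    names(tl) <- releases$station_id[sel]
    per_campaign[[mo]] <- connectivity(tl, stations,
                                       radius = cfg$connectivity_radius)
  }
  overall <- if (length(per_campaign)) Reduce(pmax, per_campaign) else NULL

  per_station <- tapply(releases$n_particles, releases$station_id, sum)
  manifest <- list(n_stations = length(unique(releases$station_id)),
                   n_releases = nrow(releases),
                   n_particles_total = sum(releases$n_particles),
                   particles_per_station = as.list(per_station),
                   n_errors = nrow(errors),
                   seed = cfg$seed)

  out <- structure(list(releases = releases, trajectories = trajs,
                        heatmap = heatmap,
                        connectivity = list(per_campaign = per_campaign,
                                            overall = overall),
                        manifest = manifest, errors = errors),
                   class = "backtrack_run")
  if (!is.null(cfg$out_dir)) write_backtrack_outputs(out, cfg$out_dir)
  out
}

write_backtrack_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(run$releases, file.path(out_dir, "releases.csv"),
                   row.names = FALSE)
  if (nrow(run$errors))
    utils::write.csv(run$errors, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
  if (!is.null(run$connectivity$overall))
    utils::write.csv(as.data.frame(run$connectivity$overall),
                     file.path(out_dir, "connectivity.csv"))
  grDevices::png(file.path(out_dir, "heatmap.png"), width = 900, height = 700)
  plot(run$heatmap)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Run the detection-filtering chain from a configuration
#'
#' Reads (or takes) the ASV table and sample metadata, applies
#' [run_filter_chain()], and computes the detection summary and the
#' permutation species accumulation curve.
#'
#' @param cfg A [run_config()] with `asv_table` and `sample_metadata`.
#' @return A list of class `detect_run`: `detections`, `summary`, `log`,
#'   `accumulation`, `blank_screen`, `table` (the filtered table) and
#'   `meta`.
#' @export
run_detect <- function(cfg) {
  cfg <- if (inherits(cfg, "run_config")) cfg else run_config(cfg)
  tab <- cfg$asv_table
  if (is.character(tab)) tab <- read_asv_table(tab)
  stopifnot(inherits(tab, "asv_table"))
  meta <- cfg$sample_metadata
  if (is.character(meta)) meta <- read_sample_metadata(meta)
  meta <- validate_sample_metadata(meta, tab)

  chain <- run_filter_chain(tab, meta, target_class = cfg$target_class,
                            min_confidence = cfg$min_confidence,
                            contaminants = cfg$contaminants)
  inc <- detection_incidence(chain$detections, meta)
  acc <- accumulation_curve(inc, seed = cfg$seed)
  out <- structure(list(detections = chain$detections,
                        summary = summarize_detections(chain$detections, meta),
                        log = chain$log, accumulation = acc,
                        blank_screen = chain$blank_screen,
                        table = chain$table, meta = meta),
                   class = "detect_run")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$detections$by_sample,
                     file.path(cfg$out_dir, "detections.csv"),
                     row.names = FALSE)
    utils::write.csv(out$log, file.path(cfg$out_dir, "attrition.csv"),
                     row.names = FALSE)
    utils::write.csv(acc, file.path(cfg$out_dir, "accumulation.csv"),
                     row.names = FALSE)
  }
  out
}

#' Join detections to their backtracked dispersal products
#'
#' For every species-level detection (species, station, month), attaches
#' the corresponding release's maximum straight-line distance and areal
#' extent, and aggregates mean and sd over detections — the
#' detection-conditioned dispersal statistics. Detections at a
#' station-month with no trajectory set raise an error naming it.
#'
#' @param bt A [run_backtrack()] result.
#' @param det A [run_detect()] result.
#' @return A list of class `dispersal_report`: `per_detection` (joined
#'   data frame), `max_distance` and `areal_extent` aggregates
#'   ([aggregate_dispersal()] lists), `n_detections`. With no detections,
#'   an empty report with a `notice`.
#' @export
run_report <- function(bt, det) {
  stopifnot(inherits(bt, "backtrack_run"), inherits(det, "detect_run"))
  d <- det$detections$by_station_month
  if (!nrow(d)) {
    return(structure(list(per_detection = d, max_distance = NULL,
                          areal_extent = NULL, n_detections = 0L,
                          notice = "no detections to report"),
                     class = "dispersal_report"))
  }
  key <- paste(d$station, d$month, sep = ".")
  rkey <- paste(bt$releases$station_id, bt$releases$month, sep = ".")
  hit <- match(key, rkey)
  if (anyNA(hit))
    stop("no trajectory set for detection(s) at: ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  per <- cbind(d, bt$releases[hit, c("max_distance_km", "areal_extent_km2"),
                              drop = FALSE])
  rownames(per) <- NULL
  # aggregate over distinct detection-coincident releases
  rel_sel <- unique(hit)
  structure(list(
    per_detection = per,
    max_distance = aggregate_dispersal(bt$releases$max_distance_km[rel_sel]),
    areal_extent = aggregate_dispersal(bt$releases$areal_extent_km2[rel_sel]),
    n_detections = nrow(per)),
    class = "dispersal_report")
}

#' @export
print.dispersal_report <- function(x, ...) {
  if (!x$n_detections) {
    cat("dispersal_report: no detections to report\n")
    return(invisible(x))
  }
  cat(sprintf(
    "dispersal_report: %d detections over %d detection-coincident releases\n  max straight-line distance: %.1f km (sd %.1f)\n  areal extent: %.1f km2 (sd %.1f)\n",
    x$n_detections, x$max_distance$n,
    x$max_distance$mean, x$max_distance$sd,
    x$areal_extent$mean, x$areal_extent$sd))
  invisible(x)
}
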