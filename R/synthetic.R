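#' Uniform synthetic flow field
#'
#' Spatially and temporally constant currents over an all-wet square
#' domain: the closed-form test bed (displacement after time `T` is exactly
#' `(u0, v0) * T`).
#'
#' @param u0,v0 Velocity components in m/s.
#' @param extent Domain edge length in metres (domain is
#'   `[-extent/2, extent/2]^2`).
#' @param duration Field time span in seconds.
#' @param resolution Node spacing in metres.
#' @param time_step Stored time resolution in seconds (default 300 = 5 min,
#'   the usual hindcast output cadence).
#' @return A [flow_field()].
#' @export
make_uniform_field <- function(u0, v0, extent = 60000, duration = 345600,
                               resolution = extent, time_step = 300) {
  if (extent <= 0 || duration <= 0 || resolution <= 0 || time_step <= 0)
    stop("extent, duration, resolution and time_step must be positive")
  x <- seq(-extent / 2, extent / 2, by = min(resolution, extent))
  if (length(x) < 2) x <- c(-extent / 2, extent / 2)
  times <- seq(0, duration, by = time_step)
  nt <- length(times); ny <- length(x); nx <- length(x)
  flow_field(x = x, y = x, times = times,
             u = array(u0, c(nt, ny, nx)),
             v = array(v0, c(nt, ny, nx)))
}

#' Oscillatory (tidal) synthetic flow field
#'
#' A spatially uniform single-constituent tide with an optional residual
#' drift: `u(t) = ur + U sin(2 pi t / period + phase)`,
#' `v(t) = vr + V cos(2 pi t / period + phase)`. The default period,
#' 44,712 s (12.42 h), is the M2 semi-diurnal constituent that dominates
#' shelf-sea currents; one constituent preserves the oscillatory-plus-
#' residual structure that drives dispersal asymmetry without a full
#' harmonic synthesis.
#'
#' @param U,V Tidal velocity amplitudes (m/s), `>= 0`.
#' @param period Tidal period in seconds.
#' @param phase Phase offset in radians.
#' @param residual Length-2 residual (net drift) velocity `(ur, vr)` m/s.
#' @inheritParams make_uniform_field
#' @return A [flow_field()].
#' @export
make_tidal_field <- function(U, V, period = 44712, phase = 0,
                             residual = c(0, 0), extent = 60000,
                             duration = 345600, time_step = 300) {
  if (U < 0 || V < 0) stop("tidal amplitudes must be >= 0")
  if (period <= 0) stop("period must be positive")
  x <- c(-extent / 2, extent / 2)
  times <- seq(0, duration, by = time_step)
  nt <- length(times)
  ut <- residual[1] + U * sin(2 * pi * times / period + phase)
  vt <- residual[2] + V * cos(2 * pi * times / period + phase)
  flow_field(x = x, y = x, times = times,
             u = array(rep(ut, times = 4L), c(nt, 2L, 2L)),
             v = array(rep(vt, times = 4L), c(nt, 2L, 2L)))
}

#' Enclosed-bay synthetic flow field with a land mask
#'
#' A rectangular bay enclosed by land on all sides, carrying a tidally
#' modulated single-gyre circulation derived from a streamfunction
#' `psi = psi0 sin(pi x / Lx) sin(pi y / Ly)`, so interior streamlines are
#' closed and particles cannot leave the bay. Node velocities are obtained
#' from `psi` by central differences (making the discrete field
#' divergence-free under the matching stencil) and modulated in time by
#' `residual + sin(2 pi t / period)`. The one-node border ring is land:
#' velocities are zero there and the wet mask encodes the coastline. This
#' is the stand-in for a coastal embayment at desk scale.
#'
#' @param Lx,Ly Bay extent in metres.
#' @param resolution Node spacing in metres.
#' @param max_speed Peak tidal current speed in m/s (scales `psi0`).
#' @param period Tidal period in seconds (default M2, 44,712 s).
#' @param residual Dimensionless residual fraction added to the tidal
#'   modulation (default 0.1: a ~10% net gyre circulation).
#' @param duration Field time span in seconds.
#' @param time_step Stored time resolution in seconds.
#' @return A [flow_field()] whose domain is `[0, Lx] x [0, Ly]`.
#' @export
make_bay_field <- function(Lx = 30000, Ly = 20000, resolution = 500,
                           max_speed = 0.4, period = 44712, residual = 0.1,
                           duration = 345600, time_step = 300) {
  x <- seq(0, Lx, by = resolution)
  y <- seq(0, Ly, by = resolution)
  nx <- length(x); ny <- length(y)
  if (nx < 5L || ny < 5L) stop("bay too small for the given resolution")
  times <- seq(0, duration, by = time_step)
  nt <- length(times)

  psi0 <- max_speed * min(Lx, Ly) / pi
  psi <- outer(sin(pi * y / Ly), sin(pi * x / Lx)) * psi0  # (ny x nx)
  U <- matrix(0, ny, nx); V <- matrix(0, ny, nx)
  dyy <- y[2] - y[1]; dxx <- x[2] - x[1]
  U[2:(ny - 1), ] <- -(psi[3:ny, ] - psi[1:(ny - 2), ]) / (2 * dyy)
  V[, 2:(nx - 1)] <- (psi[, 3:nx] - psi[, 1:(nx - 2)]) / (2 * dxx)

  wet <- matrix(TRUE, ny, nx)
  wet[c(1L, ny), ] <- FALSE
  wet[, c(1L, nx)] <- FALSE
  U[!wet] <- 0; V[!wet] <- 0

  amp <- residual + sin(2 * pi * times / period)
  u <- array(0, c(nt, ny, nx)); v <- array(0, c(nt, ny, nx))
  for (k in seq_len(nt)) {
    u[k, , ] <- amp[k] * U
    v[k, , ] <- amp[k] * V
  }
  flow_field(x = x, y = y, times = times, u = u, v = v, wet = wet)
}

#' Default synthetic station layout for a bay field
#'
#' Places stations on a regular arc through the bay interior, well away
#' from the land ring.
#'
#' @param field A [make_bay_field()] result.
#' @param n_stations Number of stations.
#' @return Data frame `station_id`, `name`, `x`, `y`.
#' @export
make_bay_stations <- function(field, n_stations = 10) {
  Lx <- max(field$x); Ly <- max(field$y)
  th <- seq(0.15, 0.85, length.out = n_stations) * pi
  data.frame(station_id = sprintf("S%02d", seq_len(n_stations)),
             name = sprintf("station %d", seq_len(n_stations)),
             x = Lx / 2 + 0.30 * Lx * cos(th),
             y = Ly / 2 + 0.30 * Ly * sin(th),
             stringsAsFactors = FALSE)
}

# curated elasmobranch species pool for synthetic surveys (coastal NE
# Atlantic taxa), with class/order/family/genus
elasmo_pool <- function() {
  data.frame(
    class = "Elasmobranchii",
    order = c("Carcharhiniformes", "Carcharhiniformes", "Carcharhiniformes",
              "Carcharhiniformes", "Rajiformes", "Rajiformes", "Rajiformes",
              "Rajiformes", "Rajiformes", "Squatiniformes",
              "Myliobatiformes"),
    family = c("Scyliorhinidae", "Scyliorhinidae", "Triakidae", "Triakidae",
               "Rajidae", "Rajidae", "Rajidae", "Rajidae", "Rajidae",
               "Squatinidae", "Dasyatidae"),
    genus = c("Scyliorhinus", "Scyliorhinus", "Mustelus", "Galeorhinus",
              "Raja", "Raja", "Raja", "Raja", "Raja", "Squatina",
              "Dasyatis"),
    species = c("Scyliorhinus canicula", "Scyliorhinus stellaris",
                "Mustelus asterias", "Galeorhinus galeus", "Raja clavata",
                "Raja microocellata", "Raja undulata", "Raja montagui",
                "Raja brachyura", "Squatina squatina", "Dasyatis pastinaca"),
    stringsAsFactors = FALSE)
}

#' Synthetic ASV survey with known ground truth
#'
#' Emulates the post-denoising ASV table of a monthly two-season eDNA
#' survey: one water sample plus one paired field control per station and
#' month (240 columns at the defaults), a pool of target (elasmobranch)
#' species with planted detections, abundant non-target (teleost)
#' background rows, contaminant taxa from outside the study area, one
#' genus-only row whose species assignment misses the confidence
#' threshold, control leakage and singleton noise. Every injected artefact
#' is recorded in the returned `truth` for exact attrition bookkeeping.
#'
#' Planted detections receive log-normally distributed read counts floored
#' at 2 (so the singleton rule never erases a real detection); singleton
#' noise adds 1-read cells to previously empty target cells; leakage
#' copies a few reads of a planted detection into the paired control,
#' which the control-subtraction step then (correctly, by design of the
#' rule) removes along with the real signal.
#'
#' @param n_stations,n_months Survey layout (defaults 10 stations x 12
#'   months).
#' @param species_pool Number of target species planted (max 11).
#' @param detection_prob Probability a given species is present at a given
#'   station-month sample (default 0.09, a realistic order for
#'   elasmobranch eDNA in temperate coastal water: ~1 in 11 slots).
#' @param leakage_rate Fraction of planted detections whose ASV also leaks
#'   into the paired field control (default 0.05).
#' @param singleton_rate Probability of injecting a 1-read singleton into
#'   an empty target-species cell (default 0.02).
#' @param contaminant_rate Per-sample probability of reads from a
#'   contaminant taxon (default 0.05).
#' @param seed RNG seed; the whole survey is deterministic given it.
#' @return A list: `table` ([asv_table()]), `meta` (sample metadata),
#'   `truth` (class `survey_truth`: `planted` long data frame,
#'   `leakage_events`, `singleton_events`, `contaminant_species`,
#'   `genus_only_asvs`, `expected` detections after leakage).
#' @export
make_survey <- function(n_stations = 10, n_months = 12, species_pool = 11,
                        detection_prob = 0.09, leakage_rate = 0.05,
                        singleton_rate = 0.02, contaminant_rate = 0.05,
                        seed = 1L) {
  stopifnot(n_stations >= 1, n_months >= 1,
            species_pool >= 1, species_pool <= 11)
  rates <- c(detection_prob, leakage_rate, singleton_rate, contaminant_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  with_seed(seed, function() {
    stations <- sprintf("S%02d", seq_len(n_stations))
    months <- if (n_months <= 12) month.abb[seq_len(n_months)] else
      sprintf("M%02d", seq_len(n_months))
    grid <- expand.grid(station = stations, month = months,
                        stringsAsFactors = FALSE)
    sample_ids <- sprintf("%s_%s_S", grid$station, grid$month)
    control_ids <- sprintf("%s_%s_C", grid$station, grid$month)
    blanks <- c("EXT_BLANK_1", "EXT_BLANK_2", "PCR_BLANK_1", "PCR_BLANK_2")
    meta <- rbind(
      data.frame(sample_id = sample_ids, station_id = grid$station,
                 month = grid$month, type = "sample",
                 paired_control_id = control_ids, stringsAsFactors = FALSE),
      data.frame(sample_id = control_ids, station_id = grid$station,
                 month = grid$month, type = "field_control",
                 paired_control_id = NA_character_, stringsAsFactors = FALSE),
      data.frame(sample_id = blanks, station_id = "",
                 month = "", type = rep(c("extraction_control",
                                          "pcr_control"), each = 2L),
                 paired_control_id = NA_character_, stringsAsFactors = FALSE))

    pool <- elasmo_pool()[seq_len(species_pool), ]
    tele <- data.frame(
      class = "Actinopteri", order = "Clupeiformes", family = "Clupeidae",
      genus = c("Sprattus", "Clupea", "Engraulis"),
      species = c("Sprattus sprattus", "Clupea harengus",
                  "Engraulis encrasicolus"), stringsAsFactors = FALSE)
    contam <- data.frame(
      class = "Elasmobranchii", order = "Carcharhiniformes",
      family = "Carcharhinidae", genus = c("Carcharhinus", "Himantura"),
      species = c("Carcharhinus amblyrhynchos", "Himantura uarnak"),
      stringsAsFactors = FALSE)
    contam$family[2] <- "Dasyatidae"; contam$order[2] <- "Myliobatiformes"
    subgenus <- data.frame(
      class = "Elasmobranchii", order = "Rajiformes", family = "Rajidae",
      genus = "Raja", species = "", stringsAsFactors = FALSE)

    tax <- rbind(pool, tele, contam, subgenus)
    tax$asv_id <- sprintf("ASV_%03d", seq_len(nrow(tax)))
    tax$confidence <- c(stats::runif(nrow(pool), 60, 95),
                        stats::runif(nrow(tele), 60, 95),
                        stats::runif(nrow(contam), 60, 95),
                        45)  # genus-level only, species below threshold
    all_cols <- c(sample_ids, control_ids, blanks)
    reads <- matrix(0L, nrow(tax), length(all_cols),
                    dimnames = list(tax$asv_id, all_cols))

    # planted target detections: one sample per station-month
    planted <- do.call(rbind, lapply(seq_len(nrow(pool)), function(sp) {
      hit <- stats::runif(nrow(grid)) < detection_prob
      if (!any(hit)) return(NULL)
      data.frame(species = pool$species[sp], asv_id = tax$asv_id[sp],
                 station = grid$station[hit], month = grid$month[hit],
                 sample_id = sample_ids[hit],
                 reads = pmax(2L, as.integer(round(stats::rlnorm(
                   sum(hit), meanlog = 4, sdlog = 1)))),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(planted))
      planted <- data.frame(species = character(), asv_id = character(),
                            station = character(), month = character(),
                            sample_id = character(), reads = integer(),
                            stringsAsFactors = FALSE)
    if (nrow(planted))
      reads[cbind(match(planted$asv_id, tax$asv_id),
                  match(planted$sample_id, all_cols))] <- planted$reads

    # control leakage: a planted ASV also shows up in the paired control
    leak <- planted[stats::runif(nrow(planted)) < leakage_rate, , drop = FALSE]
    if (nrow(leak)) {
      ctl <- meta$paired_control_id[match(leak$sample_id, meta$sample_id)]
      leak$control_id <- ctl
      leak$control_reads <- 1L + as.integer(stats::runif(nrow(leak)) < 0.5)
      reads[cbind(match(leak$asv_id, tax$asv_id),
                  match(ctl, all_cols))] <- leak$control_reads
    } else leak$control_id <- character(0)

    # teleost background: widespread, reads >= 2 so they attrit only at the
    # target-class filter
    for (r in which(tax$class != "Elasmobranchii")) {
      on_cols <- stats::runif(length(all_cols)) < 0.6
      reads[r, on_cols] <- pmax(2L, as.integer(round(stats::rlnorm(
        sum(on_cols), meanlog = 6, sdlog = 1))))
    }
    # contaminant taxa: sparse reads (>= 2) in samples only
    for (r in match(contam$species, tax$species)) {
      on <- stats::runif(length(sample_ids)) < contaminant_rate
      reads[r, sample_ids[on]] <- pmax(2L, as.integer(round(stats::rlnorm(
        sum(on), meanlog = 3, sdlog = 0.5))))
    }
    # genus-only row: a handful of confident genus-level records
    gs <- sample(sample_ids, min(3L, length(sample_ids)))
    reads[nrow(tax), gs] <- pmax(2L, as.integer(round(stats::rlnorm(
      length(gs), meanlog = 3, sdlog = 0.5))))

    # singleton noise: 1-read cells in empty target-species sample cells
    target_rows <- seq_len(nrow(pool))
    cand <- which(reads[target_rows, sample_ids, drop = FALSE] == 0L,
                  arr.ind = TRUE)
    take <- stats::runif(nrow(cand)) < singleton_rate
    singles <- data.frame(asv_id = tax$asv_id[target_rows][cand[take, 1]],
                          sample_id = sample_ids[cand[take, 2]],
                          stringsAsFactors = FALSE)
    if (nrow(singles))
      reads[cbind(match(singles$asv_id, tax$asv_id),
                  match(singles$sample_id, all_cols))] <- 1L

    lost <- paste(leak$asv_id, leak$sample_id)
    expected <- planted[!(paste(planted$asv_id, planted$sample_id) %in% lost),
                        , drop = FALSE]

    # direct attrition bookkeeping, counted straight off the assembled
    # matrix: cells any control-subtraction must zero, and the 1-read cells
    # the singleton rule must zero among target-class rows afterwards
    ctl_hit <- reads[, control_ids, drop = FALSE] >= 1L
    smp_pos <- reads[, sample_ids, drop = FALSE] > 0L
    zero_sub <- sum(smp_pos & ctl_hit)
    after_sub <- reads[, sample_ids, drop = FALSE]
    after_sub[ctl_hit] <- 0L
    zero_single <- sum(after_sub[tax$class == "Elasmobranchii", ,
                                 drop = FALSE] == 1L)
    truth <- structure(
      list(planted = planted, leakage_events = leak,
           singleton_events = singles,
           contaminant_species = contam$species,
           genus_only_asvs = tax$asv_id[nrow(tax)],
           expected = expected,
           expected_cells_zeroed = c(subtract_controls = zero_sub,
                                     drop_singletons = zero_single)),
      class = "survey_truth")
    list(table = asv_table(reads, tax[, c("asv_id", "class", "order",
                                          "family", "genus", "species",
                                          "confidence")]),
         meta = meta, truth = truth)
  })
}
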