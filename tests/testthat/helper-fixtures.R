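# shared fixtures, all built in code

# a small 4x5-node field with reproducible non-trivial node velocities
random_field <- function(nt = 3, ny = 4, nx = 5, seed = 42) {
  set.seed(seed)
  flow_field(x = seq(0, 4000, length.out = nx),
             y = seq(0, 3000, length.out = ny),
             times = seq(0, (nt - 1) * 600, by = 600),
             u = array(runif(nt * ny * nx, -1, 1), c(nt, ny, nx)),
             v = array(runif(nt * ny * nx, -1, 1), c(nt, ny, nx)))
}

# coarse enclosed bay for fast trajectory tests
small_bay <- function(duration = 100000) {
  make_bay_field(Lx = 20000, Ly = 14000, resolution = 1000,
                 max_speed = 0.4, duration = duration, time_step = 300)
}

# hand-built asv_table: reads is a named list sample -> named ASV counts
tiny_asv_table <- function(reads, taxonomy) {
  samples <- names(reads)
  asvs <- taxonomy$asv_id
  m <- matrix(0L, length(asvs), length(samples),
              dimnames = list(asvs, samples))
  for (s in samples) if (length(reads[[s]]))
    m[names(reads[[s]]), s] <- as.integer(reads[[s]])
  asv_table(m, taxonomy)
}

tiny_taxonomy <- function(asv_id, class = "Elasmobranchii",
                          order = "Carcharhiniformes",
                          family = "Scyliorhinidae", genus = "Scyliorhinus",
                          species = "Scyliorhinus canicula",
                          confidence = 90) {
  data.frame(asv_id = asv_id, class = class, order = order, family = family,
             genus = genus, species = species, confidence = confidence,
             stringsAsFactors = FALSE)
}

tiny_meta <- function(samples, stations = "ST1", months = "Jan") {
  data.frame(sample_id = c(samples, paste0(samples, "_C")),
             station_id = c(rep_len(stations, length(samples)),
                            rep_len(stations, length(samples))),
             month = c(rep_len(months, length(samples)),
                       rep_len(months, length(samples))),
             type = rep(c("sample", "field_control"), each = length(samples)),
             paired_control_id = c(paste0(samples, "_C"),
                                   rep(NA_character_, length(samples))),
             stringsAsFactors = FALSE)
}

# a trajectory_set built directly from given record positions (for
# geometry oracles); xs, ys are (n_particles x n_records)
manual_traj <- function(xs, ys, station_x = 0, station_y = 0,
                        record_interval = 300) {
  xs <- rbind(xs); ys <- rbind(ys)
  structure(list(station_id = "MAN", sample_time = 0,
                 elapsed = seq(0, by = record_interval,
                               length.out = ncol(xs)),
                 x = xs, y = ys,
                 status = matrix(0L, nrow(xs), ncol(xs)),
                 release = cbind(xs[, 1], ys[, 1]),
                 station_x = station_x, station_y = station_y,
                 spec = NULL),
            class = "trajectory_set")
}
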