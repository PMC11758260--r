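test_that("release positions fill the disc and respect the seed", {
  st <- station("PO", 1000, 2000)
  spec <- release_spec(seed = 7)
  pos <- release_positions(st, spec)
  expect_equal(nrow(pos), 1000L)
  r <- sqrt((pos[, 1] - 1000)^2 + (pos[, 2] - 2000)^2)
  expect_true(all(r <= 200))
  expect_gt(max(r), 150)               # draws reach the rim
  # uniform areal density: about half the draws inside r/sqrt(2)
  expect_equal(mean(r <= 200 / sqrt(2)), 0.5, tolerance = 0.06)

  expect_identical(pos, release_positions(st, spec))
  expect_false(identical(pos, release_positions(st, release_spec(seed = 8))))

  p0 <- release_positions(st, release_spec(radius = 0, seed = 1))
  expect_true(all(p0[, 1] == 1000 & p0[, 2] == 2000))
})

test_that("release spec validates its divisibility contracts", {
  expect_error(release_spec(dt = 70), "divide")
  expect_error(release_spec(record_interval = 299), "divide")
  expect_error(release_spec(n_particles = 0), ">= 1")
  expect_error(release_spec(radius = -1), ">= 0")
})

test_that("particles are stationary in a still field and record on schedule", {
  f <- make_uniform_field(0, 0, duration = 7200, time_step = 600)
  spec <- release_spec(n_particles = 5, duration = 3600,
                       record_interval = 300, dt = 60, seed = 3)
  pos <- release_positions(station("A", 0, 0), spec)
  tr <- advect(f, pos, 0, spec)
  expect_equal(ncol(tr$x), 3600 / 300 + 1)
  expect_equal(tr$elapsed, seq(0, 3600, by = 300))
  for (k in seq_len(ncol(tr$x))) {
    expect_equal(tr$x[, k], pos[, 1])
    expect_equal(tr$y[, k], pos[, 2])
  }
})

test_that("default record schedule spans 3 days of 5-minute intervals", {
  spec <- release_spec()
  expect_equal(spec$duration / spec$record_interval + 1, 865)
})

test_that("uniform flow advection matches the closed form u * T", {
  f <- make_uniform_field(0.1, 0, extent = 20000, duration = 30000)
  spec <- release_spec(n_particles = 10, radius = 50, duration = 21600,
                       record_interval = 300, dt = 60, seed = 5)
  pos <- release_positions(station("A", -5000, 0), spec)
  tr <- advect(f, pos, 0, spec)
  disp <- tr$x[, ncol(tr$x)] - tr$x[, 1]
  expect_equal(disp, rep(0.1 * 21600, 10), tolerance = 1e-9)
  expect_equal(tr$y[, ncol(tr$y)], tr$y[, 1], tolerance = 1e-9)
})

test_that("a pure sinusoidal tide advects to zero net displacement", {
  P <- 44712
  f <- make_tidal_field(U = 0.5, V = 0, period = P, extent = 40000,
                        duration = 2 * P, time_step = 72)
  spec <- release_spec(n_particles = 3, radius = 10, duration = 2 * P,
                       record_interval = 72, dt = 36, seed = 2)
  pos <- release_positions(station("A", 0, 0), spec)
  tr <- advect(f, pos, 0, spec)
  net <- abs(tr$x[, ncol(tr$x)] - tr$x[, 1])
  expect_lt(max(net), 10)
})

test_that("halving dt barely moves endpoints (4th-order convergence)", {
  f <- make_tidal_field(U = 0.5, V = 0.3, residual = c(0.03, 0),
                        extent = 40000, duration = 100000)
  run <- function(dt) {
    spec <- release_spec(n_particles = 5, radius = 100, duration = 86400,
                         record_interval = 300, dt = dt, seed = 4)
    pos <- release_positions(station("A", 0, 0), spec)
    tr <- advect(f, pos, 0, spec)
    cbind(tr$x[, ncol(tr$x)], tr$y[, ncol(tr$y)])
  }
  e60 <- run(60); e30 <- run(30)
  expect_lt(max(sqrt(rowSums((e60 - e30)^2))), 1)
})

test_that("particles freeze on beaching and never reactivate", {
  # uniform eastward flow toward the land ring of a bay: particles beach
  bay <- small_bay(duration = 90000)
  ny <- length(bay$y); nx <- length(bay$x)
  push <- flow_field(x = bay$x, y = bay$y, times = bay$times,
                     u = array(0.3, c(length(bay$times), ny, nx)),
                     v = array(0, c(length(bay$times), ny, nx)),
                     wet = bay$wet)
  spec <- release_spec(n_particles = 30, radius = 100, duration = 72000,
                       record_interval = 600, dt = 60, seed = 9)
  pos <- release_positions(station("A", 17000, 7000), spec)
  tr <- advect(push, pos, 0, spec)
  final <- tr$status[, ncol(tr$status)]
  expect_true(all(final == 1L))
  # monotone: once non-active, never active again, position frozen
  for (p in seq_len(nrow(tr$status))) {
    s <- tr$status[p, ]
    first <- match(1L, s)
    expect_false(any(s[first:length(s)] != 1L))
    expect_true(all(tr$x[p, first:ncol(tr$x)] == tr$x[p, first]))
  }
  # frozen positions remain wet (last valid location)
  expect_true(all(is_wet(push, tr$x[, ncol(tr$x)], tr$y[, ncol(tr$y)])))
})

test_that("particles leaving the open boundary freeze as out_of_domain", {
  f <- make_uniform_field(0.5, 0, extent = 10000, duration = 30000)
  spec <- release_spec(n_particles = 10, radius = 50, duration = 21600,
                       record_interval = 300, dt = 60, seed = 6)
  pos <- release_positions(station("A", 3000, 0), spec)
  tr <- advect(f, pos, 0, spec)
  expect_true(all(tr$status[, ncol(tr$status)] == 2L))
  expect_true(all(tr$x[, ncol(tr$x)] <= 5000))
})

test_that("advection refuses a field shorter than the tracking window", {
  f <- make_uniform_field(0.1, 0, duration = 3600)
  spec <- release_spec(n_particles = 2, duration = 7200,
                       record_interval = 300, dt = 60)
  expect_error(advect(f, cbind(0, 0), 0, spec), "configuration error")
  expect_error(backtrack(f, station("A", 0, 0), 3600, spec),
               "configuration error")
})

test_that("backtracking in uniform flow lands upstream by u0 * tau", {
  u0 <- 0.1
  f <- make_uniform_field(u0, 0, extent = 20000, duration = 40000)
  spec <- release_spec(n_particles = 20, radius = 100, duration = 21600,
                       record_interval = 300, dt = 60, seed = 12)
  st <- station("A", 2000, 0)
  tr <- backtrack(f, st, sample_time = 30000, spec = spec)
  # elapsed-0 record: the arrival constraint
  r0 <- sqrt((tr$x[, 1] - st$x)^2 + (tr$y[, 1] - st$y)^2)
  expect_true(all(r0 <= spec$radius + 1e-9))
  # at elapsed tau the particle was u0 * tau upstream (to release offset)
  for (k in c(10, 40, ncol(tr$x))) {
    tau <- tr$elapsed[k]
    expect_equal(tr$x[, k], tr$x[, 1] - u0 * tau, tolerance = 1e-9)
  }
})

test_that("backtrack then forward advection returns to the release disc", {
  bay <- small_bay(duration = 120000)
  spec <- release_spec(n_particles = 50, radius = 200, duration = 43200,
                       record_interval = 300, dt = 60, seed = 21)
  st <- station("B", 14000, 9000)
  tr <- backtrack(bay, st, sample_time = 100000, spec = spec)
  endp <- cbind(tr$x[, ncol(tr$x)], tr$y[, ncol(tr$y)])
  fw <- advect(bay, endp, t_start = 100000 - spec$duration, spec = spec)
  err <- sqrt((fw$x[, ncol(fw$x)] - tr$x[, 1])^2 +
              (fw$y[, ncol(fw$y)] - tr$y[, 1])^2)
  expect_lt(max(err), 50)
})

test_that("a trajectory set is bit-reproducible under a fixed seed", {
  bay <- small_bay(duration = 40000)
  spec <- release_spec(n_particles = 10, duration = 10800,
                       record_interval = 300, dt = 60, seed = 31)
  st <- station("C", 10000, 7000)
  a <- backtrack(bay, st, 20000, spec)
  b <- backtrack(bay, st, 20000, spec)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$status, b$status)
})

test_that("trajectory sets round-trip through HDF5", {
  bay <- small_bay(duration = 40000)
  spec <- release_spec(n_particles = 8, duration = 7200,
                       record_interval = 600, dt = 60, seed = 2)
  tr <- backtrack(bay, station("D", 9000, 8000), 30000, spec)
  path <- withr::local_tempfile(fileext = ".h5")
  write_trajectories(tr, path)
  tr2 <- read_trajectories(path)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$y, tr$y)
  expect_equal(tr2$status, tr$status)
  expect_equal(tr2$elapsed, tr$elapsed)
  expect_equal(tr2$station_id, tr$station_id)
  expect_equal(tr2$station_x, tr$station_x)
})
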