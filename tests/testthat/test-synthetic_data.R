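test_that("single-dwell spec yields a constant track with all-stopped labels", {
  spec <- trajectory_spec(n_segments = 1, seed = 3)
  sim <- simulate_trajectory(spec)
  expect_true(all(sim$track$positions == 0))
  expect_true(all(sim$labels$labels == 1L))
})

test_that("moves hit their endpoint exactly and dwells are strictly static", {
  d <- c(0.5, -0.2, 0.1)
  spec <- trajectory_spec(n_segments = 3,
                          dwell_duration_range = c(1, 1),
                          move_duration_range = c(2, 2),
                          move_distance_range = cbind(d, d), seed = 5)
  sim <- simulate_trajectory(spec)
  expect_equal(unname(sim$track$positions[nrow(sim$track$positions), ]), d,
               tolerance = 1e-9)
  # labels and trajectory mutually consistent: zero displacement in dwells
  segs <- rle(sim$labels$labels)
  ends <- cumsum(segs$lengths); starts <- ends - segs$lengths + 1L
  for (i in which(segs$values == 1L)) {
    p <- sim$track$positions[starts[i]:ends[i], , drop = FALSE]
    expect_equal(max(abs(sweep(p, 2, p[1, ]))), 0)
  }
})

test_that("finite-difference peak acceleration matches the minimum-jerk closed form", {
  for (seed in 1:3) {
    d <- 0.4; Tm <- 1.5
    spec <- trajectory_spec(n_segments = 2,
                            dwell_duration_range = c(1, 1),
                            move_duration_range = c(Tm, Tm),
                            move_distance_range = cbind(c(d, 0, 0), c(d, 0, 0)),
                            seed = seed)
    sim <- simulate_trajectory(spec)
    a_fd <- max(abs(diff(sim$track$positions[, 1], differences = 2))) * 120 ^ 2
    expect_equal(a_fd, 10 * d / (sqrt(3) * Tm ^ 2), tolerance = 0.02)
  }
})

test_that("all-zero error spec on a static track gives identically zero sensors", {
  sim <- simulate_trajectory(trajectory_spec(n_segments = 1, seed = 1))
  trial <- corrupt_to_imu(sim$track, sim$labels, noise_free_errors())
  expect_true(all(trial$accel == 0))
  expect_true(all(trial$gyro == 0))
})

test_that("noise-free corrupt + double integration recovers per-segment displacement", {
  e <- clean_trial()
  dt <- 1 / e$trial$sample_rate
  segs <- find_moving_segments(e$labels)
  expect_gt(nrow(segs), 0)
  for (i in seq_len(nrow(segs))) {
    idx <- (segs$b[i] + 1L):(segs$e[i] + 1L)
    v <- integrate_series(e$trial$accel[idx, , drop = FALSE], dt)
    p <- integrate_series(v, dt)
    truth <- e$track$positions[idx, , drop = FALSE]
    net_true <- truth[nrow(truth), ] - truth[1, ]
    expect_lt(max(abs(p[nrow(p), ] - net_true)), 0.01 * max(abs(net_true), 0.01))
  }
})

test_that("same seed gives bit-identical trials; different seeds differ", {
  sim <- simulate_trajectory(short_spec(seed = 9))
  err <- imu_error_spec(seed = 21L)
  t1 <- corrupt_to_imu(sim$track, sim$labels, err)
  t2 <- corrupt_to_imu(sim$track, sim$labels, err)
  expect_identical(t1$accel, t2$accel)
  expect_identical(t1$gyro, t2$gyro)
  err2 <- imu_error_spec(seed = 22L)
  expect_false(identical(corrupt_to_imu(sim$track, sim$labels, err2)$accel,
                         t1$accel))
})

test_that("make_dataset counts, determinism and subject-disjoint splits", {
  spec <- trajectory_spec(n_segments = 1)  # minimal trials, counting only
  ds <- make_dataset(13, c("RSHO", "LSHO", "RUPA", "LUPA", "RTOE", "LTOE"),
                     1, spec, noise_free_errors(), master_seed = 2L)
  expect_length(ds, 78L)
  subjects <- vapply(ds, `[[`, character(1), "subject_id")
  expect_length(unique(subjects), 13L)
  ds2 <- make_dataset(13, c("RSHO", "LSHO", "RUPA", "LUPA", "RTOE", "LTOE"),
                      1, spec, noise_free_errors(), master_seed = 2L)
  expect_identical(lapply(ds, function(e) e$trial$accel),
                   lapply(ds2, function(e) e$trial$accel))
  # a subject-wise split never shares subjects across folds
  fold <- group_kfold(subjects, 3L, seed = 1L)
  for (f in 1:3)
    expect_length(intersect(unique(subjects[fold == f]),
                            unique(subjects[fold != f])), 0L)
})

test_that("accelerometer noise degrades naive double integration monotonically", {
  sds <- c(0, 0.05, 0.25)
  mean_ate <- vapply(sds, function(s) {
    mean(vapply(1:10, function(k) {
      sim <- simulate_trajectory(short_spec(seed = 100 + k, n_segments = 3L))
      err <- imu_error_spec(accel_noise_sd = s, gyro_noise_sd = 0,
                            accel_bias_rw_sd = 0, gravity_leak_amplitude = 0,
                            gyro_motion_scale = 0, seed = 200 + k)
      est <- naive_dead_reckoning(corrupt_to_imu(sim$track, sim$labels, err))
      trajectory_errors(sim$track, est$track)$ate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ate) > 0))
})
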