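test_that("integrate_series implements the Euler update exactly", {
  expect_equal(integrate_series(rep(0, 10), 0.1), rep(0, 10))
  v <- integrate_series(rep(1, 120), 1 / 120)
  expect_equal(v[120], 1.0)
  expect_equal(v[1], 1 / 120)
  # double integration of constant a over T approaches a T^2 / 2
  a <- rep(2, 240)
  p <- integrate_series(integrate_series(a, 1 / 120), 1 / 120)
  expect_equal(p[240], 2 * 2 ^ 2 / 2, tolerance = 0.01)
  expect_error(integrate_series(a, 0), "dt")
})

test_that("find_moving_segments enumerates maximal zero runs", {
  expect_equal(nrow(find_moving_segments(label_sequence(rep(1L, 5)))), 0L)
  segs <- find_moving_segments(label_sequence(c(1L, 0L, 0L, 1L, 0L, 1L)))
  expect_equal(segs$b, c(1L, 4L))
  expect_equal(segs$e, c(2L, 4L))
  all_move <- find_moving_segments(label_sequence(rep(0L, 7)))
  expect_equal(unlist(all_move), c(b = 0L, e = 6L))
})

test_that("remove_linear_drift is exact on constructed cases", {
  t <- seq(0, 2, by = 1 / 120)
  # no drift: unchanged
  v <- cbind(sin(t), cos(t), t * 0)
  v[length(t), ] <- v[1, ]
  expect_equal(remove_linear_drift(v, t), v)
  # pure ramp from zero collapses to zero
  ramp <- cbind(3 * t, -2 * t, 0.5 * t)
  expect_lt(max(abs(remove_linear_drift(ramp, t))), 1e-12)
  # truth + linear contamination restored to machine precision
  truth <- cbind(sin(2 * pi * t), cos(2 * pi * t) - 1, t * (2 - t))
  truth[length(t), ] <- truth[1, ]          # equal endpoints
  contaminated <- truth + outer(t - t[1], c(0.7, -1.3, 0.2))
  expect_lt(max(abs(remove_linear_drift(contaminated, t) - truth)), 1e-10)
  # length-1 segment unchanged
  expect_equal(remove_linear_drift(matrix(1:3, 1), 0.5), matrix(1:3, 1))
})

test_that("drift-corrected segments end at their starting velocity", {
  e <- noisy_dataset()[[1]]
  est <- gated_dead_reckoning(e$trial, e$labels, drift_correction = TRUE)
  segs <- find_moving_segments(e$labels)
  for (i in seq_len(nrow(segs)))
    expect_lt(max(abs(est$velocity[segs$e[i] + 1L, ])), 1e-10)
})

test_that("all-stopped labels freeze the position regardless of acceleration", {
  trial <- imu_trial(matrix(rnorm(300), 100, 3), matrix(0, 100, 3))
  est <- gated_dead_reckoning(trial, label_sequence(rep(1L, 100)))
  expect_true(all(est$track$positions == 0))
  expect_true(all(est$velocity == 0))
  expect_error(gated_dead_reckoning(trial, label_sequence(rep(1L, 99))),
               "mismatch")
})

test_that("noise-free round trip: gated tracking error < 1% of path length", {
  e <- clean_trial()
  est <- gated_dead_reckoning(e$trial, e$labels, drift_correction = TRUE)
  ate <- trajectory_errors(e$track, est$track)$ate
  expect_lt(ate, 0.01 * path_length(e$track))
})

test_that("a constant in-segment bias is fully removed by drift correction", {
  # stationary truth with a spurious accelerometer bias inside one segment
  n <- 240
  labels <- label_sequence(c(rep(1L, 60), rep(0L, 120), rep(1L, 60)))
  accel <- matrix(0, n, 3)
  accel[61:180, 1] <- 0.5                    # bias beta on x while "moving"
  trial <- imu_trial(accel, matrix(0, n, 3))
  with_dc <- gated_dead_reckoning(trial, labels, drift_correction = TRUE)
  without <- gated_dead_reckoning(trial, labels, drift_correction = FALSE)
  # truth displacement is zero; bias gives exactly linear velocity drift
  expect_lt(abs(with_dc$track$positions[n, 1]),
            abs(without$track$positions[n, 1]) * 1e-6)
})

test_that("position is continuous across segment boundaries", {
  e <- noisy_dataset()[[2]]
  est <- gated_dead_reckoning(e$trial, e$labels)
  jumps <- sqrt(rowSums(diff(est$track$positions) ^ 2))
  dt <- 1 / e$trial$sample_rate
  vmax <- max(sqrt(rowSums(est$velocity ^ 2)))
  expect_lt(max(jumps), max(vmax * dt * 1.5, 1e-9))
})

test_that("gating with truth labels beats naive integration on noisy data", {
  ds <- noisy_dataset()
  ate <- vapply(ds, function(e) {
    c(naive = trajectory_errors(e$track, naive_dead_reckoning(e$trial)$track)$ate,
      gated = trajectory_errors(e$track,
        gated_dead_reckoning(e$trial, e$labels, FALSE)$track)$ate)
  }, numeric(2))
  expect_lt(mean(ate["gated", ]), mean(ate["naive", ]))
})
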