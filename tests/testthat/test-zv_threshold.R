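make_trial <- function(accel, gyro, rate = 120)
  imu_trial(accel, gyro, sample_rate = rate)

test_that("shoe_statistic matches the hand-computed definition", {
  tr <- make_trial(rbind(c(1, 0, 0), c(0, 1, 0)), rbind(c(0, 0, 0), c(0, 0, 1)))
  p <- shoe_params(N = 2L, gamma = 1, sigma_a2 = 1, sigma_w2 = 1)
  expect_equal(shoe_statistic(tr, 0, p), 1.5)

  zero <- make_trial(matrix(0, 5, 3), matrix(0, 5, 3))
  expect_equal(shoe_statistic(zero, 0, shoe_params(N = 5L)), 0)

  # doubling sigma_a2 with zero gyro halves the statistic
  tr2 <- make_trial(matrix(rnorm(30), 10, 3), matrix(0, 10, 3))
  s1 <- shoe_statistic(tr2, 0, shoe_params(N = 10L, sigma_a2 = 1))
  s2 <- shoe_statistic(tr2, 0, shoe_params(N = 10L, sigma_a2 = 2))
  expect_equal(s2, s1 / 2)

  expect_error(shoe_statistic(tr, 1, p), "out of range")
})

test_that("ared_statistic ignores acceleration", {
  tr <- make_trial(matrix(rnorm(6, sd = 5), 2, 3),
                   rbind(c(0, 0, 1), c(0, 1, 1)))
  expect_equal(ared_statistic(tr, 0, ared_params(N = 2L)), 1.5)
  lab <- ared_detect(make_trial(matrix(100, 40, 3), matrix(0, 40, 3)),
                     ared_params(N = 30L, gamma_w = 1e-4))
  expect_true(all(lab$labels == 1L))
})

test_that("shoe_detect boundary semantics are strict-less-than", {
  # constant signal: statistic is exactly ||a||^2 everywhere
  tr <- make_trial(matrix(c(1, 0, 0), 40, 3, byrow = TRUE), matrix(0, 40, 3))
  at_gamma <- shoe_detect(tr, shoe_params(N = 30L, gamma = 1))
  expect_true(all(at_gamma$labels == 0L))      # statistic == gamma -> moving
  above <- shoe_detect(tr, shoe_params(N = 30L, gamma = 1 + 1e-9))
  expect_true(all(above$labels == 1L))
})

test_that("noise-free detectors agree with the simulator truth inside segments", {
  e <- clean_trial()
  # windows wholly inside one segment are unambiguous; transitions are not
  sp <- shoe_params(N = 30L, gamma = 0.5, sigma_a2 = 1e-6, sigma_w2 = 1e-6)
  lab <- shoe_detect(e$trial, sp)
  win <- sliding_windows(e$trial$n_samples, window_spec(30L))
  # one-sample guard on each side: the central-difference acceleration
  # smears segment boundaries by a single sample
  inside <- vapply(seq_len(nrow(win)), function(i) {
    lo <- max(1L, win$start[i]); hi <- min(e$trial$n_samples, win$end[i] + 1L)
    y <- e$labels$labels[lo:hi]
    all(y == y[1])
  }, logical(1))
  frames <- win$labeled_frame[inside] + 1L
  expect_equal(lab$labels[frames], e$labels$labels[frames])
})

test_that("stopped count is monotone in the threshold", {
  e <- noisy_dataset()[[1]]
  base <- ared_params(N = 30L, gamma_w = 1)
  counts <- vapply(c(1e-4, 1e-2, 0.1, 1, 10), function(g)
    sum(ared_detect(e$trial, ared_params(30L, g))$labels), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("SHOE with huge sigma_a2 reduces to ARED under gamma = gamma_w / sigma_w2", {
  e <- noisy_dataset()[[2]]
  gw <- 0.05
  ared <- ared_detect(e$trial, ared_params(30L, gw))
  shoe <- shoe_detect(e$trial, shoe_params(30L, gamma = gw / 0.3,
                                           sigma_a2 = 1e12, sigma_w2 = 0.3))
  expect_identical(shoe$labels, ared$labels)
})

test_that("detectors are invariant to axis sign flips", {
  e <- noisy_dataset()[[3]]
  flipped <- imu_trial(e$trial$accel %*% diag(c(-1, 1, -1)),
                       e$trial$gyro %*% diag(c(1, -1, -1)),
                       e$trial$sample_rate)
  sp <- shoe_params(30L, 2, 0.01, 0.01)
  expect_identical(shoe_detect(e$trial, sp)$labels,
                   shoe_detect(flipped, sp)$labels)
  ap <- ared_params(30L, 0.05)
  expect_identical(ared_detect(e$trial, ap)$labels,
                   ared_detect(flipped, ap)$labels)
})

test_that("calibrate_threshold lands in the statistic gap on clean data", {
  ds <- clean_dataset()
  trials <- lapply(ds, `[[`, "trial")
  truth <- lapply(ds, `[[`, "labels")

  single <- calibrate_threshold("ared", trials, truth, candidates = 0.123)
  expect_equal(single$gamma_w, 0.123)

  cal <- calibrate_threshold("ared", trials, truth)
  # oracle: exhaustive accuracy curve over the pooled statistics
  expect_gt(attr(cal, "accuracy"), 0.95)
  # gap check: clean data has zero gyro when stopped, positive when moving
  stats <- lapply(trials, zuptr:::detector_statistics,
                  params = ared_params(30L, 1))
  s_all <- unlist(stats)
  expect_gt(cal$gamma_w, 0)
  expect_lte(cal$gamma_w, max(s_all) * (1 + 1e-6))

  # tie rule: two candidates that classify identically -> smaller returned
  tied <- calibrate_threshold("ared", trials, truth,
                              candidates = c(1e-9, 2e-9))
  expect_equal(tied$gamma_w, 1e-9)
})

test_that("calibrated SHOE estimates noise variances from stationary frames", {
  ds <- noisy_dataset()
  cal <- calibrate_threshold("shoe", lapply(ds, `[[`, "trial"),
                             lapply(ds, `[[`, "labels"))
  expect_gt(cal$sigma_a2, 0)
  expect_gt(cal$sigma_w2, 0)
  expect_gt(attr(cal, "accuracy"), 0.8)
})
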