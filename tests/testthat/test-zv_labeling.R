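test_that("constant track labels all-stopped", {
  track <- position_track(matrix(1.5, 200, 3))
  lab <- label_from_position(track, labeling_params())
  expect_true(all(lab$labels == 1L))
})

test_that("uniform motion above the average-velocity threshold flips to moving", {
  # 1.2 cm of straight-line motion inside a 30-sample window at 120 Hz is an
  # average velocity of 0.048 m/s > 0.04 m/s: moving while previously moving
  n <- 240
  v <- 0.048                        # m/s on x
  pos <- cbind((0:(n - 1)) / 120 * v, 0, 0)
  track <- position_track(pos, 120)
  par <- labeling_params(0.01, 3, 30)
  lab <- label_from_position(track, par)
  # hysteresis: initial state stopped, elevated threshold 3 cm; max in-window
  # displacement is 1.2 cm (counting from the window start) so the state
  # never leaves stopped
  expect_true(all(lab$labels == 1L))
  # with T = 1 the same motion is labeled moving everywhere
  lab1 <- label_from_position(track, labeling_params(0.01, 1, 30))
  expect_true(all(lab1$labels == 0L))
})

test_that("hysteresis holds the stopped state below T*thresh and releases above it", {
  # 2 cm displacement inside the window: > thresh but < 3 * thresh
  make_step_track <- function(step) {
    pos <- matrix(0, 120, 3)
    pos[31:120, 1] <- seq(0, step, length.out = 90)
    position_track(pos, 120)
  }
  par <- labeling_params(0.01, 3, 30)
  lab2 <- label_from_position(make_step_track(0.02 * (90 / 29)), par)
  # per-window displacement ~2 cm (29 in-window steps of the ramp)
  expect_true(all(lab2$labels == 1L))
  lab4 <- label_from_position(make_step_track(0.04 * (90 / 29)), par)
  expect_true(any(lab4$labels == 0L))
})

test_that("raising T never converts a stopped label to moving", {
  e <- clean_trial()
  for (T1 in c(1, 2)) {
    a <- label_from_position(e$track, labeling_params(0.01, T1, 30))$labels
    b <- label_from_position(e$track, labeling_params(0.01, T1 + 2, 30))$labels
    expect_true(all(b >= a))       # stopped set only grows with T
  }
})

test_that("T = 1 labeling equals the pure per-window threshold rule", {
  e <- clean_trial()
  par <- labeling_params(0.012, 1, 30)
  lab <- label_from_position(e$track, par)
  win <- sliding_windows(nrow(e$track$positions), window_spec(30L))
  oracle <- vapply(seq_len(nrow(win)), function(i) {
    p <- e$track$positions[(win$start[i] + 1L):win$end[i], , drop = FALSE]
    m <- sqrt(max(rowSums(sweep(p, 2, p[1, ]) ^ 2)))
    as.integer(m <= par$thresh)
  }, integer(1))
  expect_equal(lab$labels[win$labeled_frame + 1L], oracle)
})

test_that("labeling is invariant to rigid translation of the track", {
  e <- clean_trial()
  shifted <- position_track(sweep(e$track$positions, 2, c(3, -7, 0.5), "+"),
                            e$track$sample_rate)
  expect_identical(label_from_position(e$track, labeling_params())$labels,
                   label_from_position(shifted, labeling_params())$labels)
})

test_that("automatic labels recover the simulator truth on clean tracks", {
  for (e in clean_dataset()) {
    rep <- compare_labels(label_from_position(e$track, labeling_params()),
                          e$labels)
    expect_gt(rep$accuracy, 0.9)
  }
})

test_that("compare_labels counts the stopped class as positive", {
  truth <- label_sequence(c(1L, 1L, 0L, 0L))
  pred <- label_sequence(c(1L, 0L, 0L, 0L))
  r <- compare_labels(pred, truth)
  expect_equal(r[c("tp", "fn", "tn", "fp")], list(tp = 1L, fn = 1L, tn = 2L, fp = 0L))
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$precision, 1.0)
  expect_equal(r$recall, 0.5)

  ident <- compare_labels(truth, truth)
  expect_equal(c(ident$accuracy, ident$precision, ident$recall), c(1, 1, 1))

  compl <- compare_labels(label_sequence(1L - truth$labels), truth)
  expect_equal(compl$accuracy, 0)
})

test_that("fit_labeling_params maximises accuracy with deterministic ties", {
  tracks <- lapply(clean_dataset(), `[[`, "track")
  manual <- lapply(clean_dataset(), `[[`, "labels")

  one <- data.frame(thresh = 0.02, T_hyst = 2, N = 30)
  expect_equal(fit_labeling_params(tracks, manual, one)$thresh, 0.02)

  grid <- expand.grid(thresh = c(0.005, 0.01, 0.02, 0.05, 0.1),
                      T_hyst = c(1, 3), N = 30)
  best <- fit_labeling_params(tracks, manual, grid)
  # clean minimum-jerk moves of >= 15 cm: small thresholds separate nearly
  # perfectly, so the winner must lie at the small end of the grid
  expect_lte(best$thresh, 0.02)
  expect_gt(attr(best, "accuracy"), 0.9)

  # exact tie: two rows with identical parameters except thresh
  tie <- data.frame(thresh = c(0.02, 0.01), T_hyst = 1, N = 30)
  accs <- attr(fit_labeling_params(tracks, manual, tie), "grid")$accuracy
  if (accs[1] == accs[2])
    expect_equal(fit_labeling_params(tracks, manual, tie)$thresh, 0.01)
})
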