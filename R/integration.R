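#' Euler (rectangular) integration of a vector series
#'
#' `out_t = out_{t-1} + in_t * dt` with `out_0` seeded from `initial`. Applied
#' once this maps acceleration to velocity; applied twice, to position.
#'
#' @param series numeric matrix (`T x d`) or vector.
#' @param dt sample period in seconds (> 0).
#' @param initial starting value (length `d`), default zeros.
#' @return matrix/vector of the same shape as `series`.
#' @export
integrate_series <- function(series, dt, initial = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  vec <- is.null(dim(series))
  m <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  if (is.null(initial)) initial <- numeric(ncol(m))
  out <- apply(m, 2, cumsum) * dt
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(m))
  out <- sweep(out, 2, initial, "+")
  if (vec) drop(out) else out
}

#' Find maximal runs of moving frames
#'
#' @param labels a [label_sequence()] (1 = stopped, 0 = moving).
#' @return data.frame with 0-based inclusive columns `b` (first moving index)
#'   and `e` (last moving index), one row per maximal moving run, in order.
#' @export
find_moving_segments <- function(labels) {
  y <- labels$labels
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 0L
  data.frame(b = starts[keep] - 1L, e = ends[keep] - 1L)
}

#' Remove linearly accumulated drift from a segment's velocity
#'
#' The accumulated drift over a moving segment is taken to be the difference
#' between the end and start velocity, spread linearly over the segment:
#' `drift_rate = (v_e - v_b) / (t_e - t_b)` per axis, and
#' `v_corrected(t_i) = v(t_i) - drift_rate * (t_i - t_b)`. The corrected
#' velocity equals `v_b` at both segment ends. Length-1 segments are returned
#' unchanged.
#'
#' @param velocity numeric matrix (`n x 3`) or vector of velocities over one
#'   moving segment.
#' @param t numeric vector of sample times (s), same length.
#' @return corrected velocity, same shape.
#' @export
remove_linear_drift <- function(velocity, t) {
  vec <- is.null(dim(velocity))
  v <- if (vec) matrix(velocity, ncol = 1) else as.matrix(velocity)
  n <- nrow(v)
  stopifnot(length(t) == n)
  if (n >= 2L && t[n] > t[1]) {
    rate <- (v[n, ] - v[1, ]) / (t[n] - t[1])
    v <- v - outer(t - t[1], rate)
  }
  if (vec) drop(v) else v
}

#' Zero-velocity-gated dead reckoning
#'
#' Double-integrates the acceleration only inside moving segments: during
#' frames labeled stopped the velocity is forced to zero and the position is
#' frozen at its last value. Each moving segment starts from zero velocity
#' (the zero-velocity update) and continues from the segment's entry
#' position, so the track is continuous. With `drift_correction = TRUE` the
#' per-segment velocity is linear-drift-corrected before the second
#' integration, which also forces the segment's end velocity back to zero.
#'
#' @param trial an [imu_trial()].
#' @param labels a [label_sequence()] covering the trial.
#' @param drift_correction logical, apply [remove_linear_drift()] per segment.
#' @return list with `track` (a [position_track()] starting at the origin)
#'   and `velocity` (`n x 3` matrix).
#' @export
gated_dead_reckoning <- function(trial, labels, drift_correction = TRUE) {
  n <- trial$n_samples
  if (length(labels$labels) != n)
    stop("label/trial length mismatch")
  dt <- 1 / trial$sample_rate
  segs <- find_moving_segments(labels)
  vel <- matrix(0, n, 3)
  pos <- matrix(0, n, 3)
  last_pos <- c(0, 0, 0)
  prev_end <- 0L                                   # 0-based, exclusive
  for (i in seq_len(nrow(segs))) {
    b <- segs$b[i]; e <- segs$e[i]
    if (b > prev_end)                              # stopped span before segment
      pos[(prev_end + 1L):b, ] <- matrix(last_pos, b - prev_end, 3, byrow = TRUE)
    idx <- (b + 1L):(e + 1L)
    v <- integrate_series(trial$accel[idx, , drop = FALSE], dt)   # v_b = 0
    if (drift_correction) v <- drift_correct_from_rest(v, idx, dt)
    p <- integrate_series(v, dt, initial = last_pos)
    vel[idx, ] <- v
    pos[idx, ] <- p
    last_pos <- p[nrow(p), ]
    prev_end <- e + 1L
  }
  if (prev_end < n)
    pos[(prev_end + 1L):n, ] <- matrix(last_pos, n - prev_end, 3, byrow = TRUE)
  list(track = position_track(pos, trial$sample_rate), velocity = vel)
}

# Drift-correct a moving segment's velocity anchored at the zero-velocity
# update: the segment entered from rest, so v_b = 0 one sample before the
# first in-segment sample. A constant accelerometer bias then produces an
# exactly linear velocity ramp which this removes completely (end velocity
# returns to zero).
drift_correct_from_rest <- function(v, idx, dt) {
  t_aug <- c(idx[1] - 2L, idx - 1L) * dt
  v_aug <- rbind(0, v)
  remove_linear_drift(v_aug, t_aug)[-1, , drop = FALSE]
}

#' Naive (ungated) double integration of a whole trial
#'
#' Reference baseline: integrate the acceleration twice from rest at the
#' origin with no zero-velocity information at all.
#'
#' @param trial an [imu_trial()].
#' @return list with `track` and `velocity` as in [gated_dead_reckoning()].
#' @export
naive_dead_reckoning <- function(trial) {
  dt <- 1 / trial$sample_rate
  v <- integrate_series(trial$accel, dt)
  p <- integrate_series(v, dt)
  list(track = position_track(p, trial$sample_rate), velocity = v)
}
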