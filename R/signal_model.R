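#' Construct an IMU trial
#'
#' An `imu_trial` holds one recording of a single body-worn IMU: a six-channel
#' inertial stream (3-axis gravity-removed linear acceleration plus 3-axis
#' angular velocity) sampled at a fixed rate, together with the identity of
#' the subject and body placement it came from.
#'
#' @param accel numeric matrix, `n x 3`, linear acceleration in m/s^2 with the
#'   gravity component already removed upstream.
#' @param gyro numeric matrix, `n x 3`, angular velocity in rad/s.
#' @param sample_rate sampling frequency in Hz (> 0). Default 120.
#' @param subject_id identifier of the subject the trial belongs to.
#' @param placement identifier of the body placement (e.g. `"RSHO"`,
#'   `"LTOE"`); free text is allowed.
#' @return an object of class `imu_trial`.
#' @export
imu_trial <- function(accel, gyro, sample_rate = 120,
                      subject_id = "S1", placement = "RSHO") {
  accel <- as_xyz_matrix(accel, "accel")
  gyro <- as_xyz_matrix(gyro, "gyro")
  trial <- structure(
    list(accel = accel, gyro = gyro,
         sample_rate = as.numeric(sample_rate),
         subject_id = as.character(subject_id),
         placement = as.character(placement),
         n_samples = nrow(accel)),
    class = "imu_trial")
  v <- validate_trial(trial)
  if (length(v)) stop("invalid imu_trial: ", paste(v, collapse = "; "))
  trial
}

#' Construct a 3D position track
#'
#' @param positions numeric matrix, `n x 3`, positions in metres.
#' @param sample_rate sampling frequency in Hz.
#' @param origin_anchored logical; if `TRUE` the track is expressed in the
#'   trial-start frame and must begin at `[0,0,0]`.
#' @return an object of class `position_track`.
#' @export
position_track <- function(positions, sample_rate = 120, origin_anchored = FALSE) {
  positions <- as_xyz_matrix(positions, "positions")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (origin_anchored && any(abs(positions[1, ]) > 1e-12))
    stop("origin-anchored track must start at [0,0,0]")
  structure(list(positions = positions,
                 sample_rate = as.numeric(sample_rate),
                 origin_anchored = isTRUE(origin_anchored)),
            class = "position_track")
}

#' Construct a binary zero-velocity label sequence
#'
#' Labels use the convention 1 = stopped (the positive class), 0 = moving.
#' Window-based producers cannot label the first and last few frames; the
#' `valid_range` records the span actually labeled, and frames outside it are
#' filled with the nearest labeled value so that a full-length sequence is
#' always available to the integrator.
#'
#' @param labels integer/numeric vector of 0/1 values, full trial length.
#' @param valid_range integer length-2, first and last labeled index.
#' @return an object of class `label_sequence`.
#' @export
label_sequence <- function(labels, valid_range = c(1L, length(labels))) {
  labels <- as.integer(labels)
  if (!length(labels)) stop("labels must be non-empty")
  vr <- as.integer(valid_range)
  if (length(vr) != 2L || vr[1] < 1L || vr[2] > length(labels) || vr[1] > vr[2])
    stop("invalid valid_range")
  core <- labels[vr[1]:vr[2]]
  if (anyNA(core) || !all(core %in% c(0L, 1L)))
    stop("labels must be 0/1 inside valid_range")
  # nearest-label fill outside the valid range
  if (vr[1] > 1L) labels[seq_len(vr[1] - 1L)] <- labels[vr[1]]
  n <- length(labels)
  if (vr[2] < n) labels[(vr[2] + 1L):n] <- labels[vr[2]]
  structure(list(labels = labels, valid_range = vr), class = "label_sequence")
}

#' Sliding-window specification
#'
#' @param N window length in samples (>= 2).
#' @param stride samples between consecutive window starts (>= 1).
#' @param label_index 0-based index within the window whose frame receives the
#'   window's label; default `floor(N/2)`, i.e. the window centre.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(N = 30L, stride = 1L, label_index = floor(N / 2)) {
  N <- as.integer(N); stride <- as.integer(stride); label_index <- as.integer(label_index)
  if (N < 2L) stop("N must be >= 2")
  if (stride < 1L) stop("stride must be >= 1")
  if (label_index < 0L || label_index >= N) stop("label_index must be in [0, N)")
  structure(list(N = N, stride = stride, label_index = label_index),
            class = "window_spec")
}

#' Validate a trial (and optionally a paired track)
#'
#' Checks every `imu_trial` invariant and, when a position track is supplied,
#' that its length matches the trial's. Violations are returned as character
#' messages rather than raised, so callers can collect them.
#'
#' @param trial an `imu_trial` (or a list with the same fields).
#' @param track optional `position_track` paired with the trial.
#' @return character vector of violations; empty when everything holds.
#' @export
validate_trial <- function(trial, track = NULL) {
  v <- character()
  if (!is.matrix(trial$accel) || ncol(trial$accel) != 3L)
    v <- c(v, "accel must be an n x 3 matrix")
  if (!is.matrix(trial$gyro) || ncol(trial$gyro) != 3L)
    v <- c(v, "gyro must be an n x 3 matrix")
  if (is.matrix(trial$accel) && is.matrix(trial$gyro) &&
      nrow(trial$accel) != nrow(trial$gyro))
    v <- c(v, sprintf("accel/gyro length mismatch (%d vs %d)",
                      nrow(trial$accel), nrow(trial$gyro)))
  if (is.matrix(trial$accel) && nrow(trial$accel) < 1L)
    v <- c(v, "trial must contain at least one sample")
  if (!is.numeric(trial$sample_rate) || length(trial$sample_rate) != 1L ||
      !is.finite(trial$sample_rate) || trial$sample_rate <= 0)
    v <- c(v, "sample_rate must be a positive scalar")
  if (is.matrix(trial$accel) && !all(is.finite(trial$accel)))
    v <- c(v, "accel contains non-finite values")
  if (is.matrix(trial$gyro) && !all(is.finite(trial$gyro)))
    v <- c(v, "gyro contains non-finite values")
  if (!is.null(track)) {
    if (nrow(track$positions) != nrow(trial$accel))
      v <- c(v, sprintf("track length %d does not match trial length %d",
                        nrow(track$positions), nrow(trial$accel)))
  }
  v
}

#' Enumerate sliding windows over a sequence
#'
#' Windows are half-open `[start, end)` in 0-based index convention and are
#' returned together with the 0-based frame that receives the window's label.
#'
#' @param length total number of samples available.
#' @param spec a [window_spec()].
#' @return data.frame with integer columns `start`, `end` (exclusive) and
#'   `labeled_frame`, one row per window, in order.
#' @export
sliding_windows <- function(length, spec) {
  length <- as.integer(length)
  if (length < spec$N)
    stop(sprintf("input too short: length %d < window size %d", length, spec$N))
  n_win <- (length - spec$N) %/% spec$stride + 1L
  start <- (seq_len(n_win) - 1L) * spec$stride
  data.frame(start = start,
             end = start + spec$N,
             labeled_frame = start + spec$label_index)
}

# ---- internal helpers -------------------------------------------------------

as_xyz_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop(what, " must have 3 columns")
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- unname(as.matrix(x))
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must have 3 columns")
  x
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> subject=%s placement=%s  %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$placement, x$n_samples, x$sample_rate,
              x$n_samples / x$sample_rate))
  invisible(x)
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d frames, %.1f%% stopped, valid [%d, %d]\n",
              length(x$labels), 100 * mean(x$labels),
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

# ---- trial CSV I/O ----------------------------------------------------------

#' Write a trial (and optional ground-truth track) to CSV
#'
#' One row per sample with header `t,ax,ay,az,gx,gy,gz[,px,py,pz]`; units are
#' seconds, m/s^2, rad/s and metres.
#'
#' @param trial an `imu_trial`.
#' @param path output file path.
#' @param track optional `position_track` to append as `px,py,pz` columns.
#' @export
write_trial_csv <- function(trial, path, track = NULL) {
  n <- trial$n_samples
  df <- data.frame(t = (seq_len(n) - 1) / trial$sample_rate,
                   ax = trial$accel[, 1], ay = trial$accel[, 2], az = trial$accel[, 3],
                   gx = trial$gyro[, 1], gy = trial$gyro[, 2], gz = trial$gyro[, 3])
  if (!is.null(track)) {
    stopifnot(nrow(track$positions) == n)
    df$px <- track$positions[, 1]; df$py <- track$positions[, 2]
    df$pz <- track$positions[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial CSV written by [write_trial_csv()]
#'
#' @param path CSV path with header `t,ax,ay,az,gx,gy,gz[,px,py,pz]`.
#' @param subject_id,placement identity to attach (not stored in the CSV).
#' @return list with elements `trial` (an `imu_trial`) and `track` (a
#'   `position_track` or `NULL` when no position columns are present).
#' @export
read_trial_csv <- function(path, subject_id = "S1", placement = "RSHO") {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df)))
    stop("trial CSV must contain columns ", paste(need, collapse = ","))
  dts <- diff(df$t)
  if (length(dts) && (max(dts) - min(dts)) > 1e-6 * max(abs(dts)))
    stop("trial CSV has a non-constant sample period")
  rate <- if (length(dts)) 1 / mean(dts) else 120
  trial <- imu_trial(as.matrix(df[, c("ax", "ay", "az")]),
                     as.matrix(df[, c("gx", "gy", "gz")]),
                     sample_rate = rate, subject_id = subject_id,
                     placement = placement)
  track <- NULL
  if (all(c("px", "py", "pz") %in% names(df)))
    track <- position_track(as.matrix(df[, c("px", "py", "pz")]), sample_rate = rate)
  list(trial = trial, track = track)
}

#' Write a label sequence to CSV (`t,label`)
#' @param labels a `label_sequence`.
#' @param path output path.
#' @param sample_rate Hz, used to reconstruct the time column.
#' @export
write_labels_csv <- function(labels, path, sample_rate = 120) {
  df <- data.frame(t = (seq_along(labels$labels) - 1) / sample_rate,
                   label = labels$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a label CSV written by [write_labels_csv()]
#' @param path CSV with columns `t,label`.
#' @return a `label_sequence`.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  label_sequence(df$label)
}
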