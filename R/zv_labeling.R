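#' Parameters of the windowed-displacement labeling rule
#'
#' Default values are the calibrated operating point for 120 Hz motion-capture
#' data: a 1 cm displacement threshold over a 30-sample (0.25 s) window --
#' equivalently an average-velocity threshold of 0.04 m/s -- with a hysteresis
#' multiplier of 3, so that a segment previously at rest needs 3 cm of
#' movement inside the window before it is declared moving.
#'
#' @param thresh displacement threshold in metres (> 0). Default 0.01.
#' @param T_hyst hysteresis multiplier (>= 1). Default 3.
#' @param N window size in samples (>= 2). Default 30.
#' @return an object of class `labeling_params`.
#' @export
labeling_params <- function(thresh = 0.01, T_hyst = 3, N = 30L) {
  if (thresh <= 0) stop("thresh must be > 0")
  if (T_hyst < 1) stop("T_hyst must be >= 1")
  if (N < 2) stop("N must be >= 2")
  structure(list(thresh = thresh, T_hyst = T_hyst, N = as.integer(N)),
            class = "labeling_params")
}

#' Label stopped/moving states from a ground-truth position track
#'
#' Slides a window over the track and computes a movement measure for each
#' window; the label (1 = stopped) is placed at the window's centre frame.
#' The movement measure is, by default, the maximum Euclidean deviation from
#' the window's first sample. A window is declared moving when the measure
#' exceeds the threshold; while the previous state is stopped the threshold
#' is elevated to `T_hyst * thresh` (hysteresis), suppressing label chatter.
#' Movement exactly at the threshold keeps the current stopped state (strict
#' inequality). The initial state is stopped, since trials begin at rest at
#' the origin. Frames before the first and after the last window centre
#' inherit the nearest labeled value.
#'
#' @param track a [position_track()].
#' @param params a [labeling_params()].
#' @param window optional [window_spec()]; defaults to `window_spec(params$N)`.
#' @param measure `"max_deviation"` (default) or `"path_length"` (sum of
#'   consecutive displacements inside the window).
#' @return a [label_sequence()] covering the whole track.
#' @export
label_from_position <- function(track, params = labeling_params(),
                                window = NULL,
                                measure = c("max_deviation", "path_length")) {
  measure <- match.arg(measure)
  if (is.null(window)) window <- window_spec(params$N)
  p <- track$positions
  n <- nrow(p)
  if (n < window$N)
    stop(sprintf("input too short: track length %d < window size %d", n, window$N))
  win <- sliding_windows(n, window)
  m <- window_movement(p, win, measure)
  labels <- rep(NA_integer_, n)
  state <- 1L                                  # trials begin at rest
  for (i in seq_len(nrow(win))) {
    eff <- if (state == 1L) params$T_hyst * params$thresh else params$thresh
    state <- if (m[i] > eff) 0L else 1L
    labels[win$labeled_frame[i] + 1L] <- state
  }
  vr <- range(win$labeled_frame) + 1L
  labels[seq_len(vr[1] - 1L)] <- labels[vr[1]]
  if (vr[2] < n) labels[(vr[2] + 1L):n] <- labels[vr[2]]
  label_sequence(labels, valid_range = vr)
}

# movement measure per window, vectorised over windows
window_movement <- function(p, win, measure) {
  vapply(seq_len(nrow(win)), function(i) {
    idx <- (win$start[i] + 1L):win$end[i]
    q <- p[idx, , drop = FALSE]
    if (measure == "max_deviation") {
      d <- sweep(q, 2, q[1, ])
      sqrt(max(rowSums(d ^ 2)))
    } else {
      sum(sqrt(rowSums(diff(q) ^ 2)))
    }
  }, numeric(1))
}

#' Compare a predicted label sequence against the truth
#'
#' Counts are computed over the intersection of the two valid ranges with
#' positive = stopped (label 1).
#'
#' @param pred,truth [label_sequence()] objects.
#' @return an object of class `classification_report`: list with `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `precision`, `recall` (the last two `NaN` when
#'   undefined).
#' @export
compare_labels <- function(pred, truth) {
  lo <- max(pred$valid_range[1], truth$valid_range[1])
  hi <- min(pred$valid_range[2], truth$valid_range[2])
  if (lo > hi) stop("label sequences have no overlapping valid range")
  yp <- pred$labels[lo:hi]
  yt <- truth$labels[lo:hi]
  tp <- sum(yp == 1L & yt == 1L); fp <- sum(yp == 1L & yt == 0L)
  tn <- sum(yp == 0L & yt == 0L); fn <- sum(yp == 0L & yt == 1L)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
    recall = if (tp + fn > 0) tp / (tp + fn) else NaN),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> acc %.4f  prec %.4f  rec %.4f  (TP %d FP %d TN %d FN %d)\n",
              x$accuracy, x$precision, x$recall, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Calibrate labeling parameters against manually labeled tracks
#'
#' Exhaustively evaluates a candidate grid and returns the parameter set that
#' maximises the mean labeling accuracy over the supplied tracks. Ties are
#' broken towards the smallest threshold, then the smallest hysteresis
#' multiplier.
#'
#' @param tracks list of [position_track()] objects.
#' @param manual_labels list of matching [label_sequence()] objects.
#' @param grid data.frame with columns `thresh`, `T_hyst`, `N` (one candidate
#'   per row).
#' @return the winning [labeling_params()], with the achieved mean accuracy in
#'   attribute `"accuracy"` and the evaluated grid in attribute `"grid"`.
#' @export
fit_labeling_params <- function(tracks, manual_labels, grid) {
  stopifnot(length(tracks) >= 1, length(tracks) == length(manual_labels),
            nrow(grid) >= 1)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    par <- labeling_params(grid$thresh[g], grid$T_hyst[g], grid$N[g])
    mean(vapply(seq_along(tracks), function(i) {
      pred <- label_from_position(tracks[[i]], par)
      compare_labels(pred, manual_labels[[i]])$accuracy
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-acc, grid$thresh, grid$T_hyst)
  best <- ord[1]
  out <- labeling_params(grid$thresh[best], grid$T_hyst[best], grid$N[best])
  attr(out, "accuracy") <- acc[best]
  attr(out, "grid") <- cbind(grid, accuracy = acc)
  out
}
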