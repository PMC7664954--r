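#' SHOE detector parameters
#'
#' Stance Hypothesis Optimal Estimation: a window statistic combining the
#' variance-normalised energy of the gravity-removed acceleration and of the
#' angular rate.
#'
#' @param N window size in samples (>= 1).
#' @param gamma detection threshold (dimensionless, > 0).
#' @param sigma_a2 accelerometer noise variance, (m/s^2)^2 (> 0).
#' @param sigma_w2 gyroscope noise variance, (rad/s)^2 (> 0).
#' @return an object of class `shoe_params`.
#' @export
shoe_params <- function(N = 30L, gamma = 1, sigma_a2 = 1, sigma_w2 = 1) {
  stopifnot(N >= 1, gamma > 0, sigma_a2 > 0, sigma_w2 > 0)
  structure(list(N = as.integer(N), gamma = gamma,
                 sigma_a2 = sigma_a2, sigma_w2 = sigma_w2),
            class = "shoe_params")
}

#' ARED detector parameters
#'
#' Angular Rate Energy Detector: windowed mean squared norm of the angular
#' velocity compared against a threshold.
#'
#' @param N window size in samples (>= 1).
#' @param gamma_w threshold in (rad/s)^2 (> 0).
#' @return an object of class `ared_params`.
#' @export
ared_params <- function(N = 30L, gamma_w = 0.01) {
  stopifnot(N >= 1, gamma_w > 0)
  structure(list(N = as.integer(N), gamma_w = gamma_w), class = "ared_params")
}

#' SHOE window statistic
#'
#' `(1/N) * sum_{n=k}^{k+N-1} (||a_n||^2 / sigma_a^2 + ||w_n||^2 / sigma_w^2)`
#' for the window starting at 0-based index `k`.
#'
#' @param trial an [imu_trial()].
#' @param k 0-based window start index.
#' @param params a [shoe_params()].
#' @return non-negative scalar.
#' @export
shoe_statistic <- function(trial, k, params) {
  if (k < 0 || k + params$N > trial$n_samples) stop("window out of range")
  idx <- (k + 1L):(k + params$N)
  mean(rowSums(trial$accel[idx, , drop = FALSE] ^ 2) / params$sigma_a2 +
         rowSums(trial$gyro[idx, , drop = FALSE] ^ 2) / params$sigma_w2)
}

#' ARED window statistic
#'
#' `(1/N) * sum ||w_n||^2` over the window starting at 0-based index `k`.
#'
#' @inheritParams shoe_statistic
#' @param params an [ared_params()].
#' @return non-negative scalar.
#' @export
ared_statistic <- function(trial, k, params) {
  if (k < 0 || k + params$N > trial$n_samples) stop("window out of range")
  idx <- (k + 1L):(k + params$N)
  mean(rowSums(trial$gyro[idx, , drop = FALSE] ^ 2))
}

# windowed mean of a per-sample series, one value per window start (stride 1)
windowed_mean <- function(x, N) {
  cs <- cumsum(c(0, x))
  (cs[(N + 1):length(cs)] - cs[1:(length(cs) - N)]) / N
}

# all stride-1 window statistics for a trial
detector_statistics <- function(trial, params) {
  if (inherits(params, "shoe_params")) {
    s <- rowSums(trial$accel ^ 2) / params$sigma_a2 +
      rowSums(trial$gyro ^ 2) / params$sigma_w2
  } else {
    s <- rowSums(trial$gyro ^ 2)
  }
  windowed_mean(s, params$N)
}

# turn per-window statistics into a full-length label sequence
threshold_to_labels <- function(stat, gamma, N, n_samples) {
  centre <- floor(N / 2)
  frames <- seq_along(stat) - 1L + centre          # 0-based labeled frames
  labels <- rep(NA_integer_, n_samples)
  labels[frames + 1L] <- as.integer(stat < gamma)  # strict <: stopped
  vr <- range(frames) + 1L
  labels[seq_len(vr[1] - 1L)] <- labels[vr[1]]
  if (vr[2] < n_samples) labels[(vr[2] + 1L):n_samples] <- labels[vr[2]]
  label_sequence(labels, valid_range = vr)
}

#' SHOE zero-velocity detection
#'
#' Labels frame `k + floor(N/2)` as stopped (1) when the SHOE statistic of the
#' window starting at `k` is strictly below `gamma`; boundary frames inherit
#' the nearest label.
#'
#' @param trial an [imu_trial()].
#' @param params a [shoe_params()].
#' @return a [label_sequence()].
#' @export
shoe_detect <- function(trial, params) {
  if (trial$n_samples < params$N) stop("trial shorter than detector window")
  stat <- detector_statistics(trial, params)
  threshold_to_labels(stat, params$gamma, params$N, trial$n_samples)
}

#' ARED zero-velocity detection
#'
#' @param trial an [imu_trial()].
#' @param params an [ared_params()].
#' @return a [label_sequence()].
#' @export
ared_detect <- function(trial, params) {
  if (trial$n_samples < params$N) stop("trial shorter than detector window")
  stat <- detector_statistics(trial, params)
  threshold_to_labels(stat, params$gamma_w, params$N, trial$n_samples)
}

#' Estimate sensor noise variances from stationary frames
#'
#' Pooled per-axis variance of the accelerometer and gyroscope samples taken
#' while the truth labels say "stopped"; used to normalise the SHOE statistic
#' when the variances are not supplied externally.
#'
#' @param trials list of [imu_trial()] objects.
#' @param labels list of matching truth [label_sequence()] objects.
#' @return list with `sigma_a2` and `sigma_w2`.
#' @export
estimate_noise_variances <- function(trials, labels) {
  acc <- do.call(rbind, lapply(seq_along(trials), function(i)
    trials[[i]]$accel[labels[[i]]$labels == 1L, , drop = FALSE]))
  gyr <- do.call(rbind, lapply(seq_along(trials), function(i)
    trials[[i]]$gyro[labels[[i]]$labels == 1L, , drop = FALSE]))
  pooled_var <- function(m) {
    v <- mean(apply(m, 2, stats::var))
    max(v, 1e-12)                              # guard: noise-free synthetic data
  }
  list(sigma_a2 = pooled_var(acc), sigma_w2 = pooled_var(gyr))
}

#' Calibrate a detector threshold on labeled training trials
#'
#' Evaluates candidate thresholds and returns the parameter set whose labels
#' maximise accuracy pooled over all training frames; ties go to the smallest
#' threshold. The default candidate grid is logarithmically spaced between
#' the smallest and largest windowed statistic observed in the training data.
#'
#' @param kind `"shoe"` or `"ared"`.
#' @param trials list of [imu_trial()] objects.
#' @param truth list of matching [label_sequence()] objects.
#' @param candidates optional numeric vector of thresholds; computed from the
#'   data when `NULL`.
#' @param N detector window size in samples.
#' @param sigma_a2,sigma_w2 SHOE normalisation variances; estimated from
#'   stationary training frames via [estimate_noise_variances()] when `NULL`.
#' @param n_candidates size of the automatic grid; 400 points resolve the
#'   many-decade dynamic range of the variance-normalised statistic to ~15%
#'   threshold granularity.
#' @return calibrated [shoe_params()] or [ared_params()], with the achieved
#'   pooled accuracy in attribute `"accuracy"`.
#' @export
calibrate_threshold <- function(kind = c("shoe", "ared"), trials, truth,
                                candidates = NULL, N = 30L,
                                sigma_a2 = NULL, sigma_w2 = NULL,
                                n_candidates = 400L) {
  kind <- match.arg(kind)
  stopifnot(length(trials) >= 1, length(trials) == length(truth))
  if (kind == "shoe" && (is.null(sigma_a2) || is.null(sigma_w2))) {
    est <- estimate_noise_variances(trials, truth)
    if (is.null(sigma_a2)) sigma_a2 <- est$sigma_a2
    if (is.null(sigma_w2)) sigma_w2 <- est$sigma_w2
  }
  proto <- if (kind == "shoe") shoe_params(N, 1, sigma_a2, sigma_w2)
           else ared_params(N, 1)
  if (any(vapply(trials, `[[`, integer(1), "n_samples") < N))
    stop("trial shorter than detector window")
  stats_list <- lapply(trials, detector_statistics, params = proto)
  if (is.null(candidates)) {
    rng <- range(unlist(stats_list))
    lo <- max(rng[1], 1e-12); hi <- max(rng[2], lo * 10)
    candidates <- exp(seq(log(lo), log(hi), length.out = n_candidates))
  }
  if (!length(candidates)) stop("empty candidate set")
  acc <- vapply(candidates, function(g) {
    hits <- 0L; total <- 0L
    for (i in seq_along(trials)) {
      lab <- threshold_to_labels(stats_list[[i]], g, N, trials[[i]]$n_samples)
      vr <- lab$valid_range
      hits <- hits + sum(lab$labels[vr[1]:vr[2]] ==
                           truth[[i]]$labels[vr[1]:vr[2]])
      total <- total + (vr[2] - vr[1] + 1L)
    }
    hits / total
  }, numeric(1))
  best <- order(-acc, candidates)[1]
  out <- if (kind == "shoe") shoe_params(N, candidates[best], sigma_a2, sigma_w2)
         else ared_params(N, candidates[best])
  attr(out, "accuracy") <- acc[best]
  out
}
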