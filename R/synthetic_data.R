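#' Trajectory specification for the synthetic human-motion simulator
#'
#' A trial is an alternating sequence of stationary dwells and bounded
#' movements, starting (and therefore dwelling) at the origin. During a move
#' each axis follows a minimum-jerk displacement profile, the standard model
#' of human point-to-point sub-movements: zero velocity and zero acceleration
#' at both endpoints, which is exactly the structure zero-velocity updates
#' rely on.
#'
#' @param sample_rate Hz; default 120, the rate of the motion-capture setup
#'   the simulator emulates.
#' @param n_segments total number of alternating segments (>= 1); odd indices
#'   are dwells, even indices moves, so a trial always begins at rest.
#' @param dwell_duration_range length-2 numeric, seconds, uniform range for
#'   dwell durations.
#' @param move_duration_range length-2 numeric, seconds, uniform range for
#'   movement durations.
#' @param move_distance_range per-axis displacement range in metres: either a
#'   length-2 vector applied to every axis or a 3 x 2 matrix with one row per
#'   axis. A non-negative, non-degenerate range is a magnitude range and the
#'   direction is drawn at random; a degenerate (`lo == hi`) or signed range
#'   is used literally.
#' @param motion_profile only `"minimum_jerk"` is implemented.
#' @param seed integer seed making the trajectory reproducible.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(sample_rate = 120, n_segments = 9,
                            dwell_duration_range = c(1, 3),
                            move_duration_range = c(1, 3),
                            move_distance_range = c(0.2, 0.6),
                            motion_profile = "minimum_jerk",
                            seed = 1L) {
  if (n_segments < 1) stop("invalid spec: n_segments must be >= 1")
  stopifnot(all(dwell_duration_range > 0), all(move_duration_range > 0))
  if (is.null(dim(move_distance_range)))
    move_distance_range <- matrix(move_distance_range, nrow = 3, ncol = 2, byrow = TRUE)
  motion_profile <- match.arg(motion_profile, "minimum_jerk")
  structure(list(sample_rate = sample_rate, n_segments = as.integer(n_segments),
                 dwell_duration_range = dwell_duration_range,
                 move_duration_range = move_duration_range,
                 move_distance_range = move_distance_range,
                 motion_profile = motion_profile, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' IMU error specification
#'
#' Models the dominant error sources of a body-worn MEMS IMU whose linear
#' acceleration has been gravity-compensated upstream: white measurement
#' noise, a slowly wandering accelerometer bias (random walk), and a
#' low-frequency sinusoidal "gravity leak" standing in for residual gravity
#' caused by imperfect orientation estimation. The gyroscope signal is not
#' derivable from a position-only trajectory, so it is simulated as an
#' Ornstein-Uhlenbeck process whose stationary magnitude switches between a
#' movement scale and a (much smaller) rest scale -- the statistical contrast
#' the SHOE and ARED detectors exploit.
#'
#' @param accel_noise_sd white accelerometer noise, m/s^2.
#' @param gyro_noise_sd gyroscope magnitude while stationary, rad/s.
#' @param accel_bias_rw_sd accelerometer bias random-walk intensity,
#'   m/s^2 per sqrt(s).
#' @param gravity_leak_amplitude amplitude of the sinusoidal leak, m/s^2.
#' @param gravity_leak_period leak period, s (slow compared with movements).
#' @param gyro_motion_scale gyroscope magnitude while moving, rad/s.
#' @param seed integer seed.
#' @return an object of class `imu_error_spec`.
#' @export
imu_error_spec <- function(accel_noise_sd = 0.05, gyro_noise_sd = 0.02,
                           accel_bias_rw_sd = 0.005,
                           gravity_leak_amplitude = 0.05,
                           gravity_leak_period = 60,
                           gyro_motion_scale = 1.0, seed = 1L) {
  vals <- c(accel_noise_sd, gyro_noise_sd, accel_bias_rw_sd,
            gravity_leak_amplitude, gravity_leak_period, gyro_motion_scale)
  if (any(vals < 0)) stop("error-spec parameters must be non-negative")
  structure(list(accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 accel_bias_rw_sd = accel_bias_rw_sd,
                 gravity_leak_amplitude = gravity_leak_amplitude,
                 gravity_leak_period = gravity_leak_period,
                 gyro_motion_scale = gyro_motion_scale, seed = as.integer(seed)),
            class = "imu_error_spec")
}

#' Minimum-jerk displacement profile
#'
#' Normalised profile s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5 on tau in [0,1]:
#' s(0)=0, s(1)=1, with zero velocity and acceleration at both endpoints. Its
#' peak acceleration for a move of distance d over duration T is
#' 10 d / (sqrt(3) T^2).
#'
#' @param tau numeric vector in [0, 1].
#' @return numeric vector of normalised displacements.
#' @export
min_jerk_profile <- function(tau) {
  tau ^ 3 * (10 - 15 * tau + 6 * tau ^ 2)
}

#' Simulate a ground-truth trajectory with exact zero-velocity labels
#'
#' @param spec a [trajectory_spec()].
#' @return list with elements `track` (an origin-anchored [position_track()])
#'   and `labels` (a [label_sequence()], 1 during dwells).
#' @export
simulate_trajectory <- function(spec) {
  if (!inherits(spec, "trajectory_spec")) stop("invalid spec")
  rng <- local_rng(spec$seed)
  rate <- spec$sample_rate
  segs <- vector("list", spec$n_segments)
  pos <- c(0, 0, 0)
  for (k in seq_len(spec$n_segments)) {
    if (k %% 2L == 1L) {                      # dwell
      dur <- runif(1, spec$dwell_duration_range[1], spec$dwell_duration_range[2])
      n <- max(1L, round(dur * rate))
      segs[[k]] <- list(kind = "dwell",
                        pos = matrix(pos, n, 3, byrow = TRUE))
    } else {                                  # move
      dur <- runif(1, spec$move_duration_range[1], spec$move_duration_range[2])
      n <- max(2L, round(dur * rate))
      d <- numeric(3)
      for (ax in 1:3) {
        lo <- spec$move_distance_range[ax, 1]; hi <- spec$move_distance_range[ax, 2]
        mag <- runif(1, lo, hi)
        # non-negative, non-degenerate ranges are magnitude ranges: pick a
        # random direction; a degenerate or signed range is used literally
        if (lo >= 0 && hi > lo) mag <- mag * sample(c(-1, 1), 1)
        d[ax] <- mag
      }
      tau <- seq_len(n) / n                  # endpoint reached exactly at tau=1
      prof <- min_jerk_profile(tau)
      segs[[k]] <- list(kind = "move",
                        pos = matrix(pos, n, 3, byrow = TRUE) + outer(prof, d))
      pos <- pos + d
    }
  }
  positions <- do.call(rbind, lapply(segs, `[[`, "pos"))
  labels <- unlist(lapply(segs, function(s)
    rep(if (s$kind == "dwell") 1L else 0L, nrow(s$pos))))
  list(track = position_track(positions, rate, origin_anchored = TRUE),
       labels = label_sequence(labels))
}

#' Corrupt a ground-truth trajectory into a synthetic IMU stream
#'
#' The clean acceleration is the second central finite difference of position
#' times the squared sample rate (endpoints, which sit inside dwells, are
#' zero). Error terms from `err` are then added; with an all-zero error spec
#' the output is the exact discretised acceleration, so the
#' integrate-back-to-position round trip has discretisation error only.
#'
#' @param track a [position_track()].
#' @param labels the matching ground-truth [label_sequence()].
#' @param err an [imu_error_spec()].
#' @param subject_id,placement identity recorded on the output trial.
#' @return an [imu_trial()], deterministic for a fixed `err$seed`.
#' @export
corrupt_to_imu <- function(track, labels, err, subject_id = "S1", placement = "RSHO") {
  p <- track$positions
  n <- nrow(p)
  if (n < 3L) stop("track must contain at least 3 samples")
  rate <- track$sample_rate
  dt <- 1 / rate
  rng <- local_rng(err$seed)

  accel <- matrix(0, n, 3)
  accel[2:(n - 1), ] <- (p[3:n, ] - 2 * p[2:(n - 1), ] + p[1:(n - 2), ]) * rate ^ 2

  tvec <- (seq_len(n) - 1) * dt
  moving <- labels$labels == 0L
  gyro <- matrix(0, n, 3)
  for (ax in 1:3) {
    accel[, ax] <- accel[, ax] +
      rnorm(n, 0, err$accel_noise_sd) +
      cumsum(rnorm(n, 0, err$accel_bias_rw_sd * sqrt(dt)))
    if (err$gravity_leak_amplitude > 0)
      accel[, ax] <- accel[, ax] + err$gravity_leak_amplitude *
        sin(2 * pi * tvec / err$gravity_leak_period + runif(1, 0, 2 * pi))
    # unit-variance OU process, correlation time ~0.3 s, scaled per state
    z <- ou_process(n, dt, tau = 0.3)
    scale <- ifelse(moving, err$gyro_motion_scale, err$gyro_noise_sd)
    gyro[, ax] <- z * scale
  }
  imu_trial(accel, gyro, sample_rate = rate,
            subject_id = subject_id, placement = placement)
}

#' Generate a full synthetic dataset
#'
#' Emulates a multi-subject, multi-placement collection: per-trial seeds are
#' derived deterministically from `master_seed` and the (subject, placement,
#' trial) identity, and `subject_id` is recorded on every trial so group-wise
#' (subject-disjoint) splits are possible downstream.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param placements character vector of body placements.
#' @param trials_per_subject trials per subject x placement (>= 1).
#' @param spec a [trajectory_spec()] template (its seed is overridden per trial).
#' @param err an [imu_error_spec()] template (seed overridden per trial).
#' @param master_seed integer master seed.
#' @return list of entries, each with `trial`, `track`, `labels`,
#'   `subject_id`, `placement`.
#' @export
make_dataset <- function(n_subjects, placements = c("RSHO", "LSHO", "RUPA",
                                                    "LUPA", "RTOE", "LTOE"),
                         trials_per_subject = 1, spec = trajectory_spec(),
                         err = imu_error_spec(), master_seed = 1L) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1, length(placements) >= 1)
  out <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (pi in seq_along(placements)) {
      for (tr in seq_len(trials_per_subject)) {
        sd <- trial_seed(master_seed, s, pi, tr)
        sp <- spec; sp$seed <- sd
        er <- err; er$seed <- (sd + 7919L) %% .Machine$integer.max
        sim <- simulate_trajectory(sp)
        trial <- corrupt_to_imu(sim$track, sim$labels, er,
                                subject_id = sid, placement = placements[pi])
        out[[length(out) + 1L]] <- list(trial = trial, track = sim$track,
                                        labels = sim$labels, subject_id = sid,
                                        placement = placements[pi], seed = sd)
      }
    }
  }
  out
}

#' Deterministic per-trial seed
#'
#' Stable arithmetic hash of (master seed, subject, placement, trial index),
#' kept inside the 32-bit integer range.
#'
#' @param master_seed,subject,placement_index,trial_index integers.
#' @return a positive integer seed.
#' @export
trial_seed <- function(master_seed, subject, placement_index, trial_index) {
  h <- (as.double(master_seed) * 2654435761 +
          as.double(subject) * 40503 +
          as.double(placement_index) * 9973 +
          as.double(trial_index) * 101) %% 2147483629
  as.integer(h) + 1L
}

# ---- internal ---------------------------------------------------------------

# Seed the RNG for a generator call. Generators are deterministic given their
# spec seed; callers that need to preserve their own RNG state should wrap
# calls in withr::with_seed or similar.
local_rng <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# Stationary unit-variance Ornstein-Uhlenbeck sample path.
ou_process <- function(n, dt, tau = 0.3) {
  phi <- exp(-dt / tau)
  innov_sd <- sqrt(1 - phi ^ 2)
  z <- numeric(n)
  e <- rnorm(n)
  z[1] <- e[1]
  for (i in 2:n) z[i] <- phi * z[i - 1] + innov_sd * e[i]
  z
}
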