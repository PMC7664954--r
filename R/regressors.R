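# LSTM displacement regressors for moving segments: the integrative-weight
# warm start (an untrained network that IS Euler double integration), the
# pre-trained warm start, and plain randomly initialised variants.

#' Integrative weights for one LSTM layer
#'
#' Constructs LSTM parameters that make the layer compute a discrete Euler
#' integral of one input channel: the candidate weight on that channel is the
#' sampling period `dt`, every other weight is a tiny random value in
#' (-1e-6, 1e-6) (symmetry breaking), gate biases are large positive so the
#' sigmoid gates saturate at ~1 and let everything through, and the cell
#' activations are the identity. Unit 1 then carries
#' `c_t = c_{t-1} + dt * x_t`, i.e. the running integral, and `h_t = c_t`.
#'
#' @param input_dim input channel count.
#' @param units number of LSTM units.
#' @param dt sampling period in seconds.
#' @param input_index which input channel is integrated (default 1).
#' @param gate_bias gate bias; 16 puts the sigmoid within 1.2e-7 of 1, small
#'   enough that no measurable cell-state decay accumulates over
#'   thousand-step sequences.
#' @param gate_scale,cand_scale half-widths of the uniform symmetry-breaking
#'   perturbations. Gate weights sit behind a saturated sigmoid, so 1e-6
#'   is harmless there; candidate-path perturbations feed the integral
#'   directly and accumulate linearly with sequence length, so they are
#'   drawn an order of magnitude-cubed smaller (still inside the
#'   (-1e-6, 1e-6) envelope) to keep the warm start numerically faithful.
#' @return an LSTM layer (identity activations) with integrative weights.
#' @export
integrative_lstm_layer <- function(input_dim, units, dt, input_index = 1L,
                                   gate_bias = 16, gate_scale = 1e-6,
                                   cand_scale = 1e-9) {
  H <- units
  gi <- 1:(3 * H); gc <- (3 * H + 1):(4 * H)      # gate rows, candidate rows
  W <- matrix(0, 4 * H, input_dim)
  W[gi, ] <- stats::runif(3 * H * input_dim, -gate_scale, gate_scale)
  W[gc, ] <- stats::runif(H * input_dim, -cand_scale, cand_scale)
  U <- matrix(0, 4 * H, H)
  U[gi, ] <- stats::runif(3 * H * H, -gate_scale, gate_scale)
  U[gc, ] <- stats::runif(H * H, -cand_scale, cand_scale)
  b <- c(rep(gate_bias, 3 * H), stats::runif(H, -cand_scale, cand_scale))
  W[3 * H + 1L, input_index] <- dt                # candidate row of unit 1
  layer <- lstm_layer(input_dim, H, activation = "identity")
  layer$W <- W; layer$U <- U; layer$b <- b
  layer
}

#' Two-layer LSTM with integrative warm start (variant A)
#'
#' An untrained model that already performs Euler double integration of a
#' single-axis acceleration series: layer 1 integrates acceleration to
#' velocity in its first unit, layer 2 integrates that unit's output to
#' position, and the linear head passes layer 2's integrating unit through
#' with weight 1. Cell activations are linear (the hyperbolic tangents of the
#' standard cell are replaced by identities) so the integral is exact up to
#' gate saturation. Training then only has to learn corrections for the
#' errors in the acceleration signal.
#'
#' @param dt sampling period in seconds (> 0).
#' @param units LSTM units per layer (default 30).
#' @param seed integer seed for the symmetry-breaking perturbations.
#' @return an `rnn_model` mapping a `T x 1` acceleration series to a `T x 1`
#'   displacement series.
#' @export
build_integrative_model <- function(dt, units = 30L, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  set.seed(seed)
  l1 <- integrative_lstm_layer(1L, units, dt, input_index = 1L)
  l2 <- integrative_lstm_layer(units, units, dt, input_index = 1L)
  head <- dense_layer(units, 1L, activation = "linear")
  head$W <- matrix(stats::runif(units, -1e-9, 1e-9), 1L, units)
  head$W[1, 1] <- 1
  head$b <- stats::runif(1, -1e-9, 1e-9)
  rnn_model(list(l1, l2, head))
}

#' One-layer LSTM + linear head used for integration pre-training (variant B)
#'
#' Standard nonlinear LSTM cells; nothing is hand-set. The model is trained
#' to map a single-axis acceleration series to its (optionally
#' drift-corrected) Euler-integrated velocity, thereby *learning* the
#' integration operation that variant A encodes analytically.
#'
#' @param units LSTM units (default 30).
#' @param seed integer seed.
#' @return an `rnn_model` (`T x 1` in, `T x 1` out).
#' @export
build_single_integrator <- function(units = 30L, seed = 1L) {
  set.seed(seed)
  rnn_model(list(lstm_layer(1L, units, activation = "tanh"),
                 dense_layer(units, 1L, activation = "linear")))
}

#' Pre-train a one-layer LSTM to perform integration
#'
#' Builds training pairs from the moving segments of a dataset -- each axis
#' of each segment is an independent sample whose input is the acceleration
#' series and whose target is the Euler-integrated velocity (from zero at
#' segment start), drift-corrected first when `drift_correct` is `TRUE` --
#' and trains a [build_single_integrator()] on them with batch size 1.
#'
#' @param dataset list of entries with `trial`, `labels` (truth).
#' @param drift_correct use drift-corrected velocity targets.
#' @param units LSTM units.
#' @param protocol a [training_protocol()]; batch size is forced to 1.
#' @param seed integer seed.
#' @param verbose print epoch losses.
#' @return list with trained `model`, `history`.
#' @export
pretrain_single_integrator <- function(dataset, drift_correct = FALSE,
                                       units = 30L,
                                       protocol = training_protocol(batch_size = 1L),
                                       seed = 1L, verbose = FALSE) {
  protocol$batch_size <- 1L
  samples <- integration_samples(dataset, drift_correct)
  sp <- split_subjects(samples$subjects, 0.3, seed)
  tr <- samples$samples[samples$subjects %in% sp$train]
  va <- samples$samples[samples$subjects %in% sp$val]
  model <- build_single_integrator(units, seed)
  fit <- train_rnn(model, tr, va, protocol, loss = "mse", seed = seed + 1L,
                   verbose = verbose)
  list(model = fit$model, history = fit$history, best_val = fit$best_val)
}

# per-axis (accel -> velocity) samples over moving segments
integration_samples <- function(dataset, drift_correct = FALSE) {
  samples <- list(); subjects <- character()
  for (entry in dataset) {
    dt <- 1 / entry$trial$sample_rate
    segs <- find_moving_segments(entry$labels)
    for (i in seq_len(nrow(segs))) {
      idx <- (segs$b[i] + 1L):(segs$e[i] + 1L)
      a <- entry$trial$accel[idx, , drop = FALSE]
      v <- integrate_series(a, dt)
      if (drift_correct) v <- drift_correct_from_rest(v, idx, dt)
      for (ax in 1:3) {
        samples[[length(samples) + 1L]] <-
          list(x = matrix(a[, ax], ncol = 1), y = matrix(v[, ax], ncol = 1))
        subjects <- c(subjects, entry$trial$subject_id)
      }
    }
  }
  list(samples = samples, subjects = subjects)
}

#' Assemble a two-layer model from pre-trained single-integrator weights
#'
#' Stacks LSTM + head, LSTM + head, each initialised from a trained
#' [pretrain_single_integrator()] model. In the plain variant the same
#' weights fill both layers; in the drift variant the first layer takes the
#' drift-corrected integrator's weights and the second layer the plain ones
#' (drift removal is specific to the acceleration-to-velocity step).
#'
#' @param first_layer,second_layer trained `rnn_model`s from
#'   [pretrain_single_integrator()] (LSTM + dense each).
#' @return an `rnn_model` with four layers (`T x 1` in, `T x 1` out).
#' @export
assemble_warm_start_model <- function(first_layer, second_layer = first_layer) {
  stopifnot(length(first_layer$layers) == 2L, length(second_layer$layers) == 2L)
  rnn_model(list(first_layer$layers[[1]], first_layer$layers[[2]],
                 second_layer$layers[[1]], second_layer$layers[[2]]))
}

#' Two-layer LSTM regressor with no customised initialisation (variant C)
#'
#' Default (Glorot) initialisation; the input may be the 3D acceleration
#' alone, acceleration + angular velocity, or acceleration + angular velocity
#' + the position estimated by plain double integration. Output is the 3D
#' displacement per timestep.
#'
#' @param input_channels 3, 6 or 9.
#' @param units LSTM units per layer (default 30).
#' @param seed integer seed.
#' @return an `rnn_model` (`T x input_channels` in, `T x 3` out).
#' @export
build_no_init_model <- function(input_channels = 3L, units = 30L, seed = 1L) {
  if (!input_channels %in% c(3L, 6L, 9L))
    stop("input_channels must be 3, 6 or 9")
  set.seed(seed)
  rnn_model(list(lstm_layer(input_channels, units),
                 lstm_layer(units, units),
                 dense_layer(units, 3L, activation = "linear")))
}

#' Build per-segment displacement samples
#'
#' For the per-axis variants (A, B) each axis of each moving segment is one
#' sample: input the acceleration series, target the displacement since
#' segment start. For variant C the sample is 3D, with optional gyro and
#' INS-position input channels.
#'
#' @param dataset list of entries with `trial`, `track`, `labels`.
#' @param mode `"per_axis"` or one of `"c3"`, `"c6"`, `"c9"`.
#' @return list with `samples` (x/y pairs) and `subjects`.
#' @export
displacement_samples <- function(dataset, mode = c("per_axis", "c3", "c6", "c9")) {
  mode <- match.arg(mode)
  samples <- list(); subjects <- character()
  for (entry in dataset) {
    dt <- 1 / entry$trial$sample_rate
    segs <- find_moving_segments(entry$labels)
    for (i in seq_len(nrow(segs))) {
      idx <- (segs$b[i] + 1L):(segs$e[i] + 1L)
      a <- entry$trial$accel[idx, , drop = FALSE]
      p <- entry$track$positions[idx, , drop = FALSE]
      disp <- sweep(p, 2, p[1, ])                # displacement since segment start
      if (mode == "per_axis") {
        for (ax in 1:3) {
          samples[[length(samples) + 1L]] <-
            list(x = matrix(a[, ax], ncol = 1), y = matrix(disp[, ax], ncol = 1))
          subjects <- c(subjects, entry$trial$subject_id)
        }
      } else {
        x <- a
        if (mode %in% c("c6", "c9"))
          x <- cbind(x, entry$trial$gyro[idx, , drop = FALSE])
        if (mode == "c9") {
          v <- integrate_series(a, dt)
          x <- cbind(x, integrate_series(v, dt))  # INS position input
        }
        samples[[length(samples) + 1L]] <- list(x = x, y = disp)
        subjects <- c(subjects, entry$trial$subject_id)
      }
    }
  }
  list(samples = samples, subjects = subjects)
}

#' Train a displacement regressor on moving segments
#'
#' MSE loss, batch size 1 (segments have different lengths), subject-wise 7:3
#' train/validation split, early stopping per the protocol.
#'
#' @param model an `rnn_model` whose input width matches the samples.
#' @param samples output of [displacement_samples()] (or a compatible list
#'   with `samples` and `subjects`).
#' @param protocol a [training_protocol()]; batch size forced to 1.
#' @param seed integer seed.
#' @param verbose print epoch losses.
#' @return list with trained `model`, `history`, `best_val`.
#' @export
train_displacement_regressor <- function(model, samples,
                                         protocol = training_protocol(batch_size = 1L),
                                         seed = 1L, verbose = FALSE) {
  protocol$batch_size <- 1L
  sp <- split_subjects(samples$subjects, 0.3, seed)
  tr <- samples$samples[samples$subjects %in% sp$train]
  va <- samples$samples[samples$subjects %in% sp$val]
  fit <- train_rnn(model, tr, va, protocol, loss = "mse", seed = seed + 1L,
                   verbose = verbose)
  list(model = fit$model, history = fit$history, best_val = fit$best_val)
}

#' Reconstruct a full-trial track from a per-axis segment regressor
#'
#' Runs the regressor over each moving segment (per axis), adds the predicted
#' displacement to the segment's entry position, and freezes the position
#' during stopped frames.
#'
#' @param model a per-axis `rnn_model` (variants A/B).
#' @param trial an [imu_trial()].
#' @param labels a [label_sequence()].
#' @return a [position_track()].
#' @export
predict_track_per_axis <- function(model, trial, labels) {
  n <- trial$n_samples
  segs <- find_moving_segments(labels)
  pos <- matrix(0, n, 3)
  last <- c(0, 0, 0); prev_end <- 0L
  for (i in seq_len(nrow(segs))) {
    b <- segs$b[i]; e <- segs$e[i]
    if (b > prev_end)
      pos[(prev_end + 1L):b, ] <- matrix(last, b - prev_end, 3, byrow = TRUE)
    idx <- (b + 1L):(e + 1L)
    d <- vapply(1:3, function(ax)
      rnn_forward(model, matrix(trial$accel[idx, ax], ncol = 1))$out[, 1],
      numeric(length(idx)))
    pos[idx, ] <- sweep(matrix(d, ncol = 3), 2, last, "+")
    last <- pos[e + 1L, ]
    prev_end <- e + 1L
  }
  if (prev_end < n)
    pos[(prev_end + 1L):n, ] <- matrix(last, n - prev_end, 3, byrow = TRUE)
  position_track(pos, trial$sample_rate)
}
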