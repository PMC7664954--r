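#' Build an LSTM zero-velocity classifier architecture
#'
#' `"lstm30"` is a single LSTM layer with 30 units and 20% recurrent dropout;
#' `"lstm6x80"` stacks six LSTM layers of 80 units with a 20% dropout layer
#' before the head. Both end in a one-unit dense layer with sigmoid
#' activation that reads the last timestep of the window and emits the
#' probability that the window's centre frame is stopped.
#'
#' @param arch `"lstm30"` or `"lstm6x80"`.
#' @param input_dim number of input channels (6 for raw inertial windows).
#' @param seed integer seed for weight initialisation.
#' @return an `rnn_model`.
#' @export
build_sequence_classifier <- function(arch = c("lstm30", "lstm6x80"),
                                      input_dim = 6L, seed = 1L) {
  arch <- match.arg(arch)
  set.seed(seed)
  layers <- if (arch == "lstm30") {
    list(lstm_layer(input_dim, 30L, recurrent_dropout = 0.2,
                    return_sequences = FALSE),
         dense_layer(30L, 1L, activation = "sigmoid"))
  } else {
    c(lapply(seq_len(6L), function(k)
        lstm_layer(if (k == 1L) input_dim else 80L, 80L,
                   return_sequences = k < 6L)),
      list(dropout_layer(0.2),
           dense_layer(80L, 1L, activation = "sigmoid")))
  }
  rnn_model(layers)
}

# windows of standardized six-channel data as training samples
windows_as_samples <- function(dataset, window, std = NULL) {
  samples <- list(); subjects <- character()
  for (entry in dataset) {
    tr <- entry$trial
    sig <- cbind(tr$accel, tr$gyro)
    if (!is.null(std)) sig <- apply_standardizer(std, sig)
    win <- sliding_windows(tr$n_samples, window)
    for (i in seq_len(nrow(win))) {
      y <- entry$labels$labels[win$labeled_frame[i] + 1L]
      samples[[length(samples) + 1L]] <-
        list(x = sig[(win$start[i] + 1L):win$end[i], , drop = FALSE], y = y)
      subjects <- c(subjects, tr$subject_id)
    }
  }
  list(samples = samples, subjects = subjects)
}

#' Fit an LSTM zero-velocity classifier on labeled trials
#'
#' Windows of raw six-channel inertial data, standardised per channel with
#' training-set statistics, are fed to the chosen architecture; training uses
#' binary cross-entropy under the common protocol (Adam, batch 32, early
#' stopping) with a subject-wise 7:3 train/validation split of the training
#' subjects.
#'
#' @param arch `"lstm30"` or `"lstm6x80"`.
#' @param dataset list of entries with `trial` and `labels` (the training
#'   subjects' data).
#' @param window a [window_spec()]; raise `stride` to thin the window set.
#' @param protocol a [training_protocol()] (batch size 32 by default).
#' @param seed integer seed (weights, split, shuffling, dropout).
#' @param verbose print per-epoch losses.
#' @return object of class `sequence_classifier`: trained `model`,
#'   channel `standardizer`, `window`, training `history`.
#' @export
fit_sequence_classifier <- function(arch = c("lstm30", "lstm6x80"), dataset,
                                    window = window_spec(30L, stride = 1L),
                                    protocol = training_protocol(batch_size = 32L),
                                    seed = 1L, verbose = FALSE) {
  arch <- match.arg(arch)
  subjects <- vapply(dataset, function(e) e$trial$subject_id, character(1))
  sp <- split_subjects(subjects, 0.3, seed)
  raw <- do.call(rbind, lapply(dataset[subjects %in% sp$train],
                               function(e) cbind(e$trial$accel, e$trial$gyro)))
  std <- fit_standardizer(raw)
  tr <- windows_as_samples(dataset[subjects %in% sp$train], window, std)
  va <- windows_as_samples(dataset[subjects %in% sp$val], window, std)
  if (!length(va$samples)) stop("empty validation split")
  model <- build_sequence_classifier(arch, input_dim = 6L, seed = seed)
  fit <- train_rnn(model, tr$samples, va$samples, protocol, loss = "bce",
                   seed = seed + 1L, verbose = verbose)
  structure(list(arch = arch, model = fit$model, standardizer = std,
                 window = window, history = fit$history,
                 split = sp),
            class = "sequence_classifier")
}

#' Stopped-probabilities or labels for a whole trial
#'
#' @param object a `sequence_classifier`.
#' @param trial an [imu_trial()].
#' @param type `"labels"` (default) returns a [label_sequence()] with
#'   boundary/nearest fill; `"prob"` returns the per-window probabilities.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.sequence_classifier <- function(object, trial,
                                        type = c("labels", "prob"), ...) {
  type <- match.arg(type)
  sig <- apply_standardizer(object$standardizer, cbind(trial$accel, trial$gyro))
  win <- sliding_windows(trial$n_samples, object$window)
  p <- vapply(seq_len(nrow(win)), function(i)
    rnn_forward(object$model,
                sig[(win$start[i] + 1L):win$end[i], , drop = FALSE])$out[1, 1],
    numeric(1))
  if (type == "prob") return(p)
  labels <- rep(NA_integer_, trial$n_samples)
  labels[win$labeled_frame + 1L] <- as.integer(p > 0.5)
  vr <- range(win$labeled_frame) + 1L
  labels[seq_len(vr[1] - 1L)] <- labels[vr[1]]
  if (vr[2] < trial$n_samples) labels[(vr[2] + 1L):trial$n_samples] <- labels[vr[2]]
  if (anyNA(labels)) labels <- fill_nearest(labels)
  label_sequence(labels, valid_range = vr)
}

#' Median-filter a binary label sequence
#'
#' Sliding binary median with edge replication; a kernel of 1 is the
#' identity. Used as post-processing on classifier outputs, where it removes
#' isolated label flips. The default kernel of 31 samples spans about 0.26 s
#' at 120 Hz.
#'
#' @param labels a [label_sequence()].
#' @param kernel odd positive window length.
#' @return a filtered [label_sequence()] (same valid range).
#' @export
median_filter_labels <- function(labels, kernel = 31L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) stop("kernel must be odd and >= 1")
  if (kernel == 1L) return(labels)
  y <- labels$labels
  h <- (kernel - 1L) %/% 2L
  pad <- c(rep(y[1], h), y, rep(y[length(y)], h))
  cs <- cumsum(c(0L, pad))
  sums <- cs[(kernel + 1):length(cs)] - cs[1:(length(cs) - kernel)]
  label_sequence(as.integer(sums > h), valid_range = labels$valid_range)
}
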