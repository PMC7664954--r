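# Stacked network: a zero-velocity detection stage whose per-timestep
# stopped-probability is concatenated back onto the inertial input of a
# displacement regression stage, trained jointly with a weighted
# classification + regression loss.

#' Joint classification/regression loss
#'
#' `L = (1 - alpha) * BCE(y_cl, p_cl) + alpha * MSE(y_reg, yhat_reg)`, both
#' terms means over the `N` timesteps (the MSE additionally over the 3 axes).
#' `alpha = 1` reduces the loss to plain MSE of the regression head;
#' `alpha = 0` to plain binary cross-entropy. Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param y_cl 0/1 truth labels (1 = stopped), length `N`.
#' @param p_cl predicted stopped-probabilities, length `N`.
#' @param y_reg truth displacement, `N x 3`.
#' @param yhat_reg predicted displacement, `N x 3`.
#' @param alpha weight in `[0, 1]`.
#' @return scalar loss.
#' @export
joint_loss <- function(y_cl, p_cl, y_reg, yhat_reg, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  stopifnot(length(y_cl) == length(p_cl), all(dim(as.matrix(y_reg)) ==
                                                dim(as.matrix(yhat_reg))))
  pc <- pmin(pmax(p_cl, EPS_PROB), 1 - EPS_PROB)
  bce <- -mean(y_cl * log(pc) + (1 - y_cl) * log(1 - pc))
  mse <- mean((as.matrix(y_reg) - as.matrix(yhat_reg)) ^ 2)
  (1 - alpha) * bce + alpha * mse
}

#' Build the stacked joint model
#'
#' An LSTM(30) + sigmoid dense stage maps the six-channel inertial stream of
#' a whole trial to a per-timestep stopped-probability; that probability is
#' concatenated with the input (7 channels) and fed through two further
#' LSTM(30) layers, a dropout layer (rate 0.25) and a linear dense head that
#' emits the 3D displacement since trial start at every timestep.
#'
#' @param input_dim inertial channel count (default 6).
#' @param units LSTM units per layer (default 30).
#' @param dropout_rate dropout before the regression head (default 0.25).
#' @param seed integer seed for initialisation.
#' @return an object of class `stacked_model`.
#' @export
build_stacked_model <- function(input_dim = 6L, units = 30L,
                                dropout_rate = 0.25, seed = 1L) {
  set.seed(seed)
  structure(list(layers = list(
    lstm_layer(input_dim, units),                       # 1: detector LSTM
    dense_layer(units, 1L, activation = "sigmoid"),     # 2: stopped-probability
    lstm_layer(input_dim + 1L, units),                  # 3: regressor LSTM 1
    lstm_layer(units, units),                           # 4: regressor LSTM 2
    dropout_layer(dropout_rate),                        # 5
    dense_layer(units, 3L, activation = "linear")),     # 6: 3D displacement
    input_dim = input_dim),
    class = "stacked_model")
}

stacked_forward <- function(model, x, training = FALSE) {
  X <- t(as.matrix(x))                                  # D x T
  L <- model$layers
  f1 <- lstm_forward(L[[1]], X, training)
  f2 <- dense_forward(L[[2]], f1$out, training)         # 1 x T probabilities
  XC <- rbind(X, f2$out)                                # (D+1) x T
  f3 <- lstm_forward(L[[3]], XC, training)
  f4 <- lstm_forward(L[[4]], f3$out, training)
  f5 <- dropout_forward(L[[5]], f4$out, training)
  f6 <- dense_forward(L[[6]], f5$out, training)
  list(prob = as.vector(f2$out), reg = t(f6$out),
       caches = list(f1$cache, f2$cache, f3$cache, f4$cache, f5$cache, f6$cache))
}

# dProb: length-T gradient wrt the probability output; dReg: T x 3
stacked_backward <- function(model, caches, dProb, dReg) {
  L <- model$layers
  g <- vector("list", 6L)
  b6 <- dense_backward(L[[6]], caches[[6]], t(dReg)); g[[6]] <- b6$grads
  b5 <- dropout_backward(L[[5]], caches[[5]], b6$dX); g[[5]] <- b5$grads
  b4 <- lstm_backward(L[[4]], caches[[4]], b5$dX); g[[4]] <- b4$grads
  b3 <- lstm_backward(L[[3]], caches[[3]], b4$dX); g[[3]] <- b3$grads
  D <- model$input_dim
  dP <- matrix(dProb, 1) + b3$dX[D + 1L, , drop = FALSE]
  b2 <- dense_backward(L[[2]], caches[[2]], dP); g[[2]] <- b2$grads
  b1 <- lstm_backward(L[[1]], caches[[1]], b2$dX); g[[1]] <- b1$grads
  g
}

#' Predict with a (trained) stacked model
#'
#' @param object a `stacked_model` (wrapped in a fit or raw).
#' @param trial an [imu_trial()] or a `T x 6` matrix (already standardised
#'   when predicting from a raw model).
#' @param ... unused.
#' @return list with `prob` (length `T`) and `displacement` (`T x 3`).
#' @export
predict.stacked_model <- function(object, trial, ...) {
  x <- if (inherits(trial, "imu_trial")) cbind(trial$accel, trial$gyro) else trial
  fw <- stacked_forward(object, x)
  list(prob = fw$prob, displacement = fw$reg)
}

#' Train the stacked joint model on full trials
#'
#' Each sample is an entire trial: the six-channel stream (standardised with
#' training-subject statistics) as input, with the truth zero-velocity labels
#' and the displacement-since-trial-start as the two targets of the joint
#' loss. Batch size 1, subject-wise 7:3 train/validation split, early
#' stopping per the protocol.
#'
#' @param dataset list of entries with `trial`, `track`, `labels`.
#' @param alpha joint-loss weight in `[0, 1]`.
#' @param units LSTM units per layer.
#' @param protocol a [training_protocol()] (batch size forced to 1).
#' @param seed integer seed.
#' @param verbose print epoch losses.
#' @return object of class `stacked_fit`: trained `model`, channel
#'   `standardizer`, `alpha`, `history`.
#' @export
train_stacked_model <- function(dataset, alpha = 1, units = 30L,
                                protocol = training_protocol(batch_size = 1L),
                                seed = 1L, verbose = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  protocol$batch_size <- 1L
  subjects <- vapply(dataset, function(e) e$trial$subject_id, character(1))
  sp <- split_subjects(subjects, 0.3, seed)
  raw <- do.call(rbind, lapply(dataset[subjects %in% sp$train],
                               function(e) cbind(e$trial$accel, e$trial$gyro)))
  std <- fit_standardizer(raw)
  make_samples <- function(entries) lapply(entries, function(e) {
    p <- e$track$positions
    list(x = apply_standardizer(std, cbind(e$trial$accel, e$trial$gyro)),
         y_cl = e$labels$labels,
         y_reg = sweep(p, 2, p[1, ]))
  })
  tr <- make_samples(dataset[subjects %in% sp$train])
  va <- make_samples(dataset[subjects %in% sp$val])
  if (!length(va)) stop("empty validation split")
  model <- build_stacked_model(6L, units, seed = seed)
  set.seed(seed + 1L)
  state <- adam_state(model)
  eval_loss <- function(s) {
    fw <- stacked_forward(model, s$x)
    joint_loss(s$y_cl, fw$prob, s$y_reg, fw$reg, alpha)
  }
  best <- list(val = mean(vapply(va, eval_loss, numeric(1))),
               layers = model$layers, epoch = 0L)
  hist <- data.frame()
  for (epoch in seq_len(protocol$max_epochs)) {
    idx <- sample(seq_along(tr))
    tr_loss <- 0
    for (i in idx) {
      s <- tr[[i]]
      fw <- stacked_forward(model, s$x, training = TRUE)
      n <- length(s$y_cl)
      pc <- pmin(pmax(fw$prob, EPS_PROB), 1 - EPS_PROB)
      tr_loss <- tr_loss + joint_loss(s$y_cl, fw$prob, s$y_reg, fw$reg, alpha)
      dProb <- (1 - alpha) * (pc - s$y_cl) / (pc * (1 - pc)) / n
      dReg <- alpha * 2 * (fw$reg - s$y_reg) / (3 * n)
      g <- stacked_backward(model, fw$caches, dProb, dReg)
      g <- grads_clip(g, protocol$clip_norm)
      upd <- adam_step(model, g, state, protocol)
      model <- upd$model; state <- upd$state
    }
    tr_loss <- tr_loss / length(tr)
    val_loss <- mean(vapply(va, eval_loss, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, tr_loss, val_loss))
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, layers = model$layers, epoch = epoch)
    } else if (epoch - best$epoch >= protocol$patience) break
  }
  model$layers <- best$layers
  structure(list(model = model, standardizer = std, alpha = alpha,
                 history = hist, split = sp),
            class = "stacked_fit")
}

#' Predict a full-trial track with a trained stacked fit
#'
#' @param object a `stacked_fit` from [train_stacked_model()].
#' @param trial an [imu_trial()].
#' @param ... unused.
#' @return list with `track` (a [position_track()]), `prob` and `labels`
#'   (thresholded probability as a [label_sequence()]).
#' @export
predict.stacked_fit <- function(object, trial, ...) {
  x <- apply_standardizer(object$standardizer, cbind(trial$accel, trial$gyro))
  fw <- stacked_forward(object$model, x)
  list(track = position_track(fw$reg, trial$sample_rate),
       prob = fw$prob,
       labels = label_sequence(as.integer(fw$prob > 0.5)))
}
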