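# Minimal recurrent-network engine: LSTM and dense layers, analytic
# backpropagation through time, Adam with L2 weight decay and global-norm
# gradient clipping. Written for the modest sequence lengths and unit counts
# this package uses (tens of units, thousands of timesteps); correctness is
# pinned by finite-difference gradient checks in the test suite.
#
# Conventions: a sample is a T x D matrix (time by channels). Inside layers
# signals are stored D x T so that per-timestep work is column slicing. Gate
# rows of the stacked LSTM matrices are ordered [input; forget; output;
# candidate].

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training protocol for the LSTM-based models
#'
#' Defaults follow the common recipe used across every network in this
#' package: Adam, learning rate 5e-3, weight decay 1e-5, early stopping after
#' 20 epochs without validation improvement, and gradient clipping.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient.
#' @param batch_size samples per gradient step (32 for window classifiers, 1
#'   for the variable-length regressors).
#' @param patience early-stopping patience in epochs.
#' @param clip_norm global gradient-norm ceiling.
#' @param max_epochs hard epoch cap.
#' @return an object of class `training_protocol`.
#' @export
training_protocol <- function(learning_rate = 5e-3, weight_decay = 1e-5,
                              batch_size = 32L, patience = 20L,
                              clip_norm = 1.0, max_epochs = 100L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            patience >= 1, clip_norm > 0, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), clip_norm = clip_norm,
                 max_epochs = as.integer(max_epochs)),
            class = "training_protocol")
}

# ---- layer constructors -----------------------------------------------------

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' @noRd
lstm_layer <- function(input_dim, units, activation = c("tanh", "identity"),
                       recurrent_dropout = 0, return_sequences = TRUE) {
  activation <- match.arg(activation)
  H <- units; D <- input_dim
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1                       # standard forget-gate bias
  list(type = "lstm", D = D, H = H, activation = activation,
       recurrent_dropout = recurrent_dropout,
       return_sequences = return_sequences,
       W = glorot(4 * H, D), U = glorot(4 * H, H), b = b)
}

#' @noRd
dense_layer <- function(input_dim, units, activation = c("linear", "sigmoid")) {
  activation <- match.arg(activation)
  list(type = "dense", D = input_dim, H = units, activation = activation,
       W = glorot(units, input_dim), b = numeric(units))
}

#' @noRd
dropout_layer <- function(rate) list(type = "dropout", rate = rate)

# ---- forward ----------------------------------------------------------------

lstm_forward <- function(layer, X, training = FALSE) {
  # X: D x T
  H <- layer$H; Tn <- ncol(X)
  gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H); gc <- (3 * H + 1):(4 * H)
  I <- F_ <- O <- G <- C <- Hs <- matrix(0, H, Tn)
  rmask <- rep(1, H)
  if (training && layer$recurrent_dropout > 0) {
    rmask <- stats::rbinom(H, 1, 1 - layer$recurrent_dropout) /
      (1 - layer$recurrent_dropout)
  }
  hprev <- numeric(H); cprev <- numeric(H)
  WX <- layer$W %*% X                            # 4H x T, hoisted
  tanh_cells <- layer$activation == "tanh"
  for (t in seq_len(Tn)) {
    z <- WX[, t] + layer$U %*% (hprev * rmask) + layer$b
    i <- sigmoid(z[gi]); f <- sigmoid(z[gf]); o <- sigmoid(z[go])
    g <- if (tanh_cells) tanh(z[gc]) else z[gc]
    c <- f * cprev + i * g
    h <- if (tanh_cells) o * tanh(c) else o * c
    I[, t] <- i; F_[, t] <- f; O[, t] <- o; G[, t] <- g; C[, t] <- c; Hs[, t] <- h
    hprev <- h; cprev <- c
  }
  out <- if (layer$return_sequences) Hs else Hs[, Tn, drop = FALSE]
  list(out = out, cache = list(X = X, I = I, F = F_, O = O, G = G, C = C,
                               H = Hs, rmask = rmask))
}

dense_forward <- function(layer, X, training = FALSE) {
  A <- layer$W %*% X + layer$b
  out <- if (layer$activation == "sigmoid") sigmoid(A) else A
  list(out = out, cache = list(X = X, out = out))
}

dropout_forward <- function(layer, X, training = FALSE) {
  if (training && layer$rate > 0) {
    mask <- matrix(stats::rbinom(length(X), 1, 1 - layer$rate) / (1 - layer$rate),
                   nrow(X), ncol(X))
    list(out = X * mask, cache = list(mask = mask))
  } else {
    list(out = X, cache = list(mask = NULL))
  }
}

layer_forward <- function(layer, X, training = FALSE) {
  switch(layer$type,
         lstm = lstm_forward(layer, X, training),
         dense = dense_forward(layer, X, training),
         dropout = dropout_forward(layer, X, training))
}

# ---- backward ---------------------------------------------------------------

lstm_backward <- function(layer, cache, dOut) {
  H <- layer$H; Tn <- ncol(cache$X)
  gi <- 1:H; gf <- (H + 1):(2 * H); go <- (2 * H + 1):(3 * H); gc <- (3 * H + 1):(4 * H)
  dH <- matrix(0, H, Tn)
  if (layer$return_sequences) dH <- dH + dOut else dH[, Tn] <- dOut
  tanh_cells <- layer$activation == "tanh"
  dW <- matrix(0, 4 * H, layer$D); dU <- matrix(0, 4 * H, H); db <- numeric(4 * H)
  dX <- matrix(0, layer$D, Tn)
  dh_next <- numeric(H); dc_next <- numeric(H)
  rmask <- cache$rmask
  Ut <- t(layer$U); Wt <- t(layer$W)
  dZ <- matrix(0, 4 * H, Tn)
  for (t in seq(Tn, 1)) {
    i <- cache$I[, t]; f <- cache$F[, t]; o <- cache$O[, t]
    g <- cache$G[, t]; c <- cache$C[, t]
    cprev <- if (t > 1) cache$C[, t - 1] else numeric(H)
    dh <- dH[, t] + dh_next
    if (tanh_cells) {
      tc <- tanh(c)
      do_ <- dh * tc
      dc <- dh * o * (1 - tc ^ 2) + dc_next
    } else {
      do_ <- dh * c
      dc <- dh * o + dc_next
    }
    di <- dc * g; df <- dc * cprev; dg <- dc * i
    dz <- numeric(4 * H)
    dz[gi] <- di * i * (1 - i)
    dz[gf] <- df * f * (1 - f)
    dz[go] <- do_ * o * (1 - o)
    dz[gc] <- if (tanh_cells) dg * (1 - g ^ 2) else dg
    dZ[, t] <- dz
    db <- db + dz
    dh_next <- (Ut %*% dz) * rmask
    dc_next <- dc * f
  }
  dW <- dZ %*% t(cache$X)
  Hprev <- cbind(numeric(H), cache$H[, -Tn, drop = FALSE]) * rmask
  dU <- dZ %*% t(Hprev)
  dX <- Wt %*% dZ
  list(grads = list(W = dW, U = dU, b = db), dX = dX)
}

dense_backward <- function(layer, cache, dOut) {
  dA <- if (layer$activation == "sigmoid")
    dOut * cache$out * (1 - cache$out) else dOut
  list(grads = list(W = dA %*% t(cache$X), b = rowSums(dA)),
       dX = t(layer$W) %*% dA)
}

dropout_backward <- function(layer, cache, dOut) {
  dX <- if (is.null(cache$mask)) dOut else dOut * cache$mask
  list(grads = list(), dX = dX)
}

layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
         lstm = lstm_backward(layer, cache, dOut),
         dense = dense_backward(layer, cache, dOut),
         dropout = dropout_backward(layer, cache, dOut))
}

# ---- sequential model -------------------------------------------------------

rnn_model <- function(layers) structure(list(layers = layers), class = "rnn_model")

# x: T x D sample. Returns T' x M output plus caches for backward.
rnn_forward <- function(model, x, training = FALSE) {
  X <- t(as.matrix(x))
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[li]], X, training)
    caches[[li]] <- fw$cache
    X <- fw$out
  }
  list(out = t(X), caches = caches)
}

# dOut: T' x M gradient wrt the model output. Returns nested grads + dX.
rnn_backward <- function(model, caches, dOut) {
  D <- t(as.matrix(dOut))
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[li]], caches[[li]], D)
    grads[[li]] <- bw$grads
    D <- bw$dX
  }
  list(grads = grads, dX = t(D))
}

#' Forward pass of a fitted recurrent model
#' @param object an `rnn_model`.
#' @param x a `T x D` sample matrix.
#' @param ... unused.
#' @return the model output (`T x M`, or `1 x M` for last-step models).
#' @export
predict.rnn_model <- function(object, x, ...) rnn_forward(object, x)$out
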