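# Generic trainer shared by every LSTM-based model in the package.

EPS_PROB <- 1e-7

# loss functions return list(loss, dOut) with dOut the gradient wrt the model
# output (already divided by the number of terms)
loss_bce <- function(y, p) {
  pc <- pmin(pmax(p, EPS_PROB), 1 - EPS_PROB)
  n <- length(y)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  list(loss = loss, dOut = matrix((pc - y) / (pc * (1 - pc)) / n,
                                  nrow = nrow(as.matrix(p))))
}

loss_mse <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  n <- length(y)
  list(loss = mean((y - yhat) ^ 2), dOut = 2 * (yhat - y) / n)
}

# ---- parameter-tree helpers -------------------------------------------------

model_param_names <- c("W", "U", "b")

grads_zero_like <- function(model) {
  lapply(model$layers, function(l) {
    ps <- intersect(model_param_names, names(l))
    stats::setNames(lapply(ps, function(p) l[[p]] * 0), ps)
  })
}

grads_add <- function(a, b, scale = 1) {
  for (li in seq_along(a)) for (p in names(b[[li]]))
    a[[li]][[p]] <- a[[li]][[p]] + scale * b[[li]][[p]]
  a
}

grads_global_norm <- function(g) {
  sqrt(sum(vapply(g, function(l) sum(vapply(l, function(m) sum(m ^ 2),
                                            numeric(1))), numeric(1))))
}

grads_clip <- function(g, max_norm) {
  nrm <- grads_global_norm(g)
  if (is.finite(nrm) && nrm > max_norm) g <- grads_scale(g, max_norm / nrm)
  g
}

grads_scale <- function(g, s) {
  lapply(g, function(l) lapply(l, function(m) m * s))
}

adam_state <- function(model) {
  list(m = grads_zero_like(model), v = grads_zero_like(model), t = 0L)
}

adam_step <- function(model, grads, state, protocol,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr <- protocol$learning_rate
  for (li in seq_along(grads)) {
    for (p in names(grads[[li]])) {
      g <- grads[[li]][[p]] + protocol$weight_decay * model$layers[[li]][[p]]
      state$m[[li]][[p]] <- beta1 * state$m[[li]][[p]] + (1 - beta1) * g
      state$v[[li]][[p]] <- beta2 * state$v[[li]][[p]] + (1 - beta2) * g ^ 2
      mhat <- state$m[[li]][[p]] / (1 - beta1 ^ state$t)
      vhat <- state$v[[li]][[p]] / (1 - beta2 ^ state$t)
      model$layers[[li]][[p]] <- model$layers[[li]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, state = state)
}

# ---- training loop ----------------------------------------------------------

sample_loss <- function(model, s, loss_fn, training = FALSE) {
  fw <- rnn_forward(model, s$x, training = training)
  l <- loss_fn(s$y, fw$out)
  list(loss = l$loss, dOut = l$dOut, fw = fw)
}

#' Train a recurrent model with Adam and early stopping
#'
#' Minimises the chosen loss over a list of samples (each a list with `x`, a
#' `T x D` input matrix, and `y`, the matching target) in seeded shuffled
#' mini-batches. Validation loss is evaluated after every epoch; training
#' stops when it has not improved for `protocol$patience` epochs (or at
#' `max_epochs`) and the best-validation weights are restored.
#'
#' @param model an `rnn_model`.
#' @param train,val lists of samples.
#' @param protocol a [training_protocol()].
#' @param loss `"bce"` or `"mse"`.
#' @param seed integer seed for shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return list with the trained `model` and a `history` data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_rnn <- function(model, train, val, protocol = training_protocol(),
                      loss = c("mse", "bce"), seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  loss_fn <- if (loss == "bce") loss_bce else loss_mse
  if (!length(val)) stop("empty validation split")
  set.seed(seed)
  state <- adam_state(model)
  # the initial weights compete too: a warm-started model may already be at
  # (or near) the optimum, and an update pass must not be able to lose that
  val0 <- mean(vapply(val, function(s)
    sample_loss(model, s, loss_fn)$loss, numeric(1)))
  best <- list(val = val0, layers = model$layers, epoch = 0L)
  hist <- data.frame()
  for (epoch in seq_len(protocol$max_epochs)) {
    idx <- sample(seq_along(train))
    tr_loss <- 0
    for (start in seq(1, length(idx), by = protocol$batch_size)) {
      batch <- idx[start:min(start + protocol$batch_size - 1L, length(idx))]
      g <- grads_zero_like(model)
      for (i in batch) {
        sl <- sample_loss(model, train[[i]], loss_fn, training = TRUE)
        bw <- rnn_backward(model, sl$fw$caches, sl$dOut)
        g <- grads_add(g, bw$grads, scale = 1 / length(batch))
        tr_loss <- tr_loss + sl$loss
      }
      g <- grads_clip(g, protocol$clip_norm)
      upd <- adam_step(model, g, state, protocol)
      model <- upd$model; state <- upd$state
    }
    tr_loss <- tr_loss / length(train)
    val_loss <- mean(vapply(val, function(s)
      sample_loss(model, s, loss_fn)$loss, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, tr_loss, val_loss))
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, layers = model$layers, epoch = epoch)
    } else if (epoch - best$epoch >= protocol$patience) {
      break
    }
  }
  model$layers <- best$layers
  list(model = model, history = hist, best_val = best$val)
}

# deterministic split of subjects into train/validation parts, default 7:3
split_subjects <- function(subjects, val_fraction = 0.3, seed = 1L) {
  u <- unique(subjects)
  if (length(u) < 2) stop("need >= 2 subjects to form a validation split")
  set.seed(seed)
  u <- sample(u)
  n_val <- max(1L, round(length(u) * val_fraction))
  n_val <- min(n_val, length(u) - 1L)
  list(train = u[seq_len(length(u) - n_val)],
       val = u[(length(u) - n_val + 1L):length(u)])
}
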