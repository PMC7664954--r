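# Shared fixtures, built in code and memoised for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# short trajectory spec: ~8 s trials instead of the default ~18 s
short_spec <- function(seed = 1L, n_segments = 5L)
  trajectory_spec(n_segments = n_segments,
                  dwell_duration_range = c(0.8, 1.5),
                  move_duration_range = c(0.8, 1.5),
                  move_distance_range = c(0.15, 0.4),
                  seed = seed)

noise_free_errors <- function(seed = 1L)
  imu_error_spec(0, 0, 0, 0, 60, 0, seed = seed)

# noise-free sensors but with the state-scaled gyro signal the detectors
# rely on (gyro is exactly zero while stopped)
clean_errors <- function(seed = 1L)
  imu_error_spec(0, 0, 0, 0, 60, 1.0, seed = seed)

# small clean dataset: 4 subjects x 1 placement, noise-free accel + clean gyro
clean_dataset <- function()
  fixture("clean_dataset", function()
    make_dataset(4, "RSHO", 1, short_spec(), clean_errors(),
                 master_seed = 11L))

# small noisy dataset: 5 subjects x 1 placement, default error model
noisy_dataset <- function()
  fixture("noisy_dataset", function()
    make_dataset(5, "RSHO", 1, short_spec(), imu_error_spec(seed = 1L),
                 master_seed = 12L))

# one simulated trial + truth, noise-free
clean_trial <- function() clean_dataset()[[1]]

path_length <- function(track) {
  sum(sqrt(rowSums(diff(track$positions) ^ 2)))
}

# finite-difference gradient check for an rnn_model under a loss closure;
# returns the worst relative disagreement over `k` random parameters/layer
fd_grad_check <- function(model, x, loss_fn, dOut_fn, k = 5L, eps = 1e-5,
                          seed = 1L) {
  set.seed(seed)
  fw <- rnn_forward(model, x)
  bw <- rnn_backward(model, fw$caches, dOut_fn(fw$out))
  worst <- 0
  for (li in seq_along(model$layers)) {
    for (p in names(bw$grads[[li]])) {
      th <- model$layers[[li]][[p]]
      for (idx in sample(length(th), min(k, length(th)))) {
        model$layers[[li]][[p]][idx] <- th[idx] + eps
        lp <- loss_fn(rnn_forward(model, x)$out)
        model$layers[[li]][[p]][idx] <- th[idx] - eps
        lm <- loss_fn(rnn_forward(model, x)$out)
        model$layers[[li]][[p]][idx] <- th[idx]
        num <- (lp - lm) / (2 * eps)
        ana <- bw$grads[[li]][[p]][idx]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
  }
  worst
}
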