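#' Experiment configuration
#'
#' Bundles dataset generation, the subject-wise split, detector/regressor
#' choices and seeds for the end-to-end experiment drivers. Train and test
#' subject sets must be disjoint so that no participant contributes to both
#' sides.
#'
#' @param n_subjects number of simulated subjects (default 13).
#' @param n_test_subjects subjects held out for testing (default 3; the
#'   remaining subjects form the training set, split 7:3 into train and
#'   validation inside the learners).
#' @param placements body placements to simulate.
#' @param trials_per_subject trials per subject and placement.
#' @param trajectory a [trajectory_spec()] template.
#' @param errors an [imu_error_spec()] template.
#' @param detectors character subset of
#'   `c("shoe", "ared", "lr", "svm", "rf", "lstm30", "lstm6x80")`.
#' @param window_stride stride used when windowing classifier training data
#'   (1 reproduces the densest labeling; larger is faster).
#' @param median_kernel median-filter kernel for the post-processed variant.
#' @param alpha stacked-model loss weights to evaluate.
#' @param seed master seed.
#' @param out_dir optional output directory for artifacts + manifest.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 13L, n_test_subjects = 3L,
                              placements = c("RSHO", "LSHO", "RUPA",
                                             "LUPA", "RTOE", "LTOE"),
                              trials_per_subject = 1L,
                              trajectory = trajectory_spec(),
                              errors = imu_error_spec(),
                              detectors = c("shoe", "ared"),
                              window_stride = 1L,
                              median_kernel = 31L,
                              alpha = 1,
                              seed = 1L, out_dir = NULL) {
  if (n_test_subjects >= n_subjects)
    stop("need at least one training subject")
  detectors <- match.arg(detectors,
                         c("shoe", "ared", "lr", "svm", "rf", "lstm30", "lstm6x80"),
                         several.ok = TRUE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_test_subjects = as.integer(n_test_subjects),
                 placements = placements,
                 trials_per_subject = as.integer(trials_per_subject),
                 trajectory = trajectory, errors = errors,
                 detectors = detectors, window_stride = as.integer(window_stride),
                 median_kernel = as.integer(median_kernel),
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# generate the dataset and the subject-disjoint split for a config
experiment_dataset <- function(config) {
  ds <- make_dataset(config$n_subjects, config$placements,
                     config$trials_per_subject, config$trajectory,
                     config$errors, config$seed)
  subjects <- vapply(ds, function(e) e$subject_id, character(1))
  u <- unique(subjects)
  set.seed(config$seed)
  u <- sample(u)
  test_sub <- u[seq_len(config$n_test_subjects)]
  train_sub <- setdiff(u, test_sub)
  if (length(intersect(train_sub, test_sub)))
    stop("train and test subject sets overlap")
  list(data = ds, subjects = subjects,
       train = ds[subjects %in% train_sub],
       test = ds[subjects %in% test_sub],
       train_subjects = train_sub, test_subjects = test_sub)
}

#' Run a zero-velocity detection experiment
#'
#' Calibrates/trains each requested detector on the training subjects and
#' reports test-set frame accuracy with and without median filtering.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return data.frame with columns `detector`, `accuracy`,
#'   `accuracy_filtered`; the fitted detectors in attribute `"models"` and
#'   the manifest in attribute `"manifest"`.
#' @export
run_detection_experiment <- function(config, verbose = FALSE) {
  split <- experiment_dataset(config)
  train_trials <- lapply(split$train, `[[`, "trial")
  train_truth <- lapply(split$train, `[[`, "labels")
  win <- window_spec(30L, stride = config$window_stride)
  models <- list()
  rows <- list()
  for (d in config$detectors) {
    if (verbose) message("detector: ", d)
    res <- tryCatch({
      model <- switch(d,
        shoe = calibrate_threshold("shoe", train_trials, train_truth),
        ared = calibrate_threshold("ared", train_trials, train_truth),
        lr = , svm = , rf = fit_window_classifier(
          d, build_feature_table(split$train, win), seed = config$seed),
        lstm30 = fit_sequence_classifier("lstm30", split$train, win,
                                         seed = config$seed),
        lstm6x80 = fit_sequence_classifier("lstm6x80", split$train, win,
                                           seed = config$seed))
      acc <- acc_f <- numeric(length(split$test))
      for (i in seq_along(split$test)) {
        trial <- split$test[[i]]$trial
        pred <- switch(d,
          shoe = shoe_detect(trial, model),
          ared = ared_detect(trial, model),
          lr = , svm = , rf = classify_trial(model, trial, win),
          lstm30 = , lstm6x80 = predict(model, trial))
        truth <- split$test[[i]]$labels
        acc[i] <- compare_labels(pred, truth)$accuracy
        acc_f[i] <- compare_labels(
          median_filter_labels(pred, config$median_kernel), truth)$accuracy
      }
      models[[d]] <- model
      data.frame(detector = d, accuracy = mean(acc),
                 accuracy_filtered = mean(acc_f), error = NA_character_)
    }, error = function(e)
      data.frame(detector = d, accuracy = NA_real_,
                 accuracy_filtered = NA_real_, error = conditionMessage(e)))
    rows[[d]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  attr(out, "manifest") <- write_manifest(config, "detection")
  out
}

#' Run a tracking experiment (detector x regressor error matrix)
#'
#' Builds the error matrix over the test trials: naive ungated double
#' integration, then each requested detector combined with gated double
#' integration with and without drift correction, and (optionally) the
#' stacked joint model per `alpha`. Failures in one cell are recorded with a
#' reason instead of aborting the rest.
#'
#' @param config an [experiment_config()].
#' @param include_stacked also train/evaluate the stacked model (slow).
#' @param stacked_protocol protocol for stacked training (scaled down by
#'   default).
#' @param verbose print progress.
#' @return data.frame with one row per (method, metric): columns `detector`,
#'   `regressor`, `metric`, `mean`, `sd`, `error`.
#' @export
run_tracking_experiment <- function(config, include_stacked = FALSE,
                                    stacked_protocol = training_protocol(
                                      batch_size = 1L, max_epochs = 5L),
                                    verbose = FALSE) {
  split <- experiment_dataset(config)
  rows <- list()
  add_method <- function(detector, regressor, track_fn) {
    res <- tryCatch({
      reports <- lapply(split$test, function(e)
        error_report(e$track, track_fn(e)))
      agg <- aggregate_reports(reports)
      cbind(detector = detector, regressor = regressor, agg,
            error = NA_character_)
    }, error = function(err)
      data.frame(detector = detector, regressor = regressor,
                 metric = NA_character_, mean = NA_real_, sd = NA_real_,
                 error = conditionMessage(err)))
    rows[[length(rows) + 1L]] <<- res
  }
  if (verbose) message("naive double integration")
  add_method("none", "double_integration",
             function(e) naive_dead_reckoning(e$trial)$track)
  train_trials <- lapply(split$train, `[[`, "trial")
  train_truth <- lapply(split$train, `[[`, "labels")
  for (d in config$detectors) {
    if (verbose) message("detector: ", d)
    detector_model <- tryCatch(switch(d,
      shoe = calibrate_threshold("shoe", train_trials, train_truth),
      ared = calibrate_threshold("ared", train_trials, train_truth),
      stop("tracking experiment supports shoe/ared detectors; got ", d)),
      error = function(e) e)
    if (inherits(detector_model, "error")) {
      msg <- conditionMessage(detector_model)
      for (r in c("double_integration", "double_integration_drift"))
        rows[[length(rows) + 1L]] <- data.frame(
          detector = d, regressor = r, metric = NA_character_,
          mean = NA_real_, sd = NA_real_, error = msg)
      next
    }
    detect_fn <- if (d == "shoe") shoe_detect else ared_detect
    add_method(d, "double_integration", function(e)
      gated_dead_reckoning(e$trial, detect_fn(e$trial, detector_model),
                           drift_correction = FALSE)$track)
    add_method(d, "double_integration_drift", function(e)
      gated_dead_reckoning(e$trial, detect_fn(e$trial, detector_model),
                           drift_correction = TRUE)$track)
  }
  if (include_stacked) {
    for (a in config$alpha) {
      if (verbose) message("stacked model, alpha = ", a)
      fit <- train_stacked_model(split$train, alpha = a,
                                 protocol = stacked_protocol,
                                 seed = config$seed)
      add_method("stacked", sprintf("stacked_alpha_%g", a),
                 function(e) predict(fit, e$trial)$track)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- write_manifest(config, "tracking")
  out
}

# manifest: config + seeds + package version; written as YAML when an output
# directory is configured, returned invisibly either way
write_manifest <- function(config, kind) {
  manifest <- list(
    kind = kind,
    package = "zuptr",
    version = as.character(utils::packageVersion("zuptr")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    n_test_subjects = config$n_test_subjects,
    placements = config$placements,
    trials_per_subject = config$trials_per_subject,
    detectors = config$detectors,
    window_stride = config$window_stride,
    median_kernel = config$median_kernel,
    alpha = config$alpha,
    trajectory = unclass(config$trajectory),
    errors = unclass(config$errors))
  manifest$trajectory$move_distance_range <-
    as.vector(manifest$trajectory$move_distance_range)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(manifest, file.path(config$out_dir,
                                         paste0(kind, "_manifest.yaml")))
  }
  invisible(manifest)
}
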