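#' Time-domain features of one windowed channel
#'
#' The eleven statistics used by the window classifiers: mean, maximum,
#' minimum, sum, standard deviation, 0.25 and 0.75 quartiles, median,
#' variance, energy (sum of squares) and maximum discrete difference along
#' the time axis. Standard deviation and variance are population-style
#' (divide by N); quartiles use linear interpolation between order
#' statistics; the maximum discrete difference is the signed maximum of the
#' first differences (set `abs_diff = TRUE` for the absolute variant).
#'
#' @param x numeric vector, one channel of one window (length >= 2).
#' @param abs_diff logical, use `max |x_{i+1} - x_i|` instead of the signed
#'   maximum.
#' @return named numeric vector of length 11.
#' @export
extract_window_features <- function(x, abs_diff = FALSE) {
  if (length(x) < 2L) stop("window must contain at least 2 samples")
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu) ^ 2) / n
  d <- diff(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mu, max = max(x), min = min(x), sum = sum(x), sd = sqrt(v),
    q25 = q[1], q75 = q[3], median = q[2], var = v, energy = sum(x ^ 2),
    maxdiff = if (abs_diff) max(abs(d)) else max(d))
}

#' Build a window-feature table from labeled trials
#'
#' Windows each trial's six channels, extracts the 11 per-channel statistics
#' (66 columns, named `<channel>_<stat>`), and records the truth label at the
#' window's labeled frame plus the subject id (the grouping variable for
#' subject-disjoint cross-validation).
#'
#' @param dataset list of entries with `trial` ([imu_trial()]) and `labels`
#'   ([label_sequence()]), as produced by [make_dataset()].
#' @param window a [window_spec()]; increase `stride` to thin the table.
#' @param abs_diff passed to [extract_window_features()].
#' @return an object of class `feature_table`: list with `x` (numeric
#'   matrix), `y` (integer labels, 1 = stopped), `group` (character) and
#'   `feature_names`.
#' @export
build_feature_table <- function(dataset, window = window_spec(30L, stride = 1L),
                                abs_diff = FALSE) {
  channels <- c("ax", "ay", "az", "gx", "gy", "gz")
  stat_names <- names(extract_window_features(c(0, 0)))
  cols <- as.vector(outer(stat_names, channels, function(s, ch) paste(ch, s, sep = "_")))
  rows <- list(); ys <- list(); gs <- list()
  for (entry in dataset) {
    tr <- entry$trial
    sig <- cbind(tr$accel, tr$gyro)
    win <- sliding_windows(tr$n_samples, window)
    m <- matrix(NA_real_, nrow(win), length(cols))
    for (i in seq_len(nrow(win))) {
      idx <- (win$start[i] + 1L):win$end[i]
      m[i, ] <- as.vector(vapply(1:6, function(ch)
        extract_window_features(sig[idx, ch], abs_diff), numeric(11)))
    }
    rows[[length(rows) + 1L]] <- m
    ys[[length(ys) + 1L]] <- entry$labels$labels[win$labeled_frame + 1L]
    gs[[length(gs) + 1L]] <- rep(entry$trial$subject_id, nrow(win))
  }
  x <- do.call(rbind, rows)
  colnames(x) <- cols
  structure(list(x = x, y = as.integer(unlist(ys)), group = unlist(gs),
                 feature_names = cols),
            class = "feature_table")
}

#' Drop highly correlated feature columns
#'
#' Scans columns in order; a later column whose absolute Pearson correlation
#' with any already-kept column exceeds `r_threshold` is dropped (keep-first
#' rule, deterministic). Zero-variance columns correlate with nothing
#' (treated as r = 0) and are kept. The returned `dropped` list is what must
#' be applied verbatim to any other table (validation or test) so that no
#' test-set information enters the selection.
#'
#' @param x numeric matrix of training features (>= 2 rows).
#' @param r_threshold absolute-correlation cutoff, default 0.9.
#' @return list with character vectors `kept` and `dropped`.
#' @export
prune_correlated <- function(x, r_threshold = 0.9) {
  stopifnot(nrow(x) >= 2)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("V", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  kept <- integer()
  dropped <- integer()
  for (j in seq_len(ncol(x))) {
    drop_it <- FALSE
    if (sds[j] > 0 && length(kept)) {
      usable <- kept[sds[kept] > 0]
      if (length(usable)) {
        r <- abs(suppressWarnings(stats::cor(x[, j], x[, usable, drop = FALSE])))
        drop_it <- any(r > r_threshold, na.rm = TRUE)
      }
    }
    if (drop_it) dropped <- c(dropped, j) else kept <- c(kept, j)
  }
  list(kept = cn[kept], dropped = cn[dropped])
}

#' Fit standardisation parameters on training rows
#'
#' @param x numeric training matrix.
#' @return object of class `standardizer` with per-column `mean` and `sd`
#'   (zero sd is replaced by 1 so constant columns are centred only).
#' @export
fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  structure(list(mean = mu, sd = sd), class = "standardizer")
}

#' Apply a fitted standardiser to new rows
#' @param std a `standardizer` from [fit_standardizer()].
#' @param x numeric matrix with the same columns as the training matrix.
#' @return transformed matrix.
#' @export
apply_standardizer <- function(std, x) {
  sweep(sweep(x, 2, std$mean), 2, std$sd, "/")
}
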