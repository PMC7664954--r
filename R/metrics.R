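#' Per-axis RMSE and MAE between two position tracks
#'
#' Both tracks are expressed in the same (trial-start) frame, so residuals
#' are plain differences; no alignment or rotation is applied.
#'
#' @param truth,est [position_track()] objects (or `n x 3` matrices) of equal
#'   length.
#' @return list of numeric length-3 vectors `rmse` and `mae` (metres), named
#'   `x`, `y`, `z`.
#' @export
axis_errors <- function(truth, est) {
  p <- track_matrix(truth); q <- track_matrix(est)
  if (nrow(p) != nrow(q)) stop("tracks differ in length")
  r <- p - q
  rmse <- sqrt(colMeans(r ^ 2)); mae <- colMeans(abs(r))
  names(rmse) <- names(mae) <- c("x", "y", "z")
  list(rmse = rmse, mae = mae)
}

#' 3D trajectory errors: ATE and 3D MAE
#'
#' The absolute trajectory error is the RMSE of the per-timestep Euclidean
#' distances between estimate and truth (a 3D RMSE); the 3D MAE is their
#' plain mean.
#'
#' @inheritParams axis_errors
#' @return list with scalars `ate` and `mae3d` (metres).
#' @export
trajectory_errors <- function(truth, est) {
  p <- track_matrix(truth); q <- track_matrix(est)
  if (nrow(p) != nrow(q)) stop("tracks differ in length")
  d <- sqrt(rowSums((p - q) ^ 2))
  list(ate = sqrt(mean(d ^ 2)), mae3d = mean(d))
}

#' Coefficient of determination of one axis
#'
#' Implemented as the squared Pearson correlation between estimate and truth,
#' which is bounded in [0, 1] and equals 1 for perfect prediction. Note the
#' caveat that an exactly sign-flipped estimate also scores 1. The
#' variance-ratio form `Var(est)/Var(truth)` is available via `form`; the two
#' definitions coincide only when the estimate is a least-squares fit of the
#' truth.
#'
#' @param truth,est numeric vectors (one axis each).
#' @param form `"correlation"` (default) or `"variance_ratio"`.
#' @return scalar, or `NA` when either series has zero variance.
#' @export
r_squared <- function(truth, est, form = c("correlation", "variance_ratio")) {
  form <- match.arg(form)
  if (stats::var(truth) == 0 || (form == "correlation" && stats::var(est) == 0))
    return(NA_real_)
  if (form == "correlation") stats::cor(truth, est) ^ 2
  else stats::var(est) / stats::var(truth)
}

#' Full error report for one trial
#'
#' @inheritParams axis_errors
#' @return an object of class `error_report`: per-axis `rmse`, `mae`, `r2`,
#'   plus 3D `ate` and `mae3d`, `n_samples`, and the per-sample residual
#'   norms in `residual_norms`.
#' @export
error_report <- function(truth, est) {
  p <- track_matrix(truth); q <- track_matrix(est)
  ax <- axis_errors(p, q)
  tr <- trajectory_errors(p, q)
  r2 <- vapply(1:3, function(a) r_squared(p[, a], q[, a]), numeric(1))
  names(r2) <- c("x", "y", "z")
  structure(list(rmse = ax$rmse, mae = ax$mae, r2 = r2,
                 ate = tr$ate, mae3d = tr$mae3d, n_samples = nrow(p),
                 residual_norms = sqrt(rowSums((p - q) ^ 2))),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> n=%d  ATE %.4f m  3D-MAE %.4f m\n", x$n_samples,
              x$ate, x$mae3d))
  m <- rbind(RMSE = x$rmse, MAE = x$mae, R2 = x$r2)
  print(round(m, 4))
  invisible(x)
}

#' Aggregate error reports across trials
#'
#' Mean and sample standard deviation (sd 0 for a single trial) of every
#' metric across trials, the form results tables in this field report.
#'
#' @param reports list of [error_report()] objects (>= 1).
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  grab <- function(r) c(rmse_x = r$rmse[["x"]], rmse_y = r$rmse[["y"]],
                        rmse_z = r$rmse[["z"]],
                        mae_x = r$mae[["x"]], mae_y = r$mae[["y"]],
                        mae_z = r$mae[["z"]],
                        r2_x = r$r2[["x"]], r2_y = r$r2[["y"]], r2_z = r$r2[["z"]],
                        ate = r$ate, mae3d = r$mae3d)
  m <- do.call(rbind, lapply(reports, grab))
  sds <- if (nrow(m) > 1) apply(m, 2, stats::sd, na.rm = TRUE) else rep(0, ncol(m))
  data.frame(metric = colnames(m),
             mean = colMeans(m, na.rm = TRUE),
             sd = sds, row.names = NULL)
}

track_matrix <- function(x) {
  if (inherits(x, "position_track")) x$positions else as_xyz_matrix(x, "track")
}
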