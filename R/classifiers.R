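#' Assign groups to k folds
#'
#' Subjects (groups) are shuffled with the supplied seed and dealt round-robin
#' into `k` folds, so every row of a group lands in exactly one fold and no
#' subject ever straddles the train/validation boundary of a fold.
#'
#' @param group character/factor vector, one group id per row.
#' @param k number of folds (default 3).
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids (1..k) per row.
#' @export
group_kfold <- function(group, k = 3L, seed = 1L) {
  g <- unique(group)
  if (length(g) < k) stop(sprintf("invalid-cv: need >= %d distinct groups", k))
  set.seed(seed)
  g <- sample(g)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(g)), g)
  unname(fold_of[as.character(group)])
}

# ---- kernelised Pegasos SVM -------------------------------------------------
# Stochastic subgradient solver for the L2-regularised hinge loss in the
# kernel dual (Shalev-Shwartz et al.). Small and dependency-free; adequate at
# the window counts this package trains on.

svm_fit <- function(x, y, lambda = 1e-3, gamma = NULL, n_iter = NULL, seed = 1L) {
  y2 <- ifelse(y == 1L, 1, -1)
  n <- nrow(x)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  if (is.null(n_iter)) n_iter <- max(20L * n, 2000L)
  K <- rbf_kernel(x, x, gamma)
  alpha <- numeric(n)
  set.seed(seed)
  picks <- sample.int(n, n_iter, replace = TRUE)
  for (t in seq_len(n_iter)) {
    i <- picks[t]
    margin <- y2[i] * sum(alpha * y2 * K[, i]) / (lambda * t)
    if (margin < 1) alpha[i] <- alpha[i] + 1
  }
  structure(list(alpha = alpha, y = y2, x_sv = x, lambda = lambda,
                 gamma = gamma, n_iter = n_iter),
            class = "zupt_svm")
}

svm_decision <- function(model, x) {
  K <- rbf_kernel(x, model$x_sv, model$gamma)
  as.vector(K %*% (model$alpha * model$y)) / (model$lambda * model$n_iter)
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a ^ 2); bn <- rowSums(b ^ 2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# ---- random forest ----------------------------------------------------------
# Bagged CART with per-node random feature subsets and Gini splitting.

rf_fit <- function(x, y, n_trees = 25L, max_depth = 8L, mtry = NULL,
                   min_node = 5L, seed = 1L) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], y[idx], depth = 0L,
              max_depth = max_depth, mtry = mtry, min_node = min_node)
  })
  structure(list(trees = trees, n_trees = n_trees), class = "zupt_rf")
}

grow_tree <- function(x, y, depth, max_depth, mtry, min_node) {
  n <- length(y)
  p1 <- mean(y == 1L)
  if (depth >= max_depth || n < min_node || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, p = p1))
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_gain <- 0
  gini0 <- 2 * p1 * (1 - p1)
  for (j in feats) {
    o <- order(x[, j])
    xv <- x[o, j]; yv <- (y[o] == 1L)
    cs <- cumsum(yv)
    # candidate splits between distinct consecutive values
    cut_at <- which(diff(xv) > 0)
    if (!length(cut_at)) next
    nl <- cut_at; nr <- n - nl
    pl <- cs[cut_at] / nl; pr <- (cs[n] - cs[cut_at]) / nr
    gain <- gini0 - (nl / n) * 2 * pl * (1 - pl) - (nr / n) * 2 * pr * (1 - pr)
    gi <- which.max(gain)
    if (gain[gi] > best_gain + 1e-12) {
      best_gain <- gain[gi]
      best <- list(j = j, cut = (xv[cut_at[gi]] + xv[cut_at[gi] + 1L]) / 2)
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, p = p1))
  left <- x[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut,
       l = grow_tree(x[left, , drop = FALSE], y[left], depth + 1L,
                     max_depth, mtry, min_node),
       r = grow_tree(x[!left, , drop = FALSE], y[!left], depth + 1L,
                     max_depth, mtry, min_node))
}

tree_prob <- function(node, x) {
  if (node$leaf) return(rep(node$p, nrow(x)))
  out <- numeric(nrow(x))
  left <- x[, node$j] <= node$cut
  if (any(left)) out[left] <- tree_prob(node$l, x[left, , drop = FALSE])
  if (any(!left)) out[!left] <- tree_prob(node$r, x[!left, , drop = FALSE])
  out
}

rf_prob <- function(model, x) {
  rowMeans(vapply(model$trees, tree_prob, numeric(nrow(x)), x = x))
}

# ---- hyperparameter search spaces (documented defaults, overridable) --------

default_search_space <- function(kind) {
  switch(kind,
    lr = list(lambda = function(n) 10 ^ stats::runif(n, -5, 0)),
    svm = list(lambda = function(n) 10 ^ stats::runif(n, -4, -1),
               gamma = function(n) 10 ^ stats::runif(n, -3, 0)),
    rf = list(n_trees = function(n) sample(c(15L, 25L, 50L), n, replace = TRUE),
              max_depth = function(n) sample(4:10, n, replace = TRUE)))
}

# ---- unified window classifier ----------------------------------------------

#' Fit a window classifier with subject-disjoint cross-validation
#'
#' Trains a logistic regression (ridge, via glmnet), an RBF-kernel SVM, or a
#' random forest on a window-feature table. Correlated-feature pruning and
#' standardisation (skipped for the tree model) are fitted inside each
#' training fold and reapplied to its validation fold, and hyperparameters
#' are chosen by group-3-fold cross-validated accuracy using a pluggable,
#' seeded random-search strategy. The final model is refit on all rows with
#' the winning configuration.
#'
#' @param kind `"lr"`, `"svm"` or `"rf"`.
#' @param table a `feature_table` from [build_feature_table()].
#' @param n_search number of random-search configurations.
#' @param search_space named list of samplers (`function(n)`), defaults per
#'   `kind`; supply your own to change the search distribution.
#' @param r_threshold correlation-pruning cutoff.
#' @param seed integer seed controlling folds, search and model randomness.
#' @return object of class `window_classifier` with the fitted model, the
#'   preprocessing (`pruning`, `standardizer`), the winning hyperparameters
#'   and a CV report (`cv`).
#' @export
fit_window_classifier <- function(kind = c("lr", "svm", "rf"), table,
                                  n_search = 8L, search_space = NULL,
                                  r_threshold = 0.9, seed = 1L) {
  kind <- match.arg(kind)
  if (length(unique(table$group)) < 3L)
    stop("invalid-cv: need >= 3 distinct groups")
  folds <- group_kfold(table$group, 3L, seed)
  if (is.null(search_space)) search_space <- default_search_space(kind)
  set.seed(seed + 1L)
  configs <- lapply(seq_len(n_search), function(i)
    lapply(search_space, function(f) f(1)))
  cv_acc <- vapply(configs, function(cfg) {
    accs <- vapply(1:3, function(f) {
      tr <- folds != f; va <- !tr
      prep <- prep_features(table$x[tr, , drop = FALSE], kind, r_threshold)
      xt <- prep$transform(table$x[tr, , drop = FALSE])
      xv <- prep$transform(table$x[va, , drop = FALSE])
      fit <- fit_one(kind, xt, table$y[tr], cfg, seed)
      mean(predict_one(kind, fit, xv) == table$y[va])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- configs[[which.max(cv_acc)]]
  prep <- prep_features(table$x, kind, r_threshold)
  xt <- prep$transform(table$x)
  fit <- fit_one(kind, xt, table$y, best, seed)
  structure(list(kind = kind, fit = fit, pruning = prep$pruning,
                 standardizer = prep$std, hyperparams = best,
                 cv = data.frame(config = seq_along(cv_acc), accuracy = cv_acc),
                 feature_names = colnames(table$x)),
            class = "window_classifier")
}

prep_features <- function(x_train, kind, r_threshold) {
  pruning <- prune_correlated(x_train, r_threshold)
  xk <- x_train[, pruning$kept, drop = FALSE]
  std <- if (kind == "rf") NULL else fit_standardizer(xk)
  transform <- function(x) {
    xk <- x[, pruning$kept, drop = FALSE]
    if (is.null(std)) xk else apply_standardizer(std, xk)
  }
  list(pruning = pruning, std = std, transform = transform)
}

fit_one <- function(kind, x, y, cfg, seed) {
  switch(kind,
    lr = glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = cfg$lambda),
    svm = svm_fit(x, y, lambda = cfg$lambda, gamma = cfg$gamma, seed = seed),
    rf = rf_fit(x, y, n_trees = cfg$n_trees, max_depth = cfg$max_depth,
                seed = seed))
}

predict_one <- function(kind, fit, x) {
  p <- switch(kind,
    lr = as.vector(stats::predict(fit, newx = x, type = "response")),
    svm = 1 / (1 + exp(-svm_decision(fit, x))),
    rf = rf_prob(fit, x))
  as.integer(p > 0.5)
}

#' Predict stopped probabilities / labels for new windows
#'
#' @param object a `window_classifier`.
#' @param x feature matrix with the training columns (pre-pruning).
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return integer labels or numeric probabilities, one per row.
#' @export
predict.window_classifier <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xk <- x[, object$pruning$kept, drop = FALSE]
  if (!is.null(object$standardizer)) xk <- apply_standardizer(object$standardizer, xk)
  p <- switch(object$kind,
    lr = as.vector(stats::predict(object$fit, newx = xk, type = "response")),
    svm = 1 / (1 + exp(-svm_decision(object$fit, xk))),
    rf = rf_prob(object$fit, xk))
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Classify a whole trial with a fitted window classifier
#'
#' Slides the training window over the trial, extracts features, predicts a
#' label per window centre and fills the boundary frames with the nearest
#' label.
#'
#' @param model a `window_classifier`.
#' @param trial an [imu_trial()].
#' @param window the [window_spec()] used at feature-extraction time.
#' @return a [label_sequence()].
#' @export
classify_trial <- function(model, trial, window = window_spec(30L)) {
  ds <- list(list(trial = trial,
                  labels = label_sequence(rep(1L, trial$n_samples))))
  tab <- build_feature_table(ds, window)
  pred <- predict(model, tab$x)
  win <- sliding_windows(trial$n_samples, window)
  labels <- rep(NA_integer_, trial$n_samples)
  labels[win$labeled_frame + 1L] <- pred
  vr <- range(win$labeled_frame) + 1L
  labels[seq_len(vr[1] - 1L)] <- labels[vr[1]]
  if (vr[2] < trial$n_samples) labels[(vr[2] + 1L):trial$n_samples] <- labels[vr[2]]
  # stride > 1 leaves interior gaps: nearest-label fill
  if (anyNA(labels)) labels <- fill_nearest(labels)
  label_sequence(labels, valid_range = vr)
}

fill_nearest <- function(labels) {
  idx <- which(!is.na(labels))
  nearest <- idx[pmax(1L, findInterval(seq_along(labels), idx))]
  # findInterval gives the last labeled index at or before each frame; good
  # enough as "nearest" for gap fill between stride-spaced centres
  labels[is.na(labels)] <- labels[nearest[is.na(labels)]]
  labels
}
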