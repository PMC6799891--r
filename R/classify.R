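#' Training configuration for the live/dead SVM
#'
#' @param cost_grid Regularization values `C` searched by cross-validation.
#' @param gamma_grid Gaussian-kernel widths searched (on normalized
#'   features).
#' @param n_folds Stratified cross-validation folds.
#' @param min_events Minimum recommended number of training events; below
#'   this the model still fits but carries a `small_training` flag.
#' @param normalize Fit and embed a min-max normalizer (recommended).
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost_grid = c(0.1, 1, 10, 100),
                       gamma_grid = c(0.01, 0.1, 1, 10),
                       n_folds = 5L,
                       min_events = 1000L,
                       normalize = TRUE) {
  stopifnot(all(cost_grid > 0), all(gamma_grid > 0), n_folds >= 2)
  structure(list(cost_grid = cost_grid, gamma_grid = gamma_grid,
                 n_folds = as.integer(n_folds),
                 min_events = as.integer(min_events),
                 normalize = isTRUE(normalize)),
            class = "svm_config")
}

stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Train the Gaussian-kernel live/dead classifier
#'
#' Fits a C-classification SVM with a Gaussian (RBF) kernel,
#' `K(u, v) = exp(-gamma * ||u - v||^2)`, to labeled amplitude/phase
#' features (live = 1, dead = 0). Hyperparameters `(C, gamma)` are selected
#' by stratified k-fold cross-validation over a logarithmic grid,
#' maximizing accuracy; ties break toward the smaller `C` then the smaller
#' `gamma`. Features are min-max normalized with statistics learned from
#' the training set and stored in the model, so raw features can be passed
#' at prediction time.
#'
#' @param features Numeric feature matrix (one row per event).
#' @param labels Integer 0/1 labels, one per row; both classes required.
#' @param config An [svm_config()].
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `viability_svm`: the fitted `e1071::svm`
#'   model, the embedded normalizer, the cross-validation table, selected
#'   hyperparameters, and training metadata.
#' @export
train_viability_svm <- function(features, labels, config = svm_config(),
                                seed = 1L) {
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("`labels` must have one entry per feature row", call. = FALSE)
  }
  if (anyNA(features) || anyNA(labels)) {
    stop("features and labels must be complete (no NA)", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("training requires both live (1) and dead (0) events",
         call. = FALSE)
  }
  small <- FALSE
  if (nrow(features) < config$min_events) {
    warning(sprintf("training set has %d events, below the recommended %d",
                    nrow(features), config$min_events), call. = FALSE)
    small <- TRUE
  }

  normalizer <- NULL
  x <- as.matrix(features)
  if (config$normalize) {
    normalizer <- fit_normalizer(x)
    x <- apply_normalizer(normalizer, x)
  }
  y <- factor(labels, levels = c(0L, 1L))

  folds <- stratified_folds(labels, config$n_folds, seed)
  grid <- expand.grid(cost = config$cost_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        type = "C-classification", kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    grid$cv_accuracy[g] <- correct / length(y)
  }
  ord <- order(-grid$cv_accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1], ]

  model <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = best$cost, gamma = best$gamma, scale = FALSE)

  structure(list(model = model,
                 normalizer = normalizer,
                 cv = grid,
                 cost = best$cost,
                 gamma = best$gamma,
                 cv_accuracy = best$cv_accuracy,
                 n_events = nrow(features),
                 feature_names = colnames(features),
                 small_training = small,
                 seed = seed,
                 version = "0.1.0"),
            class = "viability_svm")
}

#' @export
print.viability_svm <- function(x, ...) {
  cat("Gaussian-kernel live/dead SVM\n")
  cat(sprintf("  trained on %d events, %d features\n",
              x$n_events, length(x$feature_names)))
  cat(sprintf("  C = %g, gamma = %g (CV accuracy %.3f)\n",
              x$cost, x$gamma, x$cv_accuracy))
  if (x$small_training) cat("  warning: small training set\n")
  invisible(x)
}

#' Predict live/dead labels for new events
#'
#' Applies the model's embedded normalizer to the raw features and returns
#' hard 0/1 labels (no probability calibration).
#'
#' @param object A [train_viability_svm()] model.
#' @param features Raw (un-normalized) feature matrix with the training
#'   schema.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels, one per row.
#' @export
predict.viability_svm <- function(object, features, ...) {
  x <- as.matrix(features)
  if (ncol(x) != length(object$feature_names)) {
    stop("feature schema does not match the trained model", call. = FALSE)
  }
  if (nrow(x) == 0) return(integer(0))
  if (!is.null(object$normalizer)) x <- apply_normalizer(object$normalizer, x)
  as.integer(as.character(stats::predict(object$model, x)))
}

#' Confusion matrix of live/dead predictions
#'
#' Live (1) is the positive class: `tp` counts events predicted live that
#' are truly live, `tn` events predicted dead that are truly dead.
#'
#' @param predicted,truth Equal-length 0/1 label vectors.
#' @return An object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_matrix <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty label vectors", call. = FALSE)
  p <- as.integer(predicted); t <- as.integer(truth)
  if (!all(p %in% 0:1) || !all(t %in% 0:1)) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(tp = sum(p == 1 & t == 1),
                 tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("live", "dead"),
                              predicted = c("live", "dead")))
  print(m)
  cat(sprintf("accuracy: %.3f\n", accuracy(x)))
  invisible(x)
}

#' Classification accuracy, (TP + TN) / N
#' @param cm A [confusion_matrix()].
#' @return Proportion of correct predictions.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  (cm$tp + cm$tn) / n
}

#' Per-class true-positive and true-negative rates
#'
#' `tp_rate = tp / (tp + fn)` (recall on live cells) and
#' `tn_rate = tn / (tn + fp)` (recall on dead cells).
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `c(tp_rate, tn_rate)`.
#' @export
class_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop("both classes must be present to compute per-class rates",
         call. = FALSE)
  }
  c(tp_rate = cm$tp / (cm$tp + cm$fn),
    tn_rate = cm$tn / (cm$tn + cm$fp))
}

#' Viability percentage of a predicted sample
#'
#' The number of events predicted live (label 1) divided by the total
#' number of events, times 100.
#'
#' @param predicted Vector of 0/1 predicted labels.
#' @return An object of class `viability_estimate` with `n_total`,
#'   `n_predicted_live` and `viability_percent`.
#' @export
viability_percent <- function(predicted) {
  if (length(predicted) == 0) stop("no predictions supplied", call. = FALSE)
  p <- as.integer(predicted)
  if (!all(p %in% 0:1)) stop("labels must be 0 or 1", call. = FALSE)
  structure(list(n_total = length(p),
                 n_predicted_live = sum(p == 1),
                 viability_percent = 100 * sum(p == 1) / length(p)),
            class = "viability_estimate")
}

#' @export
print.viability_estimate <- function(x, ...) {
  cat(sprintf("viability: %.1f%% (%d of %d events predicted live)\n",
              x$viability_percent, x$n_predicted_live, x$n_total))
  invisible(x)
}
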