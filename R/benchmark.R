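#' Generate a labeled feature set by running the full pipeline
#'
#' Simulates a mixed sample, detects and measures its transit events, and
#' returns the features together with matched ground-truth labels.
#' Detected events that cannot be matched to a ground-truth transit are
#' dropped.
#'
#' @inheritParams simulate_sample
#' @param mode Feature mode passed to [build_features()].
#' @param detection A [detection_config()].
#' @param ... Further arguments passed to [simulate_sample()].
#' @return List with `features` (matrix), `labels` (0/1 per row), `truth`,
#'   `events`, and `n_detected`.
#' @export
pipeline_features <- function(n_cells, live_fraction, seed,
                              mode = "both",
                              detection = detection_config(), ...) {
  sim <- simulate_sample(n_cells, live_fraction, seed, ...)
  events <- process_recording(sim$recording, detection)
  labels_all <- match_truth_labels(events, sim$truth,
                                   sim$recording$sampling_rate)
  keep <- events$flag == "ok"
  feats <- suppressMessages(build_features(events, mode))
  labels <- labels_all[keep]
  ok <- !is.na(labels)
  list(features = feats[ok, , drop = FALSE],
       labels = labels[ok],
       truth = sim$truth,
       events = events,
       n_detected = nrow(events))
}

#' Run the full synthetic viability benchmark
#'
#' End-to-end protocol: simulate a balanced training sample and an
#' independent balanced test sample with the default live/dead
#' populations, run detection and feature extraction, train the
#' Gaussian-kernel SVM per feature mode with cross-validated
#' hyperparameters, and evaluate held-out accuracy and per-class rates.
#' Optionally classifies additional mixed samples with the combined-feature
#' model and reports their predicted viability.
#'
#' @param seed Master integer seed; stage seeds are derived from it
#'   (training sample, test sample, one per mixture).
#' @param n_train Events in the balanced training sample (>= 1000 for the
#'   standard benchmark).
#' @param n_test Events in the balanced held-out sample.
#' @param modes Feature modes to evaluate.
#' @param mixtures True live fractions of extra mixed samples classified
#'   with the `"both"`-mode model (requires `"both"` in `modes`), or
#'   `NULL`.
#' @param n_mixture Events per mixed sample.
#' @param config An [svm_config()].
#' @param detection A [detection_config()].
#' @return List with one entry per mode (`model`, `confusion`, `accuracy`,
#'   `rates`, `n_train`, `n_test`) plus `mixtures`: per mixture the true
#'   live fraction and the [viability_percent()] estimate.
#' @export
viability_benchmark <- function(seed = 1L,
                                n_train = 2000L,
                                n_test = 1000L,
                                modes = c("amplitude", "phase", "both"),
                                mixtures = c(0.9, 0.5),
                                n_mixture = 1000L,
                                config = svm_config(),
                                detection = detection_config()) {
  seed <- as.integer(seed)
  train <- pipeline_features(n_train, 0.5, seed * 100L + 1L,
                             mode = "both", detection = detection)
  test <- pipeline_features(n_test, 0.5, seed * 100L + 2L,
                            mode = "both", detection = detection)

  col_sel <- function(mode, x) {
    switch(mode,
           amplitude = x[, grep("^dA_", colnames(x)), drop = FALSE],
           phase = x[, grep("^dphi_", colnames(x)), drop = FALSE],
           both = x)
  }

  out <- list()
  for (mode in modes) {
    xtr <- col_sel(mode, train$features)
    xte <- col_sel(mode, test$features)
    model <- train_viability_svm(xtr, train$labels, config,
                                 seed = seed * 100L + 3L)
    pred <- predict(model, xte)
    cm <- confusion_matrix(pred, test$labels)
    out[[mode]] <- list(model = model,
                        confusion = cm,
                        accuracy = accuracy(cm),
                        rates = class_rates(cm),
                        n_train = nrow(xtr),
                        n_test = nrow(xte))
  }

  out$mixtures <- list()
  if (!is.null(mixtures) && "both" %in% modes) {
    model <- out$both$model
    for (i in seq_along(mixtures)) {
      p <- mixtures[i]
      mix <- pipeline_features(n_mixture, p, seed * 100L + 3L + i,
                               mode = "both", detection = detection)
      pred <- predict(model, mix$features)
      out$mixtures[[i]] <- list(true_live_fraction = p,
                                estimate = viability_percent(pred),
                                n_events = length(pred))
    }
  }
  out
}
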