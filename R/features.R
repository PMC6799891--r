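#' Assemble a feature matrix from detected events
#'
#' Builds the classifier input in one of the three modes: amplitude-change
#' features only, phase-change features only, or the combined 8-feature
#' matrix (amplitude then phase, at each excitation frequency). Events
#' flagged `merged` or `edge` are dropped.
#'
#' @param events A `detected_events` data frame from [process_recording()].
#' @param mode One of `"amplitude"`, `"phase"`, `"both"`.
#' @return A numeric matrix of class `feature_matrix` (rows = usable
#'   events, in input order) with attributes `mode` and `frequencies`.
#'   Column names are `dA_<freq>` / `dphi_<freq>`.
#' @export
build_features <- function(events, mode = c("both", "amplitude", "phase")) {
  mode <- match.arg(mode)
  freqs <- attr(events, "frequencies")
  if (is.null(freqs)) {
    k <- length(grep("^dA_f", names(events)))
    freqs <- seq_len(k)
    labels <- paste0("f", seq_len(k))
  } else {
    labels <- frequency_labels(freqs)
  }
  k <- length(labels)
  keep <- events$flag == "ok"
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("dropping %d flagged event(s) from the feature matrix",
                    n_drop))
  }
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0) warning("no usable events; feature matrix is empty",
                             call. = FALSE)

  amp <- as.matrix(ev[, paste0("dA_f", seq_len(k)), drop = FALSE])
  phs <- as.matrix(ev[, paste0("dphi_f", seq_len(k)), drop = FALSE])
  colnames(amp) <- paste0("dA_", labels)
  colnames(phs) <- paste0("dphi_", labels)
  x <- switch(mode,
              amplitude = amp,
              phase = phs,
              both = cbind(amp, phs))
  rownames(x) <- NULL
  structure(x, mode = mode, frequencies = as.numeric(freqs),
            class = c("feature_matrix", class(x)))
}

#' Learn per-feature min-max normalization from training data
#'
#' Records the training minimum and maximum of each feature so that the
#' training data maps into `[0, 1]`. A constant feature is flagged
#' degenerate and maps to 0.
#'
#' @param train Numeric feature matrix (n_events >= 2).
#' @return An object of class `minmax_norm` with fields `min`, `max`,
#'   `degenerate`, `feature_names`.
#' @export
fit_normalizer <- function(train) {
  if (nrow(train) < 2) stop("need at least 2 training events", call. = FALSE)
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  structure(list(min = mins, max = maxs,
                 degenerate = maxs == mins,
                 feature_names = colnames(train)),
            class = "minmax_norm")
}

#' Apply a fitted min-max normalizer
#'
#' `x' = (x - min) / (max - min)` per feature. Test values outside the
#' training range are deliberately not clipped, so values below the
#' training minimum map below 0 and values above the maximum above 1.
#'
#' @param stats A [fit_normalizer()] object.
#' @param x Feature matrix with the same columns as the training matrix.
#' @return Normalized matrix, attributes preserved.
#' @export
apply_normalizer <- function(stats, x) {
  stopifnot(inherits(stats, "minmax_norm"))
  if (ncol(x) != length(stats$min)) {
    stop("feature count does not match the fitted normalizer", call. = FALSE)
  }
  if (!is.null(stats$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), stats$feature_names)) {
    stop("feature names do not match the fitted normalizer", call. = FALSE)
  }
  range <- stats$max - stats$min
  range[stats$degenerate] <- 1 # degenerate feature maps to 0
  out <- sweep(sweep(x, 2, stats$min, "-"), 2, range, "/")
  out[, stats$degenerate] <- 0
  out
}

#' Invert a min-max normalization (non-degenerate features only)
#' @inheritParams apply_normalizer
#' @return Matrix on the original feature scale.
#' @export
invert_normalizer <- function(stats, x) {
  stopifnot(inherits(stats, "minmax_norm"))
  range <- stats$max - stats$min
  range[stats$degenerate] <- 1
  sweep(sweep(x, 2, range, "*"), 2, stats$min, "+")
}
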