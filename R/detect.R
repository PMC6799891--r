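#' Remove slow baseline trends with a running median
#'
#' Subtracts a running-median baseline from the series. The series is
#' reflection-padded so the output has the same length and no edge bias for
#' trends slower than the window.
#'
#' @param series Numeric time series.
#' @param window Odd window length in samples, `3 <= window <= length`.
#' @return Detrended series, same length.
#' @export
detrend <- function(series, window) {
  check_window(series, window)
  pad <- (window - 1L) / 2L
  padded <- reflect_pad(series, pad)
  base <- stats::runmed(padded, k = window, endrule = "keep")
  series - base[(pad + 1L):(pad + length(series))]
}

#' Suppress white noise with a centered moving average
#'
#' Reflection-padded moving-average smoothing; keep the window well below
#' the transit width so pulse peaks are not attenuated.
#'
#' @inheritParams detrend
#' @return Smoothed series, same length.
#' @export
denoise <- function(series, window) {
  check_window(series, window)
  pad <- (window - 1L) / 2L
  padded <- reflect_pad(series, pad)
  sm <- stats::filter(padded, rep(1 / window, window), sides = 2)
  as.numeric(sm[(pad + 1L):(pad + length(series))])
}

check_window <- function(series, window) {
  if (length(window) != 1L || window %% 2 != 1 || window < 3) {
    stop("`window` must be a single odd integer >= 3", call. = FALSE)
  }
  if (window > length(series)) {
    stop("`window` must not exceed the series length", call. = FALSE)
  }
  invisible(TRUE)
}

reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad == 0L) return(x)
  c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
}

#' Event-detection configuration
#'
#' @param detrend_window Running-median window, samples (odd). Default 2001
#'   (40 ms at 50 kHz), an order of magnitude above the transit width.
#' @param smooth_window Moving-average window, samples (odd). Default 11
#'   (0.22 ms), well below the 1 ms transit width.
#' @param threshold_k Detection threshold in multiples of the robust
#'   (MAD-based) noise scale.
#' @param min_separation Events whose peaks are closer than this many
#'   samples are merged and flagged.
#' @param reference_channel Column index of the detection channel (default
#'   1, the 500 kHz channel).
#' @param baseline_margin Samples of flanking baseline used per side when
#'   measuring an event.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(detrend_window = 2001L,
                             smooth_window = 11L,
                             threshold_k = 5,
                             min_separation = 125L,
                             reference_channel = 1L,
                             baseline_margin = 150L) {
  if (detrend_window %% 2 != 1 || detrend_window < 3 ||
      smooth_window %% 2 != 1 || smooth_window < 3) {
    stop("windows must be odd and >= 3", call. = FALSE)
  }
  if (threshold_k <= 0) stop("`threshold_k` must be positive", call. = FALSE)
  if (min_separation < 1) stop("`min_separation` must be >= 1", call. = FALSE)
  structure(list(detrend_window = as.integer(detrend_window),
                 smooth_window = as.integer(smooth_window),
                 threshold_k = threshold_k,
                 min_separation = as.integer(min_separation),
                 reference_channel = as.integer(reference_channel),
                 baseline_margin = as.integer(baseline_margin)),
            class = "detection_config")
}

#' Detect single-cell transit events in a recording
#'
#' Works on the demodulated amplitude `|I + iQ|` of the reference channel:
#' the series is detrended (running median), denoised (moving average), and
#' transits appear as downward excursions. The noise scale is estimated
#' robustly as `1.4826 x MAD`; excursions exceeding
#' `threshold_k x scale` (with a small floor relative to the largest
#' excursion, so noiseless recordings remain detectable) become candidate
#' peaks. Adjacent candidates are treated as one pulse unless the valley
#' between them drops below half the smaller peak; distinct peaks closer
#' than `min_separation` samples are merged into a single event flagged
#' `"merged"`. Windows are expanded from each peak until the excursion
#' falls below 5% of the peak height; events touching the recording edge
#' are flagged `"edge"`.
#'
#' @param recording An `mf_recording`.
#' @param config A [detection_config()].
#' @return Data frame with columns `start`, `end` (half-open sample-index
#'   window), `peak_index`, `flag` (`ok`, `merged` or `edge`).
#' @export
detect_events <- function(recording, config = detection_config()) {
  stopifnot(inherits(recording, "mf_recording"))
  n <- nrow(recording$signal)
  if (n == 0) stop("recording is empty", call. = FALSE)
  if (n <= config$detrend_window) {
    stop("recording shorter than the detrend window", call. = FALSE)
  }
  amp <- Mod(recording$signal[, config$reference_channel])
  proc <- denoise(detrend(amp, config$detrend_window), config$smooth_window)
  d <- -proc # transits reduce amplitude; work with excursion depth

  scale <- robust_noise_scale(proc)
  dmax <- max(d, 0)
  threshold <- max(config$threshold_k * scale, 0.02 * dmax)
  if (threshold <= 0 || dmax <= threshold) {
    return(empty_windows())
  }

  peaks <- find_pulse_peaks(d, threshold)
  if (length(peaks) == 0) return(empty_windows())

  # cluster peaks closer than min_separation -> merged events
  cluster <- cumsum(c(1L, as.integer(diff(peaks) >= config$min_separation)))
  starts <- integer(0); ends <- integer(0); pk <- integer(0)
  flags <- character(0)
  for (cl in unique(cluster)) {
    members <- peaks[cluster == cl]
    main <- members[which.max(d[members])]
    lo <- expand_edge(d, min(members), -1L, 0.05 * d[main], threshold)
    hi <- expand_edge(d, max(members), +1L, 0.05 * d[main], threshold)
    starts <- c(starts, lo)
    ends <- c(ends, hi + 1L) # half-open [start, end)
    pk <- c(pk, main)
    flags <- c(flags, if (length(members) > 1L) "merged" else "ok")
  }
  edge <- starts <= config$baseline_margin | ends > n - config$baseline_margin
  flags[edge & flags == "ok"] <- "edge"
  data.frame(start = starts, end = ends, peak_index = pk, flag = flags,
             stringsAsFactors = FALSE)
}

# 1.4826 x MAD, iteratively re-estimated after excluding samples beyond
# 3x the current scale so that a high transit duty cycle does not inflate
# the baseline noise estimate
robust_noise_scale <- function(x, n_iter = 2L) {
  scale <- stats::mad(x)
  if (scale == 0) return(0)
  center <- stats::median(x)
  for (i in seq_len(n_iter)) {
    keep <- abs(x - center) <= 3 * scale
    if (sum(keep) < 10) break
    center <- stats::median(x[keep])
    s <- stats::mad(x[keep], center = center)
    if (s == 0) break
    scale <- s
  }
  scale
}

empty_windows <- function() {
  data.frame(start = integer(0), end = integer(0), peak_index = integer(0),
             flag = character(0), stringsAsFactors = FALSE)
}

# local maxima above threshold; neighbours without a real valley between
# them (dip above half the smaller peak) collapse to the higher one
find_pulse_peaks <- function(d, threshold) {
  n <- length(d)
  if (n < 3) return(integer(0))
  core <- d[2:(n - 1)]
  is_max <- core > d[1:(n - 2)] & core >= d[3:n] & core > threshold
  cand <- which(is_max) + 1L
  if (length(cand) <= 1) return(cand)
  keep <- cand[1]
  for (i in 2:length(cand)) {
    prev <- keep[length(keep)]
    cur <- cand[i]
    valley <- min(d[prev:cur])
    if (valley > 0.5 * min(d[prev], d[cur])) {
      if (d[cur] > d[prev]) keep[length(keep)] <- cur
    } else {
      keep <- c(keep, cur)
    }
  }
  keep
}

expand_edge <- function(d, from, step, stop_level, threshold) {
  lim <- min(stop_level, threshold)
  i <- from
  n <- length(d)
  while (i + step >= 1L && i + step <= n && d[i + step] > lim) {
    i <- i + step
  }
  i
}

#' Measure amplitude and phase changes of one detected event
#'
#' For every frequency channel (all channels share the time base because
#' demodulation is simultaneous): the baseline is the per-component median
#' of `I + iQ` over `baseline_margin` samples flanking the window on both
#' sides; the peak is the denoised complex value at the reference channel's
#' extremal-amplitude index, shared across channels. If no flanking
#' baseline is available on one side the event is flagged `"edge"` and the
#' available side is used alone.
#'
#' @param recording An `mf_recording`.
#' @param window Integer vector `c(start, end)`, a half-open sample window.
#' @param config A [detection_config()].
#' @param smoothed Optional pre-computed denoised complex matrix (same shape
#'   as `recording$signal`), to avoid re-filtering per event.
#' @return One-row data frame: `start`, `end`, `peak_index`, `flag`,
#'   `baseline_I_f*`, `baseline_Q_f*`, `dA_f*`, `dphi_f*`.
#' @export
measure_event <- function(recording, window, config = detection_config(),
                          smoothed = NULL) {
  stopifnot(inherits(recording, "mf_recording"))
  n <- nrow(recording$signal)
  start <- window[1]; end <- window[2]
  if (start < 1 || end > n + 1 || start >= end) {
    stop("`window` must be a valid half-open interval within the recording",
         call. = FALSE)
  }
  k_freq <- ncol(recording$signal)
  m <- config$baseline_margin
  left <- seq.int(max(1L, start - m), start - 1L)
  left <- left[left >= 1]
  right <- seq.int(end, min(n, end + m - 1L))
  flag <- "ok"
  if (length(left) < m / 2 || length(right) < m / 2) flag <- "edge"
  base_idx <- c(left, right)
  if (length(base_idx) == 0) {
    stop("no flanking baseline samples available", call. = FALSE)
  }

  if (is.null(smoothed)) {
    lo <- max(1L, start - config$smooth_window)
    hi <- min(n, end + config$smooth_window - 1L)
    slice <- recording$signal[lo:hi, , drop = FALSE]
    sm <- apply_smooth_complex(slice, config$smooth_window)
    offset <- lo - 1L
  } else {
    sm <- smoothed
    offset <- 0L
  }

  base <- complex(real = apply(Re(recording$signal[base_idx, , drop = FALSE]),
                               2, stats::median),
                  imaginary = apply(Im(recording$signal[base_idx, ,
                                                        drop = FALSE]),
                                    2, stats::median))

  win_idx <- start:(end - 1L)
  ref_amp <- Mod(sm[win_idx - offset, config$reference_channel])
  peak_rel <- which.max(abs(ref_amp - Mod(base[config$reference_channel])))
  peak_index <- win_idx[peak_rel]
  peak <- sm[peak_index - offset, ]

  d_a <- vapply(seq_len(k_freq),
                function(j) amplitude_change(base[j], peak[j]), numeric(1))
  d_phi <- vapply(seq_len(k_freq),
                  function(j) phase_change(base[j], peak[j]), numeric(1))

  out <- data.frame(start = start, end = end, peak_index = peak_index,
                    flag = flag, stringsAsFactors = FALSE)
  for (j in seq_len(k_freq)) out[[paste0("baseline_I_f", j)]] <- Re(base[j])
  for (j in seq_len(k_freq)) out[[paste0("baseline_Q_f", j)]] <- Im(base[j])
  for (j in seq_len(k_freq)) out[[paste0("dA_f", j)]] <- d_a[j]
  for (j in seq_len(k_freq)) out[[paste0("dphi_f", j)]] <- d_phi[j]
  out
}

apply_smooth_complex <- function(signal, window) {
  if (nrow(signal) <= window) return(signal)
  out <- signal
  for (j in seq_len(ncol(signal))) {
    out[, j] <- complex(real = denoise(Re(signal[, j]), window),
                        imaginary = denoise(Im(signal[, j]), window))
  }
  out
}

#' Normalized amplitude change between baseline and pulse peak
#'
#' `| |baseline| - |peak| | / |baseline|`: the fractional change in
#' demodulated amplitude during a transit, reported sign-free so the
#' feature is independent of channel gain and pulse polarity.
#'
#' @param baseline_complex,peak_complex Complex demodulated values.
#' @param signed If `TRUE`, keep the sign of `|baseline| - |peak|` (for
#'   diagnostics).
#' @return Amplitude change as a fraction of the baseline amplitude.
#' @export
amplitude_change <- function(baseline_complex, peak_complex, signed = FALSE) {
  b <- Mod(baseline_complex)
  if (b == 0) stop("baseline amplitude is zero", call. = FALSE)
  delta <- (b - Mod(peak_complex)) / b
  if (signed) delta else abs(delta)
}

#' Phase change between baseline and pulse peak
#'
#' `arg(peak) - arg(baseline)` via the four-quadrant arctangent, wrapped to
#' `(-180, 180]` degrees.
#'
#' @inheritParams amplitude_change
#' @return Phase change in degrees.
#' @export
phase_change <- function(baseline_complex, peak_complex) {
  if (Mod(baseline_complex) == 0 || Mod(peak_complex) == 0) {
    stop("phase undefined at zero amplitude", call. = FALSE)
  }
  d <- (Arg(peak_complex) - Arg(baseline_complex)) * 180 / pi
  wrap_degrees(d)
}

wrap_degrees <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Detect and measure all events in a recording
#'
#' Runs [detect_events()] and [measure_event()] over a recording, sharing
#' one denoised copy of all channels.
#'
#' @inheritParams detect_events
#' @return A data frame of class `detected_events` (one row per event, the
#'   [measure_event()] schema) with the recording's frequencies attached as
#'   attribute `frequencies`. Flags from detection (`merged`, `edge`)
#'   override the per-event measurement flag.
#' @export
process_recording <- function(recording, config = detection_config()) {
  windows <- detect_events(recording, config)
  freqs <- as.numeric(recording$frequencies)
  if (nrow(windows) == 0) {
    out <- empty_measurement(ncol(recording$signal))
    attr(out, "frequencies") <- freqs
    class(out) <- c("detected_events", "data.frame")
    return(out)
  }
  sm <- apply_smooth_complex(recording$signal, config$smooth_window)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    r <- measure_event(recording, c(windows$start[i], windows$end[i]),
                       config, smoothed = sm)
    if (windows$flag[i] != "ok") r$flag <- windows$flag[i]
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "frequencies") <- freqs
  class(out) <- c("detected_events", "data.frame")
  out
}

empty_measurement <- function(k_freq) {
  cols <- c("start", "end", "peak_index", "flag",
            paste0("baseline_I_f", seq_len(k_freq)),
            paste0("baseline_Q_f", seq_len(k_freq)),
            paste0("dA_f", seq_len(k_freq)),
            paste0("dphi_f", seq_len(k_freq)))
  vals <- c(list(integer(0), integer(0), integer(0), character(0)),
            rep(list(numeric(0)), 4 * k_freq))
  as.data.frame(stats::setNames(vals, cols), stringsAsFactors = FALSE)
}

#' Match detected events to ground-truth transits
#'
#' Assigns each detected event the label of the nearest ground-truth
#' transit whose center lies within `tolerance` seconds of the detected
#' peak; unmatched events get `NA`.
#'
#' @param events A `detected_events` data frame.
#' @param truth A `cell_events` ground-truth table.
#' @param sampling_rate Sampling rate of the recording, Hz.
#' @param tolerance Maximum |peak time - center| for a match, seconds.
#'   Default one mean transit width.
#' @return Integer vector of labels (0/1/NA), one per detected event.
#' @export
match_truth_labels <- function(events, truth, sampling_rate,
                               tolerance = mean(truth$width)) {
  if (nrow(events) == 0) return(integer(0))
  peak_t <- (events$peak_index - 1) / sampling_rate
  vapply(peak_t, function(p) {
    if (nrow(truth) == 0) return(NA_integer_)
    i <- which.min(abs(truth$center_time - p))
    if (abs(truth$center_time[i] - p) <= tolerance) {
      as.integer(truth$label[i])
    } else {
      NA_integer_
    }
  }, integer(1))
}
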