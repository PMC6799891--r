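#' Draw ground-truth single-cell transit events for a mixed sample
#'
#' Samples a population of cell transits with a known live fraction. Exactly
#' `round(n_cells * live_fraction)` events are live (label 1); labels are
#' randomly interleaved in time. Event centers are uniform over the usable
#' duration subject to a minimum pairwise separation, so transits never
#' overlap in the default benchmark. Per-event amplitude changes are
#' lognormal and phase changes Gaussian, drawn per frequency from the
#' event's class parameters.
#'
#' @param live_pop,dead_pop [population_params()] for the two classes.
#' @param live_fraction Proportion of live cells in `[0, 1]`.
#' @param n_cells Number of transits to draw.
#' @param duration Recording duration, seconds.
#' @param seed Integer seed; identical seeds reproduce the draw exactly.
#' @param n_freq Number of excitation frequencies (columns of the
#'   per-frequency draws).
#' @param min_separation Minimum center-to-center separation, seconds.
#'   Default 5x the live-population mean transit width.
#' @param edge_margin Keep-out zone at both ends of the recording, seconds.
#' @return A data frame of class `cell_events` with one row per transit:
#'   `center_time`, `width`, `label`, then `dA_f1..dA_fK` and
#'   `dphi_f1..dphi_fK`.
#' @export
sample_events <- function(live_pop, dead_pop, live_fraction, n_cells,
                          duration, seed,
                          n_freq = length(live_pop$delta_a_median),
                          min_separation = 5 * live_pop$transit_width_mean,
                          edge_margin = 0.05) {
  stopifnot(inherits(live_pop, "population_params"),
            inherits(dead_pop, "population_params"))
  if (live_fraction < 0 || live_fraction > 1) {
    stop("`live_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (n_cells < 0) stop("`n_cells` must be non-negative", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (length(live_pop$delta_a_median) != n_freq ||
      length(dead_pop$delta_a_median) != n_freq) {
    stop("population parameter vectors must match `n_freq`", call. = FALSE)
  }

  empty <- empty_events(n_freq)
  if (n_cells == 0) return(empty)

  span <- duration - 2 * edge_margin - (n_cells - 1) * min_separation
  if (span <= 0) {
    stop(sprintf(paste0("cannot place %d events with %.3g s separation in a ",
                        "%.3g s recording"),
                 n_cells, min_separation, duration), call. = FALSE)
  }

  n_live <- round(n_cells * live_fraction)
  withr::with_seed(seed, {
    # sorted uniforms + cumulative offsets: uniform conditional on separation
    u <- sort(stats::runif(n_cells, 0, span))
    centers <- edge_margin + u + (seq_len(n_cells) - 1L) * min_separation
    labels <- sample(rep(c(1L, 0L), c(n_live, n_cells - n_live)))
    widths <- numeric(n_cells)
    d_a <- matrix(0, n_cells, n_freq)
    d_phi <- matrix(0, n_cells, n_freq)
    for (i in seq_len(n_cells)) {
      pop <- if (labels[i] == 1L) live_pop else dead_pop
      w <- stats::rnorm(1, pop$transit_width_mean, pop$transit_width_sd)
      widths[i] <- max(w, 0.2 * pop$transit_width_mean)
      d_a[i, ] <- stats::rlnorm(n_freq, meanlog = log(pop$delta_a_median),
                                sdlog = pop$delta_a_logsd)
      d_phi[i, ] <- stats::rnorm(n_freq, pop$delta_phi_mean, pop$delta_phi_sd)
    }
  })

  out <- data.frame(center_time = centers, width = widths, label = labels)
  colnames(d_a) <- paste0("dA_f", seq_len(n_freq))
  colnames(d_phi) <- paste0("dphi_f", seq_len(n_freq))
  out <- cbind(out, as.data.frame(d_a), as.data.frame(d_phi))
  class(out) <- c("cell_events", "data.frame")
  out
}

empty_events <- function(n_freq) {
  cols <- c("center_time", "width", "label",
            paste0("dA_f", seq_len(n_freq)),
            paste0("dphi_f", seq_len(n_freq)))
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                       cols))
  class(out) <- c("cell_events", "data.frame")
  out
}

#' Synthesize a multifrequency lock-in recording from ground-truth events
#'
#' Forward model: per excitation frequency `f` the noiseless demodulated
#' signal is
#' `s_f(t) = B_f * (1 - sum_k dA_{f,k} g_k(t)) * exp(i (phi_f + sum_k dphi_{f,k} g_k(t)))`
#' where `B_f exp(i phi_f)` is the baseline set by the equivalent circuit
#' (amplitude proportional to `1/|Z(f)|`, normalized so the first channel's
#' baseline is 1) and `g_k` is a unit-peak Gaussian of standard deviation
#' `width_k` centered on the event. Transits reduce the demodulated
#' amplitude (a cell raises the channel impedance, reducing the measured
#' current). Slow sinusoidal drift, mains interference and white Gaussian
#' noise are added per [noise_config()].
#'
#' @param events A `cell_events` data frame from [sample_events()].
#' @param params [circuit_params()] setting the per-frequency baselines.
#' @param freqs [frequency_set()] of excitation frequencies.
#' @param noise [noise_config()]; use `noise_config(0, 0, 10, 0)` for a
#'   noiseless recording.
#' @param sampling_rate Demodulated sampling rate, Hz.
#' @param duration Recording duration, seconds.
#' @param seed Integer seed for the noise stream (independent of the event
#'   stream used by [sample_events()]).
#' @return An object of class `mf_recording`: list with `sampling_rate`,
#'   `duration`, `frequencies`, a complex `n x K` matrix `signal`
#'   (`I + iQ` per channel), and `meta`.
#' @export
synthesize_recording <- function(events, params = circuit_params(),
                                 freqs = frequency_set(),
                                 noise = noise_config(),
                                 sampling_rate = 5e4, duration, seed = 1L) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(noise, "noise_config"))
  freqs <- frequency_set(as.numeric(freqs))
  if (nrow(events) > 0) {
    if (any(events$center_time < 0 | events$center_time > duration)) {
      stop("all event centers must lie within the recording duration",
           call. = FALSE)
    }
    min_width <- min(events$width)
    if (sampling_rate < 50 / (10 * min_width)) {
      stop("sampling rate too low to resolve the narrowest transit",
           call. = FALSE)
    }
  }

  n <- round(sampling_rate * duration)
  tt <- (seq_len(n) - 1L) / sampling_rate
  k_freq <- length(freqs)

  z <- circuit_impedance(params, as.numeric(freqs))
  # demodulated amplitude ~ excitation / |Z|; gain fixed so channel 1 is 1.0
  b <- Mod(z[1]) / Mod(z)
  phi0 <- -Arg(z)

  # accumulate per-channel pulse trains over +-6 widths of each event
  sum_a <- matrix(0, n, k_freq)
  sum_p <- matrix(0, n, k_freq)
  if (nrow(events) > 0) {
    d_a <- as.matrix(events[, paste0("dA_f", seq_len(k_freq)), drop = FALSE])
    d_phi <- as.matrix(events[, paste0("dphi_f", seq_len(k_freq)),
                              drop = FALSE])
    for (k in seq_len(nrow(events))) {
      ctr <- events$center_time[k]
      w <- events$width[k]
      i0 <- max(1L, floor((ctr - 6 * w) * sampling_rate) + 1L)
      i1 <- min(n, ceiling((ctr + 6 * w) * sampling_rate) + 1L)
      idx <- i0:i1
      g <- exp(-((tt[idx] - ctr)^2) / (2 * w^2))
      sum_a[idx, ] <- sum_a[idx, ] + outer(g, d_a[k, ])
      sum_p[idx, ] <- sum_p[idx, ] + outer(g, d_phi[k, ])
    }
  }

  drift <- noise$drift_amplitude * sin(2 * pi * tt / noise$drift_period)
  mains <- noise$mains_amplitude *
    sin(2 * pi * noise$mains_frequency * tt)

  signal <- matrix(complex(real = 0), n, k_freq)
  withr::with_seed(seed, {
    for (j in seq_len(k_freq)) {
      amp <- b[j] * (1 - sum_a[, j] + drift + mains)
      ph <- phi0[j] + sum_p[, j] * pi / 180
      re <- amp * cos(ph)
      im <- amp * sin(ph)
      if (noise$white_sd > 0) {
        re <- re + stats::rnorm(n, 0, noise$white_sd * b[j])
        im <- im + stats::rnorm(n, 0, noise$white_sd * b[j])
      }
      signal[, j] <- complex(real = re, imaginary = im)
    }
  })
  colnames(signal) <- frequency_labels(freqs)

  structure(list(sampling_rate = sampling_rate,
                 duration = duration,
                 frequencies = freqs,
                 signal = signal,
                 meta = list(seed = seed, generator = "impedocyte-sim",
                             version = "0.1.0")),
            class = "mf_recording")
}

#' @export
print.mf_recording <- function(x, ...) {
  cat("Multifrequency impedance recording\n")
  cat(sprintf("  %d samples at %g kHz (%.3g s), %d channels: %s\n",
              nrow(x$signal), x$sampling_rate / 1e3, x$duration,
              ncol(x$signal), paste(colnames(x$signal), collapse = ", ")))
  invisible(x)
}

#' Simulate a complete labeled sample (events + recording)
#'
#' Convenience wrapper around [sample_events()] and
#' [synthesize_recording()]. The event stream uses `seed` and the noise
#' stream `seed + 1`, so the same event set can be re-synthesized under
#' different noise settings.
#'
#' @inheritParams sample_events
#' @inheritParams synthesize_recording
#' @param duration Recording duration, seconds; by default sized to hold the
#'   requested events at roughly 100 transits per second.
#' @return List with elements `recording` (an `mf_recording`) and `truth`
#'   (the `cell_events` ground-truth table).
#' @export
simulate_sample <- function(n_cells, live_fraction, seed,
                            live_pop = default_live_population(),
                            dead_pop = default_dead_population(),
                            params = circuit_params(),
                            freqs = frequency_set(),
                            noise = noise_config(),
                            sampling_rate = 5e4,
                            duration = NULL,
                            min_separation = 5 * live_pop$transit_width_mean) {
  if (is.null(duration)) {
    # ~50 transits/s: keeps the pulse duty cycle low enough that the
    # running-median baseline stays on the inter-event level
    duration <- 0.2 + n_cells * 4 * min_separation
  }
  truth <- sample_events(live_pop, dead_pop, live_fraction, n_cells,
                         duration, seed, n_freq = length(freqs),
                         min_separation = min_separation)
  rec <- synthesize_recording(truth, params, freqs, noise,
                              sampling_rate, duration, seed = seed + 1L)
  list(recording = rec, truth = truth)
}
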