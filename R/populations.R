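#' Class-conditional response parameters of a cell population
#'
#' Describes how one class of cells (live or dead) perturbs the demodulated
#' signal at each excitation frequency during a transit. Amplitude changes
#' are drawn lognormal (hence strictly positive), expressed as a fraction of
#' the channel baseline amplitude; phase changes are drawn Gaussian, in
#' degrees. Transit widths (Gaussian pulse standard deviation, seconds) are
#' drawn Gaussian and truncated away from zero.
#'
#' @param label Class label: 1 = live, 0 = dead.
#' @param delta_a_median Per-frequency median amplitude change (fraction of
#'   baseline); the lognormal log-mean is `log(delta_a_median)`.
#' @param delta_a_logsd Per-frequency lognormal log-SD of the amplitude
#'   change.
#' @param delta_phi_mean Per-frequency mean phase change, degrees.
#' @param delta_phi_sd Per-frequency SD of the phase change, degrees.
#' @param transit_width_mean,transit_width_sd Mean and SD of the transit
#'   pulse width, seconds.
#' @param n_freq Number of excitation frequencies the vectors must match.
#' @return An object of class `population_params`.
#' @seealso [default_live_population()], [default_dead_population()]
#' @export
population_params <- function(label,
                              delta_a_median,
                              delta_a_logsd,
                              delta_phi_mean,
                              delta_phi_sd,
                              transit_width_mean = 1e-3,
                              transit_width_sd = 2e-4,
                              n_freq = length(delta_a_median)) {
  if (!label %in% c(0L, 1L)) stop("`label` must be 0 (dead) or 1 (live)",
                                  call. = FALSE)
  delta_a_logsd <- rep_len(delta_a_logsd, n_freq)
  delta_phi_sd <- rep_len(delta_phi_sd, n_freq)
  if (length(delta_a_median) != n_freq || length(delta_phi_mean) != n_freq) {
    stop("per-frequency parameter vectors must match the frequency set length",
         call. = FALSE)
  }
  if (any(delta_a_median <= 0) || any(delta_a_logsd <= 0) ||
      any(delta_phi_sd <= 0)) {
    stop("amplitude medians, log-SDs and phase SDs must be positive",
         call. = FALSE)
  }
  if (transit_width_mean <= 0 || transit_width_sd <= 0) {
    stop("transit widths must be positive", call. = FALSE)
  }
  structure(list(label = as.integer(label),
                 delta_a_median = as.numeric(delta_a_median),
                 delta_a_logsd = as.numeric(delta_a_logsd),
                 delta_phi_mean = as.numeric(delta_phi_mean),
                 delta_phi_sd = as.numeric(delta_phi_sd),
                 transit_width_mean = transit_width_mean,
                 transit_width_sd = transit_width_sd),
            class = "population_params")
}

#' Default live-cell population at 500 kHz / 20 / 25 / 30 MHz
#'
#' Live cells produce larger amplitude changes than dead cells at the high
#' frequencies that probe the cell interior, and a phase change that is
#' negative at 500 kHz and positive at 20-30 MHz.
#'
#' @return A [population_params()] object with label 1.
#' @export
default_live_population <- function() {
  population_params(label = 1L,
                    delta_a_median = c(0.012, 0.018, 0.019, 0.020),
                    delta_a_logsd = 0.25,
                    delta_phi_mean = c(-2.0, 3.0, 3.5, 4.0),
                    delta_phi_sd = 1.0)
}

#' Default dead-cell population at 500 kHz / 20 / 25 / 30 MHz
#' @return A [population_params()] object with label 0.
#' @export
default_dead_population <- function() {
  population_params(label = 0L,
                    delta_a_median = c(0.010, 0.011, 0.011, 0.012),
                    delta_a_logsd = 0.25,
                    delta_phi_mean = c(-1.0, 1.0, 1.2, 1.5),
                    delta_phi_sd = 1.0)
}

#' Additive disturbance configuration for synthesized recordings
#'
#' All amplitudes are expressed as fractions of the per-channel baseline
#' amplitude. White Gaussian noise is added independently to the in-phase
#' and quadrature components; drift is a slow sinusoid on the demodulated
#' amplitude; the mains term models residual 60 Hz coupling.
#'
#' @param white_sd SD of the white noise (fraction of baseline).
#' @param drift_amplitude Amplitude of the slow baseline drift (fraction).
#' @param drift_period Period of the drift sinusoid, seconds.
#' @param mains_amplitude Amplitude of the mains interference (fraction).
#' @param mains_frequency Mains frequency, Hz.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(white_sd = 1e-3,
                         drift_amplitude = 0.01,
                         drift_period = 10,
                         mains_amplitude = 5e-4,
                         mains_frequency = 60) {
  if (white_sd < 0 || drift_amplitude < 0 || mains_amplitude < 0) {
    stop("noise amplitudes must be non-negative", call. = FALSE)
  }
  if (drift_period <= 0 || mains_frequency <= 0) {
    stop("drift period and mains frequency must be positive", call. = FALSE)
  }
  structure(list(white_sd = white_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 mains_amplitude = mains_amplitude,
                 mains_frequency = mains_frequency),
            class = "noise_config")
}
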