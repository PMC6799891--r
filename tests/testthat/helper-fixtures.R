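# shared fixtures, built once per test run

no_noise <- function() noise_config(white_sd = 0, drift_amplitude = 0,
                                    drift_period = 10, mains_amplitude = 0)

# a single live transit centered exactly on a sample, no noise
single_event_recording <- function(d_a = c(0.02, 0.025, 0.025, 0.03),
                                   d_phi = c(-2, 3, 3.5, 4),
                                   width = 1e-3, sr = 5e4) {
  center <- 2500 / sr # exactly on the sample grid
  ev <- data.frame(center_time = center, width = width, label = 1L)
  for (j in 1:4) ev[[paste0("dA_f", j)]] <- d_a[j]
  for (j in 1:4) ev[[paste0("dphi_f", j)]] <- d_phi[j]
  class(ev) <- c("cell_events", "data.frame")
  list(events = ev,
       recording = synthesize_recording(ev, noise = no_noise(),
                                        sampling_rate = sr, duration = 0.1,
                                        seed = 1L))
}

# cached default-population sample shared across signal/feature tests
.fixture_cache <- new.env(parent = emptyenv())

default_sample_200 <- function() {
  if (is.null(.fixture_cache$s200)) {
    .fixture_cache$s200 <- simulate_sample(200, 0.5, seed = 42)
  }
  .fixture_cache$s200
}

default_events_200 <- function() {
  if (is.null(.fixture_cache$e200)) {
    .fixture_cache$e200 <- process_recording(default_sample_200()$recording)
  }
  .fixture_cache$e200
}
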