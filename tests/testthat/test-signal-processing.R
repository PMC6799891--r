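test_that("detrend removes constants and slow trends but keeps pulses", {
  expect_equal(detrend(rep(3.7, 100), 11), rep(0, 100))

  # a linear ramp spanning many windows leaves at most half a window of rise
  n <- 1000
  ramp <- seq(0, 1, length.out = n)
  out <- detrend(ramp, 101)
  expect_lte(max(abs(out)), 1 / (n - 1) * 51)

  # ramp + Gaussian pulse, window 10x the pulse extent: height within 2%
  m <- 6000
  h <- 0.5
  ramp2 <- seq(0, 1, length.out = m)
  pulse <- h * exp(-((seq_len(m) - 3000)^2) / (2 * 10^2))
  rec <- detrend(ramp2 + pulse, 601)
  expect_equal(max(rec), h, tolerance = 0.02)
})

test_that("denoise preserves constants, bounds oscillations, shrinks noise", {
  expect_equal(denoise(rep(-1.5, 50), 5), rep(-1.5, 50))

  alt <- rep(c(1, -1), 50)
  expect_lte(max(abs(denoise(alt, 3)[2:99])), 1 / 3 + 1e-12)

  set.seed(1)
  x <- rnorm(1e5, sd = 2)
  expect_equal(sd(denoise(x, 9)), 2 / sqrt(9), tolerance = 0.2)
})

test_that("detrend and denoise validate their windows", {
  expect_error(detrend(1:10, 4), "odd")
  expect_error(detrend(1:10, 11), "length")
  expect_error(denoise(1:10, 2), "odd")
})

test_that("detrend and denoise are shift-equivariant away from edges", {
  set.seed(2)
  x <- rnorm(500) + sin(seq(0, 4 * pi, length.out = 500))
  shift <- 37
  xs <- c(x[(shift + 1):500], x[1:shift]) # circular shift stand-in
  core <- 100:300
  for (fn in list(function(v) detrend(v, 51), function(v) denoise(v, 7))) {
    a <- fn(x)
    b <- fn(xs)
    expect_equal(b[core], a[core + shift], tolerance = 1e-10)
  }
})

test_that("noise-only recordings yield no detections", {
  empty <- sample_events(default_live_population(),
                         default_dead_population(), 0.5, 0,
                         duration = 2, seed = 5)
  rec <- synthesize_recording(empty, duration = 2, seed = 5)
  expect_equal(nrow(detect_events(rec)), 0)
})

test_that("well-separated pulses are all recovered near their true centers", {
  sim <- default_sample_200()
  ev <- default_events_200()
  expect_equal(nrow(ev), 200) # recall 1 and precision 1 at SNR >= 10
  expect_true(all(ev$flag == "ok"))
  sr <- sim$recording$sampling_rate
  peak_t <- (ev$peak_index - 1) / sr
  d <- vapply(peak_t,
              function(p) min(abs(sim$truth$center_time - p)), numeric(1))
  expect_true(all(d <= sim$truth$width[1] * 0 + mean(sim$truth$width)))
})

test_that("two overlapping pulses merge into a single flagged event", {
  sr <- 5e4
  cfg <- detection_config()
  gap <- cfg$min_separation / 2 / sr
  # narrow pulses so the two transits are individually resolvable peaks
  ev <- data.frame(center_time = c(0.05, 0.05 + gap), width = 3e-4,
                   label = 1L)
  for (j in 1:4) ev[[paste0("dA_f", j)]] <- 0.02
  for (j in 1:4) ev[[paste0("dphi_f", j)]] <- 2
  class(ev) <- c("cell_events", "data.frame")
  rec <- synthesize_recording(ev, noise = no_noise(), sampling_rate = sr,
                              duration = 0.1, seed = 1)
  out <- detect_events(rec, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$flag, "merged")
})

test_that("events at the recording edge are flagged and measured one-sided", {
  sr <- 5e4
  ev <- data.frame(center_time = 0.002, width = 1e-3, label = 1L)
  for (j in 1:4) ev[[paste0("dA_f", j)]] <- 0.03
  for (j in 1:4) ev[[paste0("dphi_f", j)]] <- 3
  class(ev) <- c("cell_events", "data.frame")
  rec <- synthesize_recording(ev, noise = no_noise(), sampling_rate = sr,
                              duration = 0.1, seed = 1)
  out <- process_recording(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$flag, "edge")
  expect_gt(out$dA_f1, 0.02)
})

test_that("noiseless round trip recovers dA within 0.5% and dphi within 0.05 deg", {
  fx <- single_event_recording()
  out <- process_recording(fx$recording)
  expect_equal(nrow(out), 1)
  for (j in 1:4) {
    truth_a <- fx$events[[paste0("dA_f", j)]]
    truth_p <- fx$events[[paste0("dphi_f", j)]]
    expect_lt(abs(out[[paste0("dA_f", j)]] - truth_a) / truth_a, 0.005)
    expect_lt(abs(out[[paste0("dphi_f", j)]] - truth_p), 0.05)
  }
})

test_that("a window over flat baseline measures ~zero changes", {
  empty <- sample_events(default_live_population(),
                         default_dead_population(), 0.5, 0,
                         duration = 1, seed = 6)
  rec <- synthesize_recording(empty, noise = no_noise(), duration = 1,
                              seed = 6)
  out <- measure_event(rec, c(20000, 20400))
  expect_lt(out$dA_f1, 1e-10)
  expect_lt(abs(out$dphi_f1), 1e-8)
})

test_that("amplitude_change follows direct magnitude arithmetic", {
  expect_equal(amplitude_change(1 + 0i, 0.98 + 0i), 0.02)
  expect_equal(amplitude_change(1 + 0i, 1 + 0i), 0)
  expect_equal(amplitude_change(3 + 4i, 2.97 + 3.96i), 0.01)
  expect_equal(amplitude_change(1 + 0i, 1.05 + 0i, signed = TRUE), -0.05)
  expect_error(amplitude_change(0 + 0i, 1 + 0i), "zero")
})

test_that("phase_change uses four-quadrant arithmetic with wrap to (-180, 180]", {
  expect_equal(phase_change(1 + 0i, 0 + 1i), 90)
  expect_equal(phase_change(2 - 3i, 2 - 3i), 0)
  b <- complex(modulus = 1, argument = 179 * pi / 180)
  p <- complex(modulus = 1, argument = -179 * pi / 180)
  expect_equal(phase_change(b, p), 2, tolerance = 1e-10)
  expect_error(phase_change(0 + 0i, 1i), "zero")

  # wrap property on a grid of rotations, arbitrary base point
  x <- 0.3 - 1.7i
  for (theta in seq(-179, 180, by = 13.5)) {
    rot <- x * complex(modulus = 1, argument = theta * pi / 180)
    expect_equal(phase_change(x, rot), theta, tolerance = 1e-9)
  }
})

test_that("extracted phase means reproduce the low/high frequency sign flip", {
  ev <- default_events_200()
  sim <- default_sample_200()
  labels <- match_truth_labels(ev, sim$truth, sim$recording$sampling_rate)
  for (lab in c(0, 1)) {
    sub <- ev[which(labels == lab), ]
    expect_lt(mean(sub$dphi_f1), 0)
    expect_gt(mean(sub$dphi_f2), 0)
    expect_gt(mean(sub$dphi_f3), 0)
    expect_gt(mean(sub$dphi_f4), 0)
  }
  # live amplitude change exceeds dead at 20-30 MHz
  lv <- ev[which(labels == 1), ]; dd <- ev[which(labels == 0), ]
  for (j in 2:4) {
    expect_gt(mean(lv[[paste0("dA_f", j)]]), mean(dd[[paste0("dA_f", j)]]))
  }
})
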