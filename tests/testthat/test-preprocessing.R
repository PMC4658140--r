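# helper: single-channel recording holding given waveform(s)
rec_of <- function(x, rate = 250) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  eeg_recording(m, rate, paste0("E", seq_len(nrow(m))))
}
sine_amp <- function(x) {
  # amplitude of a sinusoid from RMS of the central half (avoids edge transients)
  n <- length(x)
  core <- x[round(n / 4):round(3 * n / 4)]
  sqrt(2) * sqrt(mean(core^2))
}

test_that("band-pass keeps the passband, kills DC, notch kills 50 Hz", {
  t <- seq(0, 8, by = 1 / 250)[-1]
  s10 <- sin(2 * pi * 10 * t)
  s50 <- sin(2 * pi * 50 * t)

  bp10 <- bandpass_filter(rec_of(s10))
  expect_equal(sine_amp(bp10$data[1, ]), 1, tolerance = 0.05)

  dc <- bandpass_filter(rec_of(rep(3, length(t))))
  expect_lt(abs(mean(dc$data)), 0.05)

  nt50 <- notch_filter(rec_of(s50))
  expect_lt(sine_amp(nt50$data[1, ]), 0.1)   # > 90% attenuation

  nt10 <- notch_filter(rec_of(s10))
  expect_equal(sine_amp(nt10$data[1, ]), 1, tolerance = 0.02)

  expect_error(bandpass_filter(rec_of(s10), low_hz = 40, high_hz = 30), "cutoffs")
  expect_error(bandpass_filter(rec_of(s10), high_hz = 200), "cutoffs")
})

test_that("downsampling preserves duration and passband content", {
  t <- seq(0, 10, by = 1 / 1000)[-1]     # 10 s at 1000 Hz = 10000 samples
  r <- rec_of(sin(2 * pi * 5 * t), rate = 1000)
  d <- downsample(r, 250)
  expect_equal(ncol(d$data), 2500)
  expect_equal(d$rate, 250)
  expect_equal(sine_amp(d$data[1, ]), 1, tolerance = 0.02)

  expect_identical(downsample(r, 1000), r)   # target = original rate
  expect_error(downsample(r, 2000), "target rate")

  # event markers remap onto the decimated grid
  r$events <- data.frame(sample = c(1000L, 5000L), label = c("a", "b"))
  d2 <- downsample(r, 250)
  expect_equal(d2$events$sample, c(251L, 1251L), tolerance = 1)
})

test_that("spherical-spline interpolation reproduces constants and smooth fields", {
  lay <- generate_sensor_layout(64, seed = 5)

  # constant topography: interpolated value equals the constant
  const <- matrix(7, 64, 10)
  out <- interpolate_channels(const, lay, "E10")
  expect_equal(out[10, ], rep(7, 10), tolerance = 1e-6)
  # good channels untouched
  expect_identical(out[-10, ], const[-10, ])

  # zero bad channels: identity
  expect_identical(interpolate_channels(const, lay, character(0)), const)

  # the 5-of-125 cap
  lay125 <- generate_sensor_layout(125, seed = 1)
  x125 <- matrix(0, 125, 4)
  expect_error(interpolate_channels(x125, lay125, paste0("E", 1:6)),
               "refusing to interpolate")
  expect_silent(interpolate_channels(x125, lay125, paste0("E", 1:5)))

  # leave-one-out on a smooth (low spatial frequency) field
  field <- function(p) 4 * p[, 3] + 2 * p[, 1] * p[, 2] + p[, 2]
  truth <- field(lay$positions)
  err <- vapply(seq_len(64), function(i) {
    est <- interpolate_channels(matrix(truth, 64, 1), lay, lay$channel_names[i],
                                max_fraction = 1 / 64)
    abs(est[i, 1] - truth[i])
  }, numeric(1))
  expect_lt(stats::median(err), 0.05 * diff(range(truth)))
})

test_that("average reference zeroes the channel mean and is idempotent", {
  x <- matrix(rnorm(5 * 20), 5, 20)
  y <- rereference_average(x)
  expect_equal(colMeans(y), rep(0, 20), tolerance = 1e-12)
  expect_equal(rereference_average(y), y, tolerance = 1e-12)

  two <- matrix(c(3, 1), nrow = 2, ncol = 4)
  expect_equal(rereference_average(two),
               matrix(c(1, -1), nrow = 2, ncol = 4), tolerance = 1e-12)

  expect_error(rereference_average(matrix(1, 1, 5)), ">= 2 channels")
})

test_that("artifact detection applies the step, window and amplitude rules", {
  dt <- 4  # ms at 250 Hz
  quiet <- matrix(0, 3, 250)
  expect_false(detect_artifacts(quiet, dt_ms = dt)$rejected)

  # 200 uV jump between adjacent samples = 50 uV/ms > 25
  jump <- quiet; jump[2, 100:250] <- 200
  res <- detect_artifacts(jump, dt_ms = dt)
  expect_true(res$rejected)
  expect_true("step" %in% res$rules)

  # slow ramp to 80 uV over 150 ms: window rule (80 > 75) but not bounds
  ramp <- matrix(0, 1, 250)
  ramp[1, 100:137] <- seq(0, 80, length.out = 38)  # ~2.1 uV/ms
  ramp[1, 138:250] <- 80
  res2 <- detect_artifacts(ramp, dt_ms = dt)
  expect_true("window" %in% res2$rules)
  expect_false("amplitude" %in% res2$rules)
  expect_false("step" %in% res2$rules)

  # 160 uV exceeds the +/-150 uV bound
  high <- quiet; high[1, ] <- 149; high[1, 42] <- 160
  res3 <- detect_artifacts(high, criteria = rejection_criteria(max_step = 25),
                           dt_ms = dt)
  expect_true("amplitude" %in% res3$rules)
})

test_that("loosening every rejection threshold never rejects more epochs", {
  lay <- tiny_layout(6)
  rec <- simulate_continuous_eeg(lay, 20, 250,
                                 events = data.frame(time = seq(1, 19, 0.5),
                                                     label = "x"),
                                 noise_sd = 30, seed = 7)
  eps <- make_epochs(rec)
  tight <- rejection_criteria(max_step = 5, max_window_diff = 40,
                              amp_low = -60, amp_high = 60)
  loose <- rejection_criteria(max_step = 10, max_window_diff = 80,
                              amp_low = -120, amp_high = 120)
  r_tight <- sum(vapply(reject_epochs(eps, tight), `[[`, FALSE, "rejected"))
  r_loose <- sum(vapply(reject_epochs(eps, loose), `[[`, FALSE, "rejected"))
  expect_lte(r_loose, r_tight)
})

test_that("epoching yields the exact sample count on a half-open window", {
  lay <- tiny_layout(4)
  rec <- simulate_continuous_eeg(lay, 10, 250,
                                 events = data.frame(time = c(2, 5),
                                                     label = c("cue", "fb")),
                                 seed = 3)
  eps <- make_epochs(rec, tmin_ms = -200, tmax_ms = 800)
  expect_length(eps, 2)
  expect_equal(ncol(eps[[1]]$data), 250)
  expect_equal(eps[[1]]$time_axis[1], -200)
  expect_equal(diff(eps[[1]]$time_axis)[1], 4)
  expect_lt(max(eps[[1]]$time_axis), 800)

  one <- make_epochs(rec, tmin_ms = 0, tmax_ms = 4)
  expect_equal(ncol(one[[1]]$data), 1)

  # event at the very start: no pre-stimulus data, epoch skipped
  rec$events <- data.frame(sample = 1L, label = "early")
  expect_warning(none <- make_epochs(rec), "skipped")
  expect_length(none, 0)
})

test_that("epoch averaging is the arithmetic mean of surviving epochs", {
  mk <- function(data, cond, subj, rejected = FALSE) {
    structure(list(data = data, time_axis = seq(0, by = 4, length.out = ncol(data)),
                   condition_label = cond, subject_id = subj, rejected = rejected,
                   rules = character(0)), class = "erp_epoch")
  }
  x <- matrix(rnorm(12), 3, 4)
  groups <- c(S1 = "A", S2 = "A", S3 = "B", S4 = "B")

  eps <- c(lapply(c("S1", "S2", "S3", "S4"), function(s) mk(x, "gain", s)),
           lapply(c("S1", "S2", "S3", "S4"), function(s) mk(x, "gain", s)),
           lapply(c("S1", "S2", "S3", "S4"), function(s) mk(-x, "loss", s)),
           lapply(c("S1", "S2", "S3", "S4"), function(s) mk(x, "loss", s)))
  ds <- average_epochs(eps, paste0("E", 1:3), groups)
  # identical epochs average to themselves; (x, -x) averages to zero
  expect_equal(ds$data[1, 1, , ], x)
  expect_equal(ds$data[2, 2, , ], matrix(0, 3, 4))

  # rejected epochs are excluded; empty cells raise a named error
  eps2 <- c(lapply(c("S1", "S2", "S3", "S4"), function(s) mk(x, "gain", s)),
            list(mk(5 * x, "gain", "S1", rejected = TRUE)))
  ds2 <- average_epochs(eps2, paste0("E", 1:3), groups)
  expect_equal(ds2$data[1, 1, , ], x)
  eps3 <- list(mk(x, "gain", "S1", rejected = TRUE),
               lapply(c("S2", "S3", "S4"), function(s) mk(x, "gain", s)))
  eps3 <- c(eps3[1], eps3[[2]])
  expect_error(average_epochs(eps3, paste0("E", 1:3), groups),
               "subject 'S1', condition 'gain'")
})

test_that("variance of an n-epoch average shrinks like 1/n", {
  set.seed(99)
  n_rep <- 400
  v1 <- replicate(n_rep, mean(matrix(rnorm(8), 2, 4)^2))
  v8 <- replicate(n_rep, {
    eps <- lapply(1:8, function(i) matrix(rnorm(8), 2, 4))
    mean(Reduce(`+`, eps)^2 / 64)
  })
  expect_equal(mean(v8) / mean(v1), 1 / 8, tolerance = 0.2)
})

test_that("the preprocessing chain is deterministic end-to-end", {
  lay <- tiny_layout(6)
  run <- function() {
    rec <- simulate_continuous_eeg(lay, 12, 500,
                                   events = data.frame(time = seq(1, 11, 0.8),
                                                       label = rep(c("gain", "loss"), 7)[1:13]),
                                   noise_sd = 4, seed = 17)
    rec <- bandpass_filter(rec)
    rec <- notch_filter(rec)
    rec <- downsample(rec, 250)
    rec$data <- rereference_average(
      interpolate_channels(rec$data, lay, "E3", max_fraction = 1 / 6))
    eps <- reject_epochs(make_epochs(rec, subject_id = "S1"))
    lapply(eps, `[[`, "data")
  }
  expect_identical(run(), run())
})
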