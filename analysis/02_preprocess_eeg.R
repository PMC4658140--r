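#!/usr/bin/env Rscript
# Exercise the preprocessing chain end-to-end on simulated continuous EEG:
# 1-30 Hz band-pass (12/24 dB/oct), 50 Hz notch, downsampling 1000 -> 250 Hz,
# spherical-spline repair of a bad channel, average reference, semi-automatic
# artifact rejection (25 uV/ms step, 75 uV / 200 ms window, +/-150 uV bounds)
# and [-200, 800) ms epoching. Known artifacts are injected, so the rejection
# report can be scored against ground truth. Writes results/preprocessing/.

suppressPackageStartupMessages(library(erptfce))

out_dir <- "results/preprocessing"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

layout <- generate_sensor_layout(32, seed = seed)
write_sensor_layout(layout, file.path(out_dir, "layout.sfp"))

events <- data.frame(time = seq(2, 118, by = 2),
                     label = rep(c("gain", "loss"), length.out = 59))
artifacts <- data.frame(
  type = c("step", "out_of_range", "drift"),
  channel = c("E5", "E12", "E20"),
  time = c(10.1, 30.1, 50.1),
  amplitude = c(200, 170, 90),
  duration_ms = c(400, 400, 1500)
)
rec <- simulate_continuous_eeg(layout, duration_s = 120, sampling_rate_hz = 1000,
                               events = events, artifacts = artifacts,
                               noise_sd = 4, seed = seed)

rec <- bandpass_filter(rec)        # NB: attenuates slow drifts too
rec <- notch_filter(rec)
rec <- downsample(rec, 250)
rec$data <- rereference_average(
  interpolate_channels(rec$data, layout, "E7", max_fraction = 2 / 32))

epochs <- reject_epochs(make_epochs(rec, subject_id = "S01"))
write_rejection_report(epochs, file.path(out_dir, "rejection_report.tsv"))

n_rej <- sum(vapply(epochs, `[[`, FALSE, "rejected"))
cat(sprintf("%d of %d epochs rejected\n", n_rej, length(epochs)))
cat("epochs are", ncol(epochs[[1]]$data), "samples long at 250 Hz\n")
art_windows <- round(artifacts$time)
flagged <- which(vapply(epochs, `[[`, FALSE, "rejected"))
cat("rejected epoch indices:", flagged, "\n")
cat("injected artifact times (s):", artifacts$time, "-> event indices",
    findInterval(artifacts$time, events$time), "\n")

write_manifest(file.path(out_dir, "manifest.json"), "preprocess",
               list(n_channels = 32, rate_in = 1000, rate_out = 250,
                    artifacts = artifacts), seed)
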