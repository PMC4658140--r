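#!/usr/bin/env Rscript
# Build the synthetic group study the inference stages analyse: 3 groups x
# 12 subjects x 2 feedback conditions on a reduced 32-channel, 50-sample
# grid, with two injected group effects mimicking the structure of the real
# findings — an early (~160 ms) and a later (~250 ms) posterior group
# difference that grows from HC through NC to PD, identical in both
# conditions. Writes the dataset (text matrices + JSON metadata) under
# results/erp_study/.

suppressPackageStartupMessages(library(erptfce))

out_dir <- "results/erp_study"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260927L

layout <- generate_sensor_layout(32, seed = 7)
# 50-sample crop of the feedback epoch covering both effect windows
time_axis <- seq(100, by = 4, length.out = 50)    # 100..296 ms

# posterior channel cluster (lowest z on the back half of the cap)
post <- order(layout$positions[, 3] + layout$positions[, 2])[1:6]
roi_early <- layout$channel_names[post[1:4]]
roi_late <- layout$channel_names[post[2:6]]

amp_cells <- function(a) matrix(a * c(0, 0, 0.6, 0.6, 1, 1), 3, 2, byrow = TRUE,
                                dimnames = list(c("HC", "NC", "PD"),
                                                c("gain", "loss")))
effects <- list(
  effect_spec(roi_early, c(132, 180), amp_cells(2.5)),
  effect_spec(roi_late, c(244, 280), amp_cells(3.5))
)
# the 244-280 ms window must sit inside the axis; extend if needed
stopifnot(max(time_axis) >= 280)

dataset <- simulate_erp_dataset(layout, c(HC = 12, NC = 12, PD = 12),
                                c("gain", "loss"), effects = effects,
                                time_axis = time_axis, seed = seed)
write_erp_dataset(dataset, out_dir)
cat("wrote", file.path(out_dir, "dataset.json"), "\n")
print(dataset)
cat("early effect channels:", roi_early, "(132-180 ms)\n")
cat("late effect channels:", roi_late, "(244-280 ms)\n")

write_manifest(file.path(out_dir, "manifest.json"), "simulate-erp",
               list(n_channels = 32, n_samples = 50,
                    roi_early = roi_early, roi_late = roi_late,
                    amplitudes_uV = c(early = 2.5, late = 3.5)), seed)
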