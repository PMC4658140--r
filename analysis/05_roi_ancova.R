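#!/usr/bin/env Rscript
# Post-hoc ROI models on the simulated group study: amplitudes averaged over
# the early (132-180 ms) and late (244-280 ms) posterior windows, a
# repeated-measures ANCOVA with group and the group-orthogonalized age and
# sleepiness constructs, planned pairwise group contrasts, and the extended
# model adding a (simulated) cue-component amplitude as a third covariate.
# Writes effect/contrast tables under results/roi_ancova/.

suppressPackageStartupMessages(library(erptfce))

in_dir <- "results/erp_study"
out_dir <- "results/roi_ancova"
if (!file.exists(file.path(in_dir, "dataset.json"))) {
  stop("run analysis/03_simulate_erp_study.R first", call. = FALSE)
}
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260929L

dataset <- read_erp_dataset(in_dir)
manifest <- jsonlite::read_json(file.path(in_dir, "manifest.json"),
                                simplifyVector = TRUE)
rois <- list(early = roi_spec(manifest$params$roi_early, c(132, 180)),
             late = roi_spec(manifest$params$roi_late, c(244, 280)))

age_c <- orthogonalize_covariate(dataset$covariates$age, dataset$groups)
ess_c <- orthogonalize_covariate(dataset$covariates$ess, dataset$groups)
# stand-in cue component: a synthetic subject-level salience marker
cue <- with(list(s = seed), {set.seed(s); rnorm(nrow(dataset$covariates))})

pairs <- list(c("HC", "NC"), c("HC", "PD"), c("NC", "PD"))
for (nm in names(rois)) {
  dv <- roi_average(dataset, rois[[nm]])
  fit <- rm_ancova(dv, dataset$groups,
                   covariates = data.frame(age = age_c, ess = ess_c))
  ct <- planned_contrasts(fit, pairs)
  write_ancova_result(fit, file.path(out_dir, paste0(nm, "_ancova.tsv")), ct)
  cat(sprintf("== %s component (%s, %g-%g ms) ==\n", nm,
              paste(rois[[nm]]$channels, collapse = " "),
              rois[[nm]]$window[1], rois[[nm]]$window[2]))
  print(fit)
  print(ct, row.names = FALSE)

  fit3 <- rm_ancova(dv, dataset$groups,
                    covariates = data.frame(age = age_c, ess = ess_c),
                    extra_covariates = data.frame(cue = cue))
  write_ancova_result(fit3, file.path(out_dir, paste0(nm, "_ancova_cue.tsv")))
  g_row <- fit3$effects[fit3$effects$effect == "group", ]
  cat(sprintf("with cue covariate: group F(%d,%d) = %.3f, p = %.4g\n\n",
              g_row$df_num, g_row$df_den, g_row$F, g_row$p))
}

write_manifest(file.path(out_dir, "manifest.json"), "roi-ancova",
               list(rois = lapply(rois, unclass), pairs = pairs), seed)
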