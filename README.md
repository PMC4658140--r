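# erptfce

Mass-univariate statistics for event-related potentials (ERPs) with
threshold-free cluster enhancement (TFCE) and max-statistic permutation
inference, plus everything needed to exercise that machinery without any
recorded data: a synthetic ERP/EEG generator with known injected effects, a
deterministic preprocessing chain, ROI ANCOVA models with
group-orthogonalized covariates, and a simulator of the adaptive
incentive-delay reward task.

The package is aimed at EEG researchers who compare patient groups on
channel x time ERP maps — for example reward-feedback components such as the
feedback-related negativity (FRN) across a healthy control group and two
patient groups — and who need familywise-error control over all
channel-sample pairs without picking an arbitrary cluster-forming threshold.

## The statistics at the core

At every channel-time point `(c, t)` a two-way mixed-design ANOVA is fitted
with a between-subject group factor (g levels, n per group) and a
within-subject condition factor (k levels). Group is tested against the
subject-within-group stratum, condition and interaction against the
condition x subject stratum, giving the familiar df pattern
`F(g-1, N-g)` for group (e.g. `F(2, 33)` for 3 x 12 subjects).

Each F map is then TFCE-enhanced over the sensor adjacency graph:

    TFCE(p) = sum over h = dh, 2dh, ..., max(F) of  e(p, h)^E * h^H * dh

where `e(p, h)` is the size of the connected supra-threshold cluster
containing `p` at height `h` (connectivity: neighbouring channels at the
same sample, or adjacent samples at the same channel), with the standard
sensor-space defaults `E = 0.5`, `H = 2`, 100 steps.

Familywise inference uses a two-step permutation scheme: within every
subject the condition labels are permuted, then whole subjects are
reassigned to groups. For each permutation the full ANOVA-TFCE chain is
recomputed and its map-wide maximum recorded; every point's corrected
p-value is `(1 + #{null max >= observed}) / (n_permutations + 1)`.

ROI follow-up models average amplitudes over named channels and a closed
time window and fit a repeated-measures ANCOVA in two strata, with
subject-level covariates (age, sleepiness score) centered within group so
they are orthogonal to the group factor — each fitted covariate costs one
between-subject error df (33 with none, 31 with two, 30 with three, at
3 x 12 subjects).

The task simulator implements the adaptive incentive-delay design: four cue
types (+5/+1/-1/-5 points), success iff the response beats the current
deadline, and a +/-33 ms staircase on that deadline which converges on the
responder's median reaction time, holding success near 50%.

## Worked example

The numbered drivers under `analysis/` run the whole workflow at a reduced
scale (32 channels, 50 samples, 500 permutations) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate_task.R      # behaviour + staircase calibration
Rscript analysis/02_preprocess_eeg.R     # filters, rejection, epoching
Rscript analysis/03_simulate_erp_study.R # 3 x 12 x 2 dataset, known effects
Rscript analysis/04_tfce_inference.R     # ANOVA -> TFCE -> permutation
Rscript analysis/05_roi_ancova.R         # ROI ANCOVA + planned contrasts
```

`03` injects two posterior group effects (132-180 ms and 244-280 ms windows,
amplitudes growing HC < NC < PD). `04` then prints, for the group effect:

    [group] peak E21 at 260 ms, F = 41.90, min corrected p = 0.001996, 118 sig points

— the detected peak sits inside the later injected window, and the
significant points concentrate on the injected support, while condition and
interaction maps (no injected effect) stay empty. `05` prints the ROI
follow-up for the late component:

    group F(2, 31) = 13.989, p = 4.68e-05
    HC - PD contrast: estimate = -2.99 uV, p = 9.4e-06
    with cue covariate: group F(2, 30) = 14.076

matching the expected df bookkeeping (31 with the two orthogonalized
covariates, 30 after adding a third) and recovering the injected group
ordering.

`01` prints the staircase calibration over 36 simulated sessions:

    pooled post-burn-in success rate: 0.501 (staircase target 0.50)

## Package layout

* `R/` — sensor layouts and adjacency graphs, the synthetic-data generators,
  preprocessing, the mixed-ANOVA engine, TFCE + permutation, ROI ANCOVA,
  the task simulator, text-format IO.
* `src/tfce.cpp` — the TFCE flood-fill, in C++ because the permutation loop
  evaluates it hundreds of thousands of times.
* `vignettes/erp-tfce-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the simulations do and do not show.
* `tests/testthat/` — oracle-based unit tests, property tests, and the
  calibration suites (familywise error, effect recovery, staircase).
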