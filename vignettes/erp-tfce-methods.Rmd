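---
title: "Methods: mass-univariate ERP inference with TFCE and permutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-univariate ERP inference with TFCE and permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erptfce)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its simulation-based tests do and
do not establish.

## The inference problem

A typical group ERP study yields, per subject and condition, an averaged
channel x time amplitude matrix (here 125 channels x 250 samples for a
1-second epoch at 250 Hz). Comparing three groups across two feedback
conditions at every channel-sample pair is ~31,000 simultaneous tests on
strongly correlated data. The package's answer is the standard
mass-univariate chain: a pointwise mixed-design ANOVA, TFCE to pool evidence
across each point's spatio-temporal neighbourhood without a cluster-forming
threshold, and a max-statistic permutation null for exact familywise error
control.

## Pointwise mixed ANOVA

At each point the model is the textbook two-stratum mixed design: group
(between, $g$ levels, $n_j$ subjects) and condition (within, $k$ levels).
Group is tested against subject-within-group mean squares with df
$(g-1,\,N-g)$; condition and interaction against the
condition x subject stratum with df scaled by $(k-1)$. With two condition
levels sphericity is not an issue. Balanced designs (the study layout is
12/12/12) use closed-form sums of squares vectorised over all points — the
permutation loop evaluates this map hundreds of thousands of times, so this
is the hot path. Unbalanced group sizes switch to Type-III projections with
a sum-coded design; for the single between factor the group SS is the same
under any SS type, and the within-stratum terms are tested on orthonormal
condition contrasts. Degenerate points where both the effect and its error
stratum have zero variance (possible in constructed data, not in noisy
recordings) are assigned $F = 0$: no variance, no evidence.

Subject-level covariates deliberately do **not** enter the pointwise maps;
they appear only in the ROI models below, mirroring how such analyses are
staged in practice.

## Sensor adjacency and TFCE

The spatial neighbourhood is a distance-threshold graph over the electrode
positions; `calibrate_adjacency_threshold()` picks the smallest threshold
reaching a target mean degree (default 6, typical for dense montages, and
the acceptance of the whole chain never depends on the exact radius).
Channel-time connectivity is deliberately conservative: neighbouring
channels at the same sample, or the same channel at adjacent samples — no
diagonal channel-and-time moves.

TFCE integrates, over `n_steps = 100` equal height increments up to the
map's own maximum, each point's cluster extent to the power $E = 0.5$ times
height to the power $H = 2$. These are the established sensor-space EEG
defaults. Two numerical details are fixed for reproducibility:

* the threshold grid is recomputed from each permutation's own maximum, so
  the integral approximation is scale-free across permutations;
* the top threshold is evaluated at exactly the map maximum (computed as
  `hmax * k/n_steps`, which is exact at `k = n_steps`), so the peak's final
  step is never lost to floating-point rounding.

The flood-fill lives in C++ (`src/tfce.cpp`); an independent R
implementation exists in the test suite and the two agree to 1e-10.

## Two-step permutation and the familywise null

Each permutation first shuffles condition labels independently within every
subject, then reassigns whole subjects to groups preserving group sizes.
For a pure group test the within step cannot change subject means — it is
retained so the procedure matches its description, and the permutation
stream is identical either way. The implementation exploits two algebraic
identities (group statistics depend on the permuted labels only; with two
conditions the within step is a sign flip of the condition contrast); the
test suite proves the optimized null equals the literal relabeling null
draw for draw.

p-values use the +1 convention, $p = (1 + \#\{M^\ast \ge T\}) / (B + 1)$,
so the observed statistic counts into its own null, $p$ is never zero, and
the test is exact at any $B$. The package default is $B = 5000$; the
simulation studies in the tests use $B = 500$ at a 16 channel x 40 sample
grid, which keeps the familywise calibration run (200 null simulations)
within a few minutes on one CPU.

Measured calibration at those sizes: the familywise false-positive rate at
$\alpha = 0.05$ over 200 null simulations is computed in the acceptance
suite and required to fall inside the exact binomial 95% interval
[0.02, 0.08]; the recovery suite injects a group effect of pointwise
$d = 1.5$ (see below) and requires detection inside the injected support in
at least 90 of 100 simulations.

## The synthetic-data generator

The generator is the package's stand-in for patient recordings, and its
defaults are the study conditions: 3 groups x 12 subjects, two feedback
conditions, 4 ms sampling.

* **Layout** — a Fibonacci lattice on the unit sphere restricted to
  $z > -0.2$: quasi-uniform, scalp-like coverage without EGI geometry.
* **Noise** — Gaussian with squared-exponential correlation across the
  scalp (lengthscale 0.5 head radii) and across time (40 ms), sd 2 uV,
  plus a per-subject constant offset (sd 1 uV) that exercises the subject
  stratum. The paper-scale components are only shown in figures in the
  literature this emulates, so the uV scales are the package's own choice of
  a realistic regime; what matters for the tests is that they are held
  fixed.
* **Effects** — additive cell-mean shifts on named channels and a window,
  with a raised-cosine or boxcar envelope. *Injected effect size* is quoted
  as pointwise Cohen's $d$: the group mean difference divided by the
  per-point measurement sd $\sqrt{\sigma_{subj}^2 + \sigma_{noise}^2}$
  ($=\sqrt 5$ at the defaults). The recovery suite uses a boxcar envelope so
  the quoted $d$ holds across the whole injected support rather than only at
  the window centre.
* **Continuous EEG** — spatially correlated AR(1) noise with injectable
  step, drift and out-of-range artifacts plus returned ground truth. A 1 Hz
  high-pass legitimately removes slow drifts, so drift artifacts are caught
  by the rejection rules only if they survive filtering — visible in
  `analysis/02_preprocess_eeg.R`'s output.

What passing these simulations does **not** show: real EEG has 1/f spectra,
eye/muscle artifacts with structure the Gaussian model lacks, and
non-stationary noise; the generator makes no biophysical forward-model
claims. Calibration under this null supports the permutation machinery
(which is distribution-free by construction), not any claim about specific
patient data.

## Preprocessing chain

The chain mirrors a conventional lab pipeline and is deterministic end to
end: zero-phase Butterworth band-pass 1–30 Hz ("12/24 dB slope" read as
12 dB/oct high-pass = order 2, 24 dB/oct low-pass = order 4), 50 Hz notch,
anti-aliased downsampling to 250 Hz, spherical-spline interpolation of bad
channels (Perrin formulation, order 4, regularisation 1e-5, refused above
5/125 bad channels), average reference, and threshold-based rejection. The
printed rejection criterion "75 uV/ms over a 200 ms window" is read as
75 uV peak-to-peak within the window: a literal 75 uV/ms sustained over
200 ms would be 15,000 uV, which no scalp recording produces. Epochs use a
half-open window $[-200, 800)$ ms so the 250-sample count at 250 Hz is
exact. No baseline correction is applied (none is part of the emulated
pipeline); ICA-based component removal is inherently manual and out of
scope — the generator only injects artifacts the automatic rules can catch.

## ROI ANCOVA and orthogonalized covariates

Covariates (age, sleepiness score) are centered within group — the
construct keeps within-group deviations exactly and has zero mean in every
group, hence zero correlation with any group contrast. Consequences, all
verified in tests: the group SS is unchanged by adding such covariates
(only the error df drops, one per covariate: 33 → 31 → 30 at 3 x 12
subjects), and the design can never be rank-deficient through them.
Covariates are subject-level constants, so they enter the between-subject
stratum only; the within stratum tests condition and condition x group on
condition contrasts. This is the only well-posed placement without
covariate x condition interactions, which the emulated analyses do not fit.
ROI windows are closed intervals so printed bounds like 244–280 ms include
both endpoints at 4 ms sampling. Planned pairwise contrasts compare
covariate-adjusted means at covariate value zero (the group mean after
orthogonalization) with the between-stratum error and carry no multiplicity
adjustment, as planned contrasts.

## Task simulator

The staircase moves the response deadline by −33 ms after a success and
+33 ms after a failure, independent of cue type; success is a strict
`rt < deadline` (ties have probability zero for continuous responders; the
convention is stated for determinism). Scoring is asymmetric: positive cues
pay their magnitude on success and nothing on failure; negative cues lose
their magnitude on failure and nothing on success. The staircase is a
reflecting random walk whose fixed point is the responder's median RT, so
long-run success converges to 50% for any stationary continuous RT
distribution — the calibration the acceptance suite measures (100 sessions,
first block discarded as burn-in, required within ±2 percentage points).
The initial deadline (400 ms) and whether the deadline carries across block
breaks (default: yes) are config options, as the emulated task reports
neither; a 1 ms floor keeps the walk defined for pathological responders.

## Problem sizes used by the tests

Unit and property tests run on 4–16 channel layouts and 1–40 sample grids
with exact or 1e-8/1e-10 oracle tolerances. The two simulation studies use
16 channels x 40 samples, 500 permutations, and 200 (null calibration) or
100 (recovery) simulated datasets; the analysis drivers use 32 channels x
50 samples and 500 permutations. These sizes were chosen so the full suite
runs in minutes while leaving every statistical property at its full-scale
definition; nothing in the machinery is specific to the reduced grids.

## Known limitations

* Only one within-subject factor; no trial-level regressors.
* Gaussian noise model; no 1/f spectra or realistic artifact morphology.
* No FDR or cluster-mass alternatives to TFCE; no source-space anything.
* The unbalanced-design path is GLM-correct but not optimised; the package
  assumes near-balanced cohorts as in the emulated study.
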