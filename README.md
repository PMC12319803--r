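# tacsalpha

Simulation and statistical analysis of alpha-power after-effects of
short transcranial alternating current stimulation (tACS) trains in
trial-structured multi-unit electrophysiological recordings.

## The problem

Short (10 s / 30 s) trains of tACS applied at a participant's individual
alpha frequency may leave a transient elevation of alpha-band power in
the stimulation-free intervals that follow each train.  Detecting such
after-effects requires a chain of non-trivial statistics: the
stimulation frequency (ISF, the 7–14 Hz alpha peak) differs between
participants, so spectra must be aligned to it; power changes must be
measured relative to a pre-stimulation baseline; and inference over
thousands of (unit, frequency, time) elements needs family-wise error
control, conventionally via nonparametric cluster-based permutation
tests.

`tacsalpha` implements that chain for R, together with a seeded
synthetic-data generator in which every effect parameter is known, so
that each stage — and its calibration — can be validated against ground
truth.  It is aimed at researchers developing or auditing tACS/MEG/EEG
after-effect analyses.

## The statistics at the core

Within a participant, the baseline-relative power change at each unit,
frequency offset and time point is

Δpower = (p̄_post − p̄_base) / (s_p · √(1/n₁ + 1/n₂)),

a two-sample t statistic across the 20 post-stimulation and 20 baseline
trials, with baseline power time-averaged per trial.  Group-level
inference contrasts the tACS and control sessions with a paired,
cluster-based permutation test: suprathreshold (two-tailed p < 0.05)
adjacent elements form clusters (minimum two connected members), each
cluster scores the sum of its t values, and the null distribution of the
maximum absolute cluster sum is built from random within-participant
condition swaps (exact enumeration when 2^n does not exceed the
permutation budget).  Follow-up analyses: an ISF-aligned time–frequency
cluster test, a somatosensory/frontal region split, a Wilcoxon rank-sum
contrast of the two train durations, Friedman/Conover statistics over
trial-order bins, and a filter–Hilbert "modulatory power" spectrum of
slow (0.1–2 Hz) rhythmic power fluctuations.

## Worked example

Simulate a small cohort with a +80% alpha-power gain on the
somatosensory patch of a 4 × 4 grid and run the full pipeline:

```r
library(tacsalpha)

report <- run_pipeline(list(
  n_participants = 8, layout = list(nrow = 4, ncol = 4),
  effect = list(tacs_gain = 0.8),
  blocks = "train10", n_permutations = 500, master_seed = 21,
  stages = c("tf", "binning", "modulatory")))
report
#> <pipeline_report>
#>   ISF (Hz): 8 10 8 9 12 10 10 11
#>   spatial clusters: 1
#>   power change at ISF: tACS 75.23 +- 17.05 %, control -4.68 +- 6.87 %
```

Reading the output: the pipeline estimated each participant's alpha peak
from the tACS-session baseline, found one significant positive spatial
cluster (here exactly the nine units of the somatosensory patch, by
exact sign-flip enumeration over 2^8 assignments), and the mean power
change at the ISF within that cluster is close to the injected +80% in
the tACS session and near zero in the control session.
`report$time_frequency`, `report$binning` and `report$modulatory` hold
the ISF-aligned time–frequency clusters, the Friedman bin statistics and
the slow-modulation contrasts.

Individual stages are plain functions operating on `trial_set` objects:
`segment_recording()`, `flag_artifact_trials()`, `estimate_isf()`,
`compute_tfr()`, `align_tfr()`, `delta_power()`,
`cluster_permutation_test()`, `compute_bin_series()`, `friedman_bins()`,
`trial_power_difference()`, `modulatory_power()`,
`modulatory_contrast()`.  The methods vignette
(`vignettes/tacsalpha-methods.Rmd`) describes the models, parameter
choices and validation studies in detail.

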