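---
title: "Detecting alpha-power after-effects of short tACS trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpha-power after-effects of short tACS trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tacsalpha` implements, end to end, the statistical machinery used to ask
whether short (10 s / 30 s) trains of transcranial alternating current
stimulation (tACS) at a participant's individual alpha frequency leave a
detectable elevation of alpha-band power in the stimulation-free intervals
that follow each train.  Because raw recordings from such experiments are
rarely redistributable, the package pairs the analysis chain with a
synthetic-data generator in which every effect parameter is known, so each
stage can be validated against ground truth.

The analysis chain is: segmentation of a continuous multi-unit recording
into baseline and post-stimulation trials; estimation of the individual
stimulation frequency (ISF); sliding-window Hanning time-frequency
decomposition with an ISF-aligned frequency axis; a baseline-relative
delta-power statistic; nonparametric cluster-based permutation inference
over spatial and time-frequency adjacency; trial-order binning with
Friedman/Conover rank statistics; and a filter-Hilbert "modulatory power"
spectrum of slow (0.1-2 Hz) rhythmic power fluctuations.

# The experimental design being emulated

One participant contributes two sessions (tACS and a no-stimulation
control) of two blocks each.  A block is a 2-minute resting baseline
followed by 20 stimulation trains (10 s per train in one block, 30 s in
the other), each train followed by a 15 s stimulation-free interval.
Sampling rate is 1000 Hz.  `study_design()` holds these constants.

Segmentation follows fixed arithmetic (`segment_recording()`):

* the last 10 s of the baseline are dropped and the remaining 110 s are
  cut into twenty 5.5 s epochs;
* after each train, the window 3.8-10 s relative to train offset (6.2 s)
  is the usable part of the interval; it is trimmed to 4.2-9.7 s (5.5 s)
  to strip filter edge effects, giving twenty post-stimulation trials.

Sample windows are half-open `[start, end)`, so a 5.5 s epoch at 1000 Hz
has exactly 5500 samples; this avoids duplicated boundary samples, and the
convention is asserted by the test suite.

Artifact handling is a deliberately simple robust-z amplitude flagger
(`flag_artifact_trials()`): synthetic data carry none of the hardware
artifacts that motivate semi-automatic cleaning of real recordings, and a
median/MAD rule is reproducible.  Flagged trials are retained in place --
never deleted -- because the binning analysis depends on trial order.

# The synthetic generator

`generate_participant()` synthesizes, per unit $u$ and trial $k$,

$$x(t) = a_{uk}\,\bigl(1 + m\,\sin(\varphi_k + 2\pi f_m t + \phi_u)\bigr)
        \,\sin(2\pi f_0 t_s + \theta_u) \; + \; \varepsilon(t),$$

where $f_0$ is the participant's alpha peak (ISF, integers 8-13 Hz across
a cohort), $f_m \approx 0.4$ Hz the slow amplitude modulation with depth
$m$, $t_s$ the session clock (epochs are phase-coherent cut-outs, as
excised segments of a continuous recording would be), and $\varepsilon$
Gaussian $1/f$ noise synthesized in the frequency domain with random
phases over 0.5-45 Hz.  On effect units, post-stimulation epochs of the
tACS session are scaled by $\sqrt{1 + g}$, so the injected power gain is
exactly `tacs_gain` $= g$.

Design choices that matter, with defaults and rationale:

* **Noise floor** (`noise_amp = 2.5`): sets the single-epoch spectral
  floor at the ISF to roughly 1/15 of the alpha peak, in the typical
  range for a clear parietal/somatosensory alpha rhythm.  The
  alpha-noise cross term this induces makes single-trial alpha-power
  estimates fluctuate with a CV around 0.4-0.5 -- comparable to real
  trial-level alpha power -- and is a main driver of the statistical
  power of all downstream tests.
* **Amplitude jitter** is split into a session-wide lognormal
  (`amp_jitter_sd = 0.10`, an arousal-like global fluctuation shared by
  all units) and a larger unit-local lognormal
  (`amp_jitter_local_sd = 0.15`) whose log-field is smoothed over the
  unit lattice (`local_smooth = 0.8`, an adjacency-kernel smoother with
  preserved marginal SD).  Across-trial power fluctuations are then
  strongly correlated between neighbours and moderately correlated at
  distance, matching source-level recordings, where field spread and
  shared physiology couple nearby locations.  Both extremes are
  pathological for cluster statistics: purely global jitter hands the
  permutation null over to whole-map excursions, while fully independent
  units make two adjacent suprathreshold elements -- the minimum cluster
  -- vanishingly rare, throttling the test far below its nominal level.
* **Modulation phase** is spatially coherent: one session-wide phase with
  small per-unit scatter (`mod_phase_unit_sd = 0.3` rad).  Slow power
  fluctuations behave like a global drive (plausibly bodily rhythms);
  independent per-unit phases would cancel in any unit-averaged
  quantity.
* **Modulation phase drift** (`mod_phase_jitter = 0.5` rad per epoch, a
  random walk): spontaneous slow fluctuations are quasi-periodic, not
  phase-locked over minutes.  This also prevents a strictly periodic
  0.4 Hz modulation from locking to the 25 s train cycle of the 10 s
  block (0.4 Hz x 25 s is a whole number of periods), which would
  otherwise freeze the modulation phase across all post trials and bias
  baseline-relative power changes by up to ~10%.
* **Per-trial amplitude jitter** multiplies the oscillation only, never
  the noise floor.

`generate_cohort()` draws per-participant ISFs (discrete uniform on
8-13 Hz) and derives per-participant seeds injectively from one master
seed; participants are realized lazily (`realize_participant()`) because a
fully materialized 24-participant cohort would occupy several gigabytes.
`mode = "continuous"` produces a whole-block continuous recording for
exercising `segment_recording()`; `mode = "epochs"` synthesizes only the
analysis windows (identical model, same session clock).

# Spectral estimation

**ISF** (`estimate_isf()`): per-trial single-Hanning-taper power at
integer frequencies 4-40 Hz (direct evaluation at exact integer
frequencies, since 1 Hz steps are not DFT bins of a 5.5 s epoch),
averaged over unflagged trials and over a declared unit subset (default:
the somatosensory region), then the argmax within 7-14 Hz.  Ties -- which
at machine precision means equality to within a factor of $1-10^{-12}$ --
resolve to the lower frequency and are reported via a message.  A
`window = "single"` variant tapers the concatenated baseline instead.
Per-epoch mean and linear trend are always removed first; an extra
band-pass is unnecessary because synthetic data are band-limited by
construction.

**TFR** (`compute_tfr()`): Hanning-tapered sliding-window power, 1 Hz
resolution over 5-40 Hz, 100 ms steps; the main variant uses 7 cycles per
window (frequency-dependent length), the modulatory variant a fixed
400 ms window.  Time points whose window does not fit inside the epoch
are `NA`, never zero-filled.  Power is normalized so a pure sinusoid of
amplitude $A$ reads $A^2$.

**Alignment** (`align_tfr()`): the frequency axis is re-indexed as
offsets relative to the ISF, $-2 \ldots +26$ Hz (29 bins), so stimulation
frequencies coincide across participants.  The harmonic control mode
centres on $2 f_0$ with offsets $-4 \ldots +16$ Hz, chosen so that all
cohort ISFs up to 12 Hz stay inside the 5-40 Hz analysis range;
out-of-range bins are `NA`, never extrapolated.

# Delta power and cluster inference

Within a participant, `delta_power()` computes at each element the
two-sample t statistic between the 20 post-stimulation and 20 baseline
trials,

$$\Delta = \frac{\bar p_{\text{post}} - \bar p_{\text{base}}}
                {s_p\sqrt{1/n_1 + 1/n_2}},$$

with baseline values time-averaged per trial first.  A t statistic needs
trial-level variance, so the statistic is computed across trials (the
trial-level reading of "averaging before testing"); a Welch variant is
available via `var_type = "welch"`.  The two blocks are pooled by
averaging their maps (`pool_blocks()`), keeping one map per participant
as the paired group test requires.

`cluster_permutation_test()` then contrasts conditions across
participants: per element a paired t; elements beyond the two-tailed 5%
critical value form clusters of connected elements (unit graph for
spatial maps; 4-neighbour lattice for time-frequency or
modulation-carrier planes), positive and negative excursions separately;
clusters need at least 2 connected members; the cluster statistic is the
summed t.  The null is built by randomly swapping condition labels within
participants (sign flips of paired differences), keeping each
permutation's maximum absolute cluster sum; $p = (1+k)/(P+1)$, never
exactly zero, with the seed recorded in the result.  When $2^n \le P$ the
full sign-flip enumeration replaces sampling and $p$ is exact.  Under
label exchange every cluster's sign flips and its $p$ is unchanged, which
the test suite asserts, along with agreement between the sampled and
exhaustive paths.

For ISF-level spatial maps, per-trial power at the ISF is estimated by
the whole-epoch Hanning taper (the time-collapsed estimator,
`trial_power()`): the statistic the spatial test needs is time-averaged
anyway, and the whole-epoch taper is the natural single-window version of
averaging a spectrogram over time, at a fraction of the cost.  The
time-frequency analyses use the full TFR path on the units of the
significant spatial cluster.

`region_split_test()` re-runs the time-frequency test per region
(somatosensory / frontal intersection of the cluster), and
`block_contrast()` compares the two train durations: per block, group
paired t values over cluster units, the two sets compared with the
Wilcoxon rank-sum test.

# Trial-order binning

`compute_bin_series()` turns each post trial into
$(p_{\text{trial}} - \bar p_{\text{base}})/\bar p_{\text{base}}$
(cluster-unit averaged, at the ISF), and groups the 20 trials in
recording order into 5 bins of 4.  Flagged trials contribute missing
values but keep their position, so bins never shift.  `friedman_bins()`
runs the Friedman rank test across participants (via
`stats::friedman.test`) and, only when the omnibus is significant, the
pairwise Conover post hoc with Bonferroni correction over the 10 bin
pairs.  The Conover statistic follows the published rank-based form
$t_{ij} = (R_i - R_j)/\widehat{SE}$ with
$\widehat{SE}^2 = \frac{2n(A_1-C_1)}{(n-1)(k-1)}
\bigl(1 - \frac{T_1}{n(k-1)}\bigr)$ and $(n-1)(k-1)$ degrees of freedom;
the test suite re-derives it step by step on a fixed table.  Two-sided
comparisons are used.

# Modulatory power

The exploratory question is whether slow rhythmic fluctuations of alpha
power are amplified by stimulation.  `trial_power_difference()` computes,
from the 400 ms TFR of post trials, each trial's power time course minus
the previous trial's time-averaged power (the first trial has no
predecessor and is excluded), unit-averaged over the cluster.

A 0.1 Hz component cannot be resolved inside one 5.5 s trial, so
`modulatory_power()` concatenates the trial time courses in order into
one session-level series per carrier offset, mirror-pads one series
length at each end, band-pass filters at 11 centres (0.1-0.5 Hz in 0.1 Hz
steps, then 0.25 Hz steps to 2 Hz; bandwidth $\max(0.1, 0.5f_c)$), takes
the analytic-signal magnitude and averages it over each trial's time
points.  The filter is zero-phase by construction: the series' spectrum
is multiplied by the squared magnitude response of an order-4 Butterworth
band-pass (the frequency-domain equivalent of forward-backward
filtering), and the analytic signal is obtained in the same inverse
transform by one-sided spectrum doubling.  The suite checks this fused
path against a literal `signal::filtfilt` + Hilbert oracle.

Raw envelope magnitude grows with filter bandwidth under broadband input,
so spectra are not comparable across centres; `normalize = "bandwidth"`
divides each centre by $\sqrt{bw}$ (white-noise envelope scaling), which
makes a white-noise spectrum flat and lets a cross-centre argmax identify
the modulation frequency.  Group contrasts are element-wise and therefore
invariant to this per-centre scaling; `modulatory_contrast()` runs the
standard cluster machinery on the modulation-frequency x carrier-offset
plane.

Two caveats are inherent to the trial-difference design and worth keeping
in mind when reading modulatory spectra: the per-trial offsets
$\bar p_n - \bar p_{n-1}$ inject step energy below about 0.2 Hz (one
trial per 5.5 s), so the lowest filter centres partly reflect
trial-to-trial variability rather than within-trial rhythmicity; and the
measure cannot distinguish a stronger fluctuation from a more regular
one -- only their combination ("modulatory power") is defined.

# Validation studies and problem sizes

The acceptance suite validates each claim at a scale chosen to run on a
single CPU in minutes:

* **Design arithmetic**: exact (20 x 5.5 s baseline epochs, 6.2 s / 5.5 s
  post windows, 5 bins of 4).
* **Statistic oracles**: `delta_power()` vs an independent pooled-t
  implementation on 100 random fixtures (agreement to 1e-10); Friedman,
  Conover and rank-sum statistics vs direct rank-formula computation.
* **Permutation exactness**: a 4-participant cohort, where the test
  enumerates all 16 sign assignments, against a hand-coded enumeration.
* **Null calibration**: 200 null cohorts (gain 0, n = 8, 4 x 4 layout,
  200 permutations each, known ISF); the spatial test's empirical type-I
  rate must sit inside the 95% binomial band around 0.05.
* **Effect recovery**: 50 cohorts (n = 12, gain 0.30 on the 3 x 3
  somatosensory patch of a 6 x 6 layout, default noise and jitter,
  1000 permutations); a significant positive cluster overlapping the
  patch in at least 90% of cohorts, and the recovered mean power change
  within 10 percentage points of the injected 30%.  The 6 x 6 layout is
  the smallest on which patch-versus-surround clustering is meaningful at
  this cohort size within the compute budget.
* **ISF recovery**: 50 single participants, injected integer ISFs 8-13,
  recovered exactly on the 1 Hz grid.
* **Modulatory recovery**: 50 single participants in a reduced-
  variability regime (noise_amp 1, jitter SDs 0.05) that isolates the
  estimator from trial-difference step noise -- the bandwidth-normalized
  spectrum must peak at the injected 0.4 Hz centre in at least 90% -- and
  25 cohorts (n = 8) with tACS modulation depth 0.4 vs control 0.2, in
  which the contrast must find a significant cluster containing the
  0.4 Hz row in at least 80%.

# What passing does and does not show

The generator reproduces the statistical structure the analysis assumes:
a spectral alpha peak over a 1/f floor, trial-level power variability
with global and local components, a coherent quasi-periodic slow
modulation, a spatially compact stimulation effect of known size, and
exchangeability between conditions under the null.  It does not emulate
sensor physics, volume conduction or beamformer leakage, non-sinusoidal
alpha waveforms (and hence genuine harmonic structure), stimulation
artifacts, eye/cardiac contaminants, or session-order and fatigue
effects.  Passing the suite therefore certifies the inference machinery
and its calibration, not the physiological interpretation of any
particular real dataset.

# Numerical notes

Windows are half-open at sample resolution.  Spectral estimators evaluate
exact integer frequencies by direct projection rather than zero-padded
FFTs.  The generator's noise is synthesized with FFTW; all randomness
flows through R's RNG, so results are bit-reproducible for a given seed,
including from C++ code.  Permutation tests draw their sign flips from a
recorded seed, and switch to exhaustive enumeration automatically when
$2^n$ does not exceed the permutation budget.  Cluster p values use the
$(1+k)/(P+1)$ estimator and are therefore never zero; degenerate inputs
(zero variance with equal means) yield a statistic of 0, while zero
variance with unequal means is an error rather than an infinity.
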