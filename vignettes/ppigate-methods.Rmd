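---
title: "Measuring muscular and neural prepulse inhibition with ppigate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring muscular and neural prepulse inhibition with ppigate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppigate)
```

## The measurement model

A prepulse-inhibition (PPI) session presents intense white-noise pulses (P)
either alone or preceded by a weak prepulse at a 30, 60 or 120 ms lead
interval (P30, P60, P120). Two quantities are read from the same trials:

* the **acoustic startle reflex (ASR)**, the orbicularis oculi blink measured
  as the maximum of the rectified, smoothed EMG envelope in the 20–120 ms
  window after the pulse, relative to the mean of the 50 ms pre-stimulus
  baseline;
* the **neural startle response**, the peak-to-peak amplitude `P2 − N1` of
  the stimulus-locked ERP, with N1 the most negative sample in 60–165 ms and
  P2 the most positive sample in 165–275 ms, at Fz, Cz and Pz.

For each modality and lead interval the gating statistic is
`%PPI = 100 (1 − PP/P)`, the per-subject percent reduction of the
prepulse+pulse response relative to pulse alone. `%PPI` is undefined (and
reported missing, never zero) when the pulse-alone amplitude is not
positive; it is bounded above by 100 and may be negative (facilitation).
Group summaries always average subject-level `%PPI`, never ratios of
group-mean amplitudes.

The blink that carries the muscular measure is also the main EEG artifact,
and its size co-varies with startle strength — exactly the confound that
would bias a naive neural measurement toward the muscular one. The EEG
branch therefore decomposes the scalp channels with Infomax ICA and removes
components classified as artifactual before averaging. No statistical epoch
rejection is applied to the EEG, and EMG-rejected trials are *not* removed
from the EEG branch (a config switch enables synchronized rejection for
comparison): both measures rest on the same trial set.

## Pipeline parameters

All defaults live in `pipeline_config()`; a YAML file with the same shape
overrides any subset.

| parameter | default | unit | role |
|---|---|---|---|
| `highpass_hz` | 0.25 | Hz | continuous drift removal (zero-phase, order 4) |
| `notch_base_hz` / `notch_halfwidth_hz` | 60 / 2 | Hz | mains notch at the base frequency and every harmonic below Nyquist |
| `emg$band_hz` | 24–200 | Hz | muscle band isolating orbicularis activity |
| `emg$envelope_lowpass_hz` | 15.9 | Hz | envelope smoothing after rectification |
| `emg$window_ms` / `baseline_ms` / `asr_window_ms` | −300..300 / −50..0 / 20..120 | ms | segmentation, baseline, scoring windows |
| `responder_digital_units` × `adc_resolution` | 20 × 0.0488 | µV | non-responder threshold (0.976 µV), boundary inclusive |
| `eeg$epoch_ms` / `baseline_ms` | −1000..1000 / −650..−150 | ms | ERP epochs and pre-stimulus baseline |
| `eeg$lowpass_hz` | 40 | Hz | per-epoch smoothing before averaging |
| `eeg$n1_window_ms` / `p2_window_ms` | 60..165 / 165..275 | ms | peak-search windows, endpoints inclusive |
| `ica$autocorr_lag_ms` | 20 | ms | muscle-likeness lag ("lag 20" is read as milliseconds, the plug-in convention; a sample-based lag can be set through the config) |
| `ica$focal_topo_z` / `focal_trial_z` | 3.5 / 10 | z | topographic and trial focality thresholds |
| `ica$snr_ratio_threshold` | 1 | — | post/pre-stimulus SD ratio; components *below* 1 (no stimulus-locked content) are flagged |
| `ica$ref_corr_threshold` | 0.2 | r | absolute correlation with EOG/EMG references |

Decisions taken where the method description is open:

* **EMG derivation.** "EMG1 and EMG2 form EMG" is implemented as the bipolar
  difference EMG1 − EMG2, the standard periocular montage; a `mean` option
  exists.
* **ASR baseline.** The ASR is baseline-subtracted and floored at 0, so a
  trial without a blink scores 0 µV rather than the noise floor; the raw
  maximum is available via `baseline_subtract = FALSE`.
* **Outlier trials.** A trial is rejected when its in-window envelope
  maximum exceeds mean + 3 SD of the *other* trials of its condition, or its
  baseline exceeds mean + 3 SD of the subject's other baselines
  (leave-one-out reference statistics). Leaving the candidate out prevents a
  single extreme trial from inflating the spread it is compared against,
  which would otherwise let large artifacts mask themselves; the rule stays
  single-pass, strict (a zero-variance set rejects nothing) and
  scale-equivariant. A relative epsilon (1e-9) keeps floating-point jitter
  between numerically identical trials from triggering it. The two criteria
  combine disjunctively by default (`reject_rule = "conjunctive"` requires
  both).
* **Component classification.** The five criterion flags combine as a union
  (any flag removes the component); `combine = "vote"` requires two. The
  autocorrelation "auto" threshold is mean − 2 SD across the decomposition's
  components. Classification uses absolute values and correlations
  throughout, so it is invariant to component sign and scale.
* **Post hocs** are two-sided; amplitude contrasts compare pulse-alone
  against each prepulse condition, %PPI contrasts compare all three interval
  pairs. Parametric post hocs use Tukey HSD on a randomized-block fit;
  nonparametric ones use exact paired Wilcoxon tests with Bonferroni
  multiplication by the number of pairs, capped at 1.

## Numerical conventions

* Event onsets are 0-based sample indices; a window `(a, b)` in ms maps to
  samples by rounding each boundary to the nearest sample, half-open
  `[a, b)` for segmentation and baselines, inclusive `[a, b]` for the ASR
  and peak-search windows. At 512 Hz the −300..300 ms EMG segment is 307
  samples and the −1..1 s epoch is 1024 samples.
* Peak search returns the extremum *sample*; ties resolve to the earliest
  sample, and a latency can never leave its printed window.
* Zero-phase filtering applies the designed Butterworth forward and
  backward (squared magnitude, zero phase lag) over odd-reflection padding,
  with steady-state initial conditions per pass so constant signals pass
  through bit-exactly. The stated order (4) is the design order of one pass.
* The mains notch cascades a ±2 Hz band-stop at every harmonic below
  Nyquist (60/120/180/240 Hz at 512 Hz). A narrow notch necessarily rings:
  its pole radius (~0.991) couples consecutive trials at the 1e-6 level and
  removes genuine 58–62 Hz noise energy, so recordings simulated without a
  mains component are processed with the notch disabled wherever exact
  identities are asserted.
* Infomax ICA (natural-gradient, logistic nonlinearity) runs on the mean-
  removed, sphered scalp data; the returned unmixing matrix absorbs the
  sphering, components are ordered by projected variance and sign-fixed, and
  the whole decomposition is deterministic given its seed. Stopping:
  squared weight change < 1e-7 or 512 steps; the learning rate anneals by
  0.98 whenever the update direction turns by more than 60°. The classic
  0.90 anneal constant left the weight change hovering above the tolerance
  here (the update direction rarely turns, so annealing rarely triggers),
  always exhausting the step cap. Weights are fitted on a seeded subset of
  whole epochs capped at 20 000 concatenated samples (about 8× the
  20 · channels² rank guidance for 11 channels); activations are then
  computed for all epochs. On simulated cohorts, recovery and blink
  detection at this cap were indistinguishable from a 60 000-sample fit.
* Degenerate cases are defined, not left to chance: a constant component
  activation has autocorrelation 1 (never flagged as muscle); a zero
  baseline SD makes the SNR ratio +∞ (never flagged); zero-variance
  reference channels are skipped with a warning; a fully tied Friedman
  table reports statistic 0 with p = 1; an all-ties Wilcoxon pair reports
  p = 1 with a warning; an undefined Kendall tau (constant input) is
  reported missing.
* A z-score over n values cannot exceed (n−1)/√n. Consequences: the focal-
  trial threshold (z = 10) can only fire with ≥ 102 epochs — satisfied by
  the 170-trial design — and the focal-topography threshold (z = 3.5)
  cannot fire at all with 11 scalp channels (bound ≈ 3.0). In this montage
  blink components are caught by their EOG correlation; the topography
  criterion becomes informative on denser montages. Thresholds are kept at
  their published values rather than rescaled.

## The synthetic-session generator

`simulate_session()` emulates the experiment's structure exactly: 512 Hz, 11
scalp channels (10–20 positions), bipolar EMG pair, EOG, two earlobe
references; five leading and trailing pulse-alone trials around two blocks
of 20 pseudorandomized trials per condition (170 events); inter-trial
intervals drawn uniformly from 2.6–3.2 s, chosen so −1..1 s epochs plus
filter margins never overlap.

Planted content per trial: a band-limited (24–200 Hz) noise burst under a
gamma envelope peaking 60 ms post-pulse on the EMG pair, scaled by the
condition amplitude (pulse-alone 50 µV, multiplied by 1 − PPI/100 with
muscular PPI 35/55/35 %) and per-trial lognormal jitter (σ = 0.2); a smooth
300 ms blink waveform peaking 100 ms post-pulse, mixed into EOG and scalp
through a fixed frontal-dominant rank-1 gain vector with amplitude
proportional to that trial's startle (reproducing the blink–startle
confound); an N1/P2 Gaussian-deflection template (−8 µV at 100 ms, +10 µV
at 200 ms on Fz) scaled per condition by 1 − PPI/100 with neural PPI
40/55/40 %; and 1/f noise (5 µV SD), white sensor noise (1 µV), and
common-phase 60 + 120 Hz mains (2 µV) on the non-reference channels. The
EMG carrier is drawn once per subject and reused across trials, so that
with jitter and noise disabled every scored amplitude scales exactly with
the planted condition factor and the pipeline recovers the planted %PPI to
floating-point precision (the EMG band edge at 24 Hz also blocks the slow
tail of the 0.25 Hz high-pass; the EEG branch has no such protection, so
its noise-free identity holds to ~1e-4 rather than machine precision).

What the simulator does **not** emulate: biophysical head geometry or a
forward model (the blink is a single spatial source, which makes an
11-channel ICA separation achievable by construction); startle habituation
across blocks; prepulse-evoked ERPs inside the lead interval; non-blink
artifacts (saccades, electrode pops, drift bursts); inter-subject
variability beyond the seed. Passing the recovery tests therefore shows the
chain is correct and unbiased under the stated signal model — not that the
classifier thresholds are optimal for arbitrary real recordings.

## Problem sizes used by the test suite

The acceptance properties run the full design: a noise-free session for the
exact identity; 20 cohort seeds × 8 subjects (170 trials each) for noisy
recovery of muscular (±5 points) and neural (±10 points) %PPI, with the
cleaning-efficacy metrics (≥50 % RMS-error reduction of the Fz ERP against
the planted neural ERP, ≥90 % blink-detection rate, ≤10 % neural false-flag
rate) taken from each seed's first subject; 200 random tables for the
brute-force oracle equivalence of Friedman, exact Wilcoxon, Kendall tau-b,
z-scores and the rejection rule; and 1000 null tables (16 subjects × 3
conditions) for the omnibus type-I error band of 4–6.5 %. Unit tests use
reduced 36-trial sessions. `scripts/acceptance.R` reports the same
quantities at 5 seeds × 8 subjects with efficacy metrics from all 40
subjects and 500 null tables.

## Known limitations

* ADJUST and FASTER are not re-implemented; their blink-detection role in
  the published configuration is covered by the EOG-correlation (and, on
  denser montages, focal-topography) criteria.
* Manual ("visual") component selection is out of scope; only the automated
  path exists.
* BrainVision support covers binary multiplexed float32/int16 files; EDF
  support covers classic uniform-rate EDF. No HDF5 intermediate container
  is written; the pipeline holds intermediates in memory and emits TSV/JSON.
* With 11 scalp channels and more latent sources than channels (noise is
  independent per channel), the ICA model is necessarily approximate; the
  blink is recovered reliably because it is strong and spatially fixed.
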