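---
title: "Methods: sleep EEG analysis for rocking-bed polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep EEG analysis for rocking-bed polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rockpsg` implements the analysis pipeline of a within-subject nocturnal
polysomnography design with three conditions: a still baseline (B), rocking
until sleep onset (C1) and rocking for the first 2 hours after lights out
(C2). The package covers the full chain — synthetic cohort generation with
ground truth, sleep-architecture metrics, band-power spectral analysis,
amplitude-threshold spindle detection, slow-oscillation half-wave detection,
word-pair memory scoring, and the condition-comparison statistics — but not
visual sleep staging, artifact scoring, actigraphy compliance checks, or the
physical platform control system. Artifact flags and stage labels are
inputs, never outputs.

All epoch indices are 0-based; all timestamps are seconds from lights out;
analysis windows are half-open epoch ranges `[start, end)` relative to
lights out, so "the first 2 hours" is epochs `[0, 360)` of 20 s each.

# Sleep architecture

Stages are the usual five (`W`, `N1`, `N2`, `N3`, `REM`) on 20-s epochs.
**Sleep onset is defined as the first N2 epoch.** The design pins sleep
latency to the first occurrence of N2 and anchors the C1 stimulation
off-rule on N2 runs, and never defines onset otherwise, so a single N2-based
onset is used for every derived metric (WASO, SWS/REM latency, stage
changes). Consequences worth knowing:

* WASO counts W epochs *strictly after* the onset epoch; wake before onset
  contributes to latency only, and a hypnogram with no N2 has latency `NA`
  (undefined, never zero) and WASO 0.
* The N2-from-N1 latency may be negative when N2 precedes N1; it is
  reported as-is.
* `stimulation_off_epoch_c1()` returns the third epoch of the first run of
  three consecutive N2 epochs. Whether stimulation stops at that epoch's
  start or end is not fixed by the protocol description; the package adopts
  **end of the third epoch** (so a run ending at epoch 30 gives a 620-s
  stimulation interval) and `build_timeline()` exposes the resulting
  interval explicitly so the alternative is a one-line change.

# Spectral analysis

Band power is computed on the C3–A2 derivation as the mean of five
non-overlapping 4-s Hanning-windowed periodograms per 20-s epoch (0.25 Hz
resolution). Normalization is one-sided with window-power correction so
band sums are absolute µV²: a bin-centered sinusoid of amplitude *a*
integrates to *a²/2*. Bands are delta 0.75–4.5, theta 4.5–9, alpha 9–15,
sigma 11–15 and beta 15–25 Hz, with a sub-delta split (<1, 1–2, 2–4 Hz)
available. Two printed oddities are implemented as printed and flagged
here: the **alpha band fully contains sigma**, and **edge bins shared by
adjacent bands count in both** (inclusive ranges on both sides). Band
means are taken over artifact-free NREM epochs, where "NREM" defaults to
{N1, N2, N3} and is a parameter. The delta build-up is the 180-epoch
delta sequence after sleep onset smoothed by a centered 7-epoch moving
average with shrinking edges.

# Spindle detection

The detector is the amplitude-threshold family: the derivation is
band-passed 12–15 Hz, rectified, and thresholds are set from the mean
rectified amplitude *m* over all artifact-free NREM samples — lower = 2*m*,
upper = 6*m*. Because the paper-trail pins only the filter's −3 dB points,
the filter is an 8th-order IIR band-pass (4th-order Butterworth prototype)
applied forward and backward, with design corners **tuned numerically so
the realized zero-phase response is −3 dB at 12.0 and 15.0 Hz**; the
package verifies this by probing the realized response
(`find_minus3db()`), not by trusting a design formula.

One realization choice matters: the rectified trace of a 13-Hz oscillation
dips to zero twice per cycle, so thresholding it directly would fragment
every spindle into ~37-ms pieces that the duration bound then discards.
Event extraction therefore operates on the **instantaneous amplitude**
(Hilbert envelope) of the filtered signal, which equals the oscillation
amplitude that the thresholds are expressed in; the threshold *levels*
still come from the plain rectified mean, as specified. Excursions above
the upper threshold are extended outward to the nearest lower-threshold
crossings, touching extents are merged (a flag, since the original study
does not say), and events outside 0.3–3.0 s are discarded (the
conventional bounds for this detector family; both configurable). Both
thresholds scale with the signal, so detection is invariant to overall
amplitude scaling — verified exactly under binary scalings in the tests.

# Slow-oscillation detection

The F3–A2 derivation is decimated to 128 Hz (zero-phase anti-alias
low-pass, then subsampling) and filtered by a 3rd-order Chebyshev type II
high-pass (−3 dB at 0.4 Hz) and a 6th-order Chebyshev type II low-pass
(−3 dB at 2.3 Hz), each forward-backward. Chebyshev II needs a stop-band
attenuation the protocol does not state; the package uses **20 dB for both
filters and then tunes the corner so the realized −3 dB points land on the
stated frequencies** — the stated observable is matched, the unstated
parameter is documented. The signal is segmented at zero crossings (sign
changes between consecutive samples; exact zeros adopt the preceding
sign), segments shorter than 2 samples are dropped, and each segment whose
unsigned peak reaches **37.5 µV** becomes a half-wave event of that
polarity. Counts report positive + negative combined (one number, as in
the study) with per-polarity counts alongside. Counting is restricted to
artifact-free NREM epochs by default, consistent with the spindle
statistics; an `all_sleep` option relaxes the stage restriction since the
original restriction is not explicit.

# The synthetic cohort generator

The generator exists so every downstream stage is testable with known
ground truth; its defaults are the study conditions: 18 subjects × 3
conditions, 8-h nights, 256 Hz, 20-s epochs, spindle density 2.2 and
slow-oscillation half-wave density 6.3 per NREM epoch, overnight word-pair
improvement 6.72 (SD 3.76) on a 0–40 half-point scale, and an artifact
rate of 2.5% (≈36 flagged epochs per night, the reported magnitude).

* **Hypnogram**: a per-epoch Markov chain starting in W, with the default
  transition matrix calibrated once against the reference architecture
  (sleep efficiency ≈96%, latency ≈9 min, N1 ≈10, N2 ≈250, N3 ≈94 min
  over 100 seeded nights). A stationary chain has no ultradian cycling
  and no homeostatic decline: REM latency comes out near 15 min rather
  than the observed ≈67 min, and the delta build-up curve has no rising
  trend to show. Tests that pass on these hypnograms therefore validate
  *bookkeeping*, not biology.
* **EEG**: per-epoch 1/f Gaussian background shaped in the frequency
  domain (exponent 1.0 in wake, 1.5 in sleep; broadband RMS 10 µV),
  10-Hz alpha in wake, plus injected events. Spindles are Hann-enveloped
  12.5–14.5 Hz bursts of 0.5–1.5 s placed without overlap (0.5-s minimum
  gap); their amplitude is specified as a multiple (default 10×) of the
  background's mean rectified sigma-band amplitude, and each burst is
  boosted by the inverse of its own band-pass attenuation so the
  *realized* envelope peak meets the specification — short bursts spread
  their spectrum beyond the passband and would otherwise undershoot.
  Slow oscillations are single 0.75–1.25 Hz sine cycles (two half-waves
  each) with peak amplitudes drawn uniformly from 25–80 µV, deliberately
  spanning the 37.5 µV criterion; the injection rate is stage-weighted
  (N3 and N2 full rate, N1 a quarter) so deep sleep carries more delta
  power by construction. All randomness flows from one master seed
  through named streams (subject, condition, purpose), so adding a
  subject never perturbs existing nights, and identical seeds give
  bit-identical output.
* **Condition effects** default to the direction observed during
  stimulation — an additive +0.04 shift on the probability of
  transitioning into N2 and +0.25 spindles per epoch, confined to the
  stimulation window (first 2 h for C2; until the 3-N2 run completes for
  C1). Set both to zero for a null simulation.
* **Word pairs**: immediate recall ~ N(27, 4) rounded to half points,
  delayed = immediate + N(6.72, 3.76), a latent correlation (default
  0.6) between immediate recall and a supplied spindle feature, and a
  forced ceiling fraction (default 2/18) to exercise the subject-level
  exclusion rule.

# Statistics

EEG features are compared with a randomized-block ANOVA (condition fixed,
subject as blocking factor, no interaction) — on complete balanced blocks
this is the study's univariate GLM, and Type I/III sums of squares
coincide. Post hocs are Fisher's LSD: pairwise t statistics on the pooled
residual mean square with its degrees of freedom and **unadjusted**
p-values — the absence of a multiplicity correction is the definition of
the test, not a bug to fix. Effect sizes are pooled-SD Cohen's d,
`|m2 − m1| / sqrt((sd1² + sd2²)/2)`, with the small-sample factor
`J = 1 − 3/(4(2n − 2) − 1)`; the corrected value reproduces six of the
eight published sleep effect sizes exactly at two decimals from the
published means and SDs (0.24, 0.21, 0.23, 0.01, 0.18, 0.18). The
remaining two (0.29 for N1 B-vs-C1, 0.08 for spindle counts B-vs-C1)
compute to 0.31 and 0.09 under every standard two-sample formula; they
were plausibly computed on paired data whose subject-level correlation is
not recoverable from summary statistics, and are not used as checks.

Word-pair measures use the same block ANOVA on non-excluded subjects with
Tukey-adjusted pairwise p-values (studentized range); the Kenward–Roger
degrees-of-freedom correction of the original mixed-model analysis is
deliberately not reproduced. Correlations between spindle features and
performance are two-tailed Pearson with a Bonferroni-corrected
significance threshold of 0.05/4 = 0.0125, matching the four performance
measures tested per feature. Missing cells cause listwise subject removal
with a warning; nothing is imputed.

# Numerical choices and degenerate inputs

* Zero-variance ANOVA input returns F = 0, p = 1 rather than NaN.
* A noise-free overnight gain makes the per-condition improvement
  contrast certain (p = 0) instead of erroring on zero variance.
* Zero crossings at exact zeros resolve by the preceding sample's sign;
  half-wave boundaries are linearly interpolated for reporting only.
* Word-pair scores are validated to half-point granularity by doubling
  to integers, so no floating-point drift can accumulate.
* EDF I/O uses 16-bit storage with symmetric physical ranges per channel;
  round-trip error is bounded by one quantization step and both
  truncated data and malformed headers fail loudly with byte offsets.

# Problem sizes in the test suite

The suite validates detectors on 30–60-minute nights at 128 Hz
(sensitivity and precision ≥0.9 against injected ground truth), oracle
equivalence on 1000+ randomized small instances, statistical calibration
on 1000 null replicates at the study's sample sizes (n = 16–18), and the
full pipeline on a 3-subject, 2-condition, 40-minute-night configuration.
These sizes were chosen so the whole suite runs in about a minute while
every property is still exercised at the study's parameter values where
it matters (thresholds, windows, densities, sample sizes).

# Known limitations

* The Markov hypnogram has no sleep cycles, no homeostatic delta decline
  and a too-short REM latency; architecture metrics are validated against
  oracles, not against human physiology.
* The 1/f background with injected events is far cleaner than real EEG;
  detector sensitivity/precision on synthetic nights bound performance
  only under the generator's assumptions (well-separated events, known
  SNR). Real-data performance depends on arousals, alpha intrusions and
  movement artifacts that are out of scope here.
* Absolute band-power magnitudes are only approximately matched to the
  reference table; no per-stage spectral calibration targets exist, so
  the generator aims at qualitative spectral shape, not at reproducing
  table values.
* Rotational-axis trajectories reuse the translational velocity-matching
  formula with amplitude in radians; without a lever arm the "peak
  velocity" of a rotation is nominal.
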