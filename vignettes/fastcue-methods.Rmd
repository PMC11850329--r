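---
title: "Methods: simulating and decoding fast cue-based movement training data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding fast cue-based movement training data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastcue)
```

## The problem

Asynchronous movement-based brain-computer interfaces (BCIs) must detect,
from the continuous EEG, *when* a user executes (or attempts) a movement.
Training such detectors needs many labeled movement trials, but traditional
cue-based protocols separate trials by long pauses so that visually evoked
potentials decay, stretching data collection to 8 s or more per trial. The
paradigm implemented here replaces discrete cues with a **continuously
rotating cross** overlaid on a fixed cross: the participant moves each time
the two crosses overlap, and a smoothly varying rotation speed produces
variable inter-trial intervals (ITIs) without any abrupt visual event. A
full run of 100 cued trials then fits into roughly five and a half minutes,
and three runs (300 trials) into under 18 minutes.

`fastcue` implements this paradigm generator, a synthetic-data model of the
recordings it produces, and the complete offline pipeline: preprocessing,
motion-based onset labeling, a shrinkage-LDA detector with runwise
cross-validation, event-based evaluation under a false-positive budget, and
neural-correlate analyses.

## The cue schedule

The rotation cross turns at

$$\omega(t) = \frac{90^\circ}{T_{ITI}} + A\,\sin(2\pi a_{base} t)\,
  \sin(2\pi a_{mod} t + \varphi) \quad [\text{deg/s}],$$

so the mean ITI is $T_{ITI}$ (one overlap per 90° for four-fold symmetric
crosses) and $A$ bounds the modulation. Defaults are $T_{ITI} = 3.3$ s,
$A = 10.24$ deg/s, $a_{base} = 0.032$ Hz, $a_{mod} = 0.016$ Hz and
$\varphi = 28.1$. Two slow sinusoids keep $\omega$ continuously
differentiable, so the velocity never changes abruptly within a trial.

Design choices the velocity law does not pin down:

* **Units of $\varphi$** — interpreted as radians. With this reading the
  100-trial schedule attains a minimum ITI of about 2.50 s and a maximum of
  about 4.75 s, the values the paradigm was designed for.
* **Clock origin** — $t = 0$ at rotation start, i.e. after the 1.5 s static
  hold that precedes each run; the modulation cannot act while the cross is
  static.
* **Initial tilt** — the rotation cross starts 10° away from the fixation
  cross, oriented so the first overlap occurs after 80° of rotation
  (about 3 s at mean speed), giving the participant preparation time. The
  alternative reading (overlap after 10°) would cue within half a second.
* **ITI definition** — the `n_trials - 1` intervals between consecutive
  cues. The interval from rotation start to the first cue is not an ITI.
* **Integration** — cumulative trapezoid on a 1 ms grid, cue times by
  linear interpolation of the angle trace at multiples of 90°. Halving the
  step moves cue times by well under 1 ms (checked by a convergence test).
* **Run duration** — static hold plus rotation time until the fade-out
  point 10° before the overlap after the last cue. Breaks between runs are
  participant-controlled and not modeled.

```{r schedule}
sched <- generate_cue_schedule(paradigm_config())
schedule_statistics(sched)
```

## The synthetic participant

`subject_model()` collects everything the generator needs. It emulates the
statistical structure the analysis pipeline relies on — not a biophysical
head model.

* **MRCP template**: linear negative drift from $-2$ s to a $-5\,\mu V$ peak
  at movement onset, cosine swing to $+3\,\mu V$ at $+0.6$ s, return to zero
  by $+2$ s. The scalp pattern is a Gaussian centred between C1/Cz
  (contralateral to the right hand), built from schematic 10-10 electrode
  coordinates. Cued and self-paced templates may differ to emulate
  between-condition dissimilarity.
* **Rhythms**: 10 Hz alpha and 20 Hz beta band-limited noise
  (2 µV RMS each), attenuated by `erd_depth` (default 0.6 of band power)
  from 0.5 s before onset until movement end, with a beta rebound
  (`beta_rebound` = 0.5) from 0.5-1.5 s after movement end. Power factors
  enter the amplitude as square roots.
* **Background**: $1/f$-shaped noise, 10 µV RMS per channel (spectral
  shaping of white noise, flat below 0.5 Hz). The rate of real EEG SNR is
  not published for this protocol; 10 µV against a 5 µV MRCP peak makes the
  default subject a *moderate*-SNR case, and both quantities are
  configurable.
* **Ocular activity**: blinks (~0.1/s), occasional horizontal saccades and
  per-channel slow ocular drift on four EOG channels, propagated into the
  EEG by a frontally-weighted 60x4 coupling matrix. The per-channel drift
  and per-event gain asymmetries keep the four EOG channels individually
  identifiable, which real periocular electrodes are; without them the
  horizontal pair would be perfectly collinear and no regression could
  recover the coupling.
* **Behavior**: movement onsets lag cues by a Gaussian delay
  (mean 95 ms, SD 151 ms) truncated at $\pm 3$ SD so onsets stay inside
  their trial. The finger-position trace is two raised-cosine speed pulses
  (flexion and return, 0.3 s each) separated by the 0.5 s hold, integrated
  to positions, plus 0.004-unit position noise.
* **Self-paced timeline**: bursts of movements (within-burst intervals
  $\mathcal{N}(3.5, 0.5^2)$ s truncated at 1.5 s, burst length geometric
  with mean 18) separated by pauses $\mathcal{N}(10, 1)$ s. These values
  were derived once from the targets the protocol states — long-run mean
  ITI near 3.9 s with SD near 1.4 s and pauses of about 10 s — via
  $\bar{ITI} \approx ((k-1)\,\mu_{burst} + \mu_{pause})/k$ for burst
  length $k$.

One consequence of the fast pacing worth keeping in mind: with a 3.3 s mean
ITI and MRCP support of $\pm 2$ s, neighbouring templates overlap inside any
$\pm 2$ s epoch, so grand averages carry leakage from adjacent movements
near the epoch edges. This is a property of the paradigm itself, not of the
simulation; recovery tests that need overlap-free averages use sparse (6 s
ITI) schedules.

What the generator does **not** emulate: volume-conducted correlated noise,
non-stationary artifacts (EMG, electrode drift), realistic saccade dynamics,
or trial-to-trial MRCP variability beyond additive noise. Tests passing on
synthetic data therefore demonstrate the *pipeline's* correctness and
calibration, not expected performance on real recordings.

## Preprocessing

The chain mirrors standard MRCP decoding practice: 0.5-70 Hz band-pass
(4th-order Butterworth), ocular artifact removal, 3.5 Hz low-pass (4th
order) and decimation to 10 Hz features, then common-average reference
(CAR). All filtering is zero-phase (forward-backward); the offline analyses
are time-locked to movement onset and a causal filter would bias MRCP
latencies. The 3.5 Hz low-pass doubles as the anti-alias filter for the
500 Hz to 10 Hz decimation (feature Nyquist 5 Hz). CAR is applied to
decoding features only; neural-correlate analyses use un-referenced signals
so condition differences are not redistributed across channels.

Eye-artifact removal is a fixed linear operator learned on the
eye-calibration recording: each EEG channel is regressed on the four EOG
channels by ordinary least squares, and the coefficient matrix is
subtracted from task runs. This preserves the contract of
subspace-based eye-artifact algorithms — calibrate once, apply as an affine
transformation — in a simple, testable form; a different estimator can be
slotted in behind `fit_eog_removal()`/`apply_eog_removal()`.

## Movement-onset detection from motion capture

The 30 Hz finger-position trace is differentiated (central differences) and
the speed $s = \sqrt{v_x^2 + v_y^2}$ is thresholded. One movement produces
two speed peaks (flexion, then return after the hold), so crossings are
paired: a crossing followed by a second one within 1.5 s emits the *first*
crossing time — refined by linear interpolation between the bracketing
samples, since 33 ms sampling is coarse — as the movement onset. Unpaired
crossings emit nothing; onsets within 1 s of the previous one are dropped.
The threshold defaults to `mean + 5 SD` of the speed over the
lowest-activity quarter of 1 s segments (a rest-noise estimate); the
segment-based rest pool matters, because taking the lowest quartile of
*samples* would underestimate the rest noise spread severely.

## Decoder

Feature windows of `n_window` consecutive 10 Hz samples (all 60 channels
concatenated) advance with a stride of one sample. Only the single window
ending nearest $t_{onset} + d$ is labeled *movement*; every other window is
*no movement*. The detection delay $d$ lets the window see the full
pre-onset negativity before a decision. A binary LDA with a shrunk pooled
covariance scores each window with the posterior probability of movement.

* **Shrinkage**: closed-form Ledoit-Wolf linear shrinkage toward the scaled
  identity is the default; quadratic-inverse shrinkage (QIS), a closed-form
  nonlinear eigenvalue shrinker, is available as `method = "qis"`. Both are
  cross-validation-free, which keeps hyperparameter selection cheap and
  deterministic.
* **Priors**: equal by default, placing the decision boundary at the
  Mahalanobis midpoint. With stride-one windowing the classes are imbalanced
  by two orders of magnitude; empirical priors would push every posterior
  far below 0.5 and make the sample-wise cross-validation score degenerate.
  Detection thresholds are calibrated afterwards in any case.
* **Hyperparameters**: `n_window` and `d` are selected by 3-fold *runwise*
  cross-validation over the three cue-based runs (train on one, test on the
  other two), scored by the sample-by-sample Matthews correlation
  coefficient against the exact single-sample labels; ties break toward the
  smaller window, then the smaller delay (cheaper, lower-latency model).
  The full grids default to 3-20 samples and 0-0.5 s; `run_experiment()`
  uses a 4x4 subset as its default problem size so a complete experiment
  stays desk-scale (the grids are a configuration argument either way).

## Event-based evaluation

The detector output is thresholded with a 1 s refractory period. A
detection within $[-0.5, +1]$ s of a true onset is a hit (the first one per
onset; later detections inside an already-hit window are ignored, neither
hit nor false positive); all other detections are false positives. With
overlapping hit windows a detection is credited to the nearest onset not
yet hit. TPR is the percentage of onsets hit; FP/min normalizes false
positives by the full run duration in minutes, movement periods included.

The decision threshold is chosen by sweeping every distinct score value and
maximizing TPR subject to FP/min staying at or below the budget (0.5, 1 or
2 FP/min), on the self-paced evaluation run itself. This mirrors the
protocol being reproduced but is *optimistic*: the threshold sees the test
data. The calibration function takes any score trace, so a held-out
cue-based run can be used instead when leakage matters.

## Neural-correlate analyses

* **MRCP comparison**: un-referenced 10 Hz features are epoched $\pm 1$ s
  around onsets; every (channel, sample) pair gets a two-sided Mann-Whitney
  U test, Bonferroni-corrected over the full channels x samples grid (the
  conservative reading of "corrected for multiple comparisons").
* **NRMSE**: dissimilarity of the average cued and self-paced MRCPs
  ($\pm 2$ s) per channel, normalized by the peak-to-peak range of the
  self-paced (reference) waveform — a scale-free convention chosen because
  the normalization is not otherwise fixed. Its correlation with TPR across
  subjects uses Pearson's r with the usual $t$-test on $n-2$ degrees of
  freedom.
* **ERDS maps**: 36 center frequencies (5-40 Hz, 2 Hz bandwidth, 4th-order
  zero-phase band-pass at center $\pm 1$ Hz), squared, averaged over
  trials, smoothed with a 0.2 s moving average (the smoothing window is not
  otherwise specified; 0.2 s spans two alpha cycles) and expressed as
  percent change against the $[-2, -0.5]$ s pre-movement reference.
  Significance by percentile bootstrap over trials (default 1000 resamples,
  $\alpha = 0.05$): pixels whose interval contains zero are masked.
  Percentile intervals on skewed band-power means under-cover at small
  trial counts — the null-calibration test documents a ~3x inflation at 36
  trials — which is a known property of this bootstrap, not a defect of the
  implementation.

## Numerical and degenerate-input conventions

* Filters are applied forward-backward, so quoted single-pass attenuations
  double on the amplitude scale; edge transients of the 0.5 Hz high-pass
  edge extend a few seconds and tests measure away from them.
* MCC returns 0 when a denominator factor vanishes and `NA` (flagged) for
  an all-zero confusion matrix; counts are coerced to doubles to avoid
  32-bit overflow in the denominator product.
* A schedule with a single cue has no ITIs; statistics return `NA` with a
  warning. A self-paced duration too short for one movement returns an
  empty timeline with a warning.
* All randomness flows from explicit seeds (`withr::with_seed`); equal
  seeds give bit-identical recordings, and `run_experiment()` derives all
  stage seeds from one master seed.

## Problem sizes

The defaults used by the package's own experiment runner and checks were
chosen once as desk-scale study conditions: 100-trial runs for the schedule
and behavioral statistics (the protocol's own run length); 40-trial runs,
a 120 s eye calibration and a 3x3 or smaller decoder grid for end-to-end
detection benchmarks; 15-trial runs for parameter-recovery checks. The
high-signal benchmark subject uses 1 µV background noise and half-amplitude
rhythms so that detection is limited by the pipeline, not the noise; the
null benchmark subject has a zero-amplitude MRCP so that detection *should*
fail, which the evaluation must report as chance-level TPR.

## Known limitations

* The synthetic EEG is additive and stationary per component; real
  recordings are not, and reported synthetic TPRs do not predict human
  performance.
* The eye-artifact operator is a plain regression; it removes exactly the
  linearly coupled component and nothing else.
* Calibrating the detection threshold on the evaluation run reproduces the
  protocol but inflates TPR slightly; see above.
* BrainVision/EDF readers are not included; recordings enter through the
  package's native container (`write_recording()`/`read_recording()`).
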