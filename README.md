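# fastcue

Fast cue-based training data for asynchronous movement decoding from EEG.

## The problem

Movement-based brain-computer interfaces detect movement intent from the
EEG as it happens (*asynchronous* detection). The detectors must be trained
on labeled movement trials, and for motor-impaired users the only usable
label is a visual cue — but traditional cue-based protocols need 8 s or
more per trial so that visually evoked potentials decay, making training
sessions long and exhausting.

`fastcue` implements a faster alternative: a cross that **rotates
continuously** over a fixed cross, cueing a movement at every overlap. The
angular velocity

ω(t) = 90°/T_ITI + A · sin(2π·a_base·t) · sin(2π·a_mod·t + φ)   [deg/s]

varies smoothly (defaults: T_ITI = 3.3 s, A = 10.24, a_base = 0.032 Hz,
a_mod = 0.016 Hz, φ = 28.1 rad), so inter-trial intervals range from about
2.5 to 4.75 s with no abrupt visual event — 300 cued trials fit in under
18 minutes instead of 42+.

The package contains, end to end:

* the deterministic **cue-schedule generator** and its timing statistics;
* a **synthetic-data generator** for full recordings: 60-channel EEG at
  500 Hz with movement-related cortical potentials (MRCPs), alpha/beta
  rhythms with event-related desynchronization (ERD) and beta rebound,
  1/f background noise, ocular artifacts on 4 EOG channels, a 30 Hz
  finger-motion trace, and ground-truth event tables — for cue-based runs,
  self-paced runs and eye-calibration recordings;
* **preprocessing**: zero-phase Butterworth band-pass (0.5–70 Hz),
  regression-based eye-artifact removal learned on the calibration run,
  3.5 Hz low-pass + decimation to 10 Hz features, common average reference;
* **movement-onset detection** from the motion trace (speed thresholding
  with the two-crossing rule);
* a **shrinkage-LDA detector** (closed-form Ledoit–Wolf linear shrinkage,
  optional quadratic-inverse shrinkage) over sliding feature windows, with
  window length and detection delay selected by runwise 3-fold
  cross-validation on the Matthews correlation coefficient;
* **event-by-event evaluation**: true positive rate (TPR) within a
  [−0.5, +1] s hit window, false positives per minute (FP/min) with a 1 s
  refractory period, and threshold calibration to an FP/min budget;
* **neural-correlate analyses**: MRCP condition comparison (Mann–Whitney U
  with Bonferroni correction), NRMSE-versus-TPR correlation, and ERDS maps
  with bootstrap significance.

## Worked example

```r
library(fastcue)

# 1. the paradigm: one 100-trial run
sched <- generate_cue_schedule(paradigm_config())
schedule_statistics(sched)
#> # A tibble: 1 × 6
#>   n_trials mean_iti_s sd_iti_s min_iti_s max_iti_s run_duration_s
#>      <int>      <dbl>    <dbl>     <dbl>     <dbl>          <dbl>
#> 1      100       3.32    0.625      2.51      4.75           335.
```

One run of 100 cues lasts 335 s; ITIs average 3.32 s and stay between
2.51 s and 4.75 s — three runs collect 300 trials in 16.8 minutes.

```r
# 2. the full pipeline on a strong-signal synthetic participant
cfg <- experiment_config(
  paradigm  = paradigm_config(n_trials = 40),
  subject   = subject_model(noise_scale = 1, alpha_uv = 0.5, beta_uv = 0.5),
  eye_calib_duration = 120,
  seed = 42
)
report <- run_experiment(cfg)
report
#> <experiment_report>
#>   schedule: 40 trials/run, mean ITI 3.31 s
#>   behavior: cue-to-onset delay 83 +/- 145 ms (120/120 detected)
#>   decoder: n_window = 5, d = 0.30 s (CV MCC 0.518)
#>   at <= 0.5 FP/min: TPR 100.0% (achieved 0.43 FP/min)
#>   at <= 1.0 FP/min: TPR 100.0% (achieved 0.43 FP/min)
#>   at <= 2.0 FP/min: TPR 100.0% (achieved 0.43 FP/min)
#>   elapsed: 45.0 s (seed 42)
```

The report reads: onset detection recovered all 120 cued movements with the
expected ~95 ms cue-to-onset lag; cross-validation chose a 0.5 s feature
window with a 0.3 s detection delay; and on the self-paced run the
calibrated detector found every movement while staying below every FP/min
budget — this subject is deliberately high-SNR (1 µV background against a
5 µV MRCP), so detection is limited by the pipeline, not the noise. With
the default 10 µV background the TPR drops and the budget trade-off becomes
visible. `glance(report)` returns the same numbers as a one-row tibble;
`plot_calibration(report)` and `autoplot()` on schedules, epochs and ERDS
maps draw the standard figures.

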