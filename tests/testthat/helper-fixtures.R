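# shared fixtures, built in code at test time

# subject emitting nothing into the EEG (jitter and motion still active)
silent_subject <- function(...) {
  lag <- seq(-2, 2, by = 1 / 500)
  subject_model(
    mrcp_cued = list(lag_s = lag, uv = numeric(length(lag))),
    noise_scale = 0, alpha_uv = 0, beta_uv = 0,
    eog_coupling = matrix(0, 60, 4), blink_rate = 0,
    ...
  )
}

# low-noise subject for parameter-recovery and end-to-end checks
clean_subject <- function(...) {
  subject_model(noise_scale = 1, alpha_uv = 0.5, beta_uv = 0.5, ...)
}

# short schedule for fast simulations
tiny_schedule <- function(n_trials = 5, ...) {
  generate_cue_schedule(paradigm_config(n_trials = n_trials, ...))
}

# recording built directly from matrices (white noise unless supplied)
toy_recording <- function(n = 2000, eeg = NULL, eog = NULL, rate = 500,
                          run_kind = "cued") {
  if (is.null(eeg)) eeg <- matrix(rnorm(60 * n), 60, n)
  if (is.null(eog)) eog <- matrix(rnorm(4 * n), 4, n)
  eeg_recording(eeg, eog, motion_xy = NULL, run_kind = run_kind,
                eeg_rate = rate)
}

# analytic magnitude response of a digital Butterworth low-pass designed via
# the bilinear transform: |H|^2 = 1 / (1 + (tan(pi f/fs) / tan(pi fc/fs))^2n)
butter_lowpass_gain <- function(f, fc, fs, n) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * n))
}

# analytic magnitude of a digital Butterworth band-pass from an order-n
# prototype (overall order 2n), bilinear-transformed edges fl < fh
butter_bandpass_gain <- function(f, fl, fh, fs, n) {
  v <- tan(pi * f / fs)
  vl <- tan(pi * fl / fs)
  vh <- tan(pi * fh / fs)
  1 / sqrt(1 + ((v^2 - vl * vh) / (v * (vh - vl)))^(2 * n))
}

# amplitude of a sinusoid at frequency f in a vector sampled at fs,
# measured away from the filter edges
sine_amplitude <- function(x, f, fs) {
  n <- length(x)
  i <- seq(round(n * 0.2), round(n * 0.8))
  tt <- (i - 1) / fs
  2 * sqrt(mean(x[i] * sin(2 * pi * f * tt))^2 +
             mean(x[i] * cos(2 * pi * f * tt))^2)
}
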