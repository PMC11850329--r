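#' Waveform of a movement-related cortical potential
#'
#' Piecewise-smooth template on a lag axis relative to movement onset: a
#' linear negative drift from `rise_start` seconds before onset to the peak
#' negativity `peak_uv` at lag 0, a cosine-interpolated swing to the
#' post-movement positivity `pos_uv` peaking at `pos_lag`, and a cosine decay
#' back to zero at `end` seconds. Zero outside `[rise_start, end]`.
#'
#' @param lag_s Lag axis in seconds (0 = movement onset).
#' @param peak_uv Peak negativity at onset, microvolts (negative).
#' @param pos_uv Post-movement positivity, microvolts.
#' @param pos_lag Lag of the positivity peak, seconds.
#' @param rise_start Start of the pre-movement negativity, seconds (negative).
#' @param end Lag at which the waveform has returned to zero, seconds.
#' @return Numeric vector of amplitudes, same length as `lag_s`.
#' @export
mrcp_waveform <- function(lag_s, peak_uv = -5, pos_uv = 3, pos_lag = 0.6,
                          rise_start = -2, end = 2) {
  stopifnot(rise_start < 0, end > pos_lag, pos_lag > 0)
  w <- numeric(length(lag_s))
  i <- lag_s >= rise_start & lag_s < 0
  w[i] <- peak_uv * (lag_s[i] - rise_start) / (-rise_start)
  i <- lag_s >= 0 & lag_s < pos_lag
  th <- pi * lag_s[i] / pos_lag
  w[i] <- peak_uv + (pos_uv - peak_uv) * (1 - cos(th)) / 2
  i <- lag_s >= pos_lag & lag_s <= end
  th <- pi * (lag_s[i] - pos_lag) / (end - pos_lag)
  w[i] <- pos_uv * (1 + cos(th)) / 2
  w
}

# default 4->60 ocular propagation matrix: strongest frontally, lateralised
# for the horizontal (canthus) sources
default_eog_coupling <- function(labels = fastcue_montage()) {
  pos <- electrode_positions(labels)
  front <- exp(-(1 - pos$y) / 0.5)
  cbind(
    EOGL = 0.20 * front * pmax(-pos$x, 0) + 0.02 * front,
    EOGR = 0.20 * front * pmax(pos$x, 0) + 0.02 * front,
    EOGU = 0.35 * front,
    EOGD = -0.12 * front
  )
}

#' Generative model of one synthetic participant
#'
#' Collects every parameter of the synthetic EEG/EOG/motion generator: the
#' MRCP templates for cued and self-paced movements (time course times a
#' spatial pattern over the montage), oscillatory amplitudes and
#' event-related desynchronization depth, 1/f background noise level, ocular
#' coupling, the cue-to-onset jitter distribution and the movement morphology.
#'
#' Defaults describe an idealised right-hand finger flexion: contralateral
#' central MRCP peaking at -5 uV at onset, 10 Hz alpha and 20 Hz beta
#' rhythms (2 uV) with 60 % desynchronization around movement and a beta
#' rebound after it, 10 uV RMS 1/f noise, and movement onsets lagging the cue
#' by 95 +/- 151 ms.
#'
#' @param mrcp_cued,mrcp_selfpaced MRCP time courses: lists with `lag_s` and
#'   `uv` (equal length). Defaults use [mrcp_waveform()] on a 500 Hz lag grid.
#'   The self-paced template may differ from the cued one to emulate
#'   between-condition dissimilarity.
#' @param mrcp_center,mrcp_sigma Centre electrode and spatial spread of the
#'   Gaussian MRCP scalp pattern.
#' @param erd_depth Fractional band-power drop during movement, in `[0, 1]`.
#' @param beta_rebound Fractional band-power increase of the post-movement
#'   beta synchronization.
#' @param alpha_uv,beta_uv RMS amplitude of the alpha (10 Hz) and beta (20 Hz)
#'   rhythms, microvolts.
#' @param noise_scale RMS of the 1/f background noise per channel, microvolts.
#' @param eog_coupling 60 x 4 matrix mapping the four EOG sources onto the
#'   EEG channels.
#' @param onset_jitter_mean,onset_jitter_sd Gaussian cue-to-onset delay
#'   parameters, seconds; draws are truncated at 3 SD.
#' @param movement_hold Seconds the flexion is held before the return
#'   movement.
#' @param move_pulse_s Duration of each of the two motion speed pulses
#'   (flexion, return), seconds.
#' @param move_amplitude Displacement of the flexion in position units.
#' @param motion_noise RMS position noise of the motion capture trace.
#' @param blink_rate Blink rate during task runs, per second.
#'
#' @return A list of class `subject_model`.
#' @export
subject_model <- function(mrcp_cued = NULL,
                          mrcp_selfpaced = NULL,
                          mrcp_center = "C1",
                          mrcp_sigma = 0.45,
                          erd_depth = 0.6,
                          beta_rebound = 0.5,
                          alpha_uv = 2,
                          beta_uv = 2,
                          noise_scale = 10,
                          eog_coupling = default_eog_coupling(),
                          onset_jitter_mean = 0.095,
                          onset_jitter_sd = 0.151,
                          movement_hold = 0.5,
                          move_pulse_s = 0.3,
                          move_amplitude = 1,
                          motion_noise = 0.004,
                          blink_rate = 0.1) {
  default_wave <- function() {
    lag <- seq(-2, 2, by = 1 / 500)
    list(lag_s = lag, uv = mrcp_waveform(lag))
  }
  if (is.null(mrcp_cued)) mrcp_cued <- default_wave()
  if (is.null(mrcp_selfpaced)) mrcp_selfpaced <- mrcp_cued
  check_wave <- function(w, nm) {
    stopifnot(is.list(w), length(w$lag_s) == length(w$uv))
    if (any(w$lag_s < -2 - 1e-9) || any(w$lag_s > 2 + 1e-9)) {
      stop(nm, ": template support must lie within [-2, 2] s")
    }
  }
  check_wave(mrcp_cued, "mrcp_cued")
  check_wave(mrcp_selfpaced, "mrcp_selfpaced")
  stopifnot(
    erd_depth >= 0, erd_depth <= 1, beta_rebound >= 0,
    noise_scale >= 0, alpha_uv >= 0, beta_uv >= 0,
    is.matrix(eog_coupling), ncol(eog_coupling) == 4L,
    onset_jitter_sd >= 0, movement_hold > 0, move_pulse_s > 0,
    move_amplitude >= 0, motion_noise >= 0, blink_rate >= 0
  )
  structure(
    list(
      mrcp_cued = mrcp_cued, mrcp_selfpaced = mrcp_selfpaced,
      mrcp_center = mrcp_center, mrcp_sigma = mrcp_sigma,
      erd_depth = erd_depth, beta_rebound = beta_rebound,
      alpha_uv = alpha_uv, beta_uv = beta_uv, noise_scale = noise_scale,
      eog_coupling = eog_coupling,
      onset_jitter_mean = onset_jitter_mean,
      onset_jitter_sd = onset_jitter_sd,
      movement_hold = movement_hold, move_pulse_s = move_pulse_s,
      move_amplitude = move_amplitude, motion_noise = motion_noise,
      blink_rate = blink_rate
    ),
    class = "subject_model"
  )
}
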