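# --- signal building blocks ---------------------------------------------

# 1/f-shaped noise via spectral shaping of white noise; power ~ 1/f above
# f_knee, flat below; normalised to the requested RMS
pink_noise <- function(n, rate, rms, f_knee = 0.5) {
  if (rms == 0) return(numeric(n))
  nfft <- stats::nextn(n) # highly composite length keeps the FFT fast
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- seq(0, rate, length.out = nfft + 1L)[seq_len(nfft)]
  f <- pmin(f, rate - f) # two-sided frequency magnitude
  g <- 1 / sqrt(pmax(f, f_knee))
  g[1L] <- 0 # remove DC
  x <- Re(stats::fft(W * g, inverse = TRUE))[seq_len(n)] / nfft
  x * rms / stats::sd(x)
}

# band-limited Gaussian noise (4th-order zero-phase Butterworth band-pass)
band_noise <- function(n, rate, band, rms) {
  if (rms == 0) return(numeric(n))
  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x * rms / stats::sd(x)
}

# amplitude envelope implementing ERD around movements and, optionally, the
# post-movement rebound (ERS). Power factors (1 - depth) and (1 + rebound)
# enter as square roots on the amplitude. Ramps are half-cosines of 0.25 s.
erd_envelope <- function(n, rate, onsets, move_end, depth, rebound = 0) {
  env <- rep(1, n)
  ramp <- 0.25
  amp_low <- sqrt(1 - depth)
  amp_high <- sqrt(1 + rebound)
  add_segment <- function(env, from, to, level) {
    tt <- (seq_len(n) - 1L) / rate
    up <- (tt - (from - ramp)) / ramp
    down <- ((to + ramp) - tt) / ramp
    shape <- pmin(pmax(pmin(up, down), 0), 1)
    env + (level - 1) * (1 - cos(pi * shape)) / 2
  }
  for (k in seq_along(onsets)) {
    env <- add_segment(env, onsets[k] - 0.5, move_end[k], amp_low)
    if (rebound > 0) {
      env <- add_segment(env, move_end[k] + 0.5, move_end[k] + 1.5, amp_high)
    }
  }
  env
}

# add wave * weights (outer product) into `mat` centred at each of `centers_s`
add_template <- function(mat, weights, wave, lag_s, centers_s, rate) {
  for (center_s in centers_s) {
    idx <- round((center_s + lag_s) * rate) + 1L
    ok <- idx >= 1L & idx <= ncol(mat)
    if (any(ok)) {
      mat[, idx[ok]] <- mat[, idx[ok]] + outer(weights, wave[ok])
    }
  }
  mat
}

# truncated Gaussian draws (rejection beyond `k` SDs)
rnorm_trunc <- function(n, mean, sd, k = 3) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

# two raised-cosine speed pulses (flexion and return) separated by the hold;
# returns a motion position matrix 2 x n with measurement noise
motion_trace <- function(n, rate, onsets, subject) {
  vx <- numeric(n)
  vy <- numeric(n)
  tt <- (seq_len(n) - 1L) / rate
  dir <- c(2, 1) / sqrt(5) # flexion direction in the camera plane
  peak <- 2 * subject$move_amplitude / subject$move_pulse_s
  pulse <- function(t0) {
    u <- (tt - t0) / subject$move_pulse_s
    ifelse(u >= 0 & u <= 1, peak * (1 - cos(2 * pi * u)) / 2, 0)
  }
  for (t0 in onsets) {
    s <- pulse(t0) - pulse(t0 + subject$move_pulse_s + subject$movement_hold)
    vx <- vx + dir[1L] * s
    vy <- vy + dir[2L] * s
  }
  pos <- rbind(cumsum(vx) / rate, cumsum(vy) / rate)
  pos + matrix(stats::rnorm(2L * n, 0, subject$motion_noise), 2L, n)
}

# independent per-channel ocular background: micro-movement drift plus
# measurement noise, keeping the four EOG channels individually identifiable
eog_background <- function(n, rate) {
  bg <- matrix(0, 4L, n)
  for (ch in 1:4) {
    bg[ch, ] <- band_noise(n, rate, c(0.3, 8), 6) + stats::rnorm(n)
  }
  bg
}

# ocular background during task runs: blinks plus small horizontal saccades
task_eog <- function(n, rate, subject) {
  eog <- matrix(0, 4L, n)
  tt <- (seq_len(n) - 1L) / rate
  dur <- n / rate
  n_blink <- stats::rpois(1L, subject$blink_rate * dur)
  if (n_blink > 0) {
    for (t0 in sort(stats::runif(n_blink, 1, dur - 1))) {
      u <- (tt - t0) / 0.25
      b <- ifelse(u >= 0 & u <= 1, (1 - cos(2 * pi * u)) / 2, 0)
      eog[3L, ] <- eog[3L, ] + 150 * stats::runif(1, 0.85, 1.15) * b
      eog[4L, ] <- eog[4L, ] - 40 * stats::runif(1, 0.85, 1.15) * b
    }
  }
  n_sacc <- stats::rpois(1L, 0.05 * dur)
  if (n_sacc > 0) {
    for (t0 in sort(stats::runif(n_sacc, 1, dur - 1))) {
      amp <- stats::runif(1, 20, 60) * sample(c(-1, 1), 1L)
      step <- amp * stats::plogis((tt - t0) / 0.02) *
        exp(-pmax(tt - t0, 0) / 1.5)
      eog[1L, ] <- eog[1L, ] + stats::runif(1, 0.85, 1.15) * step
      eog[2L, ] <- eog[2L, ] - stats::runif(1, 0.85, 1.15) * step
    }
  }
  eog + eog_background(n, rate)
}

# assemble EEG/EOG/motion for a set of movement onsets
build_run <- function(duration, onsets, cue_times, template, subject,
                      run_kind, eeg_rate = 500, motion_rate = 30) {
  n <- round(duration * eeg_rate)
  labels <- fastcue_montage()
  if (nrow(subject$eog_coupling) != length(labels)) {
    stop("input error: eog_coupling rows (", nrow(subject$eog_coupling),
         ") do not match the ", length(labels), "-channel montage")
  }
  weights <- spatial_pattern(labels, subject$mrcp_center, subject$mrcp_sigma)
  eeg <- matrix(0, length(labels), n)
  eeg <- add_template(eeg, weights, template$uv, template$lag_s, onsets,
                      eeg_rate)
  move_end <- onsets + 2 * subject$move_pulse_s + subject$movement_hold
  if (subject$alpha_uv > 0 || subject$beta_uv > 0) {
    env_a <- erd_envelope(n, eeg_rate, onsets, move_end, subject$erd_depth)
    env_b <- erd_envelope(n, eeg_rate, onsets, move_end, subject$erd_depth,
                          subject$beta_rebound)
    osc_w <- 0.3 + 0.7 * weights # rhythms widespread but centrally dominant
    for (ch in seq_along(labels)) {
      if (subject$alpha_uv > 0) {
        eeg[ch, ] <- eeg[ch, ] +
          osc_w[ch] * env_a * band_noise(n, eeg_rate, c(8, 12), subject$alpha_uv)
      }
      if (subject$beta_uv > 0) {
        eeg[ch, ] <- eeg[ch, ] +
          osc_w[ch] * env_b * band_noise(n, eeg_rate, c(18, 22), subject$beta_uv)
      }
    }
  }
  if (subject$noise_scale > 0) {
    for (ch in seq_along(labels)) {
      eeg[ch, ] <- eeg[ch, ] + pink_noise(n, eeg_rate, subject$noise_scale)
    }
  }
  eog <- task_eog(n, eeg_rate, subject)
  eeg <- eeg + subject$eog_coupling %*% eog
  n_m <- round(duration * motion_rate)
  motion <- motion_trace(n_m, motion_rate, onsets, subject)
  events <- dplyr::bind_rows(
    if (length(cue_times)) tibble::tibble(onset_s = cue_times, kind = "cue"),
    tibble::tibble(onset_s = onsets, kind = "movement_onset"),
    tibble::tibble(onset_s = onsets + subject$move_pulse_s +
                     subject$movement_hold, kind = "movement_offset")
  )
  events <- dplyr::arrange(events, .data$onset_s)
  eeg_recording(eeg, eog, motion, events, run_kind,
                eeg_rate = eeg_rate, motion_rate = motion_rate)
}

# --- exported simulators -------------------------------------------------

#' Simulate one cue-based run
#'
#' Generates a full synthetic recording for a cue schedule: movement onsets
#' are the cue times plus truncated-Gaussian delays
#' (`onset_jitter_mean`/`onset_jitter_sd`, truncated at 3 SD), and the EEG is
#' the sum of per-movement MRCP templates, alpha/beta rhythms with
#' event-related desynchronization and beta rebound, 1/f background noise and
#' propagated ocular activity. The motion trace shows the characteristic
#' two-peak speed profile (flexion and return separated by the hold).
#'
#' @param schedule A `cue_schedule` from [generate_cue_schedule()].
#' @param subject A [subject_model()].
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An [eeg_recording()] with `run_kind = "cued"` and ground-truth
#'   `cue`, `movement_onset` and `movement_offset` events.
#' @export
simulate_cued_run <- function(schedule, subject = subject_model(), seed = 1L) {
  stopifnot(inherits(schedule, "cue_schedule"), inherits(subject, "subject_model"))
  cues <- schedule$cues$onset_s
  if (length(cues) < 1L) stop("schedule contains no cues")
  withr::with_seed(seed, {
    jitter <- rnorm_trunc(length(cues), subject$onset_jitter_mean,
                          subject$onset_jitter_sd)
    onsets <- cues + jitter
    build_run(schedule$run_duration + 2, onsets, cues, subject$mrcp_cued,
              subject, "cued")
  })
}

#' Simulate a self-paced movement timeline
#'
#' Onset times alternating between bursts of consecutive movements
#' (within-burst intervals around 3.5 s) and pauses of about 10 s, tuned so
#' the long-run mean inter-movement interval is about 3.9 s with SD about
#' 1.4 s. All onsets lie within `[2, duration - 2]` s.
#'
#' @param duration Run duration in seconds.
#' @param subject A [subject_model()] (reserved for future morphology use).
#' @param seed Integer seed.
#' @return Numeric vector of onset times (possibly empty, with a warning, if
#'   the duration cannot fit one movement).
#' @export
simulate_self_paced_timeline <- function(duration, subject = subject_model(),
                                         seed = 1L) {
  stopifnot(is.numeric(duration), duration > 0)
  if (duration < 4.5) {
    warning("duration too short for one movement; returning empty timeline")
    return(numeric(0))
  }
  withr::with_seed(seed, {
    onsets <- numeric(0)
    t <- 2 + stats::runif(1, 0, 1)
    burst_left <- 1L + stats::rgeom(1L, 1 / 18)
    while (t <= duration - 2) {
      onsets <- c(onsets, t)
      burst_left <- burst_left - 1L
      gap <- if (burst_left > 0L) {
        max(1.5, stats::rnorm(1, 3.5, 0.5))
      } else {
        burst_left <- 1L + stats::rgeom(1L, 1 / 18)
        max(6, stats::rnorm(1, 10, 1))
      }
      t <- t + gap
    }
    onsets
  })
}

#' Simulate a self-paced run
#'
#' As [simulate_cued_run()] but for participant-chosen movement times: no cue
#' events are generated and the self-paced MRCP template variant is used.
#'
#' @param onsets Movement onset times in seconds, e.g. from
#'   [simulate_self_paced_timeline()].
#' @param subject A [subject_model()].
#' @param seed Integer seed.
#' @param duration Run duration in seconds; defaults to 2 s past the last
#'   onset.
#' @return An [eeg_recording()] with `run_kind = "self_paced"`.
#' @export
simulate_self_paced_run <- function(onsets, subject = subject_model(),
                                    seed = 1L, duration = NULL) {
  stopifnot(inherits(subject, "subject_model"), is.numeric(onsets))
  if (is.null(duration)) duration <- if (length(onsets)) max(onsets) + 2 else 10
  stopifnot(duration > 0)
  withr::with_seed(seed, {
    build_run(duration, onsets, numeric(0), subject$mrcp_selfpaced,
              subject, "self_paced")
  })
}

#' Simulate an eye-movement calibration recording
#'
#' Blocks of horizontal saccades, vertical saccades, blinks and rest are
#' cycled for the requested duration (about 7 minutes by default). The EOG
#' channels carry the corresponding waveforms; the EEG is 1/f noise plus the
#' propagated ocular activity, with no movement-related potentials. The
#' resulting recording is the input for [fit_eog_removal()].
#'
#' @param duration Recording duration in seconds.
#' @param subject A [subject_model()] supplying `eog_coupling` and
#'   `noise_scale`.
#' @param seed Integer seed.
#' @return An [eeg_recording()] with `run_kind = "eye_calibration"` and one
#'   event per block (`kind` in `horizontal`, `vertical`, `blink`, `rest`).
#' @export
simulate_eye_calibration <- function(duration = 420, subject = subject_model(),
                                     seed = 1L) {
  stopifnot(inherits(subject, "subject_model"), duration > 0)
  rate <- 500
  n <- round(duration * rate)
  kinds <- c("horizontal", "vertical", "blink", "rest")
  withr::with_seed(seed, {
    eog <- matrix(0, 4L, n)
    tt <- (seq_len(n) - 1L) / rate
    block_len <- 10
    starts <- seq(0, duration - 1e-9, by = block_len)
    blocks <- tibble::tibble(
      onset_s = starts,
      kind = kinds[(seq_along(starts) - 1L) %% 4L + 1L]
    )
    smooth_steps <- function(times, amps) {
      s <- numeric(n)
      for (k in seq_along(times)) {
        s <- s + amps[k] * stats::plogis((tt - times[k]) / 0.02)
      }
      s
    }
    for (b in seq_len(nrow(blocks))) {
      b0 <- blocks$onset_s[b]
      b1 <- min(b0 + block_len, duration)
      idx <- tt >= b0 & tt < b1
      if (b1 - b0 < 1.5) next
      if (blocks$kind[b] == "horizontal") {
        times <- seq(b0 + 0.5, b1 - 0.5, by = 1)
        amps <- 60 * rep_len(c(1, -1), length(times)) * stats::runif(length(times), 0.7, 1.3)
        s <- smooth_steps(times, amps)
        g <- stats::runif(2, 0.85, 1.15) # per-electrode gain asymmetry
        eog[1L, idx] <- eog[1L, idx] + g[1L] * s[idx]
        eog[2L, idx] <- eog[2L, idx] - g[2L] * s[idx]
      } else if (blocks$kind[b] == "vertical") {
        times <- seq(b0 + 0.5, b1 - 0.5, by = 1)
        amps <- 50 * rep_len(c(1, -1), length(times)) * stats::runif(length(times), 0.7, 1.3)
        s <- smooth_steps(times, amps)
        g <- stats::runif(2, 0.85, 1.15)
        eog[3L, idx] <- eog[3L, idx] + g[1L] * s[idx]
        eog[4L, idx] <- eog[4L, idx] - 0.4 * g[2L] * s[idx]
      } else if (blocks$kind[b] == "blink" && b1 - b0 >= 1.5) {
        for (t0 in seq(b0 + 0.75, b1 - 0.75, by = 1.5)) {
          u <- (tt - t0) / 0.25
          bl <- ifelse(u >= 0 & u <= 1, (1 - cos(2 * pi * u)) / 2, 0)
          eog[3L, ] <- eog[3L, ] + 150 * bl
          eog[4L, ] <- eog[4L, ] - 40 * bl
        }
      }
    }
    eog <- eog + eog_background(n, rate)
    labels <- fastcue_montage()
    eeg <- matrix(0, length(labels), n)
    if (subject$noise_scale > 0) {
      for (ch in seq_along(labels)) {
        eeg[ch, ] <- eeg[ch, ] + pink_noise(n, rate, subject$noise_scale)
      }
    }
    eeg <- eeg + subject$eog_coupling %*% eog
    eeg_recording(eeg, eog, NULL, blocks, "eye_calibration", eeg_rate = rate)
  })
}
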