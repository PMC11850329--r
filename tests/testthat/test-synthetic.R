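test_that("a silent subject produces identically zero EEG", {
  s <- tiny_schedule(3)
  rec <- simulate_cued_run(s, silent_subject(), seed = 1)
  expect_true(all(rec$eeg == 0))
  expect_false(all(rec$eog == 0)) # ocular activity exists but is not coupled
})

test_that("cue-to-onset jitter matches the generating distribution", {
  s <- generate_cue_schedule(paradigm_config(n_trials = 100))
  rec1 <- simulate_cued_run(s, silent_subject(), seed = 21)
  rec2 <- simulate_cued_run(s, silent_subject(), seed = 22)
  d <- c(event_times(rec1, "movement_onset") - event_times(rec1, "cue"),
         event_times(rec2, "movement_onset") - event_times(rec2, "cue"))
  n <- length(d)
  expect_equal(n, 200L)
  expect_lt(abs(mean(d) - 0.095), 3 * 0.151 / sqrt(n))
  expect_lt(abs(sd(d) - 0.151), 3 * 0.151 / sqrt(2 * n))
  expect_true(all(abs(d - 0.095) <= 3 * 0.151 + 1e-9)) # truncation
})

test_that("every cue generates exactly one movement", {
  s <- tiny_schedule(7)
  rec <- simulate_cued_run(s, silent_subject(), seed = 5)
  expect_length(event_times(rec, "movement_onset"), 7L)
  expect_length(event_times(rec, "movement_offset"), 7L)
  expect_length(event_times(rec, "cue"), 7L)
})

test_that("simulation is bit-identical under a fixed seed", {
  s <- tiny_schedule(3)
  sub <- subject_model()
  a <- simulate_cued_run(s, sub, seed = 99)
  b <- simulate_cued_run(s, sub, seed = 99)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$eog, b$eog)
  expect_identical(a$motion_xy, b$motion_xy)
  expect_identical(a$events, b$events)
  c <- simulate_cued_run(s, sub, seed = 100)
  expect_false(identical(a$eeg, c$eeg))
})

test_that("self-paced timelines alternate bursts and pauses at the target rate", {
  on <- simulate_self_paced_timeline(3000, seed = 4)
  iti <- diff(on)
  expect_true(all(iti >= 1.5))
  expect_true(all(diff(on) > 0))
  expect_true(all(on >= 2 & on <= 2998))
  expect_lt(abs(mean(iti) - 3.9), 0.3)
  expect_lt(abs(sd(iti) - 1.4), 0.6)
  expect_gt(max(iti), 6) # pauses are present
})

test_that("too-short self-paced durations yield an empty timeline", {
  expect_warning(on <- simulate_self_paced_timeline(1, seed = 1), "short")
  expect_length(on, 0L)
})

test_that("grand-average epochs recover the injected MRCP template", {
  # ITIs of 6 s so neighbouring +/-2 s templates cannot overlap in the epoch
  s <- tiny_schedule(20, t_iti = 6, a = 0)
  sub <- subject_model(noise_scale = 0.5, alpha_uv = 0, beta_uv = 0,
                       eog_coupling = matrix(0, 60, 4), blink_rate = 0)
  rec <- simulate_cued_run(s, sub, seed = 31)
  ep <- epoch_onsets(rec, event_times(rec, "movement_onset"), c(-2, 2))
  avg <- epoch_average(ep, "C1")
  w <- fastcue:::spatial_pattern(fastcue_montage(), "C1", 0.45)
  w_c1 <- w[match("C1", fastcue_montage())]
  template <- sub$mrcp_cued$uv * w_c1
  rms_err <- sqrt(mean((avg$mean_uv - template)^2))
  expect_lt(rms_err, 3 * 0.5 / sqrt(20))
  # peak negativity lands at movement onset
  expect_lt(abs(avg$time_s[which.min(avg$mean_uv)]), 0.05)
})

test_that("cued and self-paced runs share the MRCP when templates are equal", {
  # sparse timing in both runs so the epoch averages are overlap-free
  s <- tiny_schedule(15, t_iti = 6, a = 0)
  sub <- subject_model(noise_scale = 0.3, alpha_uv = 0, beta_uv = 0,
                       eog_coupling = matrix(0, 60, 4), blink_rate = 0)
  cued <- simulate_cued_run(s, sub, seed = 41)
  on <- seq(5, 89, by = 6)
  sp <- simulate_self_paced_run(on, sub, seed = 43)
  a <- epoch_average(epoch_onsets(cued, event_times(cued, "movement_onset"),
                                  c(-2, 2)), "C1")
  b <- epoch_average(suppressWarnings(
    epoch_onsets(sp, event_times(sp, "movement_onset"), c(-2, 2))
  ), "C1")
  expect_lt(nrmse(a$mean_uv, b$mean_uv), 0.06)
})

test_that("oscillations desynchronise around movement and rebound after it", {
  s <- tiny_schedule(15)
  sub <- subject_model(noise_scale = 0, alpha_uv = 2, beta_uv = 2,
                       erd_depth = 0.6, beta_rebound = 0.5,
                       eog_coupling = matrix(0, 60, 4), blink_rate = 0)
  rec <- simulate_cued_run(s, sub, seed = 51)
  on <- event_times(rec, "movement_onset")
  off <- event_times(rec, "movement_offset")
  c1 <- rec$eeg[match("C1", rec$channel_labels), ]
  tt <- (seq_along(c1) - 1) / rec$eeg_rate
  bf_a <- signal::butter(2, c(8, 12) / 250, type = "pass")
  alpha_pow <- signal::filtfilt(bf_a, c1)^2
  bf_b <- signal::butter(2, c(18, 22) / 250, type = "pass")
  beta_pow <- signal::filtfilt(bf_b, c1)^2
  in_win <- function(centers, w) {
    rowSums(outer(tt, centers, function(a, b) a >= b + w[1] & a <= b + w[2])) > 0
  }
  ref <- in_win(on, c(-2, -1))
  move <- in_win(on, c(0, 0.5))
  expect_lt(mean(alpha_pow[move]), 0.7 * mean(alpha_pow[ref]))
  rebound <- in_win(off + 0.3, c(0.5, 1.5))
  expect_gt(mean(beta_pow[rebound]), 1.1 * mean(beta_pow[ref]))
})

test_that("motion traces show the two-peak speed profile of one movement", {
  s <- tiny_schedule(5)
  sub <- subject_model(motion_noise = 0)
  rec <- simulate_cued_run(s, sub, seed = 61)
  sp <- compute_speed(rec)
  on <- event_times(rec, "movement_onset")[1]
  seg <- sp$speed[sp$time_s >= on - 0.1 & sp$time_s <= on + 1.4]
  thr <- max(seg) / 2
  runs <- rle(seg > thr)
  expect_equal(sum(runs$values), 2L) # two distinct supra-threshold pulses
})

test_that("eye-calibration recordings carry all four block kinds", {
  sub <- subject_model(noise_scale = 1)
  calib <- simulate_eye_calibration(60, sub, seed = 71)
  expect_setequal(unique(calib$events$kind),
                  c("horizontal", "vertical", "blink", "rest"))
  expect_null(calib$motion_xy)
})

test_that("uncoupled EEG is uncorrelated with the EOG channels", {
  # both signals are strongly autocorrelated, so the effective sample size
  # is far below the sample count; a long recording keeps chance |r| < 0.05
  sub <- subject_model(noise_scale = 5, eog_coupling = matrix(0, 60, 4))
  calib <- simulate_eye_calibration(400, sub, seed = 72)
  cors <- abs(stats::cor(t(calib$eeg[1:10, ]), t(calib$eog)))
  expect_lt(max(cors), 0.05)
})
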