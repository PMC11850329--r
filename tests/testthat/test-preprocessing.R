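test_that("band-pass removes DC and passes mid-band sinusoids", {
  n <- 20000
  rec_dc <- toy_recording(n, eeg = matrix(5, 60, n), eog = matrix(5, 4, n))
  out <- bandpass(rec_dc)
  # > 40 dB attenuation of DC away from the filtfilt edge transients
  expect_lt(max(abs(out$eeg[, 5000:15000])), 0.05)
  n <- 5000

  tt <- (0:(n - 1)) / 500
  rec_sin <- toy_recording(n, eeg = matrix(sin(2 * pi * 10 * tt), 60, n,
                                           byrow = TRUE))
  got <- sine_amplitude(bandpass(rec_sin)$eeg[1, ], 10, 500)
  want <- butter_bandpass_gain(10, 0.5, 70, 500, 2)^2 # zero-phase: |H|^2
  expect_equal(got, want, tolerance = 0.01)
  expect_equal(got, 1, tolerance = 0.01)
})

test_that("band-pass rejects out-of-band components per the analytic response", {
  n <- 5000
  tt <- (0:(n - 1)) / 500
  rec <- toy_recording(n, eeg = matrix(sin(2 * pi * 200 * tt), 60, n,
                                       byrow = TRUE))
  got <- sine_amplitude(bandpass(rec)$eeg[1, ], 200, 500)
  want <- butter_bandpass_gain(200, 0.5, 70, 500, 2)^2
  expect_lt(got, 0.01)
  expect_equal(got, want, tolerance = 0.25) # small numbers, relative check
})

test_that("band-pass refuses too-low sampling rates", {
  rec <- toy_recording(1000, rate = 100)
  expect_error(bandpass(rec, high = 70), "too low")
})

test_that("the ocular coupling matrix is recovered from calibration data", {
  sub <- subject_model(noise_scale = 1)
  calib <- simulate_eye_calibration(180, sub, seed = 11)
  m <- fit_eog_removal(bandpass(calib))
  rel_err <- norm(m$coupling_estimate - sub$eog_coupling, "F") /
    norm(sub$eog_coupling, "F")
  expect_lt(rel_err, 0.05)

  # residual orthogonality: cleaned EEG is uncorrelated with the EOG
  cleaned <- apply_eog_removal(m, bandpass(calib))
  cors <- abs(stats::cor(t(cleaned$eeg[seq(1, 60, by = 6), ]), t(cleaned$eog)))
  expect_lt(max(cors), 0.02)
})

test_that("zero coupling fits to near-zero coefficients", {
  sub <- subject_model(noise_scale = 2, eog_coupling = matrix(0, 60, 4))
  calib <- simulate_eye_calibration(120, sub, seed = 12)
  m <- fit_eog_removal(calib)
  expect_lt(max(abs(m$coupling_estimate)), 0.02)
})

test_that("rank-deficient EOG is rejected", {
  rec <- toy_recording(1000, eog = matrix(1, 4, 1000))
  expect_error(fit_eog_removal(rec), "rank deficient")
})

test_that("eye-artifact removal subtracts exactly the modelled component", {
  zero <- structure(
    list(coupling_estimate = matrix(0, 60, 4), fitted_on = "none"),
    class = "eog_removal_model"
  )
  rec <- toy_recording(1000)
  expect_equal(apply_eog_removal(zero, rec)$eeg, rec$eeg)

  # clean + B . EOG with the true B recovers clean
  B <- matrix(runif(240, -0.3, 0.3), 60, 4)
  clean_eeg <- matrix(rnorm(60 * 3000), 60, 3000)
  eog <- matrix(rnorm(4 * 3000, sd = 30), 4, 3000)
  rec2 <- eeg_recording(clean_eeg + B %*% eog, eog, run_kind = "cued")
  model <- structure(list(coupling_estimate = B, fitted_on = "truth"),
                     class = "eog_removal_model")
  out <- apply_eog_removal(model, rec2)
  expect_equal(unname(out$eeg), clean_eeg, tolerance = 1e-10)
})

test_that("re-fitting on cleaned data leaves it essentially unchanged", {
  sub <- subject_model(noise_scale = 2)
  calib <- simulate_eye_calibration(120, sub, seed = 13)
  m1 <- fit_eog_removal(calib)
  once <- apply_eog_removal(m1, calib)
  m2 <- fit_eog_removal(once)
  twice <- apply_eog_removal(m2, once)
  expect_lt(sqrt(mean((twice$eeg - once$eeg)^2)) / sqrt(mean(once$eeg^2)),
            0.01)
})

test_that("removal rejects mismatched dimensions", {
  m <- structure(list(coupling_estimate = matrix(0, 59, 4), fitted_on = "x"),
                 class = "eog_removal_model")
  expect_error(apply_eog_removal(m, toy_recording(100)), "mismatch")
})

test_that("feature extraction low-passes and decimates to 10 Hz", {
  n <- 5000
  rec_const <- toy_recording(n, eeg = matrix(2.5, 60, n),
                             eog = matrix(0, 4, n))
  f <- extract_lowfreq_features(rec_const)
  expect_equal(dim(f$values), c(60L, n / 50))
  # constant in, constant out (away from the edge transients)
  expect_equal(unname(f$values[1, 20:80]), rep(2.5, 61), tolerance = 1e-6)
  expect_equal(f$rate, 10)

  tt <- (0:(n - 1)) / 500
  rec_sin <- toy_recording(n, eeg = matrix(sin(2 * pi * 2 * tt) +
                                             sin(2 * pi * 10 * tt), 60, n,
                                           byrow = TRUE))
  lp <- fastcue:::filtfilt_rows(rec_sin$eeg[1, , drop = FALSE],
                                signal::butter(4, 3.5 / 250, type = "low"))
  got10 <- sine_amplitude(lp[1, ], 10, 500)
  want10 <- butter_lowpass_gain(10, 3.5, 500, 4)^2
  expect_equal(got10, want10, tolerance = 0.05)
  expect_lt(got10, 10^(-60 / 20)) # > 60 dB down after zero-phase application
  got2 <- sine_amplitude(lp[1, ], 2, 500)
  expect_equal(got2, butter_lowpass_gain(2, 3.5, 500, 4)^2, tolerance = 0.02)
})

test_that("feature extraction validates its rates", {
  rec <- toy_recording(300, rate = 512)
  expect_error(extract_lowfreq_features(rec), "integer multiple")
  expect_error(extract_lowfreq_features(toy_recording(300), cutoff = 6),
               "Nyquist")
})

test_that("common-average referencing is a projection", {
  f <- feature_series(matrix(rnorm(60 * 40), 60, 40))
  car <- common_average(f)
  expect_lt(max(abs(colMeans(car$values))), 1e-12)
  twice <- common_average(car)
  expect_equal(twice$values, car$values, tolerance = 1e-12)

  # single nonzero channel of value v over 60 channels keeps v * 59/60
  v <- 3
  one <- matrix(0, 60, 5)
  one[7, ] <- v
  got <- common_average(feature_series(one))
  expect_equal(got$values[7, ], rep(v * 59 / 60, 5))
  expect_equal(got$values[1, ], rep(-v / 60, 5))
})

test_that("the preprocessing chain is linear", {
  n <- 3000
  x <- matrix(rnorm(60 * n), 60, n)
  y <- matrix(rnorm(60 * n), 60, n)
  eog <- matrix(0, 4, n)
  chain <- function(m) {
    preprocess_run(eeg_recording(m, eog, run_kind = "cued"))$values
  }
  lhs <- chain(2 * x + 0.5 * y)
  rhs <- 2 * chain(x) + 0.5 * chain(y)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("zero-phase filtering preserves peak latency", {
  n <- 10000
  tt <- (0:(n - 1)) / 500
  peak_t <- 10
  bump <- -5 * exp(-(tt - peak_t)^2 / (2 * 0.4^2))
  rec <- toy_recording(n, eeg = matrix(bump, 60, n, byrow = TRUE),
                       eog = matrix(0, 4, n))
  f <- extract_lowfreq_features(bandpass(rec))
  ft <- fastcue:::feature_times(f)
  expect_lt(abs(ft[which.min(f$values[1, ])] - peak_t), 0.1 + 1e-9)
})
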