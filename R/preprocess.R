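#' Construct a feature series
#'
#' Low-level constructor for a multichannel feature time series, the
#' container produced by [extract_lowfreq_features()] and consumed by the
#' decoder and epoching functions.
#'
#' @param values Numeric matrix, channels x samples.
#' @param rate Sampling rate in Hz.
#' @param t0 Run-clock time of the first sample, seconds.
#' @param channel_labels Optional channel labels (row names).
#' @return A list of class `feature_series`.
#' @export
feature_series <- function(values, rate = 10, t0 = 0,
                           channel_labels = NULL) {
  stopifnot(is.matrix(values), rate > 0)
  if (is.null(channel_labels)) {
    channel_labels <- rownames(values)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(nrow(values)))
    }
  }
  stopifnot(length(channel_labels) == nrow(values))
  structure(
    list(values = values, rate = rate, t0 = t0,
         channel_labels = channel_labels),
    class = "feature_series"
  )
}

# zero-phase Butterworth application along rows of a channels x samples matrix
filtfilt_rows <- function(mat, bf) {
  out <- mat
  for (ch in seq_len(nrow(mat))) {
    out[ch, ] <- signal::filtfilt(bf, mat[ch, ])
  }
  out
}

#' Band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass (default 0.5-70 Hz) to every EEG
#' and EOG channel, forward and backward (zero phase), leaving motion and
#' events untouched.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param order Filter order of the band-pass (must be even; the analogue
#'   prototype has `order/2` poles).
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(recording, low = 0.5, high = 70, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"), low > 0, high > low,
            order >= 2, order %% 2 == 0)
  if (recording$eeg_rate <= 2 * high) {
    stop("sampling rate ", recording$eeg_rate,
         " Hz too low for a ", high, " Hz band edge")
  }
  bf <- signal::butter(order / 2, c(low, high) / (recording$eeg_rate / 2),
                       type = "pass")
  recording$eeg <- filtfilt_rows(recording$eeg, bf)
  recording$eog <- filtfilt_rows(recording$eog, bf)
  recording
}

#' Fit the regression-based eye-artifact removal operator
#'
#' Learns a fixed linear operator that removes ocular activity from the EEG:
#' each EEG channel is regressed on the four EOG channels over an
#' eye-calibration recording (ordinary least squares), and the coefficient
#' matrix is stored for later application to task runs.
#'
#' @param calibration An [eeg_recording()], typically from
#'   [simulate_eye_calibration()], containing clear EOG activity.
#' @return A list of class `eog_removal_model` with `coupling_estimate`
#'   (channels x 4) and `fitted_on`.
#' @seealso [apply_eog_removal()]
#' @export
fit_eog_removal <- function(calibration) {
  stopifnot(inherits(calibration, "eeg_recording"))
  X <- t(calibration$eog)
  if (qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    stop("EOG channels are rank deficient (constant or collinear); ",
         "cannot fit the removal operator")
  }
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(t(calibration$eeg), scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc)) # 4 x channels
  structure(
    list(
      coupling_estimate = t(B),
      fitted_on = calibration$run_kind
    ),
    class = "eog_removal_model"
  )
}

#' Remove ocular artifacts from a recording
#'
#' Subtracts the fitted linear combination of the EOG channels from every EEG
#' channel; the EOG channels themselves pass through unchanged.
#'
#' @param model An `eog_removal_model` from [fit_eog_removal()].
#' @param recording An [eeg_recording()] with matching channel counts.
#' @return The cleaned [eeg_recording()].
#' @export
apply_eog_removal <- function(model, recording) {
  stopifnot(inherits(model, "eog_removal_model"),
            inherits(recording, "eeg_recording"))
  B <- model$coupling_estimate
  if (nrow(B) != nrow(recording$eeg) || ncol(B) != nrow(recording$eog)) {
    stop("dimension mismatch between removal model (", nrow(B), "x", ncol(B),
         ") and recording (", nrow(recording$eeg), " EEG, ",
         nrow(recording$eog), " EOG channels)")
  }
  recording$eeg <- recording$eeg - B %*% recording$eog
  recording
}

#' Extract low-frequency time-series features
#'
#' Low-pass filters the EEG (4th-order Butterworth, zero phase, default
#' 3.5 Hz cut-off) and decimates it to the feature rate (default 10 Hz). The
#' low-pass doubles as the anti-alias filter (cut-off below the 5 Hz feature
#' Nyquist).
#'
#' @param recording An [eeg_recording()].
#' @param cutoff Low-pass cut-off in Hz.
#' @param rate Feature rate in Hz; must divide the EEG rate.
#' @param order Filter order.
#' @return A list of class `feature_series` with `values` (channels x
#'   samples, microvolts), `rate`, `t0` (run-clock time of the first feature
#'   sample) and `channel_labels`.
#' @export
extract_lowfreq_features <- function(recording, cutoff = 3.5, rate = 10,
                                     order = 4) {
  stopifnot(inherits(recording, "eeg_recording"), cutoff > 0, rate > 0)
  if (recording$eeg_rate %% rate != 0) {
    stop("EEG rate ", recording$eeg_rate,
         " Hz is not an integer multiple of the feature rate ", rate, " Hz")
  }
  if (cutoff >= rate / 2) {
    stop("cut-off must lie below the feature Nyquist (", rate / 2, " Hz)")
  }
  dec <- recording$eeg_rate / rate
  bf <- signal::butter(order, cutoff / (recording$eeg_rate / 2), type = "low")
  lp <- filtfilt_rows(recording$eeg, bf)
  idx <- seq(1L, ncol(lp), by = dec)
  structure(
    list(
      values = lp[, idx, drop = FALSE],
      rate = rate,
      t0 = 0,
      channel_labels = recording$channel_labels
    ),
    class = "feature_series"
  )
}

#' Re-reference features to the common average
#'
#' Subtracts, at every sample, the mean across channels from each channel.
#' Idempotent (a projection).
#'
#' @param features A `feature_series` (or any channels x samples structure
#'   with a `values` element).
#' @return The re-referenced `feature_series`.
#' @export
common_average <- function(features) {
  stopifnot(inherits(features, "feature_series"))
  if (nrow(features$values) < 2L) stop("common average needs >= 2 channels")
  features$values <- sweep(features$values, 2L,
                           colMeans(features$values), "-")
  features
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf(
    "<feature_series> %d channels x %d samples @ %g Hz (t0 = %g s)\n",
    nrow(x$values), ncol(x$values), x$rate, x$t0
  ))
  invisible(x)
}

# time axis of a feature series
feature_times <- function(features) {
  features$t0 + (seq_len(ncol(features$values)) - 1L) / features$rate
}

#' Full decoding preprocessing chain
#'
#' Convenience wrapper running the standard chain on a task run: band-pass
#' 0.5-70 Hz, eye-artifact removal, low-frequency feature extraction
#' (3.5 Hz low-pass, 10 Hz features) and, optionally, common-average
#' re-referencing (used for decoding features; neural-correlate analyses use
#' the un-referenced variant).
#'
#' @param recording An [eeg_recording()].
#' @param eog_model An `eog_removal_model`, or `NULL` to skip removal.
#' @param car Apply the common average reference.
#' @return A `feature_series`.
#' @export
preprocess_run <- function(recording, eog_model = NULL, car = TRUE) {
  rec <- bandpass(recording)
  if (!is.null(eog_model)) rec <- apply_eog_removal(eog_model, rec)
  feats <- extract_lowfreq_features(rec)
  if (car) feats <- common_average(feats)
  feats
}
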