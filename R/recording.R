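#' Construct a multichannel recording
#'
#' Container for one run: EEG and EOG at 500 Hz, a 2-D finger-position trace at
#' 30 Hz, and an event table. All simulator and preprocessing functions accept
#' and return this class.
#'
#' @param eeg Numeric matrix, channels x samples, microvolts.
#' @param eog Numeric matrix, 4 x samples, microvolts.
#' @param motion_xy Numeric matrix, 2 x samples (x and y position), arbitrary
#'   position units, or `NULL` for runs without motion capture.
#' @param events Tibble with columns `onset_s` and `kind` (one row per event,
#'   onsets in seconds of the run clock).
#' @param run_kind One of `"cued"`, `"self_paced"`, `"eye_calibration"`.
#' @param eeg_rate,motion_rate Sampling rates in Hz.
#' @param channel_labels Labels of the EEG rows.
#' @param eog_labels Labels of the EOG rows.
#'
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(eeg, eog, motion_xy = NULL,
                          events = tibble::tibble(onset_s = numeric(),
                                                  kind = character()),
                          run_kind = c("cued", "self_paced", "eye_calibration"),
                          eeg_rate = 500, motion_rate = 30,
                          channel_labels = fastcue_montage(),
                          eog_labels = fastcue_eog_labels()) {
  run_kind <- match.arg(run_kind)
  stopifnot(
    is.matrix(eeg), is.matrix(eog),
    ncol(eeg) == ncol(eog),
    nrow(eeg) == length(channel_labels),
    nrow(eog) == length(eog_labels),
    !anyDuplicated(channel_labels),
    all(c("onset_s", "kind") %in% names(events))
  )
  if (!is.null(motion_xy)) stopifnot(is.matrix(motion_xy), nrow(motion_xy) == 2L)
  rownames(eeg) <- channel_labels
  rownames(eog) <- eog_labels
  structure(
    list(
      eeg = eeg, eog = eog, motion_xy = motion_xy,
      events = tibble::as_tibble(events), run_kind = run_kind,
      eeg_rate = eeg_rate, motion_rate = motion_rate,
      channel_labels = channel_labels, eog_labels = eog_labels
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s run: %d EEG + %d EOG channels, %.1f s @ %g Hz\n",
    x$run_kind, nrow(x$eeg), nrow(x$eog), ncol(x$eeg) / x$eeg_rate, x$eeg_rate
  ))
  if (!is.null(x$motion_xy)) {
    cat(sprintf("  motion trace: %d samples @ %g Hz\n",
                ncol(x$motion_xy), x$motion_rate))
  }
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(unique(x$events$kind), collapse = ", ")))
  invisible(x)
}

#' Event times of a given kind
#'
#' @param recording An `eeg_recording`.
#' @param kind Event kind to extract, e.g. `"movement_onset"` or `"cue"`.
#' @return Numeric vector of onset times in seconds.
#' @export
event_times <- function(recording, kind = "movement_onset") {
  stopifnot(inherits(recording, "eeg_recording"))
  recording$events$onset_s[recording$events$kind == kind]
}

#' Read and write recordings in the package container format
#'
#' The native container is a single RDS file holding the full
#' [eeg_recording()] structure (exact round trip). Event tables can
#' additionally be exchanged as tab-separated sidecars with
#' [write_events()]/[read_events()].
#'
#' @param recording An `eeg_recording`.
#' @param path File path.
#' @param format Only `"container"` is supported; requesting `"brainvision"`
#'   or `"edf"` raises an informative error.
#' @param n_eeg_channels Expected number of EEG channels; loading a file with
#'   a different channel count is a validation error.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("container", "brainvision", "edf"),
                           n_eeg_channels = 60L) {
  format <- match.arg(format)
  if (format != "container") {
    stop("format '", format, "' is not supported by this build; ",
         "use the native container format")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- readRDS(path)
  if (!inherits(rec, "eeg_recording")) {
    stop("file does not contain an eeg_recording: ", path)
  }
  if (nrow(rec$eeg) != n_eeg_channels) {
    stop("validation error: recording has ", nrow(rec$eeg),
         " EEG channels, expected ", n_eeg_channels)
  }
  rec
}

#' @param events Tibble with `onset_s` and `kind` columns.
#' @rdname write_recording
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_s", "kind") %in% names(events)))
  readr::write_tsv(tibble::as_tibble(events), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

# time axis of the EEG samples of a recording (run clock, first sample t = 0)
eeg_times <- function(recording) {
  (seq_len(ncol(recording$eeg)) - 1L) / recording$eeg_rate
}
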