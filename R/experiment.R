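#' Configuration of a full synthetic experiment
#'
#' Bundles every stage configuration for [run_experiment()]: the cue
#' paradigm, the synthetic participant, onset detection, decoder grids and
#' the event-based evaluation. Defaults reproduce the study protocol (three
#' 100-trial cue-based runs, one self-paced run of matching duration, a
#' 7-minute eye-calibration recording, calibration at 0.5 / 1 / 2 FP/min).
#'
#' The default decoder grid is a reduced subset of the full
#' [select_hyperparameters()] grids, sized for a complete desk-scale
#' experiment; pass larger grids for an exhaustive search.
#'
#' @param paradigm A [paradigm_config()].
#' @param subject A [subject_model()].
#' @param n_window_grid,d_grid Decoder hyperparameter grids.
#' @param shrinkage_method `"lw_linear"` or `"qis"`.
#' @param calib_fppm Calibration levels, false positives per minute.
#' @param eval An [eval_config()] (its `max_fppm` is overridden per level).
#' @param onset_threshold Speed threshold for [detect_onsets()] (`"auto"` or
#'   numeric).
#' @param eye_calib_duration Duration of the eye-calibration recording, s.
#' @param compute_erds Whether to compute ERDS maps (the slowest analysis).
#' @param erds_channel Channel for the ERDS maps.
#' @param erds_boot Bootstrap resamples for the ERDS significance masks.
#' @param central_channels Channels used for the MRCP dissimilarity (NRMSE)
#'   summary.
#' @param seed Master seed; all run seeds derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(paradigm = paradigm_config(),
                              subject = subject_model(),
                              n_window_grid = c(5, 8, 12, 16),
                              d_grid = seq(0, 0.3, by = 0.1),
                              shrinkage_method = "lw_linear",
                              calib_fppm = c(0.5, 1, 2),
                              eval = eval_config(),
                              onset_threshold = "auto",
                              eye_calib_duration = 420,
                              compute_erds = FALSE,
                              erds_channel = "C1",
                              erds_boot = 200,
                              central_channels = c("FC3", "FC1", "FCz", "FC2",
                                                   "FC4", "C3", "C1", "Cz",
                                                   "C2", "C4", "CP3", "CP1",
                                                   "CPz", "CP2", "CP4"),
                              seed = 1L) {
  stopifnot(inherits(paradigm, "paradigm_config"),
            inherits(subject, "subject_model"),
            inherits(eval, "eval_config"),
            all(calib_fppm > 0), length(seed) == 1L)
  structure(
    list(paradigm = paradigm, subject = subject,
         n_window_grid = n_window_grid, d_grid = d_grid,
         shrinkage_method = shrinkage_method, calib_fppm = calib_fppm,
         eval = eval, onset_threshold = onset_threshold,
         eye_calib_duration = eye_calib_duration,
         compute_erds = compute_erds, erds_channel = erds_channel,
         erds_boot = erds_boot, central_channels = central_channels,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run the complete synthetic experiment
#'
#' Simulates an eye-calibration recording, three cue-based runs and one
#' self-paced run for one synthetic participant, then executes the full
#' offline pipeline: preprocessing (band-pass, eye-artifact removal,
#' low-frequency features, common average reference), motion-based onset
#' detection, runwise cross-validated hyperparameter selection, final sLDA
#' training, FP/min-calibrated event-by-event evaluation on the self-paced
#' run, and the neural-correlate analyses (MRCP condition comparison, NRMSE
#' over central channels, optional ERDS maps).
#'
#' Fully deterministic for a fixed configuration: every stage draws its
#' randomness from seeds derived from `cfg$seed`.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-stage progress.
#' @return A list of class `experiment_report`; see the elements
#'   `schedule_stats`, `behavior`, `selection`, `calibration`,
#'   `mrcp_comparison`, `nrmse_central`, `erds`, `seed`.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  base <- cfg$seed
  t_start <- Sys.time()

  say("stage 1/6: simulating runs")
  schedule <- generate_cue_schedule(cfg$paradigm)
  calib <- simulate_eye_calibration(cfg$eye_calib_duration, cfg$subject,
                                    seed = base + 101L)
  cued <- lapply(1:3, function(i) {
    simulate_cued_run(schedule, cfg$subject, seed = base + i)
  })
  sp_onsets <- simulate_self_paced_timeline(schedule$run_duration, cfg$subject,
                                            seed = base + 4L)
  selfp <- simulate_self_paced_run(sp_onsets, cfg$subject, seed = base + 5L,
                                   duration = schedule$run_duration + 2)

  say("stage 2/6: preprocessing")
  eog_model <- fit_eog_removal(bandpass(calib))
  clean <- lapply(c(cued, list(selfp)), function(r) {
    apply_eog_removal(eog_model, bandpass(r))
  })
  feats_car <- lapply(clean, function(r) common_average(extract_lowfreq_features(r)))
  feats_raw <- lapply(clean, extract_lowfreq_features)

  say("stage 3/6: onset detection")
  onsets <- lapply(c(cued, list(selfp)), function(r) {
    detect_onsets(compute_speed(r), threshold = cfg$onset_threshold)
  })
  delays <- unlist(lapply(1:3, function(i) {
    cues <- event_times(cued[[i]], "cue")
    vapply(cues, function(tc) {
      dd <- onsets[[i]] - tc
      dd <- dd[dd >= -0.5 & dd <= 1]
      if (length(dd)) dd[which.min(abs(dd))] else NA_real_
    }, numeric(1))
  }))
  behavior <- tibble::tibble(
    n_cues = 3L * nrow(schedule$cues),
    n_detected = sum(!is.na(delays)),
    mean_delay_ms = 1000 * mean(delays, na.rm = TRUE),
    sd_delay_ms = 1000 * stats::sd(delays, na.rm = TRUE)
  )

  say("stage 4/6: decoder training (grid %d x %d)",
      length(cfg$n_window_grid), length(cfg$d_grid))
  runs <- lapply(1:3, function(i) {
    list(features = feats_car[[i]], onsets = onsets[[i]])
  })
  selection <- select_hyperparameters(runs, cfg$n_window_grid, cfg$d_grid,
                                      method = cfg$shrinkage_method)

  say("stage 5/6: evaluation on the self-paced run")
  sp_feats <- feats_car[[4L]]
  sp_true <- onsets[[4L]]
  sp_duration <- ncol(selfp$eeg) / selfp$eeg_rate
  scores <- score_run(selection$model, sp_feats)
  calibration <- purrr::map_dfr(cfg$calib_fppm, function(level) {
    ev <- cfg$eval
    ev$max_fppm <- level
    calibrate_threshold(scores, sp_true, ev, sp_duration)
  })

  say("stage 6/6: neural-correlate analyses")
  cued_ep1 <- do.call(rbind_epochs, lapply(1:3, function(i) {
    epoch_onsets(feats_raw[[i]], onsets[[i]], c(-1, 1), "cued")
  }))
  sp_ep1 <- epoch_onsets(feats_raw[[4L]], sp_true, c(-1, 1), "self_paced")
  mrcp_comparison <- compare_conditions(cued_ep1, sp_ep1)
  cued_ep2 <- do.call(rbind_epochs, lapply(1:3, function(i) {
    epoch_onsets(feats_raw[[i]], onsets[[i]], c(-2, 2), "cued")
  }))
  sp_ep2 <- epoch_onsets(feats_raw[[4L]], sp_true, c(-2, 2), "self_paced")
  avg_c <- epoch_average(cued_ep2)
  avg_s <- epoch_average(sp_ep2)
  nrmse_central <- purrr::map_dfr(cfg$central_channels, function(ch) {
    tibble::tibble(
      channel = ch,
      nrmse = nrmse(avg_c$mean_uv[avg_c$channel == ch],
                    avg_s$mean_uv[avg_s$channel == ch])
    )
  })
  erds <- NULL
  if (cfg$compute_erds) {
    ecfg <- erds_config(n_boot = cfg$erds_boot)
    cued_ep4 <- suppressWarnings(
      epoch_onsets(clean[[1L]], onsets[[1L]], c(-4, 4), "cued")
    )
    sp_ep4 <- suppressWarnings(
      epoch_onsets(clean[[4L]], sp_true, c(-4, 4), "self_paced")
    )
    erds <- list(
      cued = erds_map(cued_ep4, cfg$erds_channel, ecfg, seed = base + 201L),
      self_paced = erds_map(sp_ep4, cfg$erds_channel, ecfg, seed = base + 202L)
    )
  }

  structure(
    list(
      schedule_stats = schedule_statistics(schedule),
      behavior = behavior,
      selection = selection,
      calibration = calibration,
      mrcp_comparison = mrcp_comparison,
      mrcp_averages = dplyr::bind_rows(
        dplyr::mutate(avg_c, condition = "cued"),
        dplyr::mutate(avg_s, condition = "self_paced")
      ),
      nrmse_central = nrmse_central,
      erds = erds,
      n_selfpaced_movements = length(sp_true),
      seed = cfg$seed,
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
      config = cfg
    ),
    class = "experiment_report"
  )
}

# concatenate epoch sets trial-wise (same channels/time axis)
rbind_epochs <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  d <- do.call(abind_trials, sets)
  structure(
    list(data = d, time_s = sets[[1L]]$time_s,
         channel_labels = sets[[1L]]$channel_labels,
         condition = sets[[1L]]$condition, rate = sets[[1L]]$rate),
    class = "epoch_set"
  )
}

abind_trials <- function(...) {
  sets <- list(...)
  n <- sum(vapply(sets, function(s) dim(s$data)[1L], integer(1)))
  d1 <- dim(sets[[1L]]$data)
  out <- array(0, dim = c(n, d1[2L], d1[3L]))
  at <- 0L
  for (s in sets) {
    k <- dim(s$data)[1L]
    out[at + seq_len(k), , ] <- s$data
    at <- at + k
  }
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  schedule: %d trials/run, mean ITI %.2f s\n",
              x$schedule_stats$n_trials, x$schedule_stats$mean_iti_s))
  cat(sprintf("  behavior: cue-to-onset delay %.0f +/- %.0f ms (%d/%d detected)\n",
              x$behavior$mean_delay_ms, x$behavior$sd_delay_ms,
              x$behavior$n_detected, x$behavior$n_cues))
  cat(sprintf("  decoder: n_window = %d, d = %.2f s (CV MCC %.3f)\n",
              x$selection$best$n_window, x$selection$best$d,
              x$selection$best$mcc))
  for (i in seq_len(nrow(x$calibration))) {
    cat(sprintf("  at <= %.1f FP/min: TPR %.1f%% (achieved %.2f FP/min)\n",
                x$calibration$max_fppm[i], x$calibration$tpr[i],
                x$calibration$fppm[i]))
  }
  cat(sprintf("  elapsed: %.1f s (seed %d)\n", x$elapsed_s, x$seed))
  invisible(x)
}

#' @rdname tidy.slda_model
#' @param x An `experiment_report`.
#' @export
glance.experiment_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(seed = x$seed,
                   n_window = x$selection$best$n_window,
                   d = x$selection$best$d,
                   cv_mcc = x$selection$best$mcc),
    tidyr::pivot_wider(
      dplyr::select(x$calibration, "max_fppm", "tpr"),
      names_from = "max_fppm", values_from = "tpr",
      names_prefix = "tpr_at_"
    )
  )
}
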