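#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cue schedule
#'
#' Angular velocity of the rotation cross over the run with the cue times
#' marked.
#'
#' @param object A `cue_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cue_schedule <- function(object, ...) {
  ggplot2::ggplot(object$angle, ggplot2::aes(x = .data$time_s,
                                             y = .data$omega_deg_s)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$cues$onset_s,
                        alpha = 0.25, linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "angular velocity (deg/s)",
                  title = sprintf("Rotating-cue schedule: %d cues, mean ITI %.2f s",
                                  nrow(object$cues), mean(object$itis))) +
    ggplot2::theme_minimal()
}

#' Plot a grand-average waveform of an epoch set
#'
#' Trial mean with a standard-error ribbon for one channel; the movement
#' onset is marked at lag 0.
#'
#' @param object An `epoch_set`.
#' @param channel Channel label to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epoch_set <- function(object, channel = "C1", ...) {
  avg <- epoch_average(object, channel)
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$time_s, y = .data$mean_uv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_uv - .data$se_uv,
                                      ymax = .data$mean_uv + .data$se_uv),
                         alpha = 0.3, fill = "firebrick") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time relative to movement onset (s)",
                  y = "amplitude (µV, negative up)",
                  title = sprintf("%s grand average, channel %s (%d trials)",
                                  object$condition, channel,
                                  dim(object$data)[1L])) +
    ggplot2::theme_minimal()
}

#' Plot an ERDS map
#'
#' Time-frequency raster of relative band-power change; non-significant
#' pixels (bootstrap interval containing zero) are blanked when
#' `mask_nonsignificant` is set.
#'
#' @param object An `erds_map`.
#' @param mask_nonsignificant Blank pixels that are not significant.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.erds_map <- function(object, mask_nonsignificant = FALSE, ...) {
  df <- tidyr::expand_grid(freq_hz = object$freqs, time_s = object$time_s)
  df$erds <- as.vector(t(object$values))
  df$sig <- as.vector(t(object$significant))
  if (mask_nonsignificant) df$erds[!df$sig] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$erds)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "grey30", na.value = "white",
                                  name = "ERDS (%)") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to movement onset (s)",
                  y = "frequency (Hz)",
                  title = sprintf("ERDS map, channel %s", object$channel)) +
    ggplot2::theme_minimal()
}

#' Plot calibrated detection performance
#'
#' True positive rate and achieved FP/min of an experiment report across the
#' calibrated FP/min levels.
#'
#' @param report An `experiment_report` from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  df <- tidyr::pivot_longer(
    dplyr::select(report$calibration, "max_fppm", "tpr", "fppm"),
    cols = c("tpr", "fppm"),
    names_to = "metric", values_to = "value"
  )
  df$metric <- dplyr::recode(df$metric, tpr = "TPR (%)",
                             fppm = "achieved FP/min")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$max_fppm),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "calibrated maximum FP/min", y = NULL,
                  title = "Self-paced detection performance") +
    ggplot2::theme_minimal()
}
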