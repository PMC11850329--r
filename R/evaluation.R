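#' Matthews correlation coefficient
#'
#' Balanced binary-classification metric robust to class imbalance; equals
#' the Pearson correlation of the two binary label vectors realizing the
#' confusion matrix. Returns 0 when any factor of the denominator is 0, and
#' `NA` (with a warning) for an all-zero confusion matrix.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  # counts arrive as integers from table(); the denominator product would
  # overflow 32-bit integer arithmetic
  tp <- as.numeric(tp)
  fp <- as.numeric(fp)
  tn <- as.numeric(tn)
  fn <- as.numeric(fn)
  if (tp + fp + tn + fn == 0) {
    warning("all-zero confusion matrix: MCC undefined")
    return(NA_real_)
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Event-based evaluation configuration
#'
#' @param hit_window Two-element numeric, the asymmetric window around a true
#'   onset within which a detection counts as a hit (seconds).
#' @param refractory Seconds after a detection during which further
#'   detections are suppressed.
#' @param max_fppm Maximum admissible false positives per minute for
#'   [calibrate_threshold()].
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(hit_window = c(-0.5, 1.0), refractory = 1.0,
                        max_fppm = 1.0) {
  stopifnot(length(hit_window) == 2L, hit_window[1L] < 0, hit_window[2L] > 0,
            refractory >= 0, max_fppm > 0)
  structure(
    list(hit_window = hit_window, refractory = refractory, max_fppm = max_fppm),
    class = "eval_config"
  )
}

#' Threshold the score trace into detections with a refractory period
#'
#' Emits a detection at every feature time where the score reaches the
#' threshold and no detection occurred within the preceding `refractory`
#' interval.
#'
#' @param scores Tibble with `time_s` and `score` (from [score_run()]).
#' @param threshold Score threshold in `[0, 1]`.
#' @param refractory Refractory period, seconds.
#' @return Numeric vector of detection times.
#' @export
detect_events <- function(scores, threshold, refractory = 1.0) {
  stopifnot(all(c("time_s", "score") %in% names(scores)),
            threshold >= 0, threshold <= 1, refractory >= 0)
  idx <- which(scores$score >= threshold)
  if (!length(idx)) return(numeric(0))
  tt <- scores$time_s[idx]
  det <- numeric(length(tt))
  k <- 0L
  last <- -Inf
  for (t in tt) {
    if (t - last > refractory) {
      k <- k + 1L
      det[k] <- t
      last <- t
    }
  }
  det[seq_len(k)]
}

#' Event-by-event detection metrics
#'
#' Scores detections against true movement onsets: the first detection inside
#' an onset's hit window is a hit; later detections inside the same window
#' are ignored (neither hit nor false positive); detections outside every hit
#' window are false positives. When hit windows overlap, a detection is
#' assigned to the nearest onset that has not yet been hit.
#'
#' @param detections Numeric vector of detection times, seconds.
#' @param true_onsets Numeric vector of true movement-onset times, seconds.
#' @param cfg An [eval_config()].
#' @param duration Run duration in seconds (normalizes FP/min).
#' @return One-row tibble with `n_true`, `n_hit`, `n_fp`, `tpr` (percent),
#'   `fppm` and `duration_min`.
#' @export
event_metrics <- function(detections, true_onsets, cfg = eval_config(),
                          duration) {
  stopifnot(inherits(cfg, "eval_config"), duration > 0)
  detections <- sort(detections)
  true_onsets <- sort(true_onsets)
  hit <- rep(FALSE, length(true_onsets))
  n_fp <- 0L
  for (t in detections) {
    lag <- t - true_onsets
    eligible <- lag >= cfg$hit_window[1L] & lag <= cfg$hit_window[2L]
    if (!any(eligible)) {
      n_fp <- n_fp + 1L
      next
    }
    open <- eligible & !hit
    if (any(open)) {
      hit[which(open)[which.min(abs(lag[open]))]] <- TRUE
    }
    # detections inside an already-hit window are ignored
  }
  n_true <- length(true_onsets)
  n_hit <- sum(hit)
  tibble::tibble(
    n_true = n_true,
    n_hit = n_hit,
    n_fp = n_fp,
    tpr = if (n_true > 0) 100 * n_hit / n_true else NA_real_,
    fppm = n_fp / (duration / 60),
    duration_min = duration / 60
  )
}

#' Calibrate the detection threshold to a false-positive budget
#'
#' Sweeps every distinct score value as a candidate threshold (descending)
#' and selects the one that maximizes the true positive rate subject to the
#' false-positive rate staying at or below `cfg$max_fppm`; among equal TPRs
#' the highest threshold (fewest detections) wins. If no threshold satisfies
#' the budget, a threshold above the maximum score is returned (no
#' detections, TPR 0).
#'
#' @param scores Tibble with `time_s` and `score`.
#' @param true_onsets True movement-onset times, seconds.
#' @param cfg An [eval_config()] carrying `max_fppm` and the refractory
#'   period.
#' @param duration Run duration in seconds.
#' @return One-row tibble: `threshold`, `max_fppm`, plus the achieved
#'   [event_metrics()] columns.
#' @export
calibrate_threshold <- function(scores, true_onsets, cfg = eval_config(),
                                duration) {
  stopifnot(length(true_onsets) >= 1L)
  cand <- sort(unique(scores$score), decreasing = TRUE)
  best <- NULL
  for (th in cand) {
    det <- detect_events(scores, th, cfg$refractory)
    m <- event_metrics(det, true_onsets, cfg, duration)
    if (m$fppm <= cfg$max_fppm &&
        (is.null(best) || m$tpr > best$tpr + 1e-12)) {
      best <- dplyr::bind_cols(tibble::tibble(threshold = th,
                                              max_fppm = cfg$max_fppm), m)
    }
  }
  if (is.null(best)) {
    m <- event_metrics(numeric(0), true_onsets, cfg, duration)
    best <- dplyr::bind_cols(tibble::tibble(threshold = max(scores$score) + 1,
                                            max_fppm = cfg$max_fppm), m)
  }
  best
}
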