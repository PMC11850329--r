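#' Movement speed from the finger-position trace
#'
#' Differentiates the 2-D position trace (central finite differences,
#' one-sided at the ends) and returns the scalar speed
#' \eqn{s = \sqrt{v_x^2 + v_y^2}}.
#'
#' @param motion_xy 2 x n position matrix (or an [eeg_recording()], whose
#'   motion trace is used).
#' @param rate Sampling rate of the motion trace in Hz.
#' @return A tibble of class `speed_trace` with columns `time_s` and `speed`
#'   (position units per second).
#' @export
compute_speed <- function(motion_xy, rate = 30) {
  if (inherits(motion_xy, "eeg_recording")) {
    rate <- motion_xy$motion_rate
    motion_xy <- motion_xy$motion_xy
  }
  stopifnot(is.matrix(motion_xy), nrow(motion_xy) == 2L)
  n <- ncol(motion_xy)
  if (n < 2L) stop("need at least 2 motion samples")
  d <- function(p) {
    v <- numeric(n)
    v[1L] <- (p[2L] - p[1L]) * rate
    v[n] <- (p[n] - p[n - 1L]) * rate
    if (n > 2L) v[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) * rate / 2
    v
  }
  vx <- d(motion_xy[1L, ])
  vy <- d(motion_xy[2L, ])
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) / rate,
    speed = sqrt(vx^2 + vy^2)
  )
  class(out) <- c("speed_trace", class(out))
  out
}

#' Detect movement onsets from the speed trace
#'
#' A movement consists of two speed peaks (flexion, then return after the
#' hold), so the speed crosses the threshold twice in quick succession. The
#' detector finds upward threshold crossings (times refined by linear
#' interpolation between the bracketing samples), pairs each crossing with
#' the next one if it follows within `pairing_window` seconds, and emits the
#' first crossing of each pair as the movement onset. Unpaired crossings emit
#' nothing; onsets closer than `min_separation` to the previous onset are
#' discarded.
#'
#' With `threshold = "auto"` the threshold is `mean + 5 * SD` of the speed
#' over the lowest-activity quartile of samples (a rest estimate).
#'
#' @param trace A `speed_trace` from [compute_speed()].
#' @param threshold Numeric threshold in speed units, or `"auto"`.
#' @param pairing_window Maximum separation (s) of the two crossings of one
#'   movement.
#' @param min_separation Minimum separation (s) between emitted onsets.
#' @return Numeric vector of onset times in seconds (possibly empty).
#' @export
detect_onsets <- function(trace, threshold = "auto", pairing_window = 1.5,
                          min_separation = 1.0) {
  stopifnot(inherits(trace, "speed_trace"), pairing_window > 0,
            min_separation >= 0)
  s <- trace$speed
  tt <- trace$time_s
  if (identical(threshold, "auto")) {
    # rest estimate: pool the samples of the quarter of 1 s segments with the
    # lowest mean speed, then threshold at mean + 5 SD of that pool
    rate <- 1 / stats::median(diff(tt))
    seg <- pmin(
      (seq_along(s) - 1L) %/% max(1L, round(rate)) + 1L,
      max(1L, floor(length(s) / max(1L, round(rate))))
    )
    seg_mean <- tapply(s, seg, mean)
    quiet <- as.integer(names(sort(seg_mean)))[
      seq_len(max(1L, floor(length(seg_mean) / 4)))
    ]
    rest <- s[seg %in% quiet]
    threshold <- mean(rest) + 5 * stats::sd(rest)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  above <- s > threshold
  up <- which(!above[-length(above)] & above[-1L]) # crossing between i, i+1
  if (!length(up)) return(numeric(0))
  frac <- (threshold - s[up]) / (s[up + 1L] - s[up])
  cross <- tt[up] + frac * (tt[up + 1L] - tt[up])
  onsets <- numeric(0)
  k <- 1L
  while (k < length(cross)) {
    if (cross[k + 1L] - cross[k] <= pairing_window) {
      onsets <- c(onsets, cross[k])
      k <- k + 2L
    } else {
      k <- k + 1L
    }
  }
  if (length(onsets) > 1L) {
    keep <- c(TRUE, diff(onsets) >= min_separation)
    onsets <- onsets[keep]
  }
  onsets
}
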