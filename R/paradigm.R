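#' Configuration of the rotating-cue paradigm
#'
#' Parameters of the continuously rotating visual cue. A rotation cross is
#' overlaid on a fixation cross and rotates at a time-varying angular velocity
#' \deqn{\omega(t) = 90/T_{ITI} + A \sin(2\pi a_{base} t)\,
#'       \sin(2\pi a_{mod} t + \varphi)}{%
#'       omega(t) = 90/T_ITI + A sin(2 pi a_base t) sin(2 pi a_mod t + phi)}
#' in degrees per second. Every time the cumulative rotation angle brings the
#' two four-fold symmetric crosses into overlap (every `symmetry_angle`
#' degrees), the participant is cued to execute a movement. Varying the
#' velocity smoothly yields variable inter-trial intervals (ITIs) without any
#' abrupt visual change.
#'
#' @param t_iti Mean inter-trial interval in seconds; sets the mean angular
#'   velocity `90/t_iti`.
#' @param a Spread of the velocity modulation in deg/s. `a = 0` gives constant
#'   rotation and equal ITIs.
#' @param a_base,a_mod Frequencies (Hz) of the two sinusoids whose product
#'   modulates the velocity.
#' @param phi Phase offset of the second sinusoid, radians.
#' @param n_trials Number of cues per run.
#' @param static_hold Seconds the crosses are shown statically before rotation
#'   starts.
#' @param initial_tilt Initial angle (degrees) between rotation and fixation
#'   cross at rotation start.
#' @param fadeout_angle Degrees before the cue after the last one at which the
#'   crosses fade out and the run ends.
#' @param symmetry_angle Rotation angle between successive cross overlaps
#'   (90 degrees for four-fold symmetric crosses).
#' @param integration_step Time step in seconds for numerical integration of
#'   the angular velocity.
#'
#' @return A list of class `paradigm_config`.
#' @seealso [generate_cue_schedule()], [angular_velocity()]
#' @export
#' @examples
#' cfg <- paradigm_config()
#' sched <- generate_cue_schedule(cfg)
#' schedule_statistics(sched)
paradigm_config <- function(t_iti = 3.3,
                            a = 10.24,
                            a_base = 0.032,
                            a_mod = 0.016,
                            phi = 28.1,
                            n_trials = 100,
                            static_hold = 1.5,
                            initial_tilt = 10,
                            fadeout_angle = 10,
                            symmetry_angle = 90,
                            integration_step = 1e-3) {
  stopifnot(
    is.numeric(t_iti), length(t_iti) == 1L, is.finite(t_iti), t_iti > 0,
    is.numeric(a), length(a) == 1L, is.finite(a), a >= 0,
    is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1,
    is.numeric(integration_step), integration_step > 0,
    symmetry_angle > 0, static_hold >= 0,
    initial_tilt >= 0, initial_tilt < symmetry_angle,
    fadeout_angle >= 0, fadeout_angle < symmetry_angle
  )
  structure(
    list(
      t_iti = t_iti, a = a, a_base = a_base, a_mod = a_mod, phi = phi,
      n_trials = as.integer(n_trials), static_hold = static_hold,
      initial_tilt = initial_tilt, fadeout_angle = fadeout_angle,
      symmetry_angle = symmetry_angle, integration_step = integration_step
    ),
    class = "paradigm_config"
  )
}

#' Angular velocity of the rotation cross
#'
#' Evaluates the velocity law of the rotating cue at time `t` (seconds since
#' rotation start, i.e. after the static hold). The value is bounded in
#' `90/t_iti + c(-a, a)`.
#'
#' @param t Time in seconds from rotation start; vectorised.
#' @param cfg A [paradigm_config()].
#' @return Angular velocity in deg/s, same length as `t`.
#' @export
angular_velocity <- function(t, cfg = paradigm_config()) {
  stopifnot(inherits(cfg, "paradigm_config"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric (seconds from rotation start)")
  }
  90 / cfg$t_iti +
    cfg$a * sin(2 * pi * cfg$a_base * t) * sin(2 * pi * cfg$a_mod * t + cfg$phi)
}

#' Generate the cue schedule of one cue-based run
#'
#' Integrates the angular velocity from rotation start (cumulative trapezoid on
#' an `integration_step` grid) and emits a cue each time the cumulative
#' rotation angle crosses a multiple of `symmetry_angle`, offset so that the
#' first overlap occurs after `symmetry_angle - initial_tilt` degrees of
#' rotation. Crossing times are located by linear interpolation of the angle
#' trace. The run ends when the crosses fade out, `fadeout_angle` degrees
#' before the overlap following the last cue.
#'
#' Cue times are reported relative to run start, so the first cue includes the
#' static hold. ITIs are the `n_trials - 1` intervals between consecutive
#' cues.
#'
#' @param cfg A [paradigm_config()].
#' @return A list of class `cue_schedule` with elements
#'   \describe{
#'     \item{cues}{tibble with `trial_index`, `onset_s` and `iti_s`
#'       (interval since the previous cue, `NA` for the first).}
#'     \item{itis}{numeric vector of the `n_trials - 1` inter-cue intervals.}
#'     \item{angle}{tibble `time_s`, `angle_deg`, `omega_deg_s` of the rotation
#'       (time in run clock), thinned to a 10 ms grid.}
#'     \item{run_duration}{run duration in seconds (static hold + rotation up
#'       to fade-out).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cue_schedule <- function(cfg = paradigm_config()) {
  stopifnot(inherits(cfg, "paradigm_config"))
  omega_min <- 90 / cfg$t_iti - cfg$a
  if (omega_min <= 0) {
    stop("velocity modulation `a` >= mean velocity 90/t_iti: rotation can stall")
  }
  first_angle <- cfg$symmetry_angle - cfg$initial_tilt
  targets <- first_angle + cfg$symmetry_angle * (0:cfg$n_trials)
  fade_angle <- targets[cfg$n_trials + 1L] - cfg$fadeout_angle
  # sanity horizon: slowest admissible rotation plus 10 % margin
  horizon <- 1.1 * fade_angle / omega_min + 1
  tt <- seq(0, horizon, by = cfg$integration_step)
  om <- angular_velocity(tt, cfg)
  ang <- c(0, cumsum((om[-1L] + om[-length(om)]) / 2 * cfg$integration_step))
  if (max(ang) < fade_angle) {
    stop("configuration error: ", cfg$n_trials,
         " cues unreachable within the sanity horizon")
  }
  cue_rot <- stats::approx(ang, tt, xout = targets[seq_len(cfg$n_trials)],
                           ties = "ordered")$y
  fade_rot <- stats::approx(ang, tt, xout = fade_angle, ties = "ordered")$y
  cue_times <- cfg$static_hold + cue_rot
  itis <- diff(cue_times)
  keep <- seq(1L, length(tt), by = max(1L, round(0.01 / cfg$integration_step)))
  keep <- keep[tt[keep] <= fade_rot]
  structure(
    list(
      cues = tibble::tibble(
        trial_index = seq_len(cfg$n_trials),
        onset_s = cue_times,
        iti_s = c(NA_real_, itis)
      ),
      itis = itis,
      angle = tibble::tibble(
        time_s = cfg$static_hold + tt[keep],
        angle_deg = ang[keep],
        omega_deg_s = om[keep]
      ),
      run_duration = cfg$static_hold + fade_rot,
      config = cfg
    ),
    class = "cue_schedule"
  )
}

#' Summary statistics of a cue schedule
#'
#' @param schedule A `cue_schedule` from [generate_cue_schedule()].
#' @return A one-row tibble with `n_trials`, `mean_iti_s`, `sd_iti_s`,
#'   `min_iti_s`, `max_iti_s` and `run_duration_s`. With fewer than two cues
#'   the ITI statistics are undefined and returned as `NA` with a warning.
#' @export
schedule_statistics <- function(schedule) {
  stopifnot(inherits(schedule, "cue_schedule"))
  itis <- schedule$itis
  if (length(itis) < 1L) {
    warning("fewer than two cues: ITI statistics undefined")
    itis <- NA_real_
  }
  tibble::tibble(
    n_trials = nrow(schedule$cues),
    mean_iti_s = mean(itis),
    sd_iti_s = stats::sd(itis),
    min_iti_s = min(itis),
    max_iti_s = max(itis),
    run_duration_s = schedule$run_duration
  )
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf(
    "<cue_schedule> %d cues, run duration %.1f s\n",
    nrow(x$cues), x$run_duration
  ))
  if (length(x$itis)) {
    cat(sprintf(
      "  ITI mean %.2f s, range [%.2f, %.2f] s\n",
      mean(x$itis), min(x$itis), max(x$itis)
    ))
  }
  invisible(x)
}

#' Write a cue schedule to a tab-separated events file
#'
#' Writes one row per cue with columns `onset_s`, `trial_index`, `iti_s`.
#'
#' @param schedule A `cue_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cue_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cue_schedule"))
  readr::write_tsv(
    dplyr::select(schedule$cues, "onset_s", "trial_index", "iti_s"),
    path
  )
  invisible(path)
}
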