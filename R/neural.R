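#' Epoch a signal around movement onsets
#'
#' Stacks trials on a shared time axis relative to each onset. Works on a
#' `feature_series` (10 Hz low-frequency features) or an [eeg_recording()]
#' (broadband 500 Hz EEG, e.g. for time-frequency maps). Onsets without full
#' window support are dropped with a warning.
#'
#' @param x A `feature_series` or `eeg_recording`.
#' @param onsets Movement-onset times, seconds.
#' @param window Two-element numeric, epoch window in seconds relative to
#'   onset, e.g. `c(-2, 2)`.
#' @param condition Condition label stored with the epochs (`"cued"` or
#'   `"self_paced"`).
#' @return A list of class `epoch_set`: `data` (trials x channels x time
#'   array), `time_s` (lag axis), `channel_labels`, `condition`, `rate`.
#' @export
epoch_onsets <- function(x, onsets, window = c(-2, 2), condition = "cued") {
  stopifnot(length(window) == 2L)
  if (window[2L] <= window[1L]) {
    stop("degenerate epoch window [", window[1L], ", ", window[2L], "]")
  }
  if (inherits(x, "feature_series")) {
    values <- x$values
    rate <- x$rate
    t0 <- x$t0
    labels <- x$channel_labels
  } else if (inherits(x, "eeg_recording")) {
    values <- x$eeg
    rate <- x$eeg_rate
    t0 <- 0
    labels <- x$channel_labels
  } else {
    stop("x must be a feature_series or eeg_recording")
  }
  lag_idx <- round(window[1L] * rate):round(window[2L] * rate)
  lag_s <- lag_idx / rate
  keep <- logical(length(onsets))
  rows <- vector("list", length(onsets))
  for (k in seq_along(onsets)) {
    center <- round((onsets[k] - t0) * rate) + 1L
    idx <- center + lag_idx
    if (idx[1L] >= 1L && idx[length(idx)] <= ncol(values)) {
      keep[k] <- TRUE
      rows[[k]] <- values[, idx, drop = FALSE]
    }
  }
  if (!all(keep)) {
    warning(sum(!keep), " onset(s) without full epoch support dropped")
  }
  if (!any(keep)) stop("no usable trials in the requested window")
  rows <- rows[keep]
  data <- array(0, dim = c(length(rows), nrow(values), length(lag_s)))
  for (k in seq_along(rows)) data[k, , ] <- rows[[k]]
  structure(
    list(data = data, time_s = lag_s, channel_labels = labels,
         condition = condition, rate = rate),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %s: %d trials x %d channels x %d samples (%g Hz), [%g, %g] s\n",
    x$condition, dim(x$data)[1L], dim(x$data)[2L], dim(x$data)[3L],
    x$rate, min(x$time_s), max(x$time_s)
  ))
  invisible(x)
}

#' Trial-average waveform of an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel label or index; `NULL` averages are returned for
#'   all channels.
#' @return A tibble with `channel`, `time_s`, `mean_uv` and `se_uv`.
#' @export
epoch_average <- function(epochs, channel = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  chans <- seq_along(epochs$channel_labels)
  if (!is.null(channel)) {
    chans <- if (is.character(channel)) {
      match(channel, epochs$channel_labels)
    } else {
      as.integer(channel)
    }
    if (anyNA(chans)) stop("unknown channel: ", channel)
  }
  n <- dim(epochs$data)[1L]
  purrr::map_dfr(chans, function(ch) {
    m <- epochs$data[, ch, , drop = FALSE][, 1L, ]
    if (n == 1L) m <- matrix(m, nrow = 1L)
    tibble::tibble(
      channel = epochs$channel_labels[ch],
      time_s = epochs$time_s,
      mean_uv = colMeans(m),
      se_uv = apply(m, 2L, stats::sd) / sqrt(n)
    )
  })
}

#' Mass-univariate comparison of two epoched conditions
#'
#' Applies a two-sided Mann-Whitney U test (midrank tie handling) at every
#' (channel, time) sample and Bonferroni-corrects over the full tested grid
#' of channels x time samples.
#'
#' @param a,b `epoch_set` objects on the same channel set and time axis, with
#'   at least two trials each.
#' @param alpha Family-wise significance level.
#' @return A tibble with `channel`, `time_s`, `statistic` (U of condition a),
#'   `p_value` and `significant` (Bonferroni mask).
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "epoch_set"), inherits(b, "epoch_set"),
            identical(a$channel_labels, b$channel_labels),
            isTRUE(all.equal(a$time_s, b$time_s)),
            dim(a$data)[1L] >= 2L, dim(b$data)[1L] >= 2L)
  nch <- dim(a$data)[2L]
  nt <- dim(a$data)[3L]
  out <- tidyr::expand_grid(
    channel_i = seq_len(nch),
    time_i = seq_len(nt)
  )
  stat <- p <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    xa <- a$data[, out$channel_i[r], out$time_i[r]]
    xb <- b$data[, out$channel_i[r], out$time_i[r]]
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                              correct = TRUE))
    stat[r] <- unname(wt$statistic)
    p[r] <- wt$p.value
  }
  n_comp <- nch * nt
  tibble::tibble(
    channel = a$channel_labels[out$channel_i],
    time_s = a$time_s[out$time_i],
    statistic = stat,
    p_value = p,
    significant = p < alpha / n_comp
  )
}

#' Normalized root mean squared error between two waveforms
#'
#' RMSE between the comparison and reference time courses, divided by the
#' peak-to-peak range of the reference. Scale free: multiplying both inputs
#' by a common gain leaves it unchanged.
#'
#' @param comparison,reference Numeric vectors of equal length (the reference
#'   provides the normalization range).
#' @return Non-negative scalar; `NA` with a warning if the reference has zero
#'   range.
#' @export
nrmse <- function(comparison, reference) {
  stopifnot(length(comparison) == length(reference))
  rng <- diff(range(reference))
  if (rng == 0) {
    warning("reference has zero range: NRMSE undefined")
    return(NA_real_)
  }
  sqrt(mean((comparison - reference)^2)) / rng
}

#' Correlate waveform dissimilarity with detection performance
#'
#' Pearson correlation (with a two-sided t-test on `n - 2` degrees of
#' freedom) between per-subject NRMSE values and per-subject true positive
#' rates.
#'
#' @param nrmse_per_subject,tpr_per_subject Paired numeric vectors, length
#'   >= 3.
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @export
correlate_nrmse_tpr <- function(nrmse_per_subject, tpr_per_subject) {
  stopifnot(length(nrmse_per_subject) == length(tpr_per_subject),
            length(nrmse_per_subject) >= 3L)
  if (stats::sd(nrmse_per_subject) == 0 || stats::sd(tpr_per_subject) == 0) {
    warning("zero variance: correlation undefined")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n = length(nrmse_per_subject)))
  }
  ct <- stats::cor.test(nrmse_per_subject, tpr_per_subject, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(nrmse_per_subject))
}

#' Time-frequency map configuration
#'
#' @param center_freqs Band center frequencies in Hz (default 36 values
#'   spanning 5-40 Hz).
#' @param bandwidth Band width in Hz (filters span center +/- bandwidth/2).
#' @param reference Reference interval in seconds relative to onset.
#' @param n_boot Bootstrap resamples for the significance mask.
#' @param alpha Significance level of the bootstrap percentile interval.
#' @param smooth_s Length of the moving-average power smoothing window,
#'   seconds.
#' @param map_rate Time resolution of the output map, Hz.
#' @return A list of class `erds_config`.
#' @export
erds_config <- function(center_freqs = seq(5, 40, by = 1),
                        bandwidth = 2,
                        reference = c(-2, -0.5),
                        n_boot = 1000,
                        alpha = 0.05,
                        smooth_s = 0.2,
                        map_rate = 20) {
  stopifnot(all(center_freqs >= 5 - 1e-9), all(center_freqs <= 40 + 1e-9),
            bandwidth > 0, length(reference) == 2L,
            reference[2L] > reference[1L], reference[2L] <= 0,
            n_boot >= 1, alpha > 0, alpha < 1)
  structure(
    list(center_freqs = center_freqs, bandwidth = bandwidth,
         reference = reference, n_boot = n_boot, alpha = alpha,
         smooth_s = smooth_s, map_rate = map_rate),
    class = "erds_config"
  )
}

#' Event-related (de)synchronization map with bootstrap significance
#'
#' For each center frequency the single-channel epochs are band-pass
#' filtered (4th-order Butterworth, zero phase, center +/- bandwidth/2),
#' squared, smoothed with a short moving average, averaged over trials and
#' expressed as the percentage band-power change relative to the mean over
#' the pre-movement reference interval: `100 * (A - R) / R`. Negative values
#' are desynchronization (ERD), positive values synchronization (ERS).
#' Trials are resampled with replacement `n_boot` times; map pixels whose
#' percentile `(1 - alpha)` interval contains zero are marked
#' non-significant.
#'
#' @param epochs An `epoch_set` of broadband EEG (500 Hz).
#' @param channel Channel label or index to map.
#' @param cfg An [erds_config()].
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `erds_map`: `values` (frequencies x time matrix,
#'   percent), `significant` (logical mask), `freqs`, `time_s`, `channel`.
#' @export
erds_map <- function(epochs, channel = "C1", cfg = erds_config(), seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(cfg, "erds_config"))
  ch <- if (is.character(channel)) {
    match(channel, epochs$channel_labels)
  } else {
    as.integer(channel)
  }
  if (is.na(ch)) stop("unknown channel: ", channel)
  rate <- epochs$rate
  tt <- epochs$time_s
  if (cfg$reference[1L] < min(tt) || cfg$reference[2L] > max(tt)) {
    stop("reference interval outside the epoch window")
  }
  n_tr <- dim(epochs$data)[1L]
  x <- epochs$data[, ch, , drop = FALSE][, 1L, ]
  if (n_tr == 1L) x <- matrix(x, nrow = 1L)
  sm <- max(1L, round(cfg$smooth_s * rate))
  kern <- rep(1 / sm, sm)
  dec <- max(1L, round(rate / cfg$map_rate))
  keep <- seq(1L, length(tt), by = dec)
  ref_idx <- which(tt[keep] >= cfg$reference[1L] & tt[keep] <= cfg$reference[2L])
  nf <- length(cfg$center_freqs)
  vals <- matrix(0, nf, length(keep))
  mask <- matrix(FALSE, nf, length(keep))
  boot_w <- withr::with_seed(seed, {
    matrix(sample.int(n_tr, n_tr * cfg$n_boot, replace = TRUE),
           cfg$n_boot, n_tr)
  })
  # bootstrap weights as counts for fast matrix-product resampled means
  W <- matrix(0, cfg$n_boot, n_tr)
  for (b in seq_len(cfg$n_boot)) {
    tb <- tabulate(boot_w[b, ], nbins = n_tr)
    W[b, ] <- tb / n_tr
  }
  for (fi in seq_len(nf)) {
    f0 <- cfg$center_freqs[fi]
    band <- c(f0 - cfg$bandwidth / 2, f0 + cfg$bandwidth / 2)
    bf <- signal::butter(2, band / (rate / 2), type = "pass")
    P <- matrix(0, n_tr, length(keep))
    for (k in seq_len(n_tr)) {
      pw <- signal::filtfilt(bf, x[k, ])^2
      pw <- stats::filter(pw, kern, sides = 2)
      pw[is.na(pw)] <- 0
      P[k, ] <- pw[keep]
    }
    avg <- colMeans(P)
    ref <- mean(avg[ref_idx])
    if (ref <= 0) stop("zero reference power at ", f0, " Hz")
    vals[fi, ] <- 100 * (avg - ref) / ref
    bm <- W %*% P # n_boot x time resampled trial means
    bref <- rowMeans(bm[, ref_idx, drop = FALSE])
    berds <- 100 * sweep(bm, 1L, bref, "-") / bref
    lo <- apply(berds, 2L, stats::quantile, probs = cfg$alpha / 2)
    hi <- apply(berds, 2L, stats::quantile, probs = 1 - cfg$alpha / 2)
    mask[fi, ] <- lo > 0 | hi < 0
  }
  structure(
    list(values = vals, significant = mask, freqs = cfg$center_freqs,
         time_s = tt[keep],
         channel = epochs$channel_labels[ch], config = cfg),
    class = "erds_map"
  )
}

#' @export
print.erds_map <- function(x, ...) {
  cat(sprintf(
    "<erds_map> channel %s: %d frequencies x %d time points, %.1f%% significant\n",
    x$channel, nrow(x$values), ncol(x$values), 100 * mean(x$significant)
  ))
  invisible(x)
}
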