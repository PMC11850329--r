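# window matrix: one row per feature sample with full history; row layout is
# channel-major within each of the n_window time slices (oldest slice first)
window_matrix <- function(values, n_window) {
  nc <- nrow(values)
  nf <- ncol(values)
  if (nf < n_window) stop("fewer feature samples than n_window")
  ends <- n_window:nf
  X <- matrix(0, length(ends), nc * n_window)
  for (j in seq_len(n_window)) {
    X[, ((j - 1L) * nc + 1L):(j * nc)] <- t(values[, ends - n_window + j,
                                                   drop = FALSE])
  }
  X
}

#' Extract labeled sliding windows from a feature series
#'
#' Windows of `n_window` consecutive feature samples ending at time `t` are
#' advanced with a stride of one sample. The single window whose end sample
#' is nearest to `t_onset + d` is labeled *movement* for each onset; all other
#' windows are labeled *no movement*. Onsets whose target sample lacks a full
#' window history (too close to the run start) are skipped with a warning.
#'
#' @param features A `feature_series` (10 Hz decoding features).
#' @param onsets Numeric vector of movement-onset times, seconds.
#' @param n_window Window length in feature samples.
#' @param d Detection delay in seconds added to each onset before labeling.
#' @return A list of class `windowed_dataset` with `x` (windows x features
#'   matrix), `y` (logical movement labels), `window_end_times`, `n_window`,
#'   `d` and `n_channels`.
#' @export
extract_labeled_windows <- function(features, onsets, n_window, d = 0) {
  stopifnot(inherits(features, "feature_series"), n_window >= 1, d >= 0)
  n_window <- as.integer(n_window)
  times <- feature_times(features)
  X <- window_matrix(features$values, n_window)
  end_times <- times[n_window:length(times)]
  y <- rep(FALSE, nrow(X))
  for (t0 in onsets) {
    target <- t0 + d
    if (target > max(times) + 0.5 / features$rate) {
      warning("onset at ", signif(t0, 4), " s beyond feature range; skipped")
      next
    }
    i <- which.min(abs(times - target))
    if (i < n_window) {
      warning("onset at ", signif(t0, 4),
              " s too close to run start for n_window = ", n_window,
              "; trial skipped")
      next
    }
    y[i - n_window + 1L] <- TRUE
  }
  structure(
    list(x = X, y = y, window_end_times = end_times,
         n_window = n_window, d = d, n_channels = nrow(features$values)),
    class = "windowed_dataset"
  )
}

# Ledoit-Wolf (2004) linear shrinkage of a pooled covariance toward the
# scaled identity. Xc: rows already centred (per class). Returns the shrunk
# covariance and the shrinkage intensity in [0, 1].
lw_linear_shrink <- function(Xc) {
  n <- nrow(Xc)
  p <- ncol(Xc)
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2)
  sq_norms <- rowSums(Xc^2)
  b2bar <- sum(sq_norms^2) / n^2 - sum(S^2) / n
  b2 <- min(max(b2bar, 0), d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  list(sigma = rho * diag(m, p) + (1 - rho) * S, intensity = rho)
}

# Quadratic-inverse shrinkage (closed-form nonlinear eigenvalue shrinkage of
# Ledoit & Wolf). Xc: centred rows; k degrees of freedom already consumed.
qis_shrink <- function(Xc, k = 2) {
  n0 <- nrow(Xc)
  p <- ncol(Xc)
  n <- n0 - k + 1 # effective sample size after centring
  c_ratio <- p / n
  S <- crossprod(Xc) / n
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values)
  lambda_all <- e$values[ord]
  u <- e$vectors[, ord, drop = FALSE]
  keep <- max(1L, p - n + 1L):p
  lambda <- pmax(lambda_all[keep], .Machine$double.eps)
  invlambda <- 1 / lambda
  h <- min(c_ratio^2, 1 / c_ratio^2)^0.35 / p^0.35
  Lj <- matrix(invlambda, length(invlambda), length(invlambda))
  Lj_i <- Lj - t(Lj)
  denom <- Lj_i^2 + h^2 * Lj^2
  theta <- rowMeans(Lj * Lj_i / denom)
  Htheta <- rowMeans(Lj * (h * Lj) / denom)
  Atheta2 <- theta^2 + Htheta^2
  if (p <= n) {
    delta <- 1 / ((1 - c_ratio)^2 * invlambda +
                    2 * c_ratio * (1 - c_ratio) * invlambda * theta +
                    c_ratio^2 * invlambda * Atheta2)
  } else {
    delta0 <- 1 / ((c_ratio - 1) * mean(invlambda))
    delta <- c(rep(delta0, p - n), 1 / (invlambda * Atheta2))
  }
  delta_qis <- delta * (sum(lambda) / sum(delta))
  sigma <- u %*% (delta_qis * t(u))
  list(sigma = (sigma + t(sigma)) / 2, intensity = NA_real_)
}

#' Fit a binary shrinkage LDA movement detector
#'
#' Linear discriminant analysis with a regularized pooled covariance for the
#' high-dimensional, imbalanced window classification problem. The pooled
#' (class-centred) covariance is shrunk either linearly toward a scaled
#' identity with the closed-form Ledoit-Wolf intensity (`"lw_linear"`,
#' default) or by closed-form quadratic-inverse shrinkage of its eigenvalues
#' (`"qis"`). Both estimators are cross-validation free. The detector score
#' is the posterior probability of *movement* under the shared-covariance
#' Gaussian model.
#'
#' Class priors default to equal, placing the decision boundary at the
#' Mahalanobis midpoint between the class means; with the extreme label
#' imbalance of stride-one windowing, empirical priors would drive every
#' posterior far below 0.5. Detection thresholds are calibrated downstream
#' ([calibrate_threshold()]) in either case.
#'
#' @param ds A `windowed_dataset` from [extract_labeled_windows()].
#' @param method Covariance shrinkage estimator, `"lw_linear"` or `"qis"`.
#' @param priors Either `"equal"` or a numeric vector `c(p_move, p_rest)`
#'   summing to one; `"empirical"` uses the class frequencies.
#' @return A list of class `slda_model`: `class_means`, `shrunk_cov`,
#'   `weights`, `bias`, `priors`, `shrinkage_intensity`, `method`,
#'   `n_window`, `d`, `n_channels`.
#' @export
fit_slda <- function(ds, method = c("lw_linear", "qis"), priors = "equal") {
  method <- match.arg(method)
  stopifnot(inherits(ds, "windowed_dataset"))
  y <- ds$y
  if (!any(y) || all(y)) stop("both classes must be present to fit the sLDA")
  X <- ds$x
  mu_pos <- colMeans(X[y, , drop = FALSE])
  mu_neg <- colMeans(X[!y, , drop = FALSE])
  Xc <- X
  Xc[y, ] <- sweep(X[y, , drop = FALSE], 2L, mu_pos)
  Xc[!y, ] <- sweep(X[!y, , drop = FALSE], 2L, mu_neg)
  shr <- switch(method,
    lw_linear = lw_linear_shrink(Xc),
    qis = qis_shrink(Xc, k = 2)
  )
  pr <- if (identical(priors, "equal")) {
    c(0.5, 0.5)
  } else if (identical(priors, "empirical")) {
    c(mean(y), 1 - mean(y))
  } else {
    stopifnot(is.numeric(priors), length(priors) == 2L,
              abs(sum(priors) - 1) < 1e-8)
    priors
  }
  w <- tryCatch(
    solve(shr$sigma, mu_pos - mu_neg),
    error = function(e) {
      solve(shr$sigma + diag(1e-8 * mean(diag(shr$sigma)), ncol(X)),
            mu_pos - mu_neg)
    }
  )
  bias <- -sum(w * (mu_pos + mu_neg)) / 2 + log(pr[1L] / pr[2L])
  structure(
    list(
      class_means = list(movement = mu_pos, no_movement = mu_neg),
      shrunk_cov = shr$sigma, weights = w, bias = bias, priors = pr,
      shrinkage_intensity = shr$intensity, method = method,
      n_window = ds$n_window, d = ds$d, n_channels = ds$n_channels
    ),
    class = "slda_model"
  )
}

#' @export
print.slda_model <- function(x, ...) {
  cat(sprintf(
    "<slda_model> %s shrinkage, %d features (n_window = %d, d = %.2f s)\n",
    x$method, length(x$weights), x$n_window, x$d
  ))
  if (is.finite(x$shrinkage_intensity)) {
    cat(sprintf("  shrinkage intensity %.3f\n", x$shrinkage_intensity))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an sLDA model
#'
#' One row per model weight, identifying the channel and within-window lag
#' each coefficient applies to.
#'
#' @param x An `slda_model`.
#' @param ... Unused.
#' @return A tibble with `channel`, `lag_samples` (0 = window end) and
#'   `estimate`.
#' @export
tidy.slda_model <- function(x, ...) {
  nc <- x$n_channels
  tibble::tibble(
    channel = rep(seq_len(nc), times = x$n_window),
    lag_samples = rep((x$n_window - 1L):0L, each = nc),
    estimate = as.numeric(x$weights)
  )
}

#' Glance at an sLDA model
#'
#' @param x An `slda_model`.
#' @param ... Unused.
#' @return One-row tibble with the model dimensions and shrinkage summary.
#' @export
glance.slda_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_features = length(x$weights),
    n_window = x$n_window,
    d = x$d,
    shrinkage_intensity = x$shrinkage_intensity
  )
}

#' Score a run with a fitted sLDA detector
#'
#' Computes the movement posterior for every feature sample that has a full
#' window history.
#'
#' @param model An `slda_model`.
#' @param features A `feature_series` with the same channel count the model
#'   was trained on.
#' @param n_window Window length; defaults to the model's.
#' @return A tibble with `time_s` (window end time) and `score` in `[0, 1]`.
#' @export
score_run <- function(model, features, n_window = model$n_window) {
  stopifnot(inherits(model, "slda_model"), inherits(features, "feature_series"))
  if (nrow(features$values) != model$n_channels) {
    stop("dimension mismatch: model expects ", model$n_channels,
         " channels, features have ", nrow(features$values))
  }
  X <- window_matrix(features$values, n_window)
  times <- feature_times(features)[n_window:ncol(features$values)]
  tibble::tibble(
    time_s = times,
    score = stats::plogis(as.numeric(X %*% model$weights) + model$bias)
  )
}

#' Runwise cross-validated selection of window length and detection delay
#'
#' For each candidate `(n_window, d)` pair, a 3-fold runwise cross-validation
#' is performed over the three cue-based runs: the model is trained on one
#' run and tested on the remaining two, and performance is the sample-by-
#' sample Matthews correlation coefficient of the predicted labels against
#' the exact single-sample movement labels on the test runs. The pair with
#' the highest mean MCC across folds wins (ties broken toward smaller
#' `n_window`, then smaller `d`), and the final model is refit on all three
#' runs pooled.
#'
#' @param runs List of exactly three lists, each with elements `features`
#'   (a `feature_series`) and `onsets` (numeric onset times).
#' @param n_window_grid Candidate window lengths, feature samples.
#' @param d_grid Candidate detection delays, seconds.
#' @param method Shrinkage estimator passed to [fit_slda()].
#' @return A list of class `hyperparameter_selection` with `best` (one-row
#'   tibble `n_window`, `d`, `mcc`), `results` (full grid tibble) and
#'   `model` (the final `slda_model`).
#' @export
select_hyperparameters <- function(runs,
                                   n_window_grid = 3:20,
                                   d_grid = seq(0, 0.5, by = 0.1),
                                   method = "lw_linear") {
  stopifnot(is.list(runs), length(runs) == 3L)
  if (!length(n_window_grid) || !length(d_grid)) {
    stop("hyperparameter grids must be non-empty")
  }
  grid <- tidyr::expand_grid(n_window = sort(unique(as.integer(n_window_grid))),
                             d = sort(unique(d_grid)))
  fold_mcc <- function(n_window, d) {
    ds <- lapply(runs, function(r) {
      extract_labeled_windows(r$features, r$onsets, n_window, d)
    })
    vapply(1:3, function(train_i) {
      model <- fit_slda(ds[[train_i]], method = method)
      tp <- fp <- tn <- fn <- 0
      for (test_i in setdiff(1:3, train_i)) {
        sc <- stats::plogis(as.numeric(ds[[test_i]]$x %*% model$weights) +
                              model$bias)
        pred <- sc >= 0.5
        truth <- ds[[test_i]]$y
        tp <- tp + sum(pred & truth)
        fp <- fp + sum(pred & !truth)
        tn <- tn + sum(!pred & !truth)
        fn <- fn + sum(!pred & truth)
      }
      mcc(tp, fp, tn, fn)
    }, numeric(1))
  }
  grid$mcc <- purrr::pmap_dbl(grid, function(n_window, d) {
    mean(fold_mcc(n_window, d))
  })
  best <- dplyr::arrange(grid, dplyr::desc(.data$mcc), .data$n_window, .data$d)[1L, ]
  pooled <- pool_windowed(lapply(runs, function(r) {
    extract_labeled_windows(r$features, r$onsets, best$n_window, best$d)
  }))
  structure(
    list(best = best, results = grid,
         model = fit_slda(pooled, method = method)),
    class = "hyperparameter_selection"
  )
}

# concatenate windowed datasets (same n_window/d) across runs
pool_windowed <- function(ds_list) {
  structure(
    list(
      x = do.call(rbind, lapply(ds_list, `[[`, "x")),
      y = do.call(c, lapply(ds_list, `[[`, "y")),
      window_end_times = do.call(c, lapply(ds_list, `[[`, "window_end_times")),
      n_window = ds_list[[1L]]$n_window,
      d = ds_list[[1L]]$d,
      n_channels = ds_list[[1L]]$n_channels
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.hyperparameter_selection <- function(x, ...) {
  cat(sprintf(
    "<hyperparameter_selection> best n_window = %d, d = %.2f s (CV MCC %.3f)\n",
    x$best$n_window, x$best$d, x$best$mcc
  ))
  invisible(x)
}
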