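# small synthetic feature series with known onsets
toy_features <- function(n = 200, nc = 3, seed = 1) {
  set.seed(seed)
  feature_series(matrix(rnorm(nc * n), nc, n))
}

test_that("window extraction labels one sample per movement", {
  f <- toy_features(300)
  onsets <- seq(3, 25.5, by = 2.5) # 10 onsets
  ds <- extract_labeled_windows(f, onsets, n_window = 5, d = 0.2)
  expect_equal(sum(ds$y), 10L)
  expect_equal(nrow(ds$x), 300L - 4L) # stride one, full-history windows only
  expect_equal(ncol(ds$x), 5L * 3L)
  # n_window = 5 at 10 Hz spans 0.5 s of features
  expect_equal(ds$window_end_times[1L] - 0, 0.4, tolerance = 1e-9)
  # positive windows end at the sample nearest onset + d
  pos_t <- ds$window_end_times[ds$y]
  expect_equal(pos_t, onsets + 0.2, tolerance = 0.05 + 1e-9)
})

test_that("vectorized windowing matches an explicit loop oracle", {
  f <- toy_features(300, nc = 4, seed = 2) # 30 s fixture at 10 Hz
  onsets <- c(4.03, 11.5, 19.97)
  n_window <- 6
  d <- 0.1
  ds <- extract_labeled_windows(f, onsets, n_window, d)
  # oracle: brute-force re-extraction sample by sample
  times <- (seq_len(300) - 1) / 10
  targets <- vapply(onsets, function(t0) which.min(abs(times - (t0 + d))),
                    integer(1))
  for (r in c(1L, 2L, 57L, 295L)) {
    i <- r + n_window - 1L # feature index of the window end
    want <- as.vector(f$values[, (i - n_window + 1L):i])
    expect_identical(ds$x[r, ], want)
    expect_identical(ds$y[r], i %in% targets)
  }
  expect_equal(which(ds$y), targets - n_window + 1L)
})

test_that("onsets without full window history are skipped with a warning", {
  f <- toy_features(100)
  expect_warning(ds <- extract_labeled_windows(f, c(0.1, 5), n_window = 8),
                 "too close to run start")
  expect_equal(sum(ds$y), 1L)
  expect_warning(extract_labeled_windows(f, 99, n_window = 5),
                 "beyond feature range")
})

# windowed dataset straight from matrices
as_ds <- function(x, y, n_window = 1L) {
  structure(
    list(x = x, y = y, window_end_times = seq_len(nrow(x)) / 10,
         n_window = n_window, d = 0, n_channels = ncol(x) / n_window),
    class = "windowed_dataset"
  )
}

test_that("sLDA separates well-separated Gaussian classes", {
  set.seed(3)
  n <- 300
  x <- rbind(matrix(rnorm(n * 4, mean = 0), n, 4),
             matrix(rnorm(n * 4, mean = 3), n, 4))
  y <- rep(c(FALSE, TRUE), each = n)
  model <- fit_slda(as_ds(x, y, 2L))
  pred <- stats::plogis(as.numeric(x %*% model$weights) + model$bias) >= 0.5
  cm <- table(pred, y)
  m <- mcc(cm[2, 2], cm[2, 1], cm[1, 1], cm[1, 2])
  expect_gt(m, 0.95)

  # permuted labels carry no information
  y_perm <- sample(y)
  model0 <- fit_slda(as_ds(x, y_perm, 2L))
  pred0 <- stats::plogis(as.numeric(x %*% model0$weights) + model0$bias) >= 0.5
  m0 <- mcc(sum(pred0 & y_perm), sum(pred0 & !y_perm),
            sum(!pred0 & !y_perm), sum(!pred0 & y_perm))
  expect_lt(abs(m0), 0.15)
})

test_that("single-class data is rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_slda(as_ds(x, rep(TRUE, 10))), "both classes")
})

test_that("the shrunk covariance interpolates sample covariance and identity", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30 * 6), 30, 6),
             matrix(rnorm(30 * 6, 1), 30, 6))
  y <- rep(c(FALSE, TRUE), each = 30)
  model <- fit_slda(as_ds(x, y, 3L))
  rho <- model$shrinkage_intensity
  expect_gte(rho, 0)
  expect_lte(rho, 1)
  # white-box reconstruction: sigma = rho * m * I + (1 - rho) * S
  xc <- x
  xc[y, ] <- sweep(x[y, , drop = FALSE], 2, colMeans(x[y, , drop = FALSE]))
  xc[!y, ] <- sweep(x[!y, , drop = FALSE], 2, colMeans(x[!y, , drop = FALSE]))
  S <- crossprod(xc) / nrow(xc)
  m <- mean(diag(S))
  expect_equal(model$shrunk_cov, rho * diag(m, 6) + (1 - rho) * S,
               tolerance = 1e-10)
})

test_that("shrinkage vanishes and weights converge with growing sample size", {
  set.seed(5)
  p <- 5
  A <- matrix(rnorm(p * p), p)
  Sigma <- crossprod(A) / p + diag(p)
  R <- chol(Sigma)
  delta <- rep(1, p)
  n <- 4000
  x <- rbind(matrix(rnorm(n * p), n, p) %*% R,
             sweep(matrix(rnorm(n * p), n, p) %*% R, 2, -delta))
  y <- rep(c(FALSE, TRUE), each = n)
  model <- fit_slda(as_ds(x, y, 1L))
  expect_lt(model$shrinkage_intensity, 0.05)
  w_true <- solve(Sigma, delta)
  cosang <- sum(model$weights * w_true) /
    sqrt(sum(model$weights^2) * sum(w_true^2))
  expect_gt(cosang, 0.99)
})

test_that("quadratic-inverse shrinkage yields a valid covariance", {
  set.seed(6)
  # p comparable to n: shrinkage matters
  x <- rbind(matrix(rnorm(60 * 40), 60, 40),
             matrix(rnorm(60 * 40, 0.5), 60, 40))
  y <- rep(c(FALSE, TRUE), each = 60)
  model <- fit_slda(as_ds(x, y, 4L), method = "qis")
  ev <- eigen(model$shrunk_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0)) # positive definite
  # trace is preserved relative to the sample covariance
  xc <- x
  xc[y, ] <- sweep(x[y, , drop = FALSE], 2, colMeans(x[y, , drop = FALSE]))
  xc[!y, ] <- sweep(x[!y, , drop = FALSE], 2, colMeans(x[!y, , drop = FALSE]))
  S <- crossprod(xc) / (nrow(xc) - 1)
  expect_equal(sum(diag(model$shrunk_cov)), sum(diag(S)), tolerance = 0.05)

  # with n >> p the estimator approaches the sample covariance
  set.seed(7)
  xb <- matrix(rnorm(4000 * 5), 4000, 5)
  yb <- rep(c(FALSE, TRUE), 2000)
  mq <- fit_slda(as_ds(xb, yb, 1L), method = "qis")
  Sb <- crossprod(scale(xb, scale = FALSE)) / 4000
  expect_lt(norm(mq$shrunk_cov - Sb, "F") / norm(Sb, "F"), 0.1)
})

test_that("scores are probabilities and default to the prior for a null model", {
  f <- toy_features(120, nc = 2, seed = 8)
  model <- structure(
    list(class_means = NULL, shrunk_cov = diag(10), weights = rep(0, 10),
         bias = log(0.3 / 0.7), priors = c(0.3, 0.7),
         shrinkage_intensity = 0.5, method = "lw_linear",
         n_window = 5L, d = 0, n_channels = 2L),
    class = "slda_model"
  )
  sc <- score_run(model, f)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_equal(unique(sc$score), 0.3, tolerance = 1e-12)
  expect_equal(nrow(sc), 120L - 4L)

  bad <- feature_series(matrix(0, 5, 50))
  expect_error(score_run(model, bad), "dimension mismatch")
})

test_that("MCC is invariant to class relabeling", {
  expect_equal(mcc(7, 2, 90, 3), mcc(90, 3, 7, 2))
  expect_equal(mcc(12, 5, 40, 9), mcc(40, 9, 12, 5))
})

test_that("a single-point grid is returned unchanged", {
  f <- toy_features(200, nc = 2, seed = 9)
  runs <- lapply(1:3, function(i) {
    list(features = toy_features(200, nc = 2, seed = 10 + i),
         onsets = c(5, 9, 14))
  })
  sel <- select_hyperparameters(runs, n_window_grid = 4, d_grid = 0.2)
  expect_equal(sel$best$n_window, 4L)
  expect_equal(sel$best$d, 0.2)
  expect_s3_class(sel$model, "slda_model")
  expect_error(select_hyperparameters(runs, integer(0), 0.1), "non-empty")
})

test_that("cross-validated selection matches a brute-force oracle", {
  # features with an injected class difference so MCC is informative
  make_run <- function(seed) {
    set.seed(seed)
    v <- matrix(rnorm(4 * 250), 4, 250)
    onsets <- c(6, 11, 16, 21)
    for (t0 in onsets) v[, round(t0 * 10) + 1] <- v[, round(t0 * 10) + 1] + 3
    list(features = feature_series(v), onsets = onsets)
  }
  runs <- lapply(21:23, make_run)
  nw_grid <- c(3, 5)
  d_grid <- c(0, 0.2)
  sel <- select_hyperparameters(runs, nw_grid, d_grid)
  # independent exhaustive loop over the same grid and folds
  oracle <- expand.grid(n_window = nw_grid, d = d_grid)
  oracle$mcc <- apply(oracle, 1, function(g) {
    ds <- lapply(runs, function(r) {
      extract_labeled_windows(r$features, r$onsets, g[["n_window"]], g[["d"]])
    })
    mean(sapply(1:3, function(i) {
      m <- fit_slda(ds[[i]])
      cm <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      for (j in setdiff(1:3, i)) {
        p <- stats::plogis(as.numeric(ds[[j]]$x %*% m$weights) + m$bias) >= 0.5
        cm <- cm + c(sum(p & ds[[j]]$y), sum(p & !ds[[j]]$y),
                     sum(!p & !ds[[j]]$y), sum(!p & ds[[j]]$y))
      }
      mcc(cm[1], cm[2], cm[3], cm[4])
    }))
  })
  for (r in seq_len(nrow(oracle))) {
    got <- sel$results$mcc[sel$results$n_window == oracle$n_window[r] &
                             abs(sel$results$d - oracle$d[r]) < 1e-9]
    expect_equal(got, oracle$mcc[r], tolerance = 1e-10)
  }
  best_o <- oracle[order(-oracle$mcc, oracle$n_window, oracle$d), ][1, ]
  expect_equal(sel$best$n_window, as.integer(best_o$n_window))
  expect_equal(sel$best$d, best_o$d)
})

test_that("tidy and glance expose the fitted detector", {
  set.seed(10)
  x <- rbind(matrix(rnorm(200), 50, 4), matrix(rnorm(200, 1), 50, 4))
  y <- rep(c(FALSE, TRUE), each = 50)
  model <- fit_slda(as_ds(x, y, 2L))
  td <- generics::tidy(model)
  expect_equal(nrow(td), 4L)
  expect_named(td, c("channel", "lag_samples", "estimate"))
  expect_equal(td$estimate, as.numeric(model$weights))
  gl <- generics::glance(model)
  expect_equal(gl$n_features, 4L)
  expect_equal(gl$method, "lw_linear")
})
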