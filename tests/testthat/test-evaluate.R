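test_that("a complete component set explains all PSTH variance", {
  ps <- random_psth(N = 5, S = 2, Q = 2, T_ = 6, seed = 3)
  fit <- dpca_fit(ps, q = 5)
  ev <- explained_variance(fit)
  expect_equal(ev$total_r2, 1, tolerance = 1e-8)
  expect_true(all(diff(ev$cumulative) >= -1e-10))
  # per-component marginalization splits sum to the component R^2
  labs <- names(fit$F)
  expect_lt(max(abs(rowSums(ev$components[, labs]) -
                    ev$components$expl_var)), 1e-10)
})

test_that("regression-based variance of arbitrary components is correct", {
  set.seed(5)
  N <- 6; ncol_ <- 24
  u <- rnorm(N); u <- u / sqrt(sum(u^2))
  z <- rnorm(ncol_)
  X <- u %o% z                      # rank-1 data
  ps <- array(X, dim = c(N, 2, 2, 6))
  expect_equal(explained_variance(matrix(z, 1), ps)$r2, 1, tolerance = 1e-10)
  zo <- rnorm(ncol_)
  zo <- zo - sum(zo * z) / sum(z * z) * z    # orthogonal time course
  expect_equal(explained_variance(matrix(zo, 1), ps)$r2, 0,
               tolerance = 1e-10)
})

test_that("cumulative R2 differs from summed R2 by the covariance term", {
  ps <- random_psth(N = 6, S = 3, Q = 2, T_ = 8, seed = 9)
  fit <- dpca_fit(ps, q = 2)
  ev <- explained_variance(fit)
  q2 <- 2
  tab <- fit$comp[seq_len(q2), ]
  Xt <- matrix(ps$values, 6)
  contrib <- lapply(seq_len(q2), function(i) {
    d <- fit$D[[tab$label[i]]][tab$within[i], , drop = FALSE]
    f <- fit$F[[tab$label[i]]][, tab$within[i], drop = FALSE]
    f %*% (d %*% Xt)
  })
  cross <- 2 * sum(contrib[[1]] * contrib[[2]]) / sum(Xt^2)
  gap <- sum(ev$components$expl_var[1:2]) - ev$cumulative[2]
  expect_equal(gap, cross, tolerance = 1e-10)
})

test_that("marginalization degrees of freedom partition the total", {
  S <- 6; Q <- 2; T_ <- 10
  ps <- random_psth(N = 3, S = S, Q = Q, T_ = T_, seed = 2)
  ms <- marginalize(ps)
  lv <- c(s = S, d = Q, t = T_)
  dof <- dpca:::.marg_dof(ms$grouping, lv)
  expect_equal(unname(dof["t"]), T_ - 1)
  expect_equal(unname(dof["st"]), S * T_ - T_)
  expect_equal(unname(dof["dt"]), Q * T_ - T_)
  expect_equal(unname(dof["sdt"]), S * Q * T_ - S * T_ - Q * T_ + T_)
  expect_equal(sum(dof), S * Q * T_ - 1)
})

test_that("signal variance is exact for zero noise and calibrated otherwise", {
  tt <- random_trial_tensor(N = 4, S = 2, Q = 2, T_ = 5, K = 1, seed = 4)
  ms <- marginalize(compute_psths(tt, center = TRUE))
  zero_noise <- structure(list(values = rep(0, 4), mode = "diagonal",
                               rebalanced = TRUE, K_tilde = rep(1, 4)),
                          class = "noise_covariance")
  sv0 <- signal_variance(zero_noise, ms)
  expect_equal(sv0$theta, 0)
  expect_equal(sv0$signal_fraction, 1)
  expect_equal(sum(sv0$pie_percent), 100L)

  sim <- generate_population(N = 50, S = 3, Q = 2, T_ = 20, K = 10,
                             snr = 1, seed = 77)
  ps <- compute_psths(sim$data, center = TRUE)
  ms2 <- marginalize(ps)
  nc <- estimate_noise_covariance(sim$data)
  sv <- signal_variance(nc, ms2)
  # true signal sum of squares from the generator's noiseless PSTH
  signal <- Reduce(`+`, lapply(seq_along(sim$truth$latents), function(j)
    outer(sim$truth$weights[, j], sim$truth$latents[[j]]$z)))
  signal <- signal - apply(signal, 1, mean)
  est_signal <- sum(ps$values^2) * sv$signal_fraction
  # the population-denominator noise estimate under-counts residual noise
  # by (K-1)/K, so the estimator's expectation is truth + S Q T N sd^2/K^2
  d <- dim(ps$values)
  pred <- sum(signal^2) +
    prod(d) * sim$truth$noise_sd^2 / mean(sim$data$counts)^2
  expect_lt(abs(est_signal - pred) / pred, 0.1)
  expect_lt(abs(est_signal - sum(signal^2)) / sum(signal^2), 0.2)
})

test_that("largest remainder rounding returns integers that sum to 100", {
  expect_equal(largest_remainder(c(0.405, 0.405, 0.19)), c(41L, 40L, 19L))
  expect_equal(largest_remainder(c(1, 1, 1)), c(34L, 33L, 33L))
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1))
    r <- largest_remainder(p)
    expect_true(all(r == as.integer(r)))
    expect_equal(sum(r), 100L)
  }
  expect_warning(largest_remainder(c(-0.1, 0.6, 0.5)), "clipped")
})

test_that("demixing indices stay within their theoretical bounds", {
  ms <- random_psth(N = 6, S = 3, Q = 2, T_ = 8, seed = 10) |> marginalize()
  set.seed(11)
  idx <- vapply(1:1000, function(i) demixing_index(rnorm(6), ms), 1)
  expect_true(all(idx >= 0.25 - 1e-12))
  expect_true(all(idx <= 1 + 1e-12))
  expect_warning(v <- demixing_index(rep(0, 6), ms), "zero projected")
  expect_true(is.nan(v))
})

test_that("axis significance combines the dot-product rule with Kendall", {
  expect_equal(axis_significance(diag(832)[, 1:2])$threshold,
               3.3 / sqrt(832))
  set.seed(12)
  N <- 100
  f1 <- rnorm(N); f1 <- f1 / sqrt(sum(f1^2))
  Fm <- cbind(f1, f1, c(f1[-1], 0) * 0 + diag(N)[, 5])
  Fm[, 3] <- Fm[, 3] - sum(Fm[, 3] * f1) * f1     # orthogonalize
  Fm[, 3] <- Fm[, 3] / sqrt(sum(Fm[, 3]^2))
  res <- axis_significance(Fm)
  expect_true(res$flagged[1, 2])                  # identical axes
  expect_false(res$flagged[1, 3])                 # orthogonal axes
  expect_warning(axis_significance(diag(5)[, 1:2]), "vacuous")
})

test_that("perfectly separable stimuli are decoded at ceiling", {
  sim <- generate_population(N = 15, S = 3, Q = 2, T_ = 12, K = 3,
                             n_latents = c(st = 1), noise_sd = 1e-4,
                             snr = 1e8, seed = 13)
  rep <- suppressWarnings(classification_significance(
    sim$data, q = 3, n_cv = 5, n_shuffles = 5, n_comp_per_label = 1,
    min_consecutive = 3, seed = 21))
  st_row <- which(rep$components$label == "st")
  # the stimulus latent is a bump: decoding is perfect where it is active
  expect_gt(max(rep$accuracy[st_row, ]), 0.999)
  expect_true(any(rep$mask[st_row, ]))
  # chance level for the decision classifier with Q = 2 is ~1/2
  dt_row <- which(rep$components$label == "dt")
  expect_lt(mean(rep$accuracy[dt_row, ]), 0.75)
  expect_gt(mean(rep$accuracy[dt_row, ]), 0.25)
})

test_that("trial shuffling preserves per-condition counts and rates", {
  tt <- random_trial_tensor(N = 3, S = 2, Q = 2, T_ = 4, K = 3, seed = 14)
  set.seed(15)
  sh <- shuffle_trials(tt)
  expect_identical(sh$counts, tt$counts)
  for (n in 1:3) {
    orig <- sort(as.numeric(tt$values[n, , , 1, ]))
    got <- sort(as.numeric(sh$values[n, , , 1, ]))
    expect_equal(got, orig)
  }
})

test_that("density peaks find the right number of cluster centres", {
  set.seed(16)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.03), rnorm(n, cy, 0.03))
  two <- rbind(blob(0, 0, 40), blob(1, 1, 40))
  dp2 <- density_peaks(two)
  # cluster centres: high gamma = density x delta outliers
  top <- order(dp2$gamma, decreasing = TRUE)
  expect_gt(dp2$gamma[top[2]], 10 * dp2$gamma[top[3]])
  expect_true((top[1] <= 40) != (top[2] <= 40))  # one centre per blob
  one <- blob(0, 0, 60)
  dp1 <- density_peaks(one)
  top1 <- order(dp1$gamma, decreasing = TRUE)
  expect_gt(dp1$gamma[top1[1]], 2 * dp1$gamma[top1[2]])
  expect_equal(top1[1], dp1$peak)   # the lone outlier is the density mode
  expect_equal(dp1$delta[dp1$peak],
               max(as.matrix(dist(one))[dp1$peak, ]))
})

test_that("encoder-weight diagnostics run on a fitted model", {
  sim <- generate_population(N = 25, S = 3, Q = 2, T_ = 10, K = 3, seed = 18)
  fit <- dpca_fit(sim$data, q = 4)
  dg <- encoder_weight_diagnostics(fit, n_comp = 8)
  expect_equal(ncol(dg$weights), 8)
  expect_equal(nrow(dg$weights), 25)
  expect_equal(dg$delta[dg$peak],
               max(as.matrix(dist(dg$weights))[dg$peak, ]))
})
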