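test_that("PCA explains at least as much variance as dPCA at equal q", {
  for (seed in 1:10) {
    sim <- generate_population(N = 12, S = 3, Q = 2, T_ = 8, K = 3,
                               seed = 100 + seed)
    ps <- compute_psths(sim$data, center = TRUE)
    fit <- dpca_fit(ps, q = 2)
    ev <- explained_variance(fit)
    q <- 5
    Xt <- matrix(ps$values, 12)
    U <- pca_baseline(ps, q)$F
    pca_r2 <- 1 - sum((Xt - U %*% crossprod(U, Xt))^2) / sum(Xt^2)
    expect_gte(pca_r2 + 1e-10, ev$cumulative[q])
  }
})

test_that("full PCA basis reaches R2 = 1 and rank-1 data has one PC", {
  ps <- random_psth(N = 4, seed = 31)
  pb <- pca_baseline(ps, 10)            # q clamped to N
  expect_equal(ncol(pb$F), 4)
  Xt <- matrix(ps$values, 4)
  expect_lt(sum((Xt - pb$F %*% (pb$D %*% Xt))^2), 1e-16 * sum(Xt^2))
  u <- rnorm(5); z <- rnorm(36)
  r1 <- psth_tensor(array(u %o% z, dim = c(5, 2, 3, 6)))
  expect_warning(svd1 <- pca_baseline(center_psth(r1), 3), NA)
  expect_lt(svd1$sv[2], 1e-8 * svd1$sv[1])
})

test_that("pseudo-inverse decoders equal transposes for orthogonal labels", {
  # disjoint neuron support per marginalization => orthogonal subspaces
  N <- 8; S <- 3; Q <- 2; T_ <- 10
  sim <- generate_population(N = 2, S = S, Q = Q, T_ = T_, K = 2,
                             noise_sd = 0, seed = 61)
  vals <- array(0, dim = c(N, S, Q, T_))
  ms0 <- marginalize(sim$data)
  labs <- names(ms0$tensors)
  for (i in seq_along(labs))
    vals[(2 * i - 1):(2 * i), , , ] <- ms0$tensors[[labs[i]]]
  ms <- marginalize(center_psth(psth_tensor(vals)))
  bm <- suppressWarnings(marg_pca_pinv(ms, k = 1))
  expect_lt(max(abs(bm$D - t(bm$F))), 1e-8)
})

test_that("marginalization PCA approximates dPCA on well-separated data", {
  sim <- generate_population(N = 40, S = 3, Q = 2, T_ = 15, K = 5,
                             snr = 5, seed = 71)
  ps <- compute_psths(sim$data, center = TRUE)
  ms <- marginalize(ps)
  fit <- dpca_fit(ps, q = 3)
  bm <- suppressWarnings(marg_pca_pinv(ms, k = 3))
  Xt <- matrix(ps$values, 40)
  d_dpca <- fit$D$st[1, ] %*% Xt
  d_marg <- bm$D[which(bm$labels == "st")[1], ] %*% Xt
  expect_gt(abs(cor(as.numeric(d_dpca), as.numeric(d_marg))), 0.9)

  # too small k degrades demixing when label subspaces overlap: a small
  # population with 3 latents per label leaves unmodelled directions that
  # the k = 1 pseudo-inverse decoders cannot cancel
  sim3 <- generate_population(N = 10, S = 4, Q = 3, T_ = 15, K = 5,
                              n_latents = c(t = 3, st = 3, dt = 3, sdt = 3),
                              snr = 5, seed = 72)
  ps3 <- compute_psths(sim3$data, center = TRUE)
  ms3 <- marginalize(ps3)
  dmx <- function(k) {
    bm <- suppressWarnings(marg_pca_pinv(ms3, k = k))
    mean(demixing_index(bm$D[bm$labels == "st", ], ms3))
  }
  expect_gt(dmx(3), dmx(1))
})

test_that("TDR aligns with dPCA on single-parameter data and is orthonormal", {
  sim <- generate_population(N = 30, S = 4, Q = 2, T_ = 15, K = 3,
                             n_latents = c(st = 1), noise_sd = 0.05,
                             snr = 50, seed = 81)
  ps <- compute_psths(sim$data, center = TRUE)
  # stimulus modulation in the generator is arbitrary; use a linear code
  td <- suppressWarnings(tdr(ps, stim_values = 1:4, dec_values = c(-1, 1),
                             n_pcs = 10))
  expect_lt(max(abs(crossprod(td$F) - diag(4))), 1e-8)
  fit <- suppressWarnings(dpca_fit(ps, q = 1))
  stim_axis <- td$F[, which(td$labels == "s")]
  dpca_axis <- fit$F$st[, 1]
  # generator stimulus modulators are random, not monotone in the code;
  # compare against the axis TDR was allowed to see
  expect_gt(abs(sum(stim_axis * dpca_axis)), 0.5)
})

test_that("TDR depends on the stacking order when betas are oblique", {
  sim <- generate_population(N = 20, S = 3, Q = 2, T_ = 12, K = 4,
                             snr = 3, seed = 83)
  ps <- compute_psths(sim$data, center = TRUE)
  t1 <- tdr(ps, 1:3, c(-1, 1), n_pcs = 10, order = c("s", "d", "sd"))
  t2 <- tdr(ps, 1:3, c(-1, 1), n_pcs = 10, order = c("sd", "d", "s"))
  a1 <- t1$F[, which(t1$labels == "d")]
  a2 <- t2$F[, which(t2$labels == "d")]
  expect_lt(abs(sum(a1 * a2)), 1 - 1e-6)
  expect_error(tdr(ps, rep(1, 3), c(-1, 1)), "collinear")
})

test_that("TDR demixes no better than dPCA on mixed data", {
  dmx_mean <- numeric(0)
  for (seed in c(91, 92, 93)) {
    sim <- generate_population(N = 30, S = 3, Q = 2, T_ = 15, K = 4,
                               snr = 2, seed = seed)
    ps <- compute_psths(sim$data, center = TRUE)
    ms <- marginalize(ps)
    fit <- dpca_fit(ps, q = 1)
    td <- tdr(ps, 1:3, c(-1, 1), n_pcs = 10)
    d_dpca <- mean(c(demixing_index(fit$D$st[1, ], ms),
                     demixing_index(fit$D$dt[1, ], ms),
                     demixing_index(fit$D$sdt[1, ], ms)))
    d_tdr <- mean(c(demixing_index(td$F[, td$labels == "s"], ms),
                    demixing_index(td$F[, td$labels == "d"], ms),
                    demixing_index(td$F[, td$labels == "sd"], ms)))
    dmx_mean <- c(dmx_mean, d_dpca - d_tdr)
  }
  expect_gt(mean(dmx_mean), 0)
})

test_that("factorial LDA recovers the mean-difference axis for isotropic
           classes and is rotation invariant", {
  N <- 6
  m <- rnorm(N); m <- m / sqrt(sum(m^2))
  covs <- structure(list(
    total = m %o% m * 4 + diag(N),
    marg = list(a = m %o% m * 4, b = diag(N)),
    noise = NULL, denom = 1), class = "covariance_set")
  lda <- factorial_lda(covs, "a", 1)
  expect_gt(abs(sum(lda$D[1, ] * m)), 1 - 1e-8)

  set.seed(21)
  ps <- random_psth(N = 5, seed = 22)
  cv1 <- marginalized_covariances(marginalize(ps))
  R <- qr.Q(qr(matrix(rnorm(25), 5)))
  vrot <- array(apply(matrix(ps$values, 5), 2, function(col) R %*% col),
                dim = dim(ps$values))
  cv2 <- marginalized_covariances(marginalize(center_psth(
    psth_tensor(vrot))))
  e1 <- factorial_lda(cv1, "st", 3)$values
  e2 <- factorial_lda(cv2, "st", 3)$values
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("difference-of-covariances reduces to PCA when one side is zero", {
  ps <- random_psth(N = 5, seed = 41)
  cs <- marginalized_covariances(marginalize(ps))
  cs0 <- cs
  cs0$marg$t <- cs$marg$t * 0
  dv <- doc_axes(cs0, c("st", "t"))
  e <- eigen(cs$marg$st, symmetric = TRUE)
  expect_equal(abs(diag(crossprod(dv$F[, 1:2], e$vectors[, 1:2]))),
               c(1, 1), tolerance = 1e-8)
  swapped <- doc_axes(cs0, c("t", "st"))
  expect_equal(sort(swapped$values), sort(-dv$values), tolerance = 1e-10)
})

test_that("DOC demixes worse than dPCA when label subspaces are oblique", {
  sim <- generate_population(N = 20, S = 3, Q = 2, T_ = 12, K = 4,
                             snr = 3, seed = 95)
  ps <- compute_psths(sim$data, center = TRUE)
  ms <- marginalize(ps)
  cs <- marginalized_covariances(ms)
  fit <- dpca_fit(ps, q = 1)
  dv <- doc_axes(cs, c("st", "dt"))
  top_st <- dv$F[, which(dv$labels == "st")[1]]
  expect_gte(demixing_index(fit$D$st[1, ], ms),
             demixing_index(top_st, ms) - 0.05)
})

test_that("null data yields about the nominal ANOVA false-positive rate", {
  tt <- random_trial_tensor(N = 60, S = 2, Q = 2, T_ = 6, K = 6, seed = 51)
  ct <- classical_tuning(tt)
  for (e in c("s", "d", "sd")) {
    frac <- mean(ct$p[, , e] < 0.05)
    expect_gt(frac, 0.01)
    expect_lt(frac, 0.10)
  }
})

test_that("signed effect size approaches signed R2 in the t-test limit", {
  set.seed(52)
  N_tr <- 2000
  vals <- array(NA_real_, dim = c(1, 2, 2, 1, N_tr))
  eff <- c(-0.5, 0.5)
  for (s in 1:2) for (qd in 1:2)
    vals[1, s, qd, 1, ] <- eff[s] + rnorm(N_tr)
  tt <- trial_tensor(vals, N_tr)
  ct <- classical_tuning(tt)
  # direct R2 between rate and stimulus level
  scode <- c(rep(1, N_tr), rep(2, N_tr), rep(1, N_tr), rep(2, N_tr))
  y <- c(vals[1, 1, 1, 1, ], vals[1, 2, 1, 1, ],
         vals[1, 1, 2, 1, ], vals[1, 2, 2, 1, ])
  r2 <- cor(y, scode)^2
  expect_lt(abs(ct$omega2[1, 1, "s"] - r2), 0.01)
  expect_gt(ct$omega2[1, 1, "s"], 0)
  neg <- classical_tuning(trial_tensor(-vals, N_tr))
  expect_lt(neg$omega2[1, 1, "s"], 0)
})

test_that("identical stimulus-tuned neurons average to their own PSTH", {
  S <- 3; T_ <- 4; K <- 4
  base <- array(rnorm(S * T_), dim = c(S, T_))
  vals <- array(NA_real_, dim = c(5, S, 2, T_, K))
  set.seed(53)
  noise <- array(rnorm(S * 2 * T_ * K, sd = 0.01), dim = c(S, 2, T_, K))
  for (n in 1:5) for (s in 1:S) for (qd in 1:2) for (k in 1:K)
    vals[n, s, qd, , k] <- 10 * base[s, ] + noise[s, qd, , k]
  tt <- trial_tensor(vals, K)
  ct <- classical_tuning(tt)
  pc <- ct$population_component("s", 1)
  # identical neurons share one (arbitrary) effect sign
  sgn <- sign(pc$weights[1])
  expect_equal(pc$weights, rep(sgn * 0.2, 5))
  psth1 <- compute_psths(tt, center = TRUE)$values[1, , , ]
  expect_equal(pc$component, sgn * psth1, tolerance = 1e-12)
})

test_that("demixing quality orders dPCA above the stacked-PCA baseline", {
  diffs <- numeric(0)
  for (seed in c(96, 97)) {
    sim <- generate_population(N = 30, S = 3, Q = 2, T_ = 12, K = 4,
                               snr = 2, seed = seed)
    ps <- compute_psths(sim$data, center = TRUE)
    ms <- marginalize(ps)
    fit <- dpca_fit(ps, q = 2)
    bm <- suppressWarnings(marg_pca_pinv(ms, k = 2))
    d_dpca <- mean(unlist(lapply(names(fit$D), function(l)
      demixing_index(fit$D[[l]], ms))))
    d_marg <- mean(demixing_index(bm$D, ms))
    diffs <- c(diffs, d_dpca - d_marg)
  }
  expect_gt(mean(diffs), -0.02)
})
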