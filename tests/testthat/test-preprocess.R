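test_that("Gaussian smoothing conserves spike mass away from edges", {
  trials <- list(
    list(neuron = 1, stimulus = 1, decision = 1, spikes = numeric(0),
         events = c(0, 2), window = c(0, 2)),
    list(neuron = 1, stimulus = 1, decision = 1, spikes = 1.0,
         events = c(0, 2), window = c(0, 2)),
    list(neuron = 1, stimulus = 1, decision = 1, spikes = c(0.6, 1.0, 1.4),
         events = c(0, 2), window = c(0, 2)))
  tt <- smooth_spike_trains(spike_train_set(trials))
  expect_equal(dim(tt$values)[4], 200)          # 2 s at 100 Hz
  expect_true(all(tt$values[1, 1, 1, , 1] == 0))
  i1 <- trapz(tt$time, tt$values[1, 1, 1, , 2])
  expect_equal(i1, 1.0, tolerance = 1e-3)
  i3 <- trapz(tt$time, tt$values[1, 1, 1, , 3])
  expect_equal(i3, 3.0, tolerance = 1e-2)
})

test_that("smoothing rejects bad configurations and bad spikes", {
  trials <- list(list(neuron = 1, stimulus = 1, decision = 1,
                      spikes = 0.5, events = c(0, 1), window = c(0, 1)))
  sts <- spike_train_set(trials)
  expect_error(smooth_spike_trains(sts, window = c(0.5, 0.5)), "empty")
  expect_error(smooth_spike_trains(sts, sigma_ms = 0), "sigma")
  bad <- trials
  bad[[1]]$spikes <- 2.0
  expect_error(spike_train_set(bad), "outside the trial window")
})

test_that("identity warp reproduces the input on the grid", {
  times <- seq(0, 1, by = 0.01)
  trace <- sin(2 * pi * times)
  w <- warp_trial(trace, times, c(0, 0.5, 1), c(0, 0.5, 1),
                  out_times = times)
  expect_lt(max(abs(w$values - trace)), 1e-12)
})

test_that("uniform stretch maps a ramp to half slope", {
  times <- seq(0, 1, by = 0.01)
  w <- warp_trial(times, times, c(0, 1), c(0, 2))
  expect_lt(max(abs(w$values - w$times / 2)), 1e-12)
})

test_that("piecewise warp has segment slopes equal to length ratios", {
  times <- seq(0, 1, by = 0.001)
  w <- warp_trial(times, times, c(0, 0.4, 1), c(0, 0.5, 1))
  # on [0, 0.5]: slope 0.4/0.5; on [0.5, 1]: slope 0.6/0.5
  expected <- ifelse(w$times <= 0.5, 0.8 * w$times,
                     0.4 + 1.2 * (w$times - 0.5))
  expect_lt(max(abs(w$values - expected)), 1e-9)
  expect_error(warp_trial(times, times, c(0, 0.4, 0.4), c(0, 0.5, 1)),
               "strictly increasing")
})

test_that("reference events use medians, reward over correct trials only", {
  mk <- function(ev, correct = TRUE)
    list(neuron = 1, stimulus = 1, decision = 1, spikes = numeric(0),
         events = ev, window = c(-1, 5), correct = correct)
  sts <- spike_train_set(list(
    mk(c(0, 1.0, 2.0, 2.5)), mk(c(0, 1.2, 2.2, 2.6)),
    mk(c(0, 2.0, 2.1, NA), correct = FALSE)))
  ref <- reference_events_from_medians(sts, reward_wait_floor = 0.3)
  expect_equal(ref$reference[1], 0)
  expect_equal(ref$reference[2], 1.2)           # median of {1.0, 1.2, 2.0}
  expect_equal(ref$reference[4], 2.55)          # correct trials only
  expect_equal(ref$events[3, 4], 2.1 + 0.3)     # synthetic reward event
  all_err <- spike_train_set(list(mk(c(0, 1, 2, NA), correct = FALSE)))
  expect_error(reference_events_from_medians(all_err, 0.3), "no correct")
})

test_that("PSTHs average trials and centering removes neuron means", {
  vals <- array(NA_real_, dim = c(1, 1, 1, 2, 2))
  vals[1, 1, 1, , 1] <- c(2, 2)
  vals[1, 1, 1, , 2] <- c(4, 4)
  tt <- trial_tensor(vals, 2)
  expect_equal(as.numeric(compute_psths(tt)$values), c(3, 3))
  tt2 <- random_trial_tensor(N = 5, seed = 3)
  ps <- compute_psths(tt2, center = TRUE)
  expect_lt(max(abs(apply(ps$values, 1, mean))), 1e-12)
  one <- trial_tensor(tt2$values[, , , , 1, drop = FALSE],
                      counts = 1)
  expect_equal(compute_psths(one)$values[, , , ],
               tt2$values[, , , , 1])
})

test_that("rebalanced noise variance is the unweighted condition mean", {
  # one neuron, two conditions with population variances 1 and 3
  vals <- array(NA_real_, dim = c(1, 2, 1, 2, 2))
  for (t in 1:2) {
    vals[1, 1, 1, t, ] <- c(-1, 1)            # var (denominator K) = 1
    vals[1, 2, 1, t, ] <- c(-sqrt(3), sqrt(3)) # var = 3
  }
  tt <- trial_tensor(vals, 2)
  nc <- estimate_noise_covariance(tt)
  expect_equal(as.numeric(nc$values), 2)
  expect_equal(as.numeric(nc$K_tilde), 2)
})

test_that("rebalanced noise covariance ignores trial-count replication", {
  tt <- random_trial_tensor(N = 3, S = 2, Q = 2, T_ = 4, K = 3, seed = 9)
  nc1 <- estimate_noise_covariance(tt)
  # replicate all trials of condition (1,1) three times
  d <- dim(tt$values)
  vals <- array(NA_real_, dim = c(d[1:4], 9))
  vals[, , , , 1:3] <- tt$values
  for (r in 1:2)
    vals[, 1, 1, , 3 * r + 1:3] <- tt$values[, 1, 1, , 1:3]
  counts <- tt$counts
  counts[, 1, 1] <- 9L
  nc2 <- estimate_noise_covariance(trial_tensor(vals, counts))
  expect_equal(nc1$values, nc2$values)
})

test_that("full noise covariance requires shared trials across neurons", {
  tt <- random_trial_tensor(N = 2, S = 2, Q = 1, T_ = 3, K = 4, seed = 4)
  counts <- tt$counts
  counts[1, 1, 1] <- 3L
  vals <- tt$values
  vals[1, 1, 1, , 4] <- NA_real_
  seqrec <- trial_tensor(vals, counts)
  expect_error(estimate_noise_covariance(seqrec, mode = "full"),
               "diagonal")
  full <- estimate_noise_covariance(tt, mode = "full")
  diag_ <- estimate_noise_covariance(tt, mode = "diagonal")
  expect_equal(diag(full$values), diag_$values)
  expect_true(isSymmetric(full$values))
})

test_that("trial tensors validate counts and finiteness", {
  vals <- array(0, dim = c(1, 1, 1, 2, 2))
  expect_error(trial_tensor(vals, 3), "exceed")
  expect_error(trial_tensor(vals, 0), "at least one trial")
  vals[1, 1, 1, 1, 2] <- NA
  expect_error(trial_tensor(vals, 2), "non-finite")
})
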