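#' Spike-train collection for a factorial task
#'
#' Raw input container: one entry per trial of one neuron, holding spike
#' times, alignment-event times and the trial window. Neurons may be
#' recorded sequentially; trials are grouped by
#' `(neuron, stimulus, decision)` when converted to a [trial_tensor()].
#'
#' @param trials list of trials; each trial is a list with elements
#'   `neuron`, `stimulus`, `decision` (1-based integer indices), `spikes`
#'   (numeric spike times in s), `events` (non-decreasing alignment-event
#'   times in s; `NA` allowed for events that did not occur, e.g. reward on
#'   error trials), `window` (length-2 start/end in s) and optionally
#'   `correct` (logical, default `TRUE`).
#' @return object of class `spike_train_set`.
#' @export
spike_train_set <- function(trials) {
  stopifnot(is.list(trials), length(trials) > 0L)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    for (f in c("neuron", "stimulus", "decision", "spikes", "events", "window"))
      if (is.null(tr[[f]])) stop("trial ", i, " is missing field `", f, "`")
    if (length(tr$window) != 2L || tr$window[1] >= tr$window[2])
      stop("trial ", i, ": invalid window")
    if (length(tr$spikes) &&
        (min(tr$spikes) < tr$window[1] || max(tr$spikes) > tr$window[2]))
      stop("trial ", i, " (neuron ", tr$neuron,
           "): spike times outside the trial window")
    ev <- tr$events[!is.na(tr$events)]
    if (is.unsorted(ev))
      stop("trial ", i, " (neuron ", tr$neuron,
           "): event times must be non-decreasing")
    if (is.null(tr$correct)) trials[[i]]$correct <- TRUE
  }
  structure(list(trials = trials), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$trials, function(t) t$neuron, 1)
  cat(sprintf("spike_train_set: %d trials, %d neurons\n",
              length(x$trials), length(unique(n))))
  invisible(x)
}

# Gaussian filter of one spike train, truncated at +/- 4 sigma; edge bins
# are not renormalized, so mass of spikes near the window edge is lost.
.smooth_one <- function(spikes, grid, sigma) {
  out <- numeric(length(grid))
  for (sp in spikes) {
    idx <- which(abs(grid - sp) <= 4 * sigma)
    if (length(idx))
      out[idx] <- out[idx] + stats::dnorm(grid[idx], mean = sp, sd = sigma)
  }
  out
}

#' Smooth spike trains into single-trial firing rates
#'
#' Convolves each trial's spike train with a Gaussian kernel and samples the
#' result on a regular grid, producing instantaneous firing rates in
#' spikes/s. The kernel is truncated at four standard deviations; bins near
#' the window edges are not renormalized.
#'
#' @param spikes a [spike_train_set()].
#' @param sigma_ms kernel standard deviation in milliseconds (default 50).
#' @param rate_hz sampling rate of the output grid in Hz (default 100).
#' @param window length-2 time window (s) defining the grid; defaults to
#'   the intersection of all trial windows. Bins are placed at bin centers.
#' @return a [trial_tensor()] of rates, `N x S x Q x T x Kmax`.
#' @export
smooth_spike_trains <- function(spikes, sigma_ms = 50, rate_hz = 100,
                                window = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (sigma_ms <= 0) stop("`sigma_ms` must be positive")
  if (rate_hz <= 0) stop("`rate_hz` must be positive")
  trs <- spikes$trials
  if (is.null(window)) {
    window <- c(max(vapply(trs, function(t) t$window[1], 1)),
                min(vapply(trs, function(t) t$window[2], 1)))
  }
  nbin <- floor((window[2] - window[1]) * rate_hz + 1e-9)
  if (nbin < 1L) stop("requested time grid is empty")
  dt <- 1 / rate_hz
  grid <- window[1] + (seq_len(nbin) - 0.5) * dt
  for (i in seq_along(trs))
    if (trs[[i]]$window[1] > window[1] + 1e-12 ||
        trs[[i]]$window[2] < window[2] - 1e-12)
      stop("trial ", i, " does not cover the requested time grid")
  sigma <- sigma_ms / 1000

  n_id <- vapply(trs, function(t) t$neuron, 1)
  s_id <- vapply(trs, function(t) t$stimulus, 1)
  d_id <- vapply(trs, function(t) t$decision, 1)
  N <- max(n_id); S <- max(s_id); Q <- max(d_id)
  counts <- array(0L, dim = c(N, S, Q))
  for (i in seq_along(trs))
    counts[n_id[i], s_id[i], d_id[i]] <- counts[n_id[i], s_id[i], d_id[i]] + 1L
  if (any(counts == 0L))
    stop("every (neuron, stimulus, decision) combination must have >= 1 trial")
  Kmax <- max(counts)
  vals <- array(NA_real_, dim = c(N, S, Q, nbin, Kmax))
  kseen <- array(0L, dim = c(N, S, Q))
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    k <- kseen[tr$neuron, tr$stimulus, tr$decision] + 1L
    kseen[tr$neuron, tr$stimulus, tr$decision] <- k
    vals[tr$neuron, tr$stimulus, tr$decision, , k] <-
      .smooth_one(tr$spikes, grid, sigma)
  }
  trial_tensor(vals, counts, time = grid)
}

#' Piecewise-linear time warping of one firing-rate trace
#'
#' Linearly maps each inter-event segment `[t_i, t_{i+1}]` of a trial onto
#' the corresponding reference segment `[T_i, T_{i+1}]` and resamples the
#' trace by linear interpolation, so that self-paced trials of different
#' durations become alignable and averageable. The output value at each
#' reference event equals the input value at the trial event.
#'
#' @param trace numeric firing-rate samples.
#' @param times sample times of `trace` (s), covering `[t_1, t_E]`.
#' @param trial_events strictly increasing event times of this trial (s).
#' @param reference_events strictly increasing reference event times (s),
#'   same length as `trial_events`.
#' @param out_times output grid on `[T_1, T_E]`; defaults to a uniform grid
#'   with the input sampling step.
#' @return list with `values` (warped trace) and `times` (the output grid).
#' @export
warp_trial <- function(trace, times, trial_events, reference_events,
                       out_times = NULL) {
  E <- length(trial_events)
  if (E < 2L || length(reference_events) != E)
    stop("need >= 2 alignment events, trial and reference of equal length")
  if (any(diff(trial_events) <= 0))
    stop("trial events must be strictly increasing (degenerate stretch)")
  if (any(diff(reference_events) <= 0))
    stop("reference events must be strictly increasing (degenerate stretch)")
  if (min(times) > trial_events[1] + 1e-12 ||
      max(times) < trial_events[E] - 1e-12)
    stop("trace does not cover the trial events")
  if (is.null(out_times)) {
    step <- stats::median(diff(times))
    out_times <- seq(reference_events[1], reference_events[E], by = step)
  }
  seg <- findInterval(out_times, reference_events,
                      rightmost.closed = TRUE, all.inside = TRUE)
  frac <- (out_times - reference_events[seg]) /
    (reference_events[seg + 1L] - reference_events[seg])
  src <- trial_events[seg] + frac * (trial_events[seg + 1L] - trial_events[seg])
  vals <- stats::approx(times, trace, xout = src, rule = 2)$y
  list(values = vals, times = out_times)
}

#' Reference event times from per-trial medians
#'
#' Aligns all trials on the first event (t = 0) and computes the median time
#' of each later event across trials; the reward event's median is taken
#' over correct trials only. Error trials lacking the reward event get a
#' synthetic one at the preceding event plus the experiment's minimal
#' reward-wait time.
#'
#' @param spikes a [spike_train_set()].
#' @param reward_wait_floor minimal wait between the pre-reward event and
#'   reward delivery (s), used to synthesize the reward event on error
#'   trials.
#' @param reward_event index of the reward event within the event vector.
#' @return list with `reference` (event times, first = 0) and `events`
#'   (matrix of per-trial event times relative to the first event, with
#'   synthetic reward events filled in).
#' @export
reference_events_from_medians <- function(spikes, reward_wait_floor,
                                          reward_event = 4L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  trs <- spikes$trials
  E <- length(trs[[1]]$events)
  ev <- t(vapply(trs, function(t) as.numeric(t$events), numeric(E)))
  ev <- ev - ev[, 1L]                      # first event defines t = 0
  correct <- vapply(trs, function(t) isTRUE(t$correct), TRUE)
  missing_rw <- is.na(ev[, reward_event])
  if (!any(correct & !missing_rw))
    stop("no correct trials with a reward event: reward median undefined")
  ref <- numeric(E)
  for (j in 2:E) {
    if (j == reward_event)
      ref[j] <- stats::median(ev[correct & !missing_rw, j])
    else
      ref[j] <- stats::median(ev[, j], na.rm = TRUE)
  }
  ev[missing_rw, reward_event] <-
    ev[missing_rw, reward_event - 1L] + reward_wait_floor
  list(reference = ref, events = ev)
}

#' Trial-averaged PSTHs from a trial tensor
#'
#' Averages the available trials of every `(neuron, stimulus, decision)`
#' cell; optionally removes each neuron's grand mean (centering), recording
#' the removed means.
#'
#' @param data a [trial_tensor()].
#' @param center logical; subtract per-neuron grand means.
#' @return a [psth_tensor()].
#' @export
compute_psths <- function(data, center = FALSE) {
  stopifnot(inherits(data, "trial_tensor"))
  d <- dim(data$values)
  m <- matrix(data$values, nrow = prod(d[1:4]), ncol = d[5])
  npres <- rowSums(!is.na(m))
  if (any(npres == 0L)) {
    bad <- which(array(npres, dim = d[1:4]) == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("no trials for neuron %d, stimulus %d, decision %d",
                 bad[1], bad[2], bad[3]))
  }
  avg <- array(rowSums(m, na.rm = TRUE) / npres, dim = d[1:4])
  out <- psth_tensor(avg, time = data$time)
  if (center) out <- center_psth(out)
  out
}

#' Noise covariance of trial-to-trial fluctuations
#'
#' Estimates the covariance of single-trial residuals around the condition
#' PSTH. With `rebalanced = TRUE` the per-`(stimulus, decision, time)`
#' covariances are averaged with equal weight, so that conditions with many
#' trials do not dominate; otherwise residuals are pooled (weighted by
#' trial counts). Sequentially recorded populations have no shared trials,
#' so only `mode = "diagonal"` (per-neuron noise variances) is meaningful
#' for them. All (co)variances use the trial count `K` as denominator, the
#' same convention as the data covariances.
#'
#' @param data a [trial_tensor()].
#' @param mode `"diagonal"` (default) or `"full"`.
#' @param rebalanced logical; equal-weight average over conditions.
#' @return object of class `noise_covariance`: `values` (length-`N` vector
#'   of variances, or `N x N` matrix), `mode`, `rebalanced`, and `K_tilde`
#'   (per-neuron mean trial count over conditions).
#' @export
estimate_noise_covariance <- function(data, mode = c("diagonal", "full"),
                                      rebalanced = TRUE) {
  stopifnot(inherits(data, "trial_tensor"))
  mode <- match.arg(mode)
  d <- dim(data$values)
  N <- d[1]; S <- d[2]; Q <- d[3]; T_ <- d[4]; K <- d[5]
  psth <- compute_psths(data)$values
  res <- data$values - array(rep(psth, K), dim = d)
  K_tilde <- apply(data$counts, 1, mean)

  if (mode == "diagonal") {
    ss <- array(rowSums(matrix(res^2, prod(d[1:4]), K), na.rm = TRUE),
                dim = d[1:4])
    cnt <- array(rep(data$counts, T_), dim = d[1:4])
    v <- ss / cnt                                   # per (n,s,d,t) variance
    if (rebalanced) vals <- apply(v, 1, mean)
    else vals <- apply(ss, 1, sum) / apply(cnt, 1, sum)
  } else {
    same <- apply(data$counts, c(2, 3), function(z) length(unique(z)) == 1L)
    if (!all(same))
      stop("`mode = \"full\"` needs shared trials across neurons ",
           "(simultaneous recording); use mode = \"diagonal\" for ",
           "sequentially recorded data")
    acc <- matrix(0, N, N)
    wsum <- 0
    for (s in seq_len(S)) for (q in seq_len(Q)) {
      k_sd <- data$counts[1, s, q]
      for (t in seq_len(T_)) {
        R <- matrix(res[, s, q, t, seq_len(k_sd)], nrow = N)
        Csdt <- R %*% t(R) / k_sd
        if (rebalanced) { acc <- acc + Csdt; wsum <- wsum + 1 }
        else { acc <- acc + Csdt * k_sd; wsum <- wsum + k_sd }
      }
    }
    vals <- acc / wsum
  }
  structure(list(values = vals, mode = mode, rebalanced = rebalanced,
                 K_tilde = K_tilde),
            class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("noise_covariance: %s%s, %d neurons\n", x$mode,
              if (x$rebalanced) " (re-balanced)" else "",
              length(x$K_tilde)))
  invisible(x)
}

# noise covariance as an N x N matrix
noise_matrix <- function(noise) {
  if (is.null(noise)) return(NULL)
  stopifnot(inherits(noise, "noise_covariance"))
  if (is.matrix(noise$values)) noise$values else diag(noise$values)
}
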