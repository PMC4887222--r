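# latent time-course primitives: smooth Gaussian bumps and ramps over the
# time axis, mimicking the morphology of typical PSTH components
.base_waveform <- function(T_, kind = c("bump", "ramp")) {
  kind <- match.arg(kind)
  tt <- seq(0, 1, length.out = T_)
  if (kind == "bump") {
    c0 <- stats::runif(1, 0.25, 0.75)
    w0 <- stats::runif(1, 0.08, 0.2)
    exp(-(tt - c0)^2 / (2 * w0^2))
  } else {
    slope <- sample(c(-1, 1), 1)
    slope * tt
  }
}

# condition modulators that respect the zero-mean structure of each label
.modulator <- function(S, Q, label) {
  if (label == "t") return(matrix(1, S, Q))
  if (label == "st") {
    c_s <- stats::rnorm(S); c_s <- c_s - mean(c_s)
    if (max(abs(c_s)) == 0) c_s <- seq_len(S) - mean(seq_len(S))
    return(matrix(c_s, S, Q))
  }
  if (label == "dt") {
    c_d <- stats::rnorm(Q); c_d <- c_d - mean(c_d)
    if (max(abs(c_d)) == 0) c_d <- seq_len(Q) - mean(seq_len(Q))
    return(matrix(c_d, S, Q, byrow = TRUE))
  }
  M <- matrix(stats::rnorm(S * Q), S, Q)
  sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M) - mean(M))
}

#' Simulate a neural population with known demixed structure
#'
#' Generates trial-resolved firing rates as a sum of ground-truth latent
#' components — one or more per marginalization (condition-independent,
#' stimulus, decision, interaction) — mapped into the population through
#' random unit-norm encoder weights, plus i.i.d. Gaussian noise on every
#' trial. Each latent is a smooth time course (Gaussian bump or ramp)
#' modulated across conditions so that it lies exactly in its
#' marginalization: with zero noise, [marginalize()] recovers every label
#' tensor exactly.
#'
#' Latent amplitudes are set from the signal-to-noise ratio `snr`, defined
#' as total latent variance divided by total noise variance remaining in
#' the PSTH after averaging `K` trials.
#'
#' @param N,S,Q,T_ numbers of neurons, stimuli, decisions, time bins.
#' @param K trials per condition: scalar or `N x S x Q` array.
#' @param n_latents named integer vector: latents per marginalization.
#' @param snr signal-to-noise ratio of the PSTH (default 1).
#' @param noise_sd single-trial noise standard deviation (default 1);
#'   `0` gives noiseless data with unit latent amplitudes.
#' @param seed optional integer seed (generation is bit-reproducible).
#' @return list with `data` (a [trial_tensor()]) and `truth` (class
#'   `dpca_ground_truth`): latent arrays per label, encoder `weights`
#'   (`N x J`), `amplitudes`, `noise_sd`, `snr`, `seed`.
#' @export
generate_population <- function(N = 100, S = 4, Q = 2, T_ = 50, K = 10,
                                n_latents = c(t = 1, st = 1, dt = 1, sdt = 1),
                                snr = 1, noise_sd = 1, seed = NULL) {
  stopifnot(N >= 1, S >= 1, Q >= 1, T_ >= 1, noise_sd >= 0)
  with_seed(seed, {
    counts <- if (length(K) == 1L) array(as.integer(K), dim = c(N, S, Q))
              else array(as.integer(K), dim = c(N, S, Q))
    Kmax <- max(counts)
    J <- sum(n_latents)
    amp <- if (noise_sd == 0) 1
           else sqrt(snr * noise_sd^2 * N / (mean(counts) * J))

    latents <- list()
    Wl <- matrix(0, N, 0)
    signal <- array(0, dim = c(N, S, Q, T_))
    for (lab in names(n_latents)) {
      for (j in seq_len(n_latents[[lab]])) {
        kind <- if (stats::runif(1) < 0.7) "bump" else "ramp"
        w <- .base_waveform(T_, kind)
        if (lab == "t") w <- w - mean(w)
        m <- .modulator(S, Q, lab)
        z <- outer(m, w)                            # S x Q x T
        z <- z / sqrt(mean(z^2))
        wvec <- stats::rnorm(N)
        wvec <- wvec / sqrt(sum(wvec^2))
        latents[[length(latents) + 1L]] <- list(label = lab, z = amp * z)
        Wl <- cbind(Wl, wvec)
        signal <- signal + amp * outer(wvec, z)
      }
    }
    vals <- array(NA_real_, dim = c(N, S, Q, T_, Kmax))
    for (k in seq_len(Kmax)) {
      present <- counts >= k
      eps <- array(stats::rnorm(N * S * Q * T_, sd = noise_sd),
                   dim = c(N, S, Q, T_))
      slab <- signal + eps
      mask <- array(rep(present, T_), dim = c(N, S, Q, T_))
      slab[!mask] <- NA_real_
      vals[, , , , k] <- slab
    }
    truth <- structure(list(latents = latents, weights = Wl,
                            amplitudes = rep(amp, J), noise_sd = noise_sd,
                            snr = snr, counts = counts, seed = seed),
                       class = "dpca_ground_truth")
    list(data = trial_tensor(vals, counts), truth = truth)
  })
}

#' @export
print.dpca_ground_truth <- function(x, ...) {
  labs <- vapply(x$latents, function(l) l$label, "")
  cat(sprintf("dpca_ground_truth: %d latents (%s), noise sd %.3g, snr %.3g\n",
              length(x$latents), paste(labs, collapse = ", "),
              x$noise_sd, x$snr))
  invisible(x)
}

#' Two-neuron unbalanced-design toy
#'
#' Additive two-factor toy: factor A shifts neuron 1, factor B shifts
#' neuron 2, the interaction is zero and the trial noise is uncorrelated
#' across neurons. With equal trial counts the pooled across-trial
#' correlation between the neurons is zero; when the two "congruent"
#' conditions (low/low and high/high) are oversampled, the pooled
#' correlation becomes strongly positive even though nothing about the
#' underlying factors changed — the failure mode that the re-balanced
#' (PSTH-based) formulation avoids.
#'
#' @param K_small,K_large trial counts of the rare and common conditions.
#' @param effect half-distance between the two factor levels.
#' @param noise_sd trial noise standard deviation.
#' @param seed optional integer seed.
#' @return list with `balanced` and `unbalanced` [trial_tensor()]s (2
#'   neurons, 2 x 2 conditions, constant over 2 time bins) and `effects`.
#' @export
generate_unbalanced_toy <- function(K_small = 10, K_large = 100,
                                    effect = 3, noise_sd = 1, seed = NULL) {
  with_seed(seed, {
    a <- c(-effect, effect)            # factor A -> neuron 1
    b <- c(-effect, effect)            # factor B -> neuron 2
    build <- function(counts) {
      Kmax <- max(counts)
      vals <- array(NA_real_, dim = c(2, 2, 2, 2, Kmax))
      for (s in 1:2) for (qd in 1:2) {
        k <- counts[1, s, qd]
        x1 <- a[s] + stats::rnorm(k, sd = noise_sd)
        x2 <- b[qd] + stats::rnorm(k, sd = noise_sd)
        for (t in 1:2) {
          vals[1, s, qd, t, seq_len(k)] <- x1
          vals[2, s, qd, t, seq_len(k)] <- x2
        }
      }
      trial_tensor(vals, counts)
    }
    bal <- array(as.integer(K_large), dim = c(2, 2, 2))
    unb <- array(as.integer(K_small), dim = c(2, 2, 2))
    unb[, 1, 1] <- as.integer(K_large)
    unb[, 2, 2] <- as.integer(K_large)
    list(balanced = build(bal), unbalanced = build(unb),
         effects = list(a = a, b = b, noise_sd = noise_sd))
  })
}

#' Population with per-neuron temporal jitter
#'
#' Every neuron expresses the same Gaussian-bump time course, scaled by a
#' random amplitude and shifted in time by a small random per-neuron offset
#' (as happens when sequentially recorded, self-timed responses are
#' pooled). To first order the population activity is
#' `a z(t) + (a * tau) z'(t)`, so PCA on such data shows the true waveform
#' as the first component and its temporal derivative as a spurious second
#' component. The waveform is evaluated analytically, so shifted bumps
#' never fall off the grid.
#'
#' @param N number of neurons.
#' @param jitter_sd standard deviation of the per-neuron time shifts (s).
#' @param T_ number of time bins on `t_range`.
#' @param t_range time window (s).
#' @param center,width Gaussian bump center and width (s).
#' @param amp_sd standard deviation of the amplitudes around 1.
#' @param seed optional integer seed.
#' @return list with `values` (`N x T` rates), `time`, ground-truth
#'   waveform `z` and derivative `zprime` on the grid, `amplitudes`,
#'   `shifts`.
#' @export
generate_jittered_population <- function(N = 100, jitter_sd = 0.02,
                                         T_ = 100, t_range = c(0, 1),
                                         center = 0.5, width = 0.1,
                                         amp_sd = 0.3, seed = NULL) {
  with_seed(seed, {
    tt <- seq(t_range[1], t_range[2], length.out = T_)
    a <- 1 + amp_sd * stats::rnorm(N)
    tau <- jitter_sd * stats::rnorm(N)
    z_of <- function(t) exp(-(t - center)^2 / (2 * width^2))
    vals <- t(vapply(seq_len(N),
                     function(n) a[n] * z_of(tt + tau[n]), numeric(T_)))
    z <- z_of(tt)
    zprime <- -(tt - center) / width^2 * z
    list(values = vals, time = tt, z = z, zprime = zprime,
         amplitudes = a, shifts = tau)
  })
}
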