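#' Explained-variance report
#'
#' Computes the fraction of PSTH variance explained,
#' `R^2 = 1 - ||X - F D X||^2 / ||X||^2`, per component, cumulatively over
#' the globally ordered components, and split additively across
#' marginalizations. Alternatively, for an arbitrary component matrix `Z`
#' (components in rows), reconstruction weights are found by linear
#' regression, `B = X Z' (Z Z')^-1`, and `R^2 = 1 - ||X - B Z||^2/||X||^2`.
#'
#' @param x a [dpca_fit()] result, or a numeric matrix of components
#'   (rows = components, columns matching the flattened PSTH).
#' @param psth centered [psth_tensor()] (or array); defaults to the
#'   model's training PSTH.
#' @param mset marginalization set for the per-label split; defaults to the
#'   model's.
#' @return object of class `variance_report`: `components` (data frame with
#'   per-component `expl_var` and one split column per marginalization),
#'   `cumulative` (R^2 of the top-q stacked components vs q), `total_r2`.
#'   For matrix input, a list with `r2` and the weight matrix `B`.
#' @export
explained_variance <- function(x, psth = NULL, mset = NULL) {
  if (is.matrix(x)) {
    if (is.null(psth)) stop("`psth` is required for matrix components")
    Xt <- if (inherits(psth, "psth_tensor")) flatten_mat(psth$values)
          else flatten_mat(psth)
    Z <- x
    G <- Z %*% t(Z)
    pg <- pinv_sym(G)
    if (pg$deficient)
      warning("singular component Gram matrix; using the pseudo-inverse")
    B <- Xt %*% t(Z) %*% pg$inv
    return(list(r2 = 1 - frob2(Xt - B %*% Z) / frob2(Xt), B = B))
  }
  model <- x
  stopifnot(inherits(model, "dpca"))
  if (is.null(psth)) psth <- model$psth
  else if (inherits(psth, "psth_tensor")) psth <- psth$values
  if (is.null(mset)) mset <- model$mset
  Xt <- flatten_mat(psth)
  tot <- frob2(Xt)
  mats <- mset_matrices(mset)
  labs <- names(mats)
  tab <- model$comp
  ncmp <- nrow(tab)

  split <- matrix(0, ncmp, length(labs), dimnames = list(NULL, labs))
  ev <- numeric(ncmp)
  for (i in seq_len(ncmp)) {
    dvec <- model$D[[tab$label[i]]][tab$within[i], , drop = FALSE]
    fvec <- model$F[[tab$label[i]]][, tab$within[i], drop = FALSE]
    ev[i] <- (tot - frob2(Xt - fvec %*% (dvec %*% Xt))) / tot
    for (lab in labs)
      split[i, lab] <- (frob2(mats[[lab]]) -
                        frob2(mats[[lab]] - fvec %*% (dvec %*% mats[[lab]]))) / tot
  }
  cum <- numeric(ncmp)
  for (qi in seq_len(ncmp)) {
    sel <- tab[seq_len(qi), ]
    D <- .stack_D(model, sel)
    Fm <- .stack_F(model, sel)
    cum[qi] <- (tot - frob2(Xt - Fm %*% (D %*% Xt))) / tot
  }
  components <- cbind(tab[, c("comp", "label", "within")],
                      expl_var = ev, as.data.frame(split))
  structure(list(components = components, cumulative = cum,
                 total_r2 = cum[ncmp]),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, n = 10, ...) {
  cat(sprintf("variance_report: %d components, total R2 = %.3f\n",
              nrow(x$components), x$total_r2))
  print(utils::head(x$components, n), digits = 3)
  invisible(x)
}

#' Round shares to integer percentages (largest remainder method)
#'
#' @param x non-negative weights (any scale).
#' @param total integer total (default 100).
#' @return integer vector summing exactly to `total`.
#' @export
largest_remainder <- function(x, total = 100L) {
  if (any(x < 0)) {
    warning("negative shares clipped to zero before rounding")
    x <- pmax(x, 0)
  }
  if (sum(x) == 0) x <- rep(1, length(x))
  p <- x / sum(x) * total
  fl <- floor(p)
  rem <- as.integer(total - sum(fl))
  if (rem > 0) {
    add <- order(p - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

# degrees of freedom of one grouped marginalization:
# each raw subset psi contributes prod over its parameters of (levels - 1)
.marg_dof <- function(grouping, levels) {
  vapply(grouping, function(group)
    sum(vapply(group, function(psi) prod(levels[psi] - 1), 1)), 1)
}

#' Signal variance after subtracting finite-trial noise
#'
#' The PSTHs differ from the true underlying rates because only finitely
#' many trials were averaged. The expected residual noise sum of squares is
#' `Theta = S Q T sum_n C_nn / K_n` (noise variance over mean trial count,
#' summed over neurons and scaled by the number of PSTH bins) and it splits
#' across marginalizations in proportion to their degrees of freedom
#' `K_phi` (which sum to `S Q T - 1`). The signal fraction of the total
#' PSTH variance and a noise-corrected per-marginalization pie (integer
#' percentages, largest-remainder rounding) are derived from it.
#'
#' @param noise an [estimate_noise_covariance()] result (provides the
#'   per-neuron noise variances and mean trial counts).
#' @param mset a [marginalize()] result for the same PSTHs.
#' @return list with `theta`, `theta_phi` (named), `dof` (named `K_phi`),
#'   `signal_fraction`, `pie` (named fractions) and `pie_percent` (named
#'   integers summing to 100).
#' @export
signal_variance <- function(noise, mset) {
  stopifnot(inherits(noise, "noise_covariance"),
            inherits(mset, "marginalization_set"))
  dsz <- dim(mset$tensors[[1]])
  ncond <- prod(dsz[-1])
  cnn <- if (is.matrix(noise$values)) diag(noise$values) else noise$values
  theta <- ncond * sum(cnn / noise$K_tilde)
  levels <- dsz[mset$params]
  names(levels) <- names(mset$params)
  dof <- .marg_dof(mset$grouping, levels)
  theta_phi <- dof / (ncond - 1) * theta
  norms <- vapply(mset$tensors, frob2, 1)
  tot <- sum(norms)
  sf <- 1 - theta / tot
  if (sf < 0) {
    warning("estimated noise exceeds the total PSTH variance; ",
            "signal fraction clipped at 0")
    sf <- 0
  }
  pie <- (norms - theta_phi) / (tot - theta)
  list(theta = theta, theta_phi = theta_phi, dof = dof,
       signal_fraction = sf, pie = pie,
       pie_percent = stats::setNames(largest_remainder(pmax(pie, 0)),
                                     names(pie)))
}

#' Demixing index of decoder axes
#'
#' The demixing index of an axis `d` is the largest fraction of the
#' projected variance that falls into a single marginalization,
#' `max_phi ||d X_phi||^2 / ||d X||^2`. It ranges from `1/L` (variance
#' spread equally over all `L` marginalizations) to 1 (perfectly demixed).
#'
#' @param d decoder axis (length-`N` vector) or matrix of axes in rows.
#' @param mset a [marginalize()] result.
#' @return numeric vector of demixing indices (`NaN`, with a warning, for
#'   axes with zero projected variance).
#' @export
demixing_index <- function(d, mset) {
  stopifnot(inherits(mset, "marginalization_set"))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  mats <- mset_matrices(mset)
  per <- vapply(mats, function(m) rowSums((d %*% m)^2), numeric(nrow(d)))
  if (nrow(d) == 1L) per <- matrix(per, nrow = 1)
  tot <- rowSums(per)
  out <- apply(per, 1, max) / tot
  if (any(tot == 0)) {
    warning("axis with zero projected variance: demixing index undefined")
    out[tot == 0] <- NaN
  }
  out
}

#' Significantly non-orthogonal encoder axis pairs
#'
#' Two random unit axes in `N` dimensions have a dot product with standard
#' deviation about `1/sqrt(N)`; a pair is flagged as significantly
#' non-orthogonal when `|f1 . f2| > z / sqrt(N)` (with `z = 3.3`,
#' corresponding to p < 0.001) and, for robustness against a few outlying
#' neurons, the Kendall rank correlation between the coordinate vectors is
#' also significant at the same level.
#'
#' @param F matrix of unit-norm encoder axes in columns (`N x k`).
#' @param alpha significance level (default 0.001).
#' @param z dot-product threshold multiplier (default 3.3).
#' @return list with `dot` (k x k dot products), `kendall_p` (k x k),
#'   `flagged` (logical k x k), `threshold`.
#' @export
axis_significance <- function(F, alpha = 0.001, z = 3.3) {
  N <- nrow(F)
  k <- ncol(F)
  thr <- z / sqrt(N)
  if (N < 12L)
    warning("with N = ", N, " the dot-product threshold is ",
            signif(thr, 3), "; the test is near-vacuous")
  dot <- crossprod(F)
  kp <- matrix(NA_real_, k, k)
  flagged <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (abs(dot[i, j]) > thr) {
      kp[i, j] <- suppressWarnings(
        stats::cor.test(F[, i], F[, j], method = "kendall")$p.value)
      flagged[i, j] <- kp[i, j] < alpha
    }
  }
  list(dot = dot, kendall_p = kp, flagged = flagged, threshold = thr)
}

#' Shuffle trials between conditions within each neuron
#'
#' Pools all trials of a neuron across conditions, permutes them, and
#' reassigns them so that every per-condition trial count is preserved —
#' the null model for [classification_significance()].
#'
#' @param data a [trial_tensor()].
#' @return a [trial_tensor()] with condition labels destroyed.
#' @export
shuffle_trials <- function(data) {
  stopifnot(inherits(data, "trial_tensor"))
  d <- dim(data$values)
  out <- data$values
  for (n in seq_len(d[1])) {
    pool <- NULL
    for (s in seq_len(d[2])) for (qd in seq_len(d[3])) {
      k <- data$counts[n, s, qd]
      pool <- cbind(pool, matrix(data$values[n, s, qd, , seq_len(k)], d[4]))
    }
    pool <- pool[, sample.int(ncol(pool)), drop = FALSE]
    at <- 0L
    for (s in seq_len(d[2])) for (qd in seq_len(d[3])) {
      k <- data$counts[n, s, qd]
      out[n, s, qd, , seq_len(k)] <- pool[, at + seq_len(k)]
      at <- at + k
    }
    stopifnot(at == ncol(pool))
  }
  trial_tensor(out, data$counts, time = data$time)
}

# mean time-resolved decoding accuracy over n_cv stratified splits;
# rows: the first n_comp components of each label in `labels`
.class_accuracy <- function(data, labels, n_comp, n_cv, q, lambda,
                            noise_mode = "diagonal") {
  d <- dim(data$values)
  S <- d[2]; Q <- d[3]; T_ <- d[4]
  acc <- matrix(0, length(labels) * n_comp, T_)
  for (it in seq_len(n_cv)) {
    sp <- split_train_test(data, noise_mode = noise_mode)
    fit <- suppressWarnings(
      dpca_fit(sp$train, noise = sp$noise, q = q, lambda = lambda))
    Xtest <- flatten_mat(sp$test) - fit$means
    row <- 0L
    for (lab in labels) {
      for (j in seq_len(n_comp)) {
        row <- row + 1L
        if (ncol(fit$F[[lab]]) < j) next     # label had too little variance
        dvec <- fit$D[[lab]][j, ]
        str_ <- array(dvec %*% flatten_mat(fit$psth), dim = c(S, Q, T_))
        ste <- array(dvec %*% Xtest, dim = c(S, Q, T_))
        if (lab == "st") {
          cm <- apply(str_, c(1, 3), mean)          # S x T class means
          truth <- rep(seq_len(S), Q)
        } else if (lab == "dt") {
          cm <- apply(str_, c(2, 3), mean)          # Q x T
          truth <- rep(seq_len(Q), each = S)
        } else {
          cm <- matrix(str_, S * Q, T_)             # S*Q x T
          truth <- seq_len(S * Q)
        }
        sc <- matrix(ste, S * Q, T_)
        for (t in seq_len(T_)) {
          assigned <- vapply(sc[, t],
                             function(v) which.min(abs(v - cm[, t])), 1L)
          acc[row, t] <- acc[row, t] + mean(assigned == truth)
        }
      }
    }
  }
  acc / n_cv
}

#' Decoder-based classification significance with shuffle nulls
#'
#' Uses the decoder axes of the leading components in each
#' condition-dependent marginalization as linear classifiers: on every
#' stratified Monte-Carlo split, held-out pseudo-trials are projected onto
#' the decoder and assigned per time bin to the nearest class mean
#' (stimulus components classify the `S` stimuli, decision components the
#' `Q` decisions, interaction components the `S*Q` conditions). The null
#' distribution is obtained by shuffling trials between conditions within
#' each neuron (preserving trial counts) and re-running the full procedure;
#' a time bin is flagged significant only within runs of at least
#' `min_consecutive` bins whose accuracy strictly exceeds all shuffle
#' accuracies.
#'
#' @param data a [trial_tensor()] with >= 2 trials per condition.
#' @param q,lambda dPCA fit settings used on each training split.
#' @param n_cv Monte-Carlo cross-validation iterations (reference
#'   procedure: 100).
#' @param n_shuffles number of trial shuffles for the null (reference
#'   procedure: 100).
#' @param n_comp_per_label leading components tested per marginalization.
#' @param min_consecutive minimal run length of above-null bins.
#' @param labels condition-dependent marginalizations to test.
#' @param seed optional integer seed.
#' @return object of class `significance_report`: `accuracy`
#'   (components x time), `null` (shuffles x components x time), `mask`
#'   (logical components x time), `components` (data frame), `time`.
#' @export
classification_significance <- function(data, q = 10, lambda = 0,
                                        n_cv = 100, n_shuffles = 100,
                                        n_comp_per_label = 3,
                                        min_consecutive = 10,
                                        labels = c("st", "dt", "sdt"),
                                        seed = NULL) {
  stopifnot(inherits(data, "trial_tensor"))
  if (n_cv < 100 || n_shuffles < 100)
    warning("n_cv/n_shuffles below the reference 100/100; ",
            "significance estimates will be less stringent")
  if (n_comp_per_label > q)
    stop("`n_comp_per_label` cannot exceed `q`")
  with_seed(seed, {
    acc <- .class_accuracy(data, labels, n_comp_per_label, n_cv, q, lambda)
    d <- dim(data$values)
    null <- array(NA_real_, dim = c(n_shuffles, nrow(acc), d[4]))
    for (sh in seq_len(n_shuffles)) {
      shuf <- shuffle_trials(data)
      null[sh, , ] <- .class_accuracy(shuf, labels, n_comp_per_label,
                                      n_cv, q, lambda)
    }
    null_max <- apply(null, c(2, 3), max)
    mask <- matrix(FALSE, nrow(acc), d[4])
    for (i in seq_len(nrow(acc))) {
      above <- acc[i, ] > null_max[i, ]
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_consecutive
      for (jj in which(keep)) mask[i, starts[jj]:ends[jj]] <- TRUE
    }
    comps <- data.frame(label = rep(labels, each = n_comp_per_label),
                        within = rep(seq_len(n_comp_per_label),
                                     length(labels)))
    structure(list(accuracy = acc, null = null, mask = mask,
                   components = comps, time = data$time),
              class = "significance_report")
  })
}

#' @export
print.significance_report <- function(x, ...) {
  nsig <- rowSums(x$mask)
  cat("significance_report:\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %s #%d: peak accuracy %.2f, %d significant bins\n",
                x$components$label[i], x$components$within[i],
                max(x$accuracy[i, ]), nsig[i]))
  invisible(x)
}

#' Encoder-weight distributions and density-peaks diagnostics
#'
#' Treats each neuron as a point in the space of its encoder weights on the
#' leading components and computes the two density-peaks clustering
#' statistics: a local density (Gaussian kernel) and, for each point, the
#' minimal distance to a point of higher density (for the global density
#' maximum, the distance to the furthest point). Cluster centres appear as
#' joint outliers in density and distance; a population without neuron
#' subtypes shows exactly one such outlier.
#'
#' @param model a [dpca_fit()] result.
#' @param kernel_var Gaussian kernel variance `sigma^2` (default 0.01).
#' @param n_comp number of leading components whose encoder weights are
#'   used as coordinates (default 15).
#' @return object of class `dpca_weight_diag`: `weights` (neurons x
#'   components), `density`, `delta`, `gamma` (`density * delta` ranking),
#'   `peak` (index of the global density maximum).
#' @export
encoder_weight_diagnostics <- function(model, kernel_var = 0.01,
                                       n_comp = 15) {
  stopifnot(inherits(model, "dpca"))
  if (model$dims[1] < 2L) stop("need at least two neurons")
  tab <- utils::head(model$comp, n_comp)
  W <- .stack_F(model, tab)
  dp <- density_peaks(W, kernel_var = kernel_var)
  structure(list(weights = W, density = dp$density, delta = dp$delta,
                 gamma = dp$gamma, peak = dp$peak),
            class = "dpca_weight_diag")
}

#' Density-peaks statistics of a point cloud
#'
#' For each point, a local density from a Gaussian kernel over pairwise
#' distances and the minimal distance to a point of higher density; the
#' global density maximum gets the distance to the furthest point. Density
#' ties are broken by point index.
#'
#' @param x numeric matrix, one point per row.
#' @param kernel_var Gaussian kernel variance `sigma^2` (default 0.01).
#' @return list with `density`, `delta`, `gamma` (their product) and
#'   `peak` (row index of the density maximum).
#' @export
density_peaks <- function(x, kernel_var = 0.01) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 2L)
  dmat <- as.matrix(stats::dist(x))
  dens <- rowSums(exp(-dmat^2 / (2 * kernel_var))) - 1
  ord <- order(dens, seq_len(n), decreasing = TRUE)
  delta <- numeric(n)
  delta[ord[1]] <- max(dmat[ord[1], ])
  for (i in 2:n)
    delta[ord[i]] <- min(dmat[ord[i], ord[seq_len(i - 1)]])
  list(density = dens, delta = delta, gamma = dens * delta, peak = ord[1])
}

#' @export
print.dpca_weight_diag <- function(x, ...) {
  cat(sprintf("dpca_weight_diag: %d neurons in %d-d weight space\n",
              nrow(x$weights), ncol(x$weights)))
  cat(sprintf("  density peak at neuron %d (delta = %.3f)\n",
              x$peak, x$delta[x$peak]))
  invisible(x)
}
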