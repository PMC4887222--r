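#' @rdname pca_baseline
#' @export
print.dpca_baseline <- function(x, ...) {
  cat(sprintf("baseline model: %s, %d axes\n", x$method, ncol(x$F)))
  invisible(x)
}

.baseline <- function(method, F, D, labels = NULL, extra = list()) {
  structure(c(list(method = method, F = F, D = D, labels = labels), extra),
            class = "dpca_baseline")
}

#' Principal component analysis of the PSTHs
#'
#' Standard PCA on the centered PSTH matrix; encoders and decoders are both
#' given by the stacked leading principal directions.
#'
#' @param psth a centered [psth_tensor()] (auto-centered otherwise).
#' @param q number of principal axes (clamped to the number of neurons).
#' @return a baseline model with `F` (`N x q`), `D` (`q x N`) and the
#'   singular values in `sv`.
#' @export
pca_baseline <- function(psth, q) {
  stopifnot(inherits(psth, "psth_tensor"))
  psth <- center_psth(psth)
  Xt <- flatten_mat(psth$values)
  q <- min(q, nrow(Xt))
  sv <- svd(Xt, nu = q, nv = 0)
  U <- sv$u
  for (j in seq_len(q)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  .baseline("pca", U, t(U), extra = list(sv = sv$d[seq_len(q)]))
}

#' PCA in each marginalization with pseudo-inverse decoders
#'
#' Approximates dPCA by running a separate PCA on every marginalized data
#' matrix: the top `k` principal axes of each marginalization are stacked
#' into an encoder matrix `U` (`N x L k`) and the decoders are the rows of
#' its pseudo-inverse, so that components remain readouts of the full data.
#' Too small `k` gives poor demixing; too large `k` overfits.
#'
#' @param mset a [marginalize()] result.
#' @param k principal axes per marginalization (default 10).
#' @return a baseline model; `labels` maps axes to marginalizations.
#' @export
marg_pca_pinv <- function(mset, k = 10) {
  stopifnot(inherits(mset, "marginalization_set"))
  mats <- mset_matrices(mset)
  N <- nrow(mats[[1]])
  if (length(mats) * k > N)
    warning("more stacked axes than neurons; the pseudo-inverse decoders ",
            "are underdetermined")
  U <- NULL
  labels <- character(0)
  for (lab in names(mats)) {
    kk <- min(k, N)
    u <- svd(mats[[lab]], nu = kk, nv = 0)$u
    for (j in seq_len(kk)) {
      i <- which.max(abs(u[, j]))
      if (u[i, j] < 0) u[, j] <- -u[, j]
    }
    U <- cbind(U, u)
    labels <- c(labels, rep(lab, kk))
  }
  .baseline("marg-pca-pinv", U, MASS::ginv(U), labels = labels,
            extra = list(k = k))
}

#' Targeted dimensionality reduction (regression-subspace method)
#'
#' Regresses every neuron's firing rate, per time point, on the stimulus
#' value, the decision value and their product (plus intercept); the
#' per-parameter regression-coefficient vectors are denoised by projecting
#' onto the leading principal subspace of the PSTHs, the time point with
#' maximal denoised coefficient norm is selected for each parameter (first
#' maximum on plateaus), and the selected vectors are orthogonalized by a
#' QR decomposition in the given stacking order, with the
#' condition-independent vector always last. Yields exactly one axis per
#' parameter.
#'
#' @param psth a [psth_tensor()].
#' @param stim_values numeric parametrization of the stimuli (length `S`).
#' @param dec_values numeric parametrization of the decisions (length `Q`),
#'   e.g. `c(-1, 1)`.
#' @param n_pcs principal axes of the denoising projector (default 20).
#' @param order stacking order of the parameter axes before
#'   orthogonalization; one of `"s"`, `"d"`, `"sd"` each (the result
#'   depends on this order whenever the raw vectors are not orthogonal).
#' @return a baseline model; axes are the columns of the orthonormal `Q`
#'   factor, labelled `order` then `"o"`; `t_star` gives the selected time
#'   points.
#' @export
tdr <- function(psth, stim_values, dec_values, n_pcs = 20,
                order = c("s", "d", "sd")) {
  stopifnot(inherits(psth, "psth_tensor"))
  psth <- center_psth(psth)
  d <- dim(psth$values)
  N <- d[1]; S <- d[2]; Q <- d[3]; T_ <- d[4]
  stopifnot(length(stim_values) == S, length(dec_values) == Q,
            setequal(order, c("s", "d", "sd")))
  des <- cbind(o = 1,
               s = rep(stim_values, Q),
               d = rep(dec_values, each = S))
  des <- cbind(des, sd = des[, "s"] * des[, "d"])
  if (qr(des)$rank < ncol(des))
    stop("collinear regressors: the stimulus/decision parametrization ",
         "does not span an interaction design")
  n_pcs <- min(n_pcs, N)
  U <- svd(flatten_mat(psth$values), nu = n_pcs, nv = 0)$u
  Kp <- U %*% t(U)
  beta <- array(0, dim = c(N, 4, T_), dimnames = list(NULL, colnames(des)))
  for (t in seq_len(T_)) {
    Y <- t(matrix(psth$values[, , , t], N, S * Q))     # (S Q) x N
    beta[, , t] <- t(qr.solve(des, Y))
  }
  kbeta_norm <- matrix(0, 4, T_, dimnames = list(colnames(des)))
  for (t in seq_len(T_))
    kbeta_norm[, t] <- sqrt(colSums((Kp %*% beta[, , t])^2))
  t_star <- apply(kbeta_norm, 1, which.max)            # first maximum
  stack <- c(order, "o")
  B <- vapply(stack, function(p) Kp %*% beta[, p, t_star[p]], numeric(N))
  flat <- sqrt(colSums(B^2)) < 1e-10 * max(sqrt(colSums(B^2)), 1)
  if (any(flat))
    warning("absent effect(s) ", paste(stack[flat], collapse = ", "),
            ": their axes are arbitrary within the orthocomplement")
  qrd <- qr(B)
  Qm <- qr.Q(qrd)[, seq_along(stack), drop = FALSE]
  for (j in seq_along(stack)) {
    i <- which.max(abs(Qm[, j]))
    if (Qm[i, j] < 0) Qm[, j] <- -Qm[, j]
  }
  .baseline("tdr", Qm, t(Qm), labels = stack,
            extra = list(t_star = t_star, beta = beta, n_pcs = n_pcs,
                         degenerate = stack[flat]))
}

#' Factorial linear discriminant analysis for one marginalization
#'
#' Treats the chosen marginalization as between-class covariance and
#' everything else as within-class covariance: the discriminant axes are
#' the leading eigenvectors of `C_rest^-1 C_phi`. LDA reconstructs class
#' identity rather than class means, so (unlike dPCA) it equalizes class
#' spacing.
#'
#' @param covs a [marginalized_covariances()] result.
#' @param label marginalization to discriminate.
#' @param q number of discriminant axes.
#' @param ridge optional ridge added to the within-class matrix when it is
#'   singular.
#' @return a baseline model; decoders in `D`, eigenvalues in `values`.
#' @export
factorial_lda <- function(covs, label, q, ridge = 0) {
  stopifnot(inherits(covs, "covariance_set"), label %in% names(covs$marg))
  Cphi <- covs$marg[[label]]
  Crest <- covs$total - Cphi
  if (min(eigen(Cphi, symmetric = TRUE, only.values = TRUE)$values) < -1e-8 ||
      min(eigen(Crest, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("covariance inputs are not positive semidefinite")
  if (ridge > 0) Crest <- Crest + ridge * diag(nrow(Crest))
  M <- pinv_sym(Crest)$inv %*% Cphi
  e <- eigen(M)
  ord <- order(-Re(e$values))
  D <- t(Re(e$vectors[, ord[seq_len(q)], drop = FALSE]))
  D <- D / sqrt(rowSums(D^2))
  for (j in seq_len(q)) {
    i <- which.max(abs(D[j, ]))
    if (D[j, i] < 0) D[j, ] <- -D[j, ]
  }
  .baseline("flda", t(D), D, labels = rep(label, q),
            extra = list(values = Re(e$values[ord[seq_len(q)]])))
}

#' Difference-of-covariances axes
#'
#' The eigendecomposition of `S = C_phi1 - C_phi2`: eigenvectors with
#' large positive eigenvalues maximize variance of the first
#' marginalization while minimizing the second, and vice versa for
#' negative eigenvalues. Axes are tagged with the marginalization whose
#' variance they favour.
#'
#' @param covs a [marginalized_covariances()] result.
#' @param labels character pair of marginalization labels.
#' @return a baseline model with all `N` eigen-axes, eigenvalues in
#'   `values`, per-axis tags in `labels`.
#' @export
doc_axes <- function(covs, labels) {
  stopifnot(inherits(covs, "covariance_set"), length(labels) == 2,
            all(labels %in% names(covs$marg)))
  Sm <- covs$marg[[labels[1]]] - covs$marg[[labels[2]]]
  e <- eigen((Sm + t(Sm)) / 2, symmetric = TRUE)
  U <- e$vectors
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  tags <- ifelse(e$values >= 0, labels[1], labels[2])
  .baseline("doc", U, t(U), labels = tags,
            extra = list(values = e$values))
}

# Type-II sums of squares for a two-factor design with interaction,
# computed by model comparison; reduces to the usual decomposition when
# the design is balanced
.anova2_cell <- function(y, fs, fd) {
  dfull <- data.frame(y = y, s = fs, d = fd)
  rss <- function(form) sum(stats::resid(stats::lm(form, data = dfull))^2)
  r_sd <- rss(y ~ s + d)
  r_s <- rss(y ~ s)
  r_d <- rss(y ~ d)
  r_full <- rss(y ~ s * d)
  ss_s <- r_d - r_sd
  ss_d <- r_s - r_sd
  ss_sd <- r_sd - r_full
  df_s <- nlevels(fs) - 1L
  df_d <- nlevels(fd) - 1L
  df_sd <- df_s * df_d
  df_err <- length(y) - nlevels(fs) * nlevels(fd)
  mse <- r_full / df_err
  list(ss = c(s = ss_s, d = ss_d, sd = ss_sd), df = c(s = df_s, d = df_d,
       sd = df_sd), sse = r_full, df_err = df_err, mse = mse)
}

#' Classical per-neuron ANOVA tuning analysis
#'
#' Runs a two-way ANOVA (stimulus x decision with interaction) on every
#' neuron at every time point, returning p-values and signed effect sizes
#' (partial omega squared, signed by the correlation between firing rate
#' and the parameter), the fraction of significant neurons over time, and
#' population-average components built from the significant neurons at a
#' chosen time point with sign-flipped weights `+/- 1/Ns`.
#'
#' @param data a [trial_tensor()] with >= 2 trials per condition.
#' @param alpha per-test significance level (default 0.05).
#' @param stim_values,dec_values numeric codes used for the effect-size
#'   sign (defaults: level indices).
#' @return object of class `classical_tuning`: arrays `p` and `omega2`
#'   (`N x T x effect`), `frac_significant` (`T x effect`), and the
#'   closure `population_component(effect, t0)` returning the weights and
#'   the weighted-average component (`S x Q x T`).
#' @export
classical_tuning <- function(data, alpha = 0.05, stim_values = NULL,
                             dec_values = NULL) {
  stopifnot(inherits(data, "trial_tensor"))
  if (any(data$counts < 2L))
    stop("two-way ANOVA needs >= 2 trials in every condition cell")
  d <- dim(data$values)
  N <- d[1]; S <- d[2]; Q <- d[3]; T_ <- d[4]
  if (is.null(stim_values)) stim_values <- seq_len(S)
  if (is.null(dec_values)) dec_values <- seq_len(Q)
  effects <- c("s", "d", "sd")
  p <- om <- array(NA_real_, dim = c(N, T_, 3),
                   dimnames = list(NULL, NULL, effects))
  for (n in seq_len(N)) {
    ys <- list(); fs <- fd <- NULL
    for (s in seq_len(S)) for (qd in seq_len(Q)) {
      k <- data$counts[n, s, qd]
      fs <- c(fs, rep(s, k)); fd <- c(fd, rep(qd, k))
    }
    fs <- factor(fs); fd <- factor(fd)
    code <- cbind(s = stim_values[as.integer(fs)],
                  d = dec_values[as.integer(fd)])
    code <- cbind(code,
                  sd = (code[, "s"] - mean(code[, "s"])) *
                       (code[, "d"] - mean(code[, "d"])))
    for (t in seq_len(T_)) {
      y <- unlist(lapply(seq_len(S), function(s) unlist(lapply(seq_len(Q),
        function(qd) data$values[n, s, qd, t, seq_len(data$counts[n, s, qd])]))))
      a <- .anova2_cell(y, fs, fd)
      ntot <- length(y)
      for (ei in seq_len(3)) {
        eff <- effects[ei]
        Fv <- (a$ss[eff] / a$df[eff]) / a$mse
        p[n, t, ei] <- stats::pf(Fv, a$df[eff], a$df_err, lower.tail = FALSE)
        w2 <- (a$ss[eff] - a$df[eff] * a$mse) /
              (a$ss[eff] + (ntot - a$df[eff]) * a$mse)
        sgn <- sign(suppressWarnings(stats::cor(y, code[, eff])))
        if (is.na(sgn) || sgn == 0) sgn <- 1
        om[n, t, ei] <- sgn * max(w2, -1)
      }
    }
  }
  frac <- apply(p < alpha, c(2, 3), mean)
  psth <- compute_psths(data, center = TRUE)$values
  population_component <- function(effect, t0) {
    ei <- match(effect, effects)
    sig <- which(p[, t0, ei] < alpha)
    if (!length(sig)) stop("no significant neurons for effect `", effect,
                           "` at time bin ", t0)
    w <- numeric(N)
    w[sig] <- sign(om[sig, t0, ei]) / length(sig)
    comp <- array(w %*% flatten_mat(psth), dim = c(S, Q, T_))
    list(weights = w, component = comp)
  }
  structure(list(p = p, omega2 = om, frac_significant = frac,
                 alpha = alpha, population_component = population_component),
            class = "classical_tuning")
}

#' @export
print.classical_tuning <- function(x, ...) {
  cat("classical_tuning: fraction of significant neurons (peak over time)\n")
  peaks <- apply(x$frac_significant, 2, max)
  for (e in names(peaks))
    cat(sprintf("  %s: %.2f\n", e, peaks[e]))
  invisible(x)
}
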