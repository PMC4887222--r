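#' Regularized reduced-rank regression via SVD
#'
#' Solves `min ||target - F D predictor||^2 + w tr(F D C (F D)') +
#' mu ||F D||^2` over rank-`q` maps `F D` in three steps: the ridge/noise
#' regularized least-squares solution
#' `A = target predictor' (predictor predictor' + w C + mu I)^-1`, then the
#' top `q` left singular vectors `Uq` of `A predictor`, then `F = Uq`,
#' `D = Uq' A`. Encoder columns are orthonormal and each decoder/encoder
#' pair is independent of `q` (nestedness). The sign of each pair is fixed
#' so that the largest-magnitude encoder coefficient is positive.
#'
#' @param target,predictor centered matrices with equal column counts.
#' @param q rank (number of components), `q <= nrow(predictor)`.
#' @param ridge_mu ridge penalty `mu >= 0`.
#' @param noise_term optional symmetric PSD matrix `C` (noise covariance).
#' @param noise_weight scalar weight `w` of the noise penalty.
#' @return list with `F` (encoder, `N x q`), `D` (decoder, `q x N`), `A`
#'   (full regularized regression map), `loss` (objective value) and
#'   `sv` (singular values of `A predictor`).
#' @export
rrr_solve <- function(target, predictor, q, ridge_mu = 0,
                      noise_term = NULL, noise_weight = 0) {
  N <- nrow(predictor)
  stopifnot(ncol(target) == ncol(predictor), q >= 1, q <= N, ridge_mu >= 0)
  G <- predictor %*% t(predictor)
  if (!is.null(noise_term) && noise_weight != 0)
    G <- G + noise_weight * noise_term
  if (ridge_mu > 0) G <- G + ridge_mu * diag(N)
  pg <- pinv_sym(G)
  if (pg$deficient && ridge_mu == 0 &&
      (is.null(noise_term) || noise_weight == 0))
    warning("singular normal matrix with no regularization; ",
            "using the pseudo-inverse")
  A <- target %*% t(predictor) %*% pg$inv
  M <- A %*% predictor
  sv <- svd(M, nu = q, nv = 0)
  tolsv <- max(sv$d) * 1e-12
  if (q > sum(sv$d > tolsv))
    warning("requested rank exceeds the rank of the regression fit; ",
            "trailing components have zero variance")
  Fq <- sv$u
  Dq <- t(Fq) %*% A
  for (j in seq_len(q)) {                      # reproducible sign convention
    i <- which.max(abs(Fq[, j]))
    if (Fq[i, j] < 0) { Fq[, j] <- -Fq[, j]; Dq[j, ] <- -Dq[j, ] }
  }
  FD <- Fq %*% Dq
  loss <- frob2(target - FD %*% predictor)
  if (!is.null(noise_term) && noise_weight != 0)
    loss <- loss + noise_weight * sum((FD %*% noise_term) * FD)
  if (ridge_mu > 0) loss <- loss + ridge_mu * frob2(FD)
  list(F = Fq, D = Dq, A = A, loss = loss, sv = sv$d[seq_len(q)])
}

#' Fit demixed PCA
#'
#' Runs one regularized reduced-rank regression per marginalization, with
#' the full centered PSTH matrix as predictor and the marginalized data as
#' target, yielding per-marginalization decoder and encoder axes. The ridge
#' strength is parameterized as `mu = (lambda ||X||)^2` so that `lambda` is
#' comparable across datasets; the trial-to-trial noise covariance (times
#' the number of PSTH columns) enters the regularized normal matrix, which
#' re-balances unequal trial counts. Components are numbered globally by
#' decreasing explained PSTH variance while retaining their marginalization
#' identity.
#'
#' @param x a [psth_tensor()] (centered, or centered automatically with the
#'   means recorded), or a [trial_tensor()] from which PSTHs and a diagonal
#'   re-balanced noise covariance are derived.
#' @param mset optional precomputed [marginalize()] result.
#' @param noise optional [estimate_noise_covariance()] result.
#' @param q components per marginalization: scalar (default 10) or named
#'   vector by label.
#' @param lambda regularization strength (>= 0); `mu = (lambda ||X||)^2`.
#' @param noise_weight weight of the noise covariance term; defaults to the
#'   number of PSTH columns `S Q T`.
#' @param grouping passed to [marginalize()] when `mset` is not supplied.
#' @return object of class `dpca` with encoder list `F`, decoder list `D`,
#'   global component table `comp`, the centered training PSTH, and fit
#'   metadata.
#' @export
dpca_fit <- function(x, mset = NULL, noise = NULL, q = 10, lambda = 0,
                     noise_weight = NULL, grouping = NULL) {
  if (lambda < 0) stop("`lambda` must be non-negative")
  if (inherits(x, "trial_tensor")) {
    if (is.null(noise)) noise <- estimate_noise_covariance(x)
    x <- compute_psths(x, center = TRUE)
  }
  stopifnot(inherits(x, "psth_tensor"))
  if (!x$centered) x <- center_psth(x)
  if (is.null(mset))
    mset <- marginalize(x, grouping = grouping)
  labels <- names(mset$tensors)
  d <- dim(x$values)
  Xt <- flatten_mat(x$values)
  Xnorm2 <- frob2(Xt)
  mu <- (lambda * sqrt(Xnorm2))^2
  if (is.null(noise_weight)) noise_weight <- ncol(Xt)
  noiseM <- noise_matrix(noise)

  qv <- if (length(q) == 1L) stats::setNames(rep(q, length(labels)), labels)
        else q[labels]
  if (anyNA(qv)) stop("`q` must be a scalar or named by marginalization")
  if (any(qv > d[1])) stop("`q` cannot exceed the number of neurons")

  mats <- mset_matrices(mset)
  Fs <- Ds <- stats::setNames(vector("list", length(labels)), labels)
  comp <- NULL
  for (lab in labels) {
    if (frob2(mats[[lab]]) <= 1e-12 * Xnorm2) {
      warning("marginalization `", lab,
              "` has (near-)zero variance; no components extracted")
      Fs[[lab]] <- matrix(0, d[1], 0)
      Ds[[lab]] <- matrix(0, 0, d[1])
      next
    }
    sol <- rrr_solve(mats[[lab]], Xt, q = qv[[lab]], ridge_mu = mu,
                     noise_term = noiseM, noise_weight = noise_weight)
    Fs[[lab]] <- sol$F
    Ds[[lab]] <- sol$D
    ev <- vapply(seq_len(qv[[lab]]), function(i) {
      z <- sol$D[i, , drop = FALSE] %*% Xt
      (2 * sum((sol$F[, i, drop = FALSE] %*% z) * Xt) - frob2(z)) / Xnorm2
    }, 1)
    comp <- rbind(comp, data.frame(label = lab, within = seq_len(qv[[lab]]),
                                   expl_var = ev))
  }
  comp <- comp[order(-comp$expl_var, comp$label, comp$within), ]
  comp$comp <- seq_len(nrow(comp))
  rownames(comp) <- NULL
  structure(list(F = Fs, D = Ds, comp = comp[, c("comp", "label", "within",
                                                 "expl_var")],
                 lambda = lambda, mu = mu, noise_weight = noise_weight,
                 means = x$means, dims = d, time = x$time,
                 Xnorm2 = Xnorm2, psth = x$values, mset = mset),
            class = "dpca")
}

#' @export
print.dpca <- function(x, n = 10, ...) {
  cat(sprintf("dPCA fit: %d neurons, %d x %d conditions, %d time bins\n",
              x$dims[1], x$dims[2], x$dims[3], x$dims[4]))
  cat(sprintf("  lambda = %g, %d components (%s)\n", x$lambda, nrow(x$comp),
              paste(sprintf("%s: %d", names(x$F),
                            vapply(x$F, ncol, 1L)), collapse = ", ")))
  top <- utils::head(x$comp, n)
  cat("  leading components:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    #%d [%s] %.1f%% variance\n", top$comp[i],
                top$label[i], 100 * top$expl_var[i]))
  invisible(x)
}

# decoder rows of the selected components, stacked in global order
.comp_select <- function(model, labels = NULL, comps = NULL, q = NULL) {
  tab <- model$comp
  if (!is.null(labels)) {
    if (!all(labels %in% names(model$F))) stop("unknown marginalization label")
    tab <- tab[tab$label %in% labels, ]
  }
  if (!is.null(comps)) tab <- tab[tab$comp %in% comps, ]
  if (!is.null(q)) tab <- utils::head(tab, q)
  tab
}

.stack_D <- function(model, tab) {
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    model$D[[tab$label[i]]][tab$within[i], , drop = FALSE]))
}

.stack_F <- function(model, tab) {
  do.call(cbind, lapply(seq_len(nrow(tab)), function(i)
    model$F[[tab$label[i]]][, tab$within[i], drop = FALSE]))
}

#' Project data onto demixed components
#'
#' Applies the decoder axes to new (or training) data, after centering with
#' the model's stored per-neuron means. Works on PSTH tensors, trial
#' tensors, and plain `N x ...` arrays such as single pseudo-trials.
#'
#' @param model a [dpca_fit()] result.
#' @param data data with `N` neurons in the first dimension; defaults to
#'   the training PSTH.
#' @param labels,comps,q optional component selection: by marginalization
#'   label, by global component number, or the top `q` overall.
#' @return array of scores, components in the first dimension, remaining
#'   dimensions as in the input; the component table is attached as
#'   attribute `comp`.
#' @export
dpca_transform <- function(model, data = NULL, labels = NULL, comps = NULL,
                           q = NULL) {
  stopifnot(inherits(model, "dpca"))
  precentered <- FALSE
  if (is.null(data)) {
    data <- model$psth             # stored training PSTH, already centered
    precentered <- TRUE
  } else if (inherits(data, "psth_tensor")) {
    precentered <- data$centered
    data <- data$values
  } else if (inherits(data, "trial_tensor")) data <- data$values
  dd <- dim(data)
  if (is.null(dd)) dd <- c(length(data), 1L)
  if (dd[1] != model$dims[1])
    stop("data has ", dd[1], " neurons; model expects ", model$dims[1])
  Xc <- matrix(data, nrow = dd[1])
  if (!precentered) Xc <- Xc - model$means
  tab <- .comp_select(model, labels, comps, q)
  D <- .stack_D(model, tab)
  sc <- D %*% Xc                 # columns with missing trials propagate NA
  out <- array(sc, dim = c(nrow(tab), dd[-1]))
  attr(out, "comp") <- tab
  out
}

#' Reconstruct PSTHs from selected components
#'
#' Sums the rank-one contributions `f (d X)` of the selected components,
#' evaluated on the training PSTH, and adds back the stored per-neuron
#' means.
#'
#' @inheritParams dpca_transform
#' @return a [psth_tensor()] of the reconstruction.
#' @export
dpca_reconstruct <- function(model, labels = NULL, comps = NULL, q = NULL) {
  stopifnot(inherits(model, "dpca"))
  tab <- .comp_select(model, labels, comps, q)
  Xt <- flatten_mat(model$psth)
  rec <- matrix(0, nrow(Xt), ncol(Xt))
  if (nrow(tab) > 0) {
    D <- .stack_D(model, tab)
    Fm <- .stack_F(model, tab)
    rec <- Fm %*% (D %*% Xt)
  }
  vals <- array(rec + model$means, dim = model$dims)
  psth_tensor(vals, time = model$time)
}
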