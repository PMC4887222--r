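#' Logarithmic grid of regularization strengths
#'
#' @param from,to grid endpoints (default `1e-7` to `1e-3`).
#' @param n number of points (default 30).
#' @return increasing numeric vector of `lambda` values.
#' @export
lambda_grid <- function(from = 1e-7, to = 1e-3, n = 30) {
  10^seq(log10(from), log10(to), length.out = n)
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hold-one-trial-per-condition train/test split
#'
#' For every neuron and condition, one uniformly chosen trial is held out;
#' held-out trials form `S Q` test "pseudo-trials" (neurons drawn
#' independently, since sequentially recorded neurons share no real
#' trials). The remaining trials are averaged into a training PSTH and used
#' to re-estimate the noise covariance.
#'
#' @param data a [trial_tensor()] with >= 2 trials everywhere.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param noise_mode noise covariance mode for the training estimate.
#' @return list with `train` (training [psth_tensor()], uncentered),
#'   `test` (array `N x S x Q x T` of held-out pseudo-trials), `noise`
#'   (training [estimate_noise_covariance()]), `held_out` (indices
#'   `N x S x Q`).
#' @export
split_train_test <- function(data, seed = NULL, noise_mode = "diagonal") {
  stopifnot(inherits(data, "trial_tensor"))
  if (any(data$counts < 2L))
    stop("every (neuron, condition) cell needs >= 2 trials to split")
  d <- dim(data$values)
  with_seed(seed, {
    held <- array(0L, dim = d[1:3])
    held[] <- vapply(as.integer(data$counts),
                     function(k) sample.int(k, 1L), 1L)
    test <- array(NA_real_, dim = d[1:4])
    train_vals <- data$values
    for (n in seq_len(d[1])) for (s in seq_len(d[2])) for (qd in seq_len(d[3])) {
      k <- held[n, s, qd]
      test[n, s, qd, ] <- data$values[n, s, qd, , k]
      train_vals[n, s, qd, , k] <- NA_real_
      kc <- data$counts[n, s, qd]
      if (k < kc) {                       # keep NA padding at the tail
        train_vals[n, s, qd, , k:(kc - 1L)] <- data$values[n, s, qd, , (k + 1L):kc]
        train_vals[n, s, qd, , kc] <- NA_real_
      }
    }
    train_tt <- trial_tensor(
      train_vals[, , , , seq_len(max(data$counts) - 1L), drop = FALSE],
      data$counts - 1L, time = data$time)
    list(train = compute_psths(train_tt),
         test = test,
         noise = estimate_noise_covariance(train_tt, mode = noise_mode),
         held_out = held)
  })
}

#' Cross-validation error of a dPCA fit on held-out pseudo-trials
#'
#' Computes the residual training-set variance not explained by the test
#' data: the decoders are applied to the held-out pseudo-trials and the
#' reconstruction is compared against the training marginalizations,
#' `L = sum_phi ||X_train,phi - F_phi D_phi X_test||^2 / ||X_train||^2`.
#' The direction is deliberately asymmetric: decoders fitted on training
#' data are only ever applied to test data.
#'
#' @param model a [dpca_fit()] result fitted on the training PSTH.
#' @param x_test array `N x S x Q x T` of held-out pseudo-trials.
#' @param train_mset marginalization of the training PSTH; defaults to the
#'   one stored in the model.
#' @return scalar relative cross-validation error.
#' @export
cv_error <- function(model, x_test, train_mset = NULL) {
  stopifnot(inherits(model, "dpca"))
  if (is.null(train_mset)) train_mset <- model$mset
  if (!identical(dim(x_test)[1], model$dims[1]) ||
      prod(dim(x_test)) != prod(model$dims))
    stop("test pseudo-trials must match the training PSTH shape")
  Xtest <- flatten_mat(x_test) - model$means
  mats <- mset_matrices(train_mset)
  err <- 0
  for (lab in names(mats)) {
    FD_test <- model$F[[lab]] %*% (model$D[[lab]] %*% Xtest)
    err <- err + frob2(mats[[lab]] - FD_test)
  }
  err / model$Xnorm2
}

#' Select the regularization strength by cross-validation
#'
#' Repeats the hold-one-trial-per-condition split, fits dPCA on the
#' training PSTHs for every `lambda` on the grid, and evaluates
#' [cv_error()] on the held-out pseudo-trials; the mean error curve over
#' repetitions is minimized, with ties broken toward smaller `lambda`.
#'
#' @param data a [trial_tensor()].
#' @param grid increasing vector of `lambda` values (default
#'   [lambda_grid()]).
#' @param n_reps number of random train/test splits (default 10).
#' @param q components per marginalization (default 10).
#' @param seed optional integer seed.
#' @param noise_mode noise covariance mode for the training estimates.
#' @return object of class `dpca_cv`: `grid`, `curves` (reps x grid),
#'   `mean_curve`, `lambda_opt`, `per_label` (reps x grid x label array of
#'   per-marginalization errors), `seed`.
#' @export
select_lambda <- function(data, grid = lambda_grid(), n_reps = 10, q = 10,
                          seed = NULL, noise_mode = "diagonal") {
  stopifnot(length(grid) >= 1, n_reps >= 1)
  grid <- sort(grid)
  with_seed(seed, {
    labs <- NULL
    curves <- matrix(NA_real_, n_reps, length(grid))
    per_label <- NULL
    for (r in seq_len(n_reps)) {
      sp <- split_train_test(data, noise_mode = noise_mode)
      psth_c <- center_psth(sp$train)
      mset <- marginalize(psth_c)
      if (is.null(labs)) {
        labs <- names(mset$tensors)
        per_label <- array(NA_real_,
                           dim = c(n_reps, length(grid), length(labs)),
                           dimnames = list(NULL, NULL, labs))
      }
      mats <- mset_matrices(mset)
      Xtest <- flatten_mat(sp$test) - psth_c$means
      norm2 <- frob2(flatten_mat(psth_c$values))
      for (gi in seq_along(grid)) {
        fit <- dpca_fit(psth_c, mset = mset, noise = sp$noise, q = q,
                        lambda = grid[gi])
        for (lab in labs) {
          FD_test <- fit$F[[lab]] %*% (fit$D[[lab]] %*% Xtest)
          per_label[r, gi, lab] <- frob2(mats[[lab]] - FD_test) / norm2
        }
        curves[r, gi] <- sum(per_label[r, gi, ])
      }
    }
    mean_curve <- colMeans(curves)
    if (all(!is.finite(mean_curve)))
      stop("cross-validation error curve is entirely non-finite")
    structure(list(grid = grid, curves = curves, mean_curve = mean_curve,
                   lambda_opt = grid[which.min(mean_curve)],
                   per_label = per_label, seed = seed),
              class = "dpca_cv")
  })
}

#' @export
print.dpca_cv <- function(x, ...) {
  cat(sprintf("dPCA cross-validation: %d lambdas in [%.3g, %.3g], %d reps\n",
              length(x$grid), min(x$grid), max(x$grid), nrow(x$curves)))
  cat(sprintf("  optimal lambda = %.3g (mean CV error %.4f)\n",
              x$lambda_opt, min(x$mean_curve)))
  invisible(x)
}
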