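#' Default grouping of ANOVA terms into marginalizations
#'
#' The factorial decomposition produces one term per non-empty subset of
#' task parameters. Because every neural component is expected to vary with
#' time, each purely condition-dependent term is grouped with its
#' time-interaction partner: for parameters `{s, d, t}` this yields the four
#' marginalizations `t` (condition-independent), `st = {s, st}`,
#' `dt = {d, dt}` and `sdt = {sd, sdt}`. The same construction generalizes
#' to any parameter set containing the time parameter.
#'
#' @param params character vector of parameter names (condition parameters
#'   plus the time parameter).
#' @param time name of the time parameter (default `"t"`).
#' @return named list; each element is a list of character-vector subsets
#'   of `params` that are summed into that marginalization.
#' @export
default_grouping <- function(params = c("s", "d", "t"), time = "t") {
  stopifnot(time %in% params)
  cond <- setdiff(params, time)
  out <- list(list(time))
  names(out) <- time
  if (length(cond)) {
    subsets <- .all_subsets(cond)
    for (sub in subsets) {
      lab <- paste0(paste(sub, collapse = ""), time)
      out[[lab]] <- list(sub, c(sub, time))
    }
  }
  out
}

# all non-empty subsets of a character vector, smaller first
.all_subsets <- function(x) {
  n <- length(x)
  subs <- list()
  for (sz in seq_len(n))
    subs <- c(subs, utils::combn(x, sz, simplify = FALSE))
  subs
}

# check that `grouping` partitions the non-empty subsets of `params`
.check_grouping <- function(grouping, params) {
  key <- function(s) paste(sort(s), collapse = "|")
  want <- vapply(.all_subsets(params), key, "")
  got <- unlist(lapply(grouping, function(g) vapply(g, key, "")))
  if (anyDuplicated(got))
    stop("grouping assigns some parameter subset to more than one label")
  if (!setequal(got, want))
    stop("grouping must cover every non-empty parameter subset exactly once")
  invisible(TRUE)
}

#' Marginalize a data tensor into parameter-specific averages
#'
#' Decomposes centered population data into additive, pairwise uncorrelated
#' marginalizations: for each grouped label the alternating-sign sum of
#' averages over the complementary parameters is computed, so that the label
#' tensors sum exactly to the centered data and each tensor averages to zero
#' over any parameter it was averaged over. Balanced trial-resolved input
#' additionally yields the trial-to-trial noise residual.
#'
#' @param x a centered [psth_tensor()], or a balanced [trial_tensor()]
#'   (equal trial counts everywhere).
#' @param grouping grouping scheme as produced by [default_grouping()];
#'   must cover all non-empty parameter subsets exactly once.
#' @param params named integer vector mapping parameter names to array
#'   dimensions of the PSTH (default `c(s = 2, d = 3, t = 4)`).
#' @param center `"check"` errors on non-centered input, `"auto"` centers
#'   it with a warning.
#' @return object of class `marginalization_set`: `tensors` (named list of
#'   PSTH-shaped arrays), `noise` (trial-shaped residual array, or `NULL`),
#'   `params`, `grouping`, `means` (per-neuron centering means), `time`.
#' @export
marginalize <- function(x, grouping = NULL, params = c(s = 2, d = 3, t = 4),
                        center = c("check", "auto")) {
  center <- match.arg(center)
  noise <- NULL
  if (inherits(x, "trial_tensor")) {
    if (length(unique(as.integer(x$counts))) != 1L)
      stop("trial-resolved decomposition requires balanced trial counts; ",
           "use the PSTH formulation (compute_psths + marginalize) instead")
    psth <- compute_psths(x)
    d5 <- dim(x$values)
    noise <- x$values - array(rep(psth$values, d5[5]), dim = d5)
    x <- center_psth(psth)          # centering is part of the procedure
  }
  stopifnot(inherits(x, "psth_tensor"))
  means <- x$means
  if (!x$centered) {
    if (center == "check") {
      m <- apply(x$values, 1, mean)
      if (max(abs(m)) > 1e-10 * (1 + max(abs(x$values))))
        stop("input PSTH is not centered; center_psth() it first or use ",
             "center = \"auto\"")
    } else {
      warning("input PSTH not centered; centering per neuron")
    }
    x <- center_psth(x)
    means <- x$means
  }
  if (is.null(grouping)) grouping <- default_grouping(names(params))
  .check_grouping(grouping, names(params))

  a <- x$values
  dsz <- dim(a)
  single <- names(params)[dsz[params] == 1L]

  cache <- new.env(parent = emptyenv())
  avg_keep <- function(keep_names) {
    keyv <- paste0("k:", paste(sort(keep_names), collapse = "|"))
    if (!is.null(cache[[keyv]])) return(cache[[keyv]])
    v <- marg_mean(a, params[keep_names])
    cache[[keyv]] <- v
    v
  }
  term <- function(psi) {          # alternating-sign sum over subsets of psi
    out <- array(0, dim = dsz)
    rho_sets <- c(list(character(0)), .all_subsets(psi))
    for (rho in rho_sets)
      out <- out + (-1)^(length(psi) - length(rho)) * avg_keep(rho)
    out
  }
  tensors <- lapply(grouping, function(group) {
    acc <- array(0, dim = dsz)
    for (psi in group) acc <- acc + term(psi)
    acc
  })
  if (length(single)) {
    zero <- vapply(tensors, function(z) max(abs(z)) == 0, TRUE)
    if (any(zero))
      warning("parameter(s) with a single level: label(s) ",
              paste(names(tensors)[zero], collapse = ", "),
              " are identically zero")
  }
  structure(list(tensors = tensors, noise = noise, params = params,
                 grouping = grouping, means = means, time = x$time),
            class = "marginalization_set")
}

#' @export
print.marginalization_set <- function(x, ...) {
  v <- vapply(x$tensors, frob2, 1)
  cat("marginalization_set:", paste(names(x$tensors), collapse = ", "), "\n")
  cat("  variance shares:",
      paste(sprintf("%s %.1f%%", names(v), 100 * v / sum(v)), collapse = ", "),
      "\n")
  invisible(x)
}

# label tensors flattened to N x (S Q T) matrices
mset_matrices <- function(mset) lapply(mset$tensors, flatten_mat)

# reconstructed centered PSTH (sum of all label tensors)
mset_psth <- function(mset) Reduce(`+`, mset$tensors)

#' Covariance decomposition of a marginalization set
#'
#' Splits the total data covariance into per-marginalization covariances
#' `C_phi = X_phi X_phi' / n`, all with the common denominator `n` equal to
#' the total number of sample points (trials x conditions x time bins for
#' trial-resolved data, conditions x time bins for PSTHs). For balanced
#' trial-resolved input the trial-to-trial noise covariance is included and
#' the identity `C = sum(C_phi) + C_noise` holds exactly.
#'
#' @param mset a [marginalize()] result.
#' @return object of class `covariance_set`: `total`, `marg` (named list),
#'   `noise` (or `NULL`), `denom`.
#' @export
marginalized_covariances <- function(mset) {
  stopifnot(inherits(mset, "marginalization_set"))
  mats <- mset_matrices(mset)
  npsth <- ncol(mats[[1]])
  if (!is.null(mset$noise)) {
    K <- dim(mset$noise)[5]
    denom <- npsth * K
    marg <- lapply(mats, function(m) K * (m %*% t(m)) / denom)
    Em <- flatten_mat(mset$noise)
    noise <- Em %*% t(Em) / denom
    # total computed directly from the centered trials
    psth_rep <- array(rep(mset_psth(mset), K), dim = dim(mset$noise))
    Xc <- flatten_mat(psth_rep + mset$noise)
    total <- Xc %*% t(Xc) / denom
  } else {
    denom <- npsth
    marg <- lapply(mats, function(m) (m %*% t(m)) / denom)
    Xc <- flatten_mat(mset_psth(mset))
    total <- Xc %*% t(Xc) / denom
    noise <- NULL
  }
  structure(list(total = total, marg = marg, noise = noise, denom = denom),
            class = "covariance_set")
}

#' @export
print.covariance_set <- function(x, ...) {
  cat(sprintf("covariance_set: %d neurons, labels %s%s\n", nrow(x$total),
              paste(names(x$marg), collapse = ", "),
              if (!is.null(x$noise)) " + noise" else ""))
  invisible(x)
}
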