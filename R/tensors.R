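#' Trial-resolved firing-rate tensor
#'
#' Container for per-trial firing rates of a population recorded under a
#' factorial task design. Rates are stored in a dense array
#' `neurons x stimuli x decisions x time x trials`, padded with `NA` where a
#' condition has fewer trials than the maximum, together with an integer
#' array of trial counts per `(neuron, stimulus, decision)` cell.
#'
#' @param values numeric array `N x S x Q x T x Kmax`, firing rates in
#'   spikes/s; entries beyond a cell's trial count must be `NA`.
#' @param counts integer array `N x S x Q` of trial counts (all >= 1). A
#'   scalar is recycled.
#' @param time optional numeric vector of length `T` with bin-center times
#'   in seconds.
#' @return an object of class `trial_tensor` with elements `values`,
#'   `counts`, `time`.
#' @export
trial_tensor <- function(values, counts, time = NULL) {
  if (length(dim(values)) != 5L)
    stop("`values` must be a 5-d array (neuron, stimulus, decision, time, trial)")
  d <- dim(values)
  if (length(counts) == 1L)
    counts <- array(as.integer(counts), dim = d[1:3])
  counts <- array(as.integer(counts), dim = d[1:3])
  if (any(counts < 1L))
    stop("every (neuron, stimulus, decision) cell needs at least one trial")
  if (max(counts) > d[5])
    stop("trial counts exceed the trial dimension of `values`")
  if (is.null(time)) time <- seq_len(d[4])
  if (length(time) != d[4]) stop("`time` must have length T")
  # rates must be finite wherever a trial exists
  for (k in seq_len(d[5])) {
    present <- counts >= k
    slab <- values[, , , , k, drop = FALSE]
    bad <- !is.finite(slab[rep(present, d[4])])
    if (any(bad))
      stop("non-finite rate found within the recorded trials (trial ", k, ")")
  }
  structure(list(values = values, counts = counts, time = as.numeric(time)),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "trial_tensor: %d neurons, %d stimuli x %d decisions, %d time bins\n",
    d[1], d[2], d[3], d[4]))
  cat(sprintf("  trials per condition: %d-%d (mean %.1f)\n",
              min(x$counts), max(x$counts), mean(x$counts)))
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$values)

#' Trial-averaged firing-rate tensor (PSTHs)
#'
#' @param values numeric array `N x S x Q x T` of mean firing rates.
#' @param centered logical; `TRUE` if per-neuron grand means were removed.
#' @param means per-neuron grand means removed during centering (length `N`).
#' @param time optional bin-center times (length `T`).
#' @return object of class `psth_tensor`.
#' @export
psth_tensor <- function(values, centered = FALSE, means = NULL, time = NULL) {
  if (length(dim(values)) != 4L)
    stop("`values` must be a 4-d array (neuron, stimulus, decision, time)")
  d <- dim(values)
  if (is.null(time)) time <- seq_len(d[4])
  if (is.null(means)) means <- numeric(d[1])
  if (centered) {
    m <- apply(values, 1, mean)
    if (max(abs(m)) > 1e-8 * (1 + max(abs(values))))
      stop("`centered = TRUE` but per-neuron means are not zero")
  }
  structure(list(values = values, centered = centered,
                 means = as.numeric(means), time = as.numeric(time)),
            class = "psth_tensor")
}

#' @export
print.psth_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("psth_tensor: %d neurons, %d x %d conditions, %d time bins%s\n",
              d[1], d[2], d[3], d[4],
              if (x$centered) " (centered)" else ""))
  invisible(x)
}

#' @export
dim.psth_tensor <- function(x) dim(x$values)

#' Center a PSTH tensor per neuron
#'
#' Subtracts each neuron's grand mean over all conditions and time bins and
#' records it, so that subsequent decompositions satisfy the zero-mean
#' assumption.
#'
#' @param psth a `psth_tensor`.
#' @return a centered `psth_tensor` with the removed means stored.
#' @export
center_psth <- function(psth) {
  stopifnot(inherits(psth, "psth_tensor"))
  if (psth$centered) return(psth)
  m <- apply(psth$values, 1, mean)
  v <- sweep(psth$values, 1, m)
  psth_tensor(v, centered = TRUE, means = psth$means + m, time = psth$time)
}

# ---- internal numeric helpers -------------------------------------------

# squared Frobenius norm
frob2 <- function(x) sum(as.numeric(x)^2)

# flatten an N x ... array to an N x (prod of the rest) matrix
flatten_mat <- function(a) {
  d <- dim(a)
  matrix(a, nrow = d[1], ncol = prod(d[-1]))
}

# average an array over all dims except dim 1 (neuron) and `keep`,
# then broadcast the result back to the full shape
marg_mean <- function(a, keep = integer(0)) {
  d <- dim(a)
  nd <- length(d)
  keep <- sort(unique(as.integer(keep)))
  drop_dims <- setdiff(seq_len(nd)[-1], keep)
  if (length(drop_dims) == 0L) return(a)
  m <- apply(a, c(1L, keep), mean)
  ord <- c(1L, keep, drop_dims)
  full <- array(m, dim = c(d[1L], d[keep], d[drop_dims]))
  aperm(full, order(ord))
}

# symmetric pseudo-inverse with relative eigenvalue cutoff
pinv_sym <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  cutoff <- tol * max(abs(e$values), 0)
  inv <- ifelse(e$values > cutoff, 1 / e$values, 0)
  list(inv = e$vectors %*% (inv * t(e$vectors)),
       rank = sum(e$values > cutoff),
       deficient = any(e$values <= cutoff))
}

# symmetric matrix square root (PSD input; negative round-off clipped)
sqrt_sym <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
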