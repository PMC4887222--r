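# Shared fixtures and independent oracles, built in code at test time.

# random balanced trial tensor
random_trial_tensor <- function(N = 8, S = 3, Q = 2, T_ = 10, K = 4,
                                seed = 1) {
  set.seed(seed)
  vals <- array(rnorm(N * S * Q * T_ * K), dim = c(N, S, Q, T_, K))
  trial_tensor(vals, K)
}

# random centered PSTH tensor
random_psth <- function(N = 8, S = 3, Q = 2, T_ = 10, seed = 1) {
  set.seed(seed)
  center_psth(psth_tensor(array(rnorm(N * S * Q * T_),
                                dim = c(N, S, Q, T_))))
}

# Independent oracle for the marginalization: the iterative nested-average
# definition, computed term by term (average of the residual after
# subtracting all strictly smaller terms), then grouped. `a` is a centered
# N x S x Q x T array.
oracle_marginalize <- function(a, grouping = default_grouping()) {
  params <- c(s = 2, d = 3, t = 4)
  subsets <- list()
  sizes <- c(1, 2, 3)
  all_subs <- unlist(lapply(sizes, function(k)
    combn(names(params), k, simplify = FALSE)), recursive = FALSE)
  # order by size so strict subsets are always available
  terms <- list()
  mean_keep <- function(keep) {
    d <- dim(a)
    drop_dims <- setdiff(2:4, params[keep])
    m <- apply(a, c(1, sort(params[keep])), mean)
    ord <- c(1, sort(params[keep]), drop_dims)
    aperm(array(m, dim = c(d[1], d[sort(params[keep])], d[drop_dims])),
          order(ord))
  }
  key <- function(s) paste(sort(s), collapse = "|")
  for (psi in all_subs) {
    acc <- mean_keep(psi)
    for (tau in all_subs) {
      # averaging a strictly smaller (broadcast) term changes nothing,
      # so the iterative definition reduces to a plain subtraction
      if (length(tau) < length(psi) && all(tau %in% psi))
        acc <- acc - terms[[key(tau)]]
    }
    terms[[key(psi)]] <- acc
  }
  lapply(grouping, function(group)
    Reduce(`+`, lapply(group, function(psi) terms[[key(psi)]])))
}

# trapezoid integral of a sampled trace
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# greedy matching of fitted components to ground-truth latents by maximal
# absolute correlation of their condition/time courses
match_components <- function(fit, truth) {
  labs <- vapply(truth$latents, `[[`, "", "label")
  out <- data.frame(label = labs, r = NA_real_, demix = NA_real_)
  for (j in seq_along(truth$latents)) {
    lab <- labs[j]
    if (ncol(fit$F[[lab]]) == 0) next
    z <- as.numeric(truth$latents[[j]]$z)
    sc <- dpca_transform(fit, labels = lab)
    rs <- apply(matrix(sc, nrow = dim(sc)[1]), 1,
                function(v) abs(cor(z, v)))
    best <- which.max(rs)
    out$r[j] <- rs[best]
    out$demix[j] <- demixing_index(fit$D[[lab]][best, ], fit$mset)
  }
  out
}
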