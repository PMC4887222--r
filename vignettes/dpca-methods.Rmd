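---
title: "Demixed PCA: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixed PCA: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpca)
```

## The problem

Trial-based recordings with a factorial design give, for each neuron, a
firing-rate trace per combination of stimulus `s` (of `S`), decision `d`
(of `Q`) and time `t` (of `T`), across `K` repeated trials. Individual
neurons mix these influences. dPCA looks for a small set of linear
population readouts, each tuned to a single task parameter, that together
reconstruct the trial-averaged data well.

## Marginalization

The backbone is the factorial ANOVA decomposition. For a centered data
tensor, every non-empty subset of parameters gets an additive term computed
by an alternating-sign sum of averages; `marginalize()` implements the
general formula for arbitrary parameter sets, with the three-parameter case
`{s, d, t}` as the default. Because all neural signals are expected to vary
with time, each purely condition-dependent term is grouped with its
time-interaction partner, leaving four marginalizations: condition
independent (`t`), stimulus (`st`), decision (`dt`) and interaction
(`sdt`). The grouping is a configuration object (a partition of the
parameter subsets, validated as such), not hard-coded, so designs with more
parameters can supply their own.

Key exact properties, all verified in the test suite at `1e-10`-level
tolerances: the terms sum to the centered data; each term averages to zero
over any parameter it varies with; all terms (and the trial-to-trial
residual) are pairwise uncorrelated, so the covariance splits as
`C = sum_phi C_phi + C_noise`. All covariances share one denominator, the
total number of sample points — degrees-of-freedom denominators would break
the additivity.

## The dPCA loss and its solution

Per marginalization, dPCA minimizes
`||X_phi - F D X||^2 + SQT ||F D C_noise^(1/2)||^2 + mu ||F D||^2`
over a rank-`q` map `F D`. This is reduced-rank ridge regression; the
analytic three-step solution is a regularized least-squares map
`A = X_phi X' (X X' + SQT C_noise + mu I)^(-1)`, an SVD of `A X`, and the
factorization `F = U_q`, `D = U_q' A`. The encoder has orthonormal columns,
and decoder/encoder pairs are *nested*: pair `i` does not depend on how
many pairs are extracted.

Numerical choices:

* The symmetric system matrix is inverted through an eigendecomposition
  with a relative eigenvalue cutoff of `1e-12` (a pseudo-inverse), because
  `X X'` is rank-deficient whenever `N > SQT`; an unregularized
  rank-deficient solve warns.
* Sign convention: each pair is flipped so that the encoder coefficient of
  largest magnitude is positive. This makes fits reproducible; with tied
  singular values only the subspace is well-defined, and the tests then
  compare subspaces, not axes.
* A marginalization whose variance is below `1e-12` of the total
  contributes no components (with a warning); the same relative threshold
  flags zero-variance trailing components when `q` exceeds the fit's rank.
* Components are numbered globally by explained PSTH variance while
  retaining their marginalization identity.

The ridge strength is parameterized as `mu = (lambda ||X||)^2` so that
`lambda` is comparable across datasets. With the trial-to-trial noise
covariance included, the same loss re-balances unequal trial counts: all
quantities are computed from PSTHs and a noise covariance averaged with
equal weight per condition, so conditions with many trials do not dominate.
For sequentially recorded neurons no noise correlations are estimable and a
diagonal noise covariance (per-neuron variances) is used.

## Selecting the regularization strength

`select_lambda()` holds out one random trial per neuron and condition as
`S x Q` test pseudo-trials, fits dPCA on the remaining trials' PSTHs for
each `lambda` on a log grid (default 30 points over `1e-7`–`1e-3`, 10
components per marginalization, 10 repetitions), and minimizes
`L = sum_phi ||X_train,phi - F_phi D_phi X_test||^2 / ||X_train||^2`. The
direction is deliberately asymmetric — decoders fitted on training data are
applied to held-out data only. Ties in the argmin resolve to the smaller
`lambda` (the weaker prior). The noise covariance is re-estimated per split
from training trials only, to avoid leakage. With diagonal noise
covariances the curve is typically very flat, so the *location* of the
minimum is not a meaningful quantity; the tests assert the curve's shape
(near-1 saturation as `lambda` grows, near-minimum at the unregularized
end) rather than an optimal value.

## Evaluation

* **Variance**: `R^2 = 1 - ||X - F D X||^2/||X||^2` per component,
  cumulatively, and split additively across marginalizations. For an
  arbitrary component matrix the reconstruction weights come from linear
  regression.
* **Signal variance**: finite trial counts leave residual noise in the
  PSTHs; its expected sum of squares `Theta = SQT sum_n C_nn / K_n` splits
  across marginalizations in proportion to their degrees of freedom
  (computed generally as products of `(levels - 1)` over each raw term).
  Noise-corrected percentages are rounded by the largest-remainder method
  so they sum to exactly 100. Note the population-denominator convention
  makes `Theta` an underestimate by a factor `(K-1)/K`; the tests check
  the estimator against its exact expectation.
* **Demixing index**: `max_phi ||d X_phi||^2 / ||d X||^2`, range `[1/L, 1]`
  for `L` marginalizations.
* **Axis angles**: two unit axes in `N` dimensions are flagged
  significantly non-orthogonal when `|f1 . f2| > 3.3/sqrt(N)` (p < 0.001
  under the rotation-invariant null) *and* the Kendall correlation of
  their coordinates is significant at the same level (robustness against a
  few outlying neurons). R's exact Kendall p-value is used for small `N`,
  the normal approximation otherwise.
* **Classification**: decoder axes of the leading condition-dependent
  components classify held-out pseudo-trials by nearest class mean, per
  time bin, averaged over stratified Monte-Carlo splits; the null
  distribution re-runs the identical procedure on data whose trials were
  shuffled between conditions within each neuron (trial counts preserved).
  A bin is significant only inside runs of at least 10 consecutive bins
  (on the analysis grid) whose accuracy strictly exceeds *all* shuffle
  curves. The reference setting is 100 splits x 100 shuffles; smaller
  values run faster and warn.
* **Weight diagnostics**: neurons as points in the space of their encoder
  weights on the leading 15 components; density-peaks statistics (Gaussian
  kernel, `sigma^2 = 0.01`; ties broken by index; the global mode's delta
  is the distance to the furthest point) reveal whether neuron subtypes
  exist — a single high-density/high-delta outlier means one cluster.

## Preprocessing

Spike trains are filtered with a Gaussian kernel (default sd 50 ms) and
sampled at 100 Hz (bin centers, `t = 0` at the first alignment event). The
kernel is truncated at four standard deviations and edge bins are *not*
renormalized — a deterministic, simple convention; rate mass within 4 sd of
the window edge is therefore slightly attenuated. Self-paced trials are
aligned by piecewise-linear time warping onto per-event reference times
(medians across trials; the reward median over correct trials only, and a
synthetic reward event at the previous event plus the task's minimal
reward wait on error trials). Smoothing is applied before warping, since
the warp is defined on the instantaneous firing rate. Trials are stored
dense with per-condition counts and sentinel (`NA`) padding, which keeps
all index arithmetic simple at a modest memory cost.

## The synthetic generator

`generate_population()` draws, per marginalization, latent time courses
(Gaussian bumps or ramps — the morphology typical of cortical PSTH
components) modulated across conditions so that each latent lies *exactly*
in its marginalization, maps them into the population through random
unit-norm encoder vectors, and adds i.i.d. Gaussian noise per trial. The
signal-to-noise ratio is defined on the PSTH after `K`-trial averaging:
total latent variance over `noise_sd^2/K`. Gaussian additive noise matches
the squared-error loss of the method; Poisson-like spiking variability,
neuron-specific rate scales, and temporally correlated noise are *not*
emulated, so passing recovery tests demonstrates correctness of the
algorithm, not robustness to every property of real recordings. The
defaults (N = 100, S = 4, Q = 2, T = 50, K = 10, SNR = 1) mirror the scale
at which sequential recordings support satisfactory demixing; recovery
degrades visibly at N = 10, which the tests assert as a monotonicity
check. Companion generators produce the two standard counter-example
populations: the 2-neuron unbalanced design whose pooled trial correlation
is spurious (sampling bias, not physiology), and the temporally jittered
population whose PCA spectrum contains derivative-shaped artifact
components.

## Problem sizes used by the tests

The test suite runs entirely on synthetic data built at run time: the
decomposition identities on a 20 x 3 x 2 x 40 x 5 tensor, the reduced-rank
optimum against BFGS restarts on 20 random 5 x 30 instances, recovery on
ten seeds at N = 100 (and N = 10 for the degradation check), and the
classification false-positive control on twenty condition-independent
populations at 20 cross-validation splits x 20 shuffles — sizes chosen so
the full suite completes in a few minutes on one core while still
exercising every code path at realistic shape ratios (more neurons than
conditions, more conditions than latents).

## Known limitations

* All parameter combinations must be present; missing cells would need
  parametric per-neuron models to impute, which is out of scope.
* Exact trial-resolved decomposition is only defined for balanced designs;
  unbalanced data are routed through the PSTH formulation (this is the
  method's re-balancing, not a workaround).
* Decoder axes across marginalizations are not constrained to be
  orthogonal — that is a feature (oblique parameter subspaces demix
  better), but it means encoder-axis dot products need the significance
  test above before interpretation.
* The CSV/JSON interchange format favours portability over size; very
  large recordings are better kept in memory via the generator or
  converted once.
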