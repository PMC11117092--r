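---
title: "Structure-constrained estimation of partial coherence with the adaptive graphical lasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-constrained estimation of partial coherence with the adaptive graphical lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglasso)
```

## The model

Band-limited multichannel neural activity is modelled as draws of a
zero-mean, circularly symmetric (proper) complex Gaussian vector $z \in
\mathbb{C}^n$: the per-window Fourier coefficients of $n$ channels at one
frequency.  Under properness the distribution is fully described by the
cross-spectral density (CSD) $\Theta = E[z z^H]$, and the object of
interest is its inverse, the spectral precision $\Phi = \Theta^{-1}$.
Off-diagonal zeros of $\Phi$ encode conditional independence, so the
support of $\Phi$ *is* the functional graph, and its normalization

$$\mathrm{PC}_{jk} = \frac{\Phi_{jk}}{\sqrt{\Phi_{jj}\,\Phi_{kk}}}$$

is the partial coherence: the linear dependence between channels $j$ and
$k$ per frequency once all other channels are accounted for.  Unlike
coherence ($\Theta$ normalized the same way) and imaginary coherence (its
imaginary part), partial coherence does not inherit edges from indirect
paths or from zero-lag mixing, which makes it attractive when the measured
signals are source-localized M/EEG with leakage.

## The adaptive graphical lasso

With limited samples $\Phi$ cannot be estimated by plain inversion, so the
package maximizes an L1-penalized complex Gaussian likelihood,

$$\hat\Phi = \arg\min_{\Phi \succ 0}\; -\log\det\Phi + \mathrm{tr}(\Theta\Phi)
  + \sum_{j \ne k} P_{jk}\,|\Phi_{jk}|,$$

where $|\cdot|$ is the complex modulus and the diagonal is never
penalized.  The *adaptive* element is the two-level penalty: $P_{jk} =
\lambda_1$ on edges of a hypothesized binary network (for example a
structural connectome) and $P_{jk} = \lambda_2$ elsewhere.  When
$\lambda_1 = \lambda_2$ this is exactly the vanilla graphical lasso, so the
cross-validated choice between the two levels doubles as a test of whether
the hypothesized network is informative: a selected $\lambda_1 <
\lambda_2$ means the data supported cheaper (less penalized) edges inside
the hypothesis.

Note the penalty is written over both triangles of the Hermitian matrix.
A sum over $j<k$ differs only by relabelling $\lambda \mapsto \lambda/2$
(which cross-validation absorbs), and the both-triangles convention makes
$\max_{j<k}|\Theta_{jk}|$ exactly the smallest flat penalty that zeroes
every edge, which anchors the default grid.

Fitting proceeds in three steps, matching `glasso_complex()`,
`support_of()` and `refit_support()`:

1. solve the penalized problem by block coordinate descent on the
   covariance iterate, where each column update is an L1-penalized complex
   regression solved coordinate-wise with a modulus soft-threshold
   ($z \mapsto z\,(1 - t/|z|)_+$) and an active-set strategy;
2. read the graph off the nonzero entries (relative modulus threshold
   `zero_tol = 1e-6`);
3. refit by unpenalized maximum likelihood restricted to that support,
   with a diagonal ridge $\delta = 0.001 \cdot \max_{j<k} |\Theta_{jk}|$
   guarding against rank deficiency.  The refit solves the classical
   covariance-selection problem; at its optimum $(\tilde\Phi^{-1})_{jk} =
   (\Theta + \delta I)_{jk}$ on the support and the diagonal.

Correctness of the solver is defined by the objective, not by any
particular algorithm, and the test suite holds it to a brute-force zooming
grid search on 2-node problems and to random-restart Nelder–Mead on 3-node
problems, to three decimals.

## Cross-validated penalty selection

`agl()` splits the samples into $K = 4$ contiguous ensembles, and for
every $(\lambda_1, \lambda_2)$ pair on a grid fits the penalized model and
its support refit $\tilde\Phi_i$ on each ensemble $i$, scoring it against
every held-out ensemble $j$ with the Gaussian deviance

$$\mathrm{Dev} = \sum_i \sum_{j \ne i} -\log\det\tilde\Phi_i +
  \mathrm{tr}(\Theta_j\,\tilde\Phi_i).$$

The pair with the smallest total deviance wins; ties break toward the
sparser model (larger $\lambda_1 + \lambda_2$, then larger $\lambda_2$).
The default grid holds 8 logarithmically spaced values from $0.01\,
\lambda_{\max}$ to $\lambda_{\max}$, with $\lambda_{\max}$ the largest
off-diagonal CSD modulus **over the ensembles**: the fits the
cross-validation actually performs are per-ensemble, and anchoring the
grid to the pooled CSD (whose off-diagonal maxima are systematically
smaller, since pooling averages noise down) would leave the all-zero model
unreachable.

Two readings of "the estimate" coexist in this procedure and the package
exposes both:

* the **pooled point estimate** (`$Phi`): the support refit on the
  sample-weighted mean of the ensemble CSDs at the selected pair — the
  natural single-matrix summary, and the default returned by `coef()`;
* the **per-ensemble refits** (`$ensemble_fits`): the quantities the
  cross-validation itself produces.

For the simulation metrics (`run_sim1()` and friends) the edge-weight
correlation is computed from the per-ensemble refits (their mean
correlation), because the cross-validation procedure never pools; the
recovered network (true/false positives) is the support of the pooled
fit.  `weight_estimate = "pooled"` switches to the pooled convention.

## The synthetic generative model

`generate_precision()` builds ground truth directly in precision space:
each edge of a given binary network receives weight $w \sim N(100, 30)$
and phase $\varphi \sim N(\pi/2, 0.25)$, giving $\Phi_{jk} = w
e^{i\varphi}$; off-network entries are exactly zero; the initial diagonal
is zero and positive definiteness is then enforced by `make_pd()`, which
repeatedly adds the row absolute sums to the diagonal until a Cholesky
factorization (of the real embedding) succeeds.  Rows that are entirely
zero receive a unit load so degenerate inputs (isolated nodes) still
terminate.  Samples are drawn through the half-scaled real embedding
$\tfrac12 \begin{pmatrix} \mathrm{Re}\,\Theta & -\mathrm{Im}\,\Theta\\
\mathrm{Im}\,\Theta & \mathrm{Re}\,\Theta\end{pmatrix}$, whose factor
$\tfrac12$ makes $E[zz^H] = \Theta$ exact and $E[zz^T] = 0$ (properness);
both moments are checked by Monte-Carlo tests.

One consequence of the row-sum loading deserves emphasis.  The loaded
diagonal is roughly proportional to node degree, so the true partial
coherence of an edge scales like $w / \sqrt{\deg_j \deg_k} \cdot
\tfrac1{100}$.  On a *uniform* random graph of 114 nodes and 720 edges
every node has degree near 12.6 and the median true $|PC|$ is about
0.076 — below the sampling noise floor $1/\sqrt{120} \approx 0.09$ of one
120-sample ensemble.  In that regime the held-out deviance genuinely
prefers the empty model by a small margin, and the cross-validation
collapses to the sparse corner.  A degree-heterogeneous graph of identical
size (hubs plus many low-degree nodes, as in a real connectome) has many
strong edges, the deviance margin flips decisively toward the structured
fit, and recovery matches the qualitative published behaviour; the test
suite exercises this regime as a property check on a 16-node network with
mean degree 4.  Users supplying their own connectome should be aware that
recovery depends on this effective edge strength, not only on sample
count.  This is also the main respect in which the uniform surrogate
understates real data: anatomical connectomes are modular and
heavy-tailed, so passing simulations on the surrogate say nothing about
edges whose partial coherence sits below the per-ensemble noise floor.

## Baselines

* `l2_precision()` / `cv_l2()`: ridge-penalized precision,
  $\eta\sum_{j\ne k}|\Phi_{jk}|^2$ with unpenalized diagonal.  The
  off-diagonal-only ridge has no eigenvalue closed form, so the smooth
  convex objective is minimized by Barzilai–Borwein gradient descent with
  Armijo backtracking confined to the PD cone (a damped fixed-point
  iteration on the stationarity condition was tried first and diverges
  for moderate $\eta$; the gradient scheme is validated against numerical
  differentiation).  Since no entry is ever exactly zero, the network is
  obtained by thresholding at a percentile (5–95) of the off-diagonal
  moduli, with $(\eta, \text{percentile})$ chosen by the same held-out
  deviance as the AGL.
* `bootstrap_threshold()`: coherence / imaginary-coherence networks kept
  where the row-resampled bootstrap distribution excludes zero.  For the
  real-valued imaginary coherence this is the two-sided $\alpha$-level
  percentile interval.  For complex coherence an interval "covering zero"
  is ill-posed (the magnitude is strictly positive), so the implemented
  reading tests the real and imaginary components separately at
  $\alpha/2$ each (Bonferroni) and retains the edge if either component
  excludes zero.  This is a documented interpretation, not a published
  rule.

## The MEG leakage simulation

`run_sim3()` stresses all four estimators with the spatial mixing that
source localization induces.  A quasi-physical lead field
(`synthetic_leadfield()`) places gradiometer-like sensors on an upper
hemisphere and ROI triplets of orthogonal dipoles on an interior sphere,
with a tangential-dipole inverse-square kernel so nearby ROIs project to
overlapping sensor patterns.  Scalar ROI activity is embedded along a
fixed random unit orientation per ROI (the generative model lives on
ROIs, not dipole axes), independent proper Gaussian noise is added at
25 dB SNR (power ratio of $\mathrm{tr}\,\Theta$ to total noise), sensors
are formed as $B = MS$, and sources are recovered with a depth-weighted
minimum-norm inverse: weights are per-column norms of $M$ raised to 2.5,
the regularizer is the 10th percentile of the singular values of the
weighted lead field (both exposed as parameters, since the published
description is ambiguous between norm-based and entrywise weightings),
and the operator is applied through the SVD with truncation of
singular values at the numerical noise floor — the tangential kernel
leaves radial dipole directions invisible, and without truncation those
null directions inject arbitrary noise.  Dipole triplets are collapsed to
one series per ROI by projecting on the first left singular vector of
each $3 \times T$ block (first nonzero component made real positive).

## The spectral front end

`design_bandpass()` builds elliptic band-passes with stop-band edges
0.5 Hz beyond the pass band, 100 dB stop-band attenuation and 0.02 dB
pass-band ripple.  Narrow-transition elliptic designs of this class are
numerically meaningless as transfer-function polynomials (orders above
~20 with roots packed against the unit circle), so the design lives
entirely in zero-pole-gain form — analog low-pass prototype, analog
band-pass transform and bilinear transform all applied root by root — and
filtering applies $|H(\omega)|^2$ (the forward-backward response: exactly
zero phase, twice the stop-band attenuation) in the frequency domain with
odd-reflection padding.  `multitaper_samples()` tapers non-overlapping
1-second windows with 3 Slepian tapers (time-bandwidth 2; the published
pipeline does not state taper parameters, and no window overlap is
assumed), averages the complex eigencoefficients across tapers, and
returns per-integer-frequency sample matrices; `fit_bands()` runs `agl()`
independently at every integer frequency of each band and reports at how
many frequencies the constraint was informative, and `assign_max_band()`
labels each edge with the band of its largest mean partial-coherence
magnitude (ties toward the lower-frequency band).

## Numerical choices and defaults

| parameter | default | role |
|---|---|---|
| `k_ensembles` | 4 | contiguous CV ensembles |
| `nlambda` | 8 (6 at connectome scale) | grid size per penalty level |
| grid range | $[0.01, 1] \cdot \lambda_{\max}$ | ensemble-anchored, log-spaced |
| `zero_tol` | $10^{-6}$ | relative support threshold |
| `delta_factor` | $10^{-3}$ | refit ridge, times $\max_{j<k}\lvert\Theta_{jk}\rvert$ |
| `tol` | $10^{-4}$ | objective-decrease stopping rule |
| `weight_mean`, `weight_sd` | 100, 30 | generative edge weights |
| `phase_mean`, `phase_sd` | $\pi/2$, 0.25 | generative edge phases |
| `snr_db` | 25 | source SNR in the leakage simulation |
| `n_boot`, `alpha` | 1000, 0.05 | bootstrap thresholding |

Iteration order over matrix entries is lexicographic and all randomness
derives from one master seed through a counter-based splitter
(`derive_seed()`), so every fit and every simulation is bit-reproducible.

Problem sizes used by the heavy experiment drivers: the five-node
experiments run their full 200 iterations; the connectome-scale
experiment runs 10 iterations on a 6-point grid (its published
counterpart used 200 iterations on an unstated grid); the
misspecification and method-ordering properties are checked on 16-node,
32-edge networks at 480 samples, where the per-edge signal is comfortably
above the ensemble noise floor.

## Known limitations

* The uniform random surrogate for the structural connectome produces
  near-constant degrees and therefore uniformly weak partial coherences
  at connectome scale (see above); realistic degree-heterogeneous
  hypotheses behave qualitatively better.
* The bootstrap retention rule for complex coherence is an interpretation
  of an ill-posed published criterion.
* Weighted (non-binary) constraints are deliberately out of scope: the
  penalty takes exactly two levels.
* The spectral front end assumes stationarity within 1-second windows and
  does not implement artifact handling beyond band-pass filtering.
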