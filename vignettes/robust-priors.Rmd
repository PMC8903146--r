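---
title: "Penalized regression with heuristic and beta-series priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized regression with heuristic and beta-series priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heuridge)
```

## The model

Ridge regression shrinks coefficients toward the origin, but zero
association is rarely a sensible prior belief. `heuridge` implements the
generalized form in which the penalty pulls the weights toward an
arbitrary target vector $w_{\mathrm{prior}}$:

$$\hat w = \arg\min_w \; \|y - Xw\|_2^2 + \theta\,\|w - w_{\mathrm{prior}}\|_2^2 .$$

The solution is available in closed form,
$\hat w = (X^\top X + \theta I)^{-1}(X^\top y + \theta\, w_{\mathrm{prior}})$.
At $\theta = 0$ the model is ordinary least squares; as
$\theta \to \infty$ it converges to the prior itself. The same idea
carries over to classification through a penalized logistic likelihood,
$\max_w \log \Pr[y \mid X, w] - \tfrac{\theta}{2}\|w - w_{\mathrm{prior}}\|_2^2$,
solved by damped Newton–Raphson (`logistic_ridge_fit`).

The scientific payoff comes from choosing $w_{\mathrm{prior}}$ as the
point estimate of a *constrained* model, so that the penalty path
interpolates between a simple, robust model and a flexible,
covariance-sensitive one:

* **TAL (tallying) prior.** Cue validities
  $\hat v_j = (R_j - W_j)/(R_j + W_j)$ are estimated per cue on the
  training set, giving directions $\hat q_j = \mathrm{sign}(\hat v_j)$.
  A single shared scalar is then fit by least squares with the weight
  vector constrained to $\hat q\,w$, and
  $w_{\mathrm{TAL}} = \hat q\,\hat w_{\mathrm{scale}}$: an equal-weights,
  fully compensatory prior.
* **TTB (take-the-best) prior.** The design is first rescaled column-wise
  by $\phi^{\hat r_j}$ with $\phi = 2$, where $\hat r_j$ are the ascending
  ranks of $|\hat v_j|$ (ties share a rank). The shared scalar is fit in
  that space, so equal weights there correspond to a geometric,
  non-compensatory weighting of the original cues — the regression
  analogue of deciding by the single best discriminating cue. With
  $\phi = 1$ the TAL prior is recovered exactly.
* **Permuted-OLS prior.** A control: the OLS solution with entries
  randomly permuted. Non-zero, but carrying no cue-specific information.
* **LSS prior (fMRI).** For beta-series estimation the constrained model
  is least-squares-separate: one two-regressor GLM per trial. Its trial
  weights serve as the prior for a ridge fit on the full
  one-regressor-per-trial (LSA) design, giving a continuum from LSA
  ($\theta = 0$) to LSS ($\theta \to \infty$) (`fit_lss_prior`).

## Data coding

Decision tasks are coded the standard way for paired comparison:
attributes are dichotomized by median split (strictly above the median
→ 1, ties at the median → 0; we apply the tie rule uniformly in both
the binary and ternary schemes for consistency), and every pair of
objects with unequal criterion values becomes one row of signed
attribute differences in $\{-1, 0, +1\}$, with $y = +1$ when the
right-hand object has the larger criterion. Criterion-tied pairs are
undefined under this coding and are dropped (their count is recorded on
the dataset object). The left/right orientation of each pair is
randomized under the split seed so the two outcome classes are balanced
in expectation; the orientation convention does not affect any model
because the coding is antisymmetric. Classification tasks use the
ternary median-split coding directly with labels in $\{-1, +1\}$ and no
pairwise construction. Rows with missing values are removed listwise
before any coding.

No intercept is fit anywhere: paired-comparison rows are antisymmetric
by construction, and the ternary classification coding is centered, so
an intercept would absorb nothing systematic.

## The synthetic task generator

`generate_synthetic_task()` emulates the shape of the classical
multi-cue benchmark datasets: $N$ objects, $m$ standard-normal
attributes, and a linear criterion $\sum_j \beta_j x_j + \varepsilon$.
The weight profile controls compensatoriness — equal $|\beta|$
(compensatory), $|\beta_j| \propto 2^j$ (non-compensatory), or random
log-spaced magnitudes (mixed) — with random signs. The default noise
level `noise_sd = 0.5` was chosen once so that heuristic test accuracies
fall in the 0.65–0.85 band typical of the real benchmark datasets; the
defaults `m = 5`, `N = 60` give about 1,770 comparison pairs, training
sets of 50 pairs, and the rest as test — the training size standard in
this literature's model comparisons.

What the generator deliberately does not emulate: real benchmark
datasets have correlated, non-Gaussian attributes, heterogeneous cue
validities driven by domain structure, and occasionally near-constant
cues. Passing tests on synthetic tasks therefore demonstrate the
*mechanics* of the continuum (endpoint equivalences, robustness,
entropy ordering), not performance claims about any real domain.

## The compensatoriness diagnostic

`normalized_entropy()` measures how evenly predictive force is spread
across cues:
$$\tilde H = \frac{-\sum_j \tilde w_j \log_2 \tilde w_j}{\log_2 m},
\qquad \tilde w_j = \frac{|\hat w_j|}{\|\hat w\|_1\,\phi^{\hat r_j}},$$
with $0\log 0 := 0$, $\phi = 1$ for zero- and TAL-prior weights and
$\phi = 2$ for TTB-prior weights (evaluated in the transformed space, so
the TTB prior's equal-magnitude solution scores below 1, as it should
for a non-compensatory strategy). For $\phi > 1$ the $\tilde w_j$ are
deliberately sub-normalized — we implement the definition literally and
expose `renormalize = TRUE` for the variant that rescales them to a
probability vector first. An all-zero weight vector has no defined
entropy and returns `NA` with a warning.

## Penalty sweeps and the $\theta$ grid

`run_sweep()` repeats, per iteration: split, fit the heuristic and all
priors on the training rows, solve every family at every penalty,
record test accuracy and entropy. The default grid is $\{0\}$, thirty
log-spaced values in $[10^{-2}, 10^6]$, **and $\theta = \infty$**. The
infinite endpoint evaluates the limiting model exactly
(`ridge_fit(..., Inf)` returns the prior): the continuum's endpoints —
OLS on one side, the prior (heuristic, or the zero vector) on the other
— are part of the model family being swept. This matters for the
zero-prior model: the sign classifier $\mathrm{sign}(Xw)$ is invariant
to positive rescaling of $w$, so at any *finite* penalty standard ridge
still predicts like a (shrunken) correlation classifier; only the limit
produces the all-zero weight vector whose predictions are pure coin
flips. Including the endpoint makes "standard ridge collapses to chance
under strong penalties" a computable cell of the sweep rather than an
extrapolation.

Two solver engines are exposed: `engine = "linear"` (closed-form ridge
on $y \in \{-1,+1\}$, sign predictions; the default, exact and fast) and
`engine = "logistic"` (penalized logistic on 0/1 labels, probabilities
thresholded at 0.5). On ternary coded data the two give near-identical
choices; the linear engine is the default because its endpoint algebra
(OLS at $\theta=0$) is exact rather than iterative.

Ties — zero tallies in TAL, no discriminating cue in TTB, zero scores in
`predict_choice` — are resolved by a fair coin from a seeded stream, and
accuracy counts the realized draw rather than awarding 0.5 credit.
All randomness (splits, orientations, permutations, tie-breaks, noise)
derives from one master seed through `derive_seed()`, so every component
is independently reproducible.

## The fMRI simulation

`run_simulation_study()` builds event-related runs: `l = 40` trials (20
repetitions of each of 2 stimulus types), TR = 1 s, event duration
1.5 s, ISI ∈ {2, 3, 4} s, with $\lceil l/3 \rceil$ null epochs of one
trial duration randomly interleaved and 20 s of trailing scans for
response decay (the scan count is
$n = \lceil((l + \lceil l/3\rceil)(ED + ISI) + t_{\mathrm{end}})/TR\rceil$).
Regressors are event boxcars convolved with a canonical double-gamma
HRF (gamma shapes 6 and 16, rate 1, undershoot ratio 1/6, unit peak)
on a 0.05 s grid and sampled at scan times.

Ground truth for a $7^3$-voxel signal cluster: per-stimulus mean vectors
with i.i.d. $N(0, \sigma_\Psi^2)$ entries
($\sigma_\Psi^2 \in \{10, 15, 20\}$), voxel covariance drawn once per
iteration from a scaled Wishart $W(V, d^3)/d^3$ with unit diagonal and
0.7 off-diagonal $V$, one multivariate-normal weight row per trial, rows
permuted in time, and the cluster embedded at a uniform random corner
(coordinates 1–11) of a $21^3$ brain whose other voxels are silent. The
observed signal is $Y = X\Omega + E$ with scanner noise
$\varepsilon \sim N(0, 10^4)$ smoothed separably along all four axes
(FWHM 4 mm spatially at 3 × 3 × 3.75 mm voxels, 4.5 s temporally;
normalized kernel truncated at 4σ, reflecting boundaries, no variance
rescaling). Two independently randomized runs share the means,
covariance and corner; estimation and RMSE scoring are per run against
that run's weights, then averaged.

A caveat worth knowing: with a normalized Gaussian temporal kernel at
FWHM 4.5 s, the smoothed noise retains essentially no power at the high
frequencies where closely spaced trial regressors differ. The relative
standing of the joint estimator (LSA) versus the single-trial estimator
(LSS) is sensitive to exactly this part of the noise spectrum — under
temporally white noise the collinearity-driven variance inflation of
LSA dominates and LSS wins, while under strongly low-passed noise the
comparison tightens and can reverse. The acceptance suite computes both
estimators' errors under the smoothed-noise model at desk scale; see
the test output rather than this vignette for the numbers. The
LSS-prior continuum's central property — an intermediate penalty
beating both endpoints — is robust to this choice.

## Problem sizes

The shipped tests run the benchmark at desk scale, chosen as the sizes
at which every qualitative property is already stable: five synthetic
tasks × 100 iterations × a 15-value grid for the decision benchmark,
and one design cell (ISI 3 s, $\sigma_\Psi^2 = 15$) × 25 iterations × a
10-value grid for the imaging study. The full protocol (20 datasets or
9 design cells, 1000 iterations) is available by passing larger
arguments to `run_sweep()` / `run_simulation_study()`; nothing about
the code changes, only the loop sizes.

## Numerical choices and edge cases

* Rank-deficient designs: OLS uses the SVD pseudoinverse (minimum-norm
  solution); for $\theta > 0$ the penalized normal equations are
  nonsingular by construction.
* The shared-scalar prior fits are solved in closed form (a 1-D
  projection), not iteratively; the logistic scalar is maximized with
  Brent's method on $[-50, 50]$ — the bound handles complete separation,
  where the MLE diverges; hitting it is flagged in the prior's
  diagnostics.
* Newton–Raphson for the penalized logistic model initializes at the
  prior, halves steps that would decrease the objective, and stops at a
  gradient infinity-norm of $10^{-8}$; non-convergence is flagged, not
  fatal.
* $|\hat v|$ ties at the TTB decision cue are broken by the lowest
  column index; a cue with $\hat v = 0$ has direction 0, is inert in
  both heuristics, and contributes a zero prior entry.
* Constant attribute columns code to all-zero with a warning; a
  degenerate $X\hat q = 0$ yields a zero prior scale with a warning.
* Near-singular covariance draws are jittered by $10^{-8} I$ before the
  Cholesky factorization (logged).

## Known limitations

* The heuristic priors assume binary/ternary coded designs; continuous
  attributes would work mechanically but are untested territory here.
* The fMRI simulation omits real-data nuisances (drift, motion,
  physiological noise, autocorrelation whitening) by design; it isolates
  the estimator comparison.
* The entropy diagnostic is undefined for all-zero weight vectors and
  sub-normalized for $\phi > 1$ (see above).
* The per-observation weighting and matrix-penalty generalizations of
  the objective are out of scope; the `custom` prior family accepts any
  externally supplied target vector.
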