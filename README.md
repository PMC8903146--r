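# heuridge

Penalized regression that shrinks toward *non-zero* priors derived from
simple decision heuristics, with the full evaluation machinery around it.

## The problem

Ridge regression pulls coefficients toward the origin, which encodes the
prior belief that nothing predicts anything — rarely sensible. This
package implements the generalized ridge objective

    ŵ = argmin_w  ‖y − Xw‖² + θ‖w − w_prior‖²

(and its logistic counterpart, solved by Newton–Raphson), where
`w_prior` is the point estimate of a *constrained* model. The penalty
path then interpolates between a simple robust model (large θ) and the
flexible full-information fit (θ = 0 is OLS). Three prior constructions
are provided:

* **TAL (tallying)**: per-cue validities v̂ⱼ = (Rⱼ−Wⱼ)/(Rⱼ+Wⱼ) give
  directions q̂ = sign(v̂); a single shared scalar fitted by least squares
  yields an equal-weights, fully compensatory prior `q̂·ŵ_scale`.
* **TTB (take-the-best)**: the design is rescaled column-wise by
  `2^rank(|v̂|)` before fitting the shared scalar, so the prior encodes a
  geometric, non-compensatory cue hierarchy.
* **LSS (fMRI beta series)**: trial weights from least-squares-separate
  (one two-regressor GLM per trial) serve as the prior for ridge on the
  least-squares-all design, giving a continuum LSA ↔ LSS for
  single-trial activation estimation.

Supporting machinery: median-split coding and signed paired-comparison
construction for decision datasets, a seeded synthetic multi-cue task
generator, penalty sweeps over train/test iterations with a
normalized-entropy diagnostic of how compensatory the fitted weights
are, and a synthetic event-related BOLD simulation (double-gamma HRF,
Wishart-correlated ground-truth patterns, spatiotemporally smoothed
scanner noise) scoring LSA, LSS and the LSS-prior continuum by
trial-weight RMSE.

Intended users: decision scientists comparing heuristics with regression
models, and fMRI methodologists working with beta-series estimators.

## Worked example

```r
library(heuridge)

raw <- generate_synthetic_task(m = 5, N = 60,
                               validity_profile = "compensatory", seed = 42)
dd  <- make_paired_comparisons(median_split(raw, "binary"), raw$criterion,
                               seed = 43)
sw  <- run_sweep(dd, families = c("zero", "tal", "ttb"),
                 thetas = theta_grid(15), n_iterations = 50,
                 n_train = 50, seed = 1, include_heuristics = TRUE)
best_worst_summary(sw)
#>          family best_theta best_accuracy worst_theta worst_accuracy
#> 1          zero     0.0464         0.737         Inf          0.500
#> 2           tal     4.6416         0.738         Inf          0.703
#> 3           ttb     0.0000         0.737         Inf          0.709
#> 4 heuristic_tal         NA         0.703          NA          0.703
#> 5 heuristic_ttb         NA         0.709          NA          0.709
```

Read it as: at their best penalties all regression families perform
alike (~0.74 test accuracy). At their *worst* penalty, standard ridge
(`zero`) collapses to chance (0.500) — its θ→∞ limit is the all-zero
weight vector, whose sign predictions are coin flips — while the
heuristic-prior models degrade only to their heuristics' own accuracy
(0.703 / 0.709): the prior is a safety net. The entropy diagnostic
on the same sweep averages 0.925 (TAL-prior), 0.859 (zero-prior) and
0.505 (TTB-prior), ordering the families by how compensatory their
solutions are.

For the imaging side:

```r
res <- run_simulation_study(isi = 3, sigma_psi2 = 15,
                            thetas = theta_grid(10, 1e-1, 1e4),
                            n_iterations = 25, seed = 7)
study_means(res)
```

returns the iteration-averaged trial-weight RMSE of LSA, LSS and the
LSS-prior model across the penalty grid; the LSS-prior curve dips below
both endpoint estimators at intermediate θ.

Config-driven runs (`run_from_config()`, YAML or JSON; see
`validate_config()`) write tidy CSVs, a JSON summary and a manifest;
`inst/cli/heuridge.R` is a thin shell wrapper with `decide`,
`classify`, `fmri-sim` and `generate` subcommands.

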