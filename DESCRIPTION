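Package: heuridge
Title: Penalized Regression with Heuristic and Beta-Series Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generalized ridge and logistic-ridge regression that shrinks
    coefficients toward non-zero target vectors ("priors") instead of the
    origin. Priors are constructed from simple decision heuristics --
    tallying (TAL) and take-the-best (TTB) -- fitted via cue validities on
    ternary paired-comparison data, and, for fMRI beta-series estimation,
    from the least-squares-separate (LSS) single-trial estimator. Includes
    the surrounding evaluation machinery: median-split coding of decision
    and classification datasets, pairwise-comparison construction, penalty
    sweeps over train/test iterations, a normalized Shannon entropy
    diagnostic of how compensatory a weight vector is, and a synthetic
    event-related BOLD simulation comparing LSA, LSS and the LSS-prior
    continuum by trial-weight recovery error.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
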