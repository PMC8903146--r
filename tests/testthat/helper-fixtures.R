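# Small in-code fixtures shared across test files.

# a paired-comparison dataset from a seeded synthetic task
make_test_decision_data <- function(m = 5, N = 40, seed = 11,
                                    profile = "compensatory",
                                    noise_sd = 0.5) {
  raw <- generate_synthetic_task(m = m, N = N, validity_profile = profile,
                                 noise_sd = noise_sd, seed = seed)
  coded <- median_split(raw, "binary")
  make_paired_comparisons(coded, raw$criterion, seed = seed + 1)
}

# a heuristic_model with chosen validities (predict_* only touch these fields)
mock_heuristic <- function(v) {
  structure(
    list(validities = v, directions = as.integer(sign(v)),
         ranks = vapply(seq_along(v), function(j) sum(abs(v) < abs(v[j])),
                        integer(1)),
         R = integer(length(v)), W = integer(length(v))),
    class = "heuristic_model"
  )
}

# brute-force ridge objective for oracle comparisons
ridge_objective <- function(w, X, y, theta, w_prior) {
  sum((y - X %*% w)^2) + theta * sum((w - w_prior)^2)
}

logistic_penalized_objective <- function(w, X, y01, theta, w_prior) {
  eta <- drop(X %*% w)
  ll <- sum(y01 * eta - ifelse(eta > 33, eta, log1p(exp(eta))))
  ll - theta / 2 * sum((w - w_prior)^2)
}
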