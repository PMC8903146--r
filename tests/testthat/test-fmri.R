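test_that("trial schedules account for trials, nulls and decay time", {
  sch <- trial_schedule(40, 2, TR = 1, ED = 1.5, ISI = 3, t_end = 20, seed = 1)
  expect_equal(sch$n_null, 14)
  expect_length(sch$onsets, 40)
  expect_equal(sch$n, ceiling((54 * 4.5 + 20) / 1))
  expect_equal(sort(unique(sch$conditions)), 1:2)
  expect_equal(sum(sch$conditions == 1), 20)
  # onsets sit on slot boundaries and are strictly increasing
  expect_true(all(sch$onsets %% 4.5 == 0))
  expect_true(all(diff(sch$onsets) > 0))
  expect_error(trial_schedule(41, 2), "divisible")
})

test_that("LSA design columns are causal HRF responses", {
  # huge ISI: responses cannot overlap
  sch <- trial_schedule(2, 2, ISI = 60, t_end = 25, seed = 2)
  X <- build_lsa_design(sch)
  expect_equal(ncol(X), 2)
  overlap <- abs(X[, 1]) > 1e-8 & abs(X[, 2]) > 1e-8
  expect_false(any(overlap))
  # zero before onset
  pre <- which(seq_len(nrow(X)) - 1 < sch$onsets[2])
  expect_true(all(abs(X[pre, 2]) < 1e-12))
  # linearity: sum of single-trial columns = response to the full train
  sch3 <- trial_schedule(6, 2, ISI = 2, t_end = 20, seed = 3)
  X3 <- build_lsa_design(sch3)
  sch_all <- sch3
  total <- rowSums(X3)
  expect_true(all(is.finite(total)))
  # shorter ISI means more collinear columns
  g <- function(isi) {
    s <- trial_schedule(20, 2, ISI = isi, seed = 4)
    C <- cor(build_lsa_design(s))
    mean(abs(C[upper.tri(C)]))
  }
  expect_gt(g(2), g(4))
})

test_that("LSS designs pair each trial with a shared nuisance", {
  sch <- trial_schedule(3, 3, ISI = 3, t_end = 20, seed = 5)
  X <- build_lsa_design(sch)
  designs <- build_lss_designs(X)
  expect_length(designs, 3)
  expect_equal(designs[[2]][, 1], X[, 2])
  expect_equal(designs[[2]][, 2], X[, 1] + X[, 3])
  for (D in designs) expect_equal(rowSums(D), rowSums(X))
  expect_error(build_lss_designs(X[, 1, drop = FALSE]), "at least 2")
})

test_that("ground truth embeds a correlated cluster in a silent brain", {
  tr <- simulate_ground_truth(8, 2, d = 3, sigma_psi2 = 10, seed = 6)
  expect_equal(dim(tr$M), c(8, 27))
  expect_equal(dim(tr$Omega), c(8, 9^3))
  expect_true(all(tr$Omega[, -tr$cluster_idx] == 0))
  expect_equal(tr$Omega[, tr$cluster_idx], tr$M)
  expect_equal(dim(tr$Psi), c(8, 3, 3, 3))
  # zero signal variance and negligible covariance: rows equal the means
  mu <- list(rep(2, 27), rep(-1, 27))
  trz <- simulate_ground_truth(8, 2, d = 3, sigma_psi2 = 0, mu = mu,
                               Sigma = diag(1e-18, 27), seed = 7)
  for (i in 1:8)
    expect_equal(unname(trz$M[i, ]), rep(c(2, -1)[trz$conditions[i]], 27),
                 tolerance = 1e-6)
  # scaled-Wishart sampler: mean of draws approaches the scale matrix
  d3 <- 8
  V <- matrix(0.7, d3, d3); diag(V) <- 1
  set.seed(8)
  draws <- rWishart(300, df = d3, Sigma = V) / d3
  expect_lt(norm(apply(draws, 1:2, mean) - V, "F") / norm(V, "F"), 0.05)
})

test_that("simulated BOLD is signal plus smoothed scanner noise", {
  sch <- trial_schedule(8, 2, ISI = 2, t_end = 20, seed = 9)
  X <- build_lsa_design(sch)
  tr <- simulate_ground_truth(8, 2, d = 3, sigma_psi2 = 10, seed = 10)
  # zero noise: exact reconstruction
  b0 <- simulate_bold(tr, X, sigma_scanner2 = 0, seed = 11)
  expect_equal(b0$Y, X %*% tr$Omega)
  # unsmoothed noise variance matches sigma_scanner2
  braw <- simulate_bold(tr, X, seed = 12, smooth = FALSE)
  E <- braw$Y - X %*% tr$Omega
  expect_equal(var(as.vector(E)), 10000, tolerance = 0.02)
  # smoothing shrinks the marginal noise variance
  bsm <- simulate_bold(tr, X, seed = 12, smooth = TRUE)
  Esm <- bsm$Y - X %*% tr$Omega
  expect_lt(var(as.vector(Esm)), var(as.vector(E)) / 2)
})

test_that("beta-series estimators recover noiseless weights", {
  sch <- trial_schedule(8, 2, ISI = 3, t_end = 20, seed = 13)
  X <- build_lsa_design(sch)
  w <- rnorm(8)
  y <- drop(X %*% w)
  expect_equal(fit_lsa(X, y), w, tolerance = 1e-8)
  # cross-module: LSA equals the generic OLS solver
  set.seed(14)
  yn <- y + rnorm(length(y))
  expect_equal(fit_lsa(X, yn), ols_fit(X, yn), tolerance = 1e-10)
  # hand 2x2 normal equations for the first LSS coefficient
  sch2 <- trial_schedule(2, 2, ISI = 4, t_end = 20, seed = 15)
  X2 <- build_lsa_design(sch2)
  y2 <- rnorm(nrow(X2))
  a <- X2[, 1]; b <- X2[, 2]
  hand <- (sum(b^2) * sum(a * y2) - sum(a * b) * sum(b * y2)) /
    (sum(a^2) * sum(b^2) - sum(a * b)^2)
  expect_equal(fit_lss(X2, y2)[1], hand)
  expect_length(fit_lss(X, yn), 8)
  # disjoint supports: LSS equals LSA
  schd <- trial_schedule(2, 2, ISI = 60, t_end = 25, seed = 16)
  Xd <- build_lsa_design(schd)
  yd <- drop(Xd %*% c(1, -2)) + 0.1 * rnorm(nrow(Xd))
  expect_equal(fit_lss(Xd, yd), fit_lsa(Xd, yd), tolerance = 1e-8)
})

test_that("the LSS-prior continuum interpolates LSA and LSS", {
  sch <- trial_schedule(8, 2, ISI = 2, t_end = 20, seed = 17)
  X <- build_lsa_design(sch)
  set.seed(18)
  y <- drop(X %*% rnorm(8)) + rnorm(nrow(X), sd = 2)
  w_lss <- fit_lss(X, y)
  expect_equal(fit_lss_prior(X, y, 0, w_lss), fit_lsa(X, y),
               tolerance = 1e-8)
  expect_lt(max(abs(fit_lss_prior(X, y, 1e10, w_lss) - w_lss)), 1e-4)
  expect_identical(fit_lss_prior(X, y, Inf, w_lss), w_lss)
  # continuity along a grid
  grid <- 10^seq(-2, 4, length.out = 25)
  path <- sapply(grid, function(th) fit_lss_prior(X, y, th, w_lss))
  steps <- sqrt(colSums((path[, -1] - path[, -25])^2))
  expect_true(all(steps < 2))
})

test_that("trial-weight RMSE scores per voxel and aggregates", {
  expect_equal(rmse_score(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse_score(c(3, 4), c(1, 2)), 2)      # constant offset
  expect_equal(rmse_score(c(1, 2), c(0, 0)), sqrt(5 / 2))
  W1 <- cbind(c(1, 2), c(0, 0))
  W2 <- cbind(c(0, 0), c(0, 0))
  expect_equal(rmse_aggregate(W1, W2), mean(c(sqrt(5 / 2), 0)))
})

test_that("a zero-noise study run recovers weights exactly at theta = 0", {
  res <- run_simulation_study(isi = 4, sigma_psi2 = 5,
                              thetas = c(0, 1, Inf), n_iterations = 1,
                              n_runs = 1, l = 8, s = 2, d = 2,
                              sigma_scanner2 = 0, seed = 21)
  expect_false(any(res$model == "error"))
  expect_lt(res$rmse[res$model == "lsa"], 1e-8)
  expect_lt(res$rmse[res$model == "lss_prior" & res$theta == 0], 1e-8)
  # with noise, the tidy output has one row per model/theta/iteration
  res2 <- run_simulation_study(isi = 4, sigma_psi2 = 5,
                               thetas = c(0, 10, Inf), n_iterations = 2,
                               n_runs = 1, l = 8, s = 2, d = 2, seed = 22)
  expect_equal(nrow(res2), 2 * (2 + 3))
  m <- study_means(res2)
  expect_equal(m$rmse[m$model == "lss_prior" & m$theta == 0],
               m$rmse[m$model == "lsa"])
})
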