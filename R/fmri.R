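#' Event-related trial schedule
#'
#' Serializes `n_trials` stimulus presentations (equally many per
#' stimulus type, order randomized) interleaved with `ceiling(n_trials/3)`
#' null epochs of the same duration, placed uniformly at random among the
#' slots. Each slot lasts `ED + ISI` seconds; scanning continues `t_end`
#' seconds past the last slot so the hemodynamic response can decay.
#'
#' @param n_trials number of trials (divisible by `n_stimuli`).
#' @param n_stimuli number of stimulus types.
#' @param TR repetition time (s) -- one scan per TR.
#' @param ED event (stimulus) duration (s).
#' @param ISI interstimulus interval (s).
#' @param t_end trailing scan time after the last slot (s).
#' @param seed integer seed (null-epoch placement, condition order).
#' @return object of class `trial_schedule` with onsets (s), per-trial
#'   condition labels, and the scan count `n`.
#' @export
trial_schedule <- function(n_trials = 40, n_stimuli = 2, TR = 1, ED = 1.5,
                           ISI = 3, t_end = 20, seed = 1L) {
  if (n_trials %% n_stimuli != 0)
    stop("`n_trials` must be divisible by `n_stimuli`")
  set.seed(as.integer(seed %% 2147483647))
  n_null <- ceiling(n_trials / 3)
  n_slots <- n_trials + n_null
  null_slots <- sort(sample.int(n_slots, n_null))
  trial_slots <- setdiff(seq_len(n_slots), null_slots)
  conditions <- sample(rep(seq_len(n_stimuli), n_trials / n_stimuli))
  slot_dur <- ED + ISI
  onsets <- (trial_slots - 1) * slot_dur
  n <- ceiling((n_slots * slot_dur + t_end) / TR)
  structure(
    list(n_trials = n_trials, n_stimuli = n_stimuli, conditions = conditions,
         TR = TR, ED = ED, ISI = ISI, t_end = t_end, onsets = onsets,
         n_null = n_null, n = n),
    class = "trial_schedule"
  )
}

#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities (shapes 6 and 16, rate 1) with a
#' 1/6 undershoot ratio, normalized to unit peak.
#'
#' @param t time points (s).
#' @param peak_shape,under_shape,rate,undershoot_ratio gamma parameters.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, under_shape = 16, rate = 1,
                             undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = rate) -
    undershoot_ratio * stats::dgamma(t, shape = under_shape, rate = rate)
  tt <- seq(0, 30, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak_shape, rate = rate) -
                undershoot_ratio * stats::dgamma(tt, shape = under_shape,
                                                 rate = rate))
  h / hmax
}

#' Single-trial (LSA) design matrix
#'
#' One column per trial: a boxcar of duration `ED` at the trial onset,
#' convolved with the double-gamma HRF on a fine grid and sampled at the
#' scan times. Columns are zero before their onsets.
#'
#' @param schedule a [trial_schedule()].
#' @param dt convolution grid step (s); must divide `TR` and the onsets.
#' @return `n x n_trials` design matrix.
#' @export
build_lsa_design <- function(schedule, dt = 0.05) {
  TR <- schedule$TR
  n <- schedule$n
  t_max <- n * TR
  t_fine <- seq(0, t_max + 32, by = dt)
  hrf <- hrf_double_gamma(t_fine[t_fine <= 32])
  scan_idx <- round((seq_len(n) - 1) * TR / dt) + 1
  X <- matrix(0, n, schedule$n_trials)
  for (k in seq_len(schedule$n_trials)) {
    box <- as.numeric(t_fine >= schedule$onsets[k] &
                        t_fine < schedule$onsets[k] + schedule$ED)
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(t_fine)]
    X[, k] <- conv[scan_idx] * dt
  }
  if (nrow(X) < ncol(X))
    stop("fewer scans than trials; schedule too short for this design")
  X
}

#' Per-trial two-regressor (LSS) designs
#'
#' For each trial k, the n x 2 design `[c_k, sum of all other columns]`:
#' the target trial plus one shared nuisance regressor for the rest.
#'
#' @param X_lsa the LSA design matrix (>= 2 columns).
#' @return list of `n x 2` matrices, one per trial.
#' @export
build_lss_designs <- function(X_lsa) {
  l <- ncol(X_lsa)
  if (l < 2) stop("need at least 2 trials")
  total <- rowSums(X_lsa)
  lapply(seq_len(l), function(k) cbind(X_lsa[, k], total - X_lsa[, k]))
}

#' Ground-truth trial weights for a signal cluster
#'
#' Draws the trial-by-voxel weight matrix M for a `d x d x d` cluster of
#' task-sensitive voxels: per-stimulus mean vectors with i.i.d.
#' `N(0, sigma_psi2)` entries, a shared voxel covariance from a scaled
#' Wishart `W(V, d^3)/d^3` with `V = 0.7` off-diagonal and unit diagonal,
#' one multivariate-normal row per trial, rows permuted along the
#' temporal dimension. M is embedded at a random corner of the
#' `3d`-per-side brain as Omega (zeros outside the cluster).
#'
#' @param l number of trials.
#' @param s number of stimulus types (`l` divisible by `s`).
#' @param d cluster side length (7 in the full-scale study).
#' @param sigma_psi2 variance of the mean-vector entries (SNR level).
#' @param mu optional list of `s` mean vectors (length `d^3`) to reuse
#'   across runs; drawn if `NULL`.
#' @param Sigma optional `d^3 x d^3` covariance to reuse across runs.
#' @param corner optional length-3 corner coordinate (1-based); drawn
#'   uniformly from `{1, ..., 11}` per axis if `NULL` (`d = 7` brain).
#' @param seed integer seed.
#' @return object of class `fmri_truth`: `M` (l x d^3), `Psi`
#'   (l,d,d,d), `Omega` as an `l x (3d)^3` matrix, cluster voxel column
#'   indices `cluster_idx`, plus `mu`, `Sigma`, `corner`, `conditions`.
#' @export
simulate_ground_truth <- function(l, s = 2, d = 7, sigma_psi2 = 15,
                                  mu = NULL, Sigma = NULL, corner = NULL,
                                  seed = 1L) {
  stopifnot(d >= 1, l %% s == 0)
  set.seed(as.integer(seed %% 2147483647))
  d3 <- d^3
  D <- 3 * d
  if (is.null(mu))
    mu <- lapply(seq_len(s), function(i) stats::rnorm(d3, 0, sqrt(sigma_psi2)))
  if (is.null(Sigma)) {
    V <- matrix(0.7, d3, d3)
    diag(V) <- 1
    Sigma <- stats::rWishart(1, df = d3, Sigma = V)[, , 1] / d3
  }
  Lc <- tryCatch(chol(Sigma), error = function(e) {
    message("covariance not numerically positive definite; jittering")
    chol(Sigma + 1e-8 * diag(d3))
  })
  if (is.null(corner)) corner <- sample.int(min(11, D - d + 1), 3,
                                            replace = TRUE)
  conditions0 <- rep(seq_len(s), each = l / s)
  Z <- matrix(stats::rnorm(l * d3), l, d3)
  M <- Z %*% Lc
  for (i in seq_len(l)) M[i, ] <- M[i, ] + mu[[conditions0[i]]]
  perm <- sample.int(l)
  M <- M[perm, , drop = FALSE]
  conditions <- conditions0[perm]
  # embed the cluster into the brain (column-major voxel order x,y,z)
  brain_dim <- c(D, D, D)
  xs <- corner[1]:(corner[1] + d - 1)
  ys <- corner[2]:(corner[2] + d - 1)
  zs <- corner[3]:(corner[3] + d - 1)
  grid <- expand.grid(x = xs, y = ys, z = zs)
  cluster_idx <- grid$x + (grid$y - 1) * D + (grid$z - 1) * D * D
  Omega <- matrix(0, l, D^3)
  Omega[, cluster_idx] <- M
  Psi <- array(M, dim = c(l, d, d, d))
  structure(
    list(M = M, Psi = Psi, Omega = Omega, cluster_idx = cluster_idx,
         mu = mu, Sigma = Sigma, corner = corner, conditions = conditions,
         d = d, brain_dim = brain_dim),
    class = "fmri_truth"
  )
}

# 1-D Gaussian smoothing matrix with reflect boundary, 4-sigma truncation
smoothing_matrix <- function(L, sigma, trunc = 4) {
  if (sigma <= 0) return(diag(L))
  h <- max(1L, ceiling(trunc * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (o in -h:h) {
      j <- i + o
      if (j < 1) j <- 2 - j          # reflect
      if (j > L) j <- 2 * L - j
      j <- min(max(j, 1L), L)
      K[i, j] <- K[i, j] + k[o + h + 1]
    }
  }
  K
}

# multiply smoothing matrix along axis `axis` of a 4-D array
smooth_axis <- function(A, K, axis) {
  dm <- dim(A)
  perm <- c(axis, setdiff(seq_along(dm), axis))
  B <- aperm(A, perm)
  dB <- dim(B)
  B <- K %*% matrix(B, nrow = dB[1])
  dim(B) <- dB
  aperm(B, order(perm))
}

#' Simulate observed BOLD data
#'
#' `Y = X_lsa Omega + E`, with scanner noise `E` drawn i.i.d.
#' `N(0, sigma_scanner2)` per scan and voxel and then smoothed along all
#' four axes with a separable Gaussian kernel: FWHM `fwhm_mm` in each
#' spatial axis (converted to voxel units via the voxel size) and
#' `fwhm_s` temporally (in scans via `TR`). No post-smoothing variance
#' rescaling is applied.
#'
#' @param truth an [simulate_ground_truth()] result.
#' @param X_lsa LSA design matrix (`n` rows, `l` columns).
#' @param sigma_scanner2 scanner noise variance (default 10000).
#' @param fwhm_mm spatial FWHM (mm).
#' @param fwhm_s temporal FWHM (s).
#' @param voxel_mm voxel size per spatial axis (mm).
#' @param TR repetition time (s).
#' @param seed integer seed.
#' @param smooth set `FALSE` to skip smoothing (diagnostics).
#' @return object of class `bold_data`: `Y` (`n x (3d)^3` matrix),
#'   `brain_dim`, and the noise parameters.
#' @export
simulate_bold <- function(truth, X_lsa, sigma_scanner2 = 10000,
                          fwhm_mm = 4, fwhm_s = 4.5,
                          voxel_mm = c(3, 3, 3.75), TR = 1, seed = 1L,
                          smooth = TRUE) {
  n <- nrow(X_lsa)
  if (ncol(X_lsa) != nrow(truth$Omega))
    stop("design/truth trial-count mismatch")
  D <- truth$brain_dim[1]
  set.seed(as.integer(seed %% 2147483647))
  V <- D^3
  E <- array(stats::rnorm(n * V, 0, sqrt(sigma_scanner2)), dim = c(n, D, D, D))
  if (smooth && sigma_scanner2 > 0) {
    fwhm2sigma <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548
    sig_sp <- fwhm_mm * fwhm2sigma / voxel_mm
    sig_t <- fwhm_s * fwhm2sigma / TR
    E <- smooth_axis(E, smoothing_matrix(n, sig_t), 1)
    for (ax in 2:4)
      E <- smooth_axis(E, smoothing_matrix(D, sig_sp[ax - 1]), ax)
  }
  Y <- X_lsa %*% truth$Omega + matrix(E, nrow = n)
  structure(
    list(Y = Y, brain_dim = truth$brain_dim, n = n,
         sigma_scanner2 = sigma_scanner2, fwhm_mm = fwhm_mm,
         fwhm_s = fwhm_s, voxel_mm = voxel_mm, TR = TR),
    class = "bold_data"
  )
}

#' Least-squares-all (LSA) trial weights
#'
#' One GLM with one regressor per trial; ordinary least squares,
#' column-wise over voxels. Falls back to the pseudoinverse (flagged
#' with a warning) if the design is rank deficient.
#'
#' @param X_lsa design matrix.
#' @param Y voxel time series: a vector or an `n x V` matrix.
#' @return `l x V` weight matrix (or vector for vector input).
#' @export
fit_lsa <- function(X_lsa, Y) {
  Y <- as.matrix(Y)
  qx <- qr(X_lsa)
  if (qx$rank < ncol(X_lsa)) {
    warning("rank-deficient LSA design; using pseudoinverse", call. = FALSE)
    W <- apply(Y, 2, function(y) ols_fit(X_lsa, y))
  } else {
    W <- qr.coef(qx, Y)
  }
  if (ncol(Y) == 1) drop(W) else W
}

#' Least-squares-separate (LSS) trial weights
#'
#' One two-regressor GLM per trial (target trial + shared nuisance);
#' each trial's weight is the first coefficient of its GLM. Solved from
#' the 2x2 normal equations, vectorized over voxels; near-singular
#' designs fall back to the pseudoinverse (flagged).
#'
#' @param designs list of `n x 2` designs from [build_lss_designs()],
#'   or the LSA design matrix itself (designs are built internally).
#' @param Y voxel time series: a vector or an `n x V` matrix.
#' @return `l x V` weight matrix (or vector for vector input).
#' @export
fit_lss <- function(designs, Y) {
  if (is.matrix(designs)) designs <- build_lss_designs(designs)
  Y <- as.matrix(Y)
  l <- length(designs)
  W <- matrix(NA_real_, l, ncol(Y))
  for (k in seq_len(l)) {
    a <- designs[[k]][, 1]
    b <- designs[[k]][, 2]
    aa <- sum(a * a); bb <- sum(b * b); ab <- sum(a * b)
    det <- aa * bb - ab * ab
    if (abs(det) < 1e-10 * max(aa * bb, 1)) {
      warning("near-collinear LSS design for trial ", k,
              "; using pseudoinverse", call. = FALSE)
      W[k, ] <- apply(Y, 2, function(y) ols_fit(designs[[k]], y)[1])
    } else {
      ay <- drop(crossprod(a, Y))
      by <- drop(crossprod(b, Y))
      W[k, ] <- (bb * ay - ab * by) / det
    }
  }
  if (ncol(Y) == 1) drop(W) else W
}

#' Penalized beta-series estimation with the LSS prior
#'
#' Ridge regression on the LSA design shrinking toward the LSS
#' estimates: `argmin_w ||y - X_lsa w||^2 + theta ||w - w_lss||^2`.
#' `theta = 0` equals LSA; `theta = Inf` returns the LSS estimates;
#' intermediate penalties interpolate the two estimators.
#'
#' @param X_lsa design matrix.
#' @param Y voxel time series: a vector or an `n x V` matrix.
#' @param theta penalty (`>= 0`, may be `Inf`).
#' @param W_lss LSS estimates (`l x V` matrix or length-l vector) used
#'   as the prior.
#' @return `l x V` weight matrix (or vector for vector input).
#' @export
fit_lss_prior <- function(X_lsa, Y, theta, W_lss) {
  Y <- as.matrix(Y)
  W_lss <- as.matrix(W_lss)
  if (is.infinite(theta)) {
    W <- W_lss
  } else if (theta == 0) {
    W <- fit_lsa(X_lsa, Y)
    W <- as.matrix(W)
  } else {
    A <- crossprod(X_lsa)
    diag(A) <- diag(A) + theta
    W <- solve(A, crossprod(X_lsa, Y) + theta * W_lss)
  }
  if (ncol(Y) == 1) drop(W) else W
}

#' Trial-weight recovery error
#'
#' Per voxel, the root mean squared error between estimated and true
#' trial weights; `rmse_aggregate` averages it over all signal voxels.
#'
#' @param W_hat estimated `l x V` weights (or vector).
#' @param W_true ground-truth weights of the same shape.
#' @return `rmse_score`: per-voxel RMSE vector. `rmse_aggregate`: scalar
#'   mean over voxels.
#' @export
rmse_score <- function(W_hat, W_true) {
  W_hat <- as.matrix(W_hat)
  W_true <- as.matrix(W_true)
  if (!all(dim(W_hat) == dim(W_true))) stop("dimension mismatch")
  sqrt(colMeans((W_hat - W_true)^2))
}

#' @rdname rmse_score
#' @export
rmse_aggregate <- function(W_hat, W_true) mean(rmse_score(W_hat, W_true))

#' Simulation study over the ISI-by-SNR design
#'
#' For each design cell (interstimulus interval x signal variance) and
#' iteration: draw the shared mean vectors, voxel covariance and effect
#' corner; simulate `n_runs` runs (independently randomized schedules
#' and designs); estimate the signal-cluster voxels per run with LSA,
#' LSS, and the LSS-prior model across the penalty grid; score each
#' estimate against that run's ground truth; and average over runs.
#'
#' @param isi vector of interstimulus intervals (s).
#' @param sigma_psi2 vector of signal variances (SNR levels).
#' @param thetas penalty grid for the LSS-prior model.
#' @param n_iterations iterations per design cell.
#' @param n_runs runs per iteration (default 2).
#' @param l trials per run (default 40 = 20 repetitions x 2 stimuli).
#' @param s stimulus types (default 2).
#' @param d signal-cluster side length (default 7).
#' @param sigma_scanner2 scanner noise variance (default 10000).
#' @param TR,ED,t_end schedule timing parameters (s).
#' @param seed master seed.
#' @return data frame of class `fmri_study`: one row per cell,
#'   iteration, model and penalty (`theta` is `NA` for plain LSA/LSS
#'   rows), with the run-averaged `rmse`.
#' @export
run_simulation_study <- function(isi = c(2, 3, 4),
                                 sigma_psi2 = c(10, 15, 20),
                                 thetas = theta_grid(10, 1e-1, 1e4),
                                 n_iterations = 25, n_runs = 2,
                                 l = 40, s = 2, d = 7,
                                 sigma_scanner2 = 10000,
                                 TR = 1, ED = 1.5, t_end = 20, seed = 1L) {
  stopifnot(length(isi) >= 1, length(sigma_psi2) >= 1, length(thetas) >= 1)
  rows <- list()
  for (ci in seq_along(isi)) for (cj in seq_along(sigma_psi2)) {
    for (it in seq_len(n_iterations)) {
      cell_seed <- derive_seed(seed, ci, cj, it)
      rec <- tryCatch(
        .simulate_one_iteration(isi[ci], sigma_psi2[cj], thetas, n_runs,
                                l, s, d, sigma_scanner2, TR, ED, t_end,
                                cell_seed),
        error = function(e) e)
      if (inherits(rec, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          isi = isi[ci], sigma_psi2 = sigma_psi2[cj], iteration = it,
          model = "error", theta = NA_real_, rmse = NA_real_,
          error = conditionMessage(rec))
        next
      }
      rec$isi <- isi[ci]
      rec$sigma_psi2 <- sigma_psi2[cj]
      rec$iteration <- it
      rec$error <- NA_character_
      rows[[length(rows) + 1L]] <- rec[, c("isi", "sigma_psi2", "iteration",
                                           "model", "theta", "rmse", "error")]
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "thetas") <- thetas
  class(out) <- c("fmri_study", class(out))
  out
}

.simulate_one_iteration <- function(isi, sigma_psi2, thetas, n_runs,
                                    l, s, d, sigma_scanner2, TR, ED, t_end,
                                    seed) {
  d3 <- d^3
  # shared across runs: mean vectors, covariance, effect corner
  set.seed(derive_seed(seed, 1L))
  mu <- lapply(seq_len(s), function(i) stats::rnorm(d3, 0, sqrt(sigma_psi2)))
  V <- matrix(0.7, d3, d3); diag(V) <- 1
  Sigma <- stats::rWishart(1, df = d3, Sigma = V)[, , 1] / d3
  corner <- sample.int(min(11, 3 * d - d + 1), 3, replace = TRUE)
  acc_lsa <- acc_lss <- 0
  acc_prior <- numeric(length(thetas))
  for (r in seq_len(n_runs)) {
    sch <- trial_schedule(l, s, TR = TR, ED = ED, ISI = isi, t_end = t_end,
                          seed = derive_seed(seed, 2L, r))
    X <- build_lsa_design(sch)
    truth <- simulate_ground_truth(l, s, d, sigma_psi2, mu = mu,
                                   Sigma = Sigma, corner = corner,
                                   seed = derive_seed(seed, 3L, r))
    bold <- simulate_bold(truth, X, sigma_scanner2 = sigma_scanner2,
                          TR = TR, seed = derive_seed(seed, 4L, r))
    Yc <- bold$Y[, truth$cluster_idx, drop = FALSE]
    # truth$M is l x d3 with trials as rows; estimators return the same shape
    W_lsa <- fit_lsa(X, Yc)
    designs <- build_lss_designs(X)
    W_lss <- fit_lss(designs, Yc)
    acc_lsa <- acc_lsa + rmse_aggregate(W_lsa, truth$M)
    acc_lss <- acc_lss + rmse_aggregate(W_lss, truth$M)
    XtX <- crossprod(X)
    XtY <- crossprod(X, Yc)
    for (ti in seq_along(thetas)) {
      th <- thetas[ti]
      W_th <- if (is.infinite(th)) W_lss
        else if (th == 0) W_lsa
        else {
          A <- XtX; diag(A) <- diag(A) + th
          solve(A, XtY + th * W_lss)
        }
      acc_prior[ti] <- acc_prior[ti] + rmse_aggregate(W_th, truth$M)
    }
  }
  data.frame(
    model = c("lsa", "lss", rep("lss_prior", length(thetas))),
    theta = c(NA_real_, NA_real_, thetas),
    rmse = c(acc_lsa, acc_lss, acc_prior) / n_runs
  )
}

#' Mean RMSE per cell, model and penalty
#' @param study an `fmri_study` result.
#' @return data frame of iteration-averaged RMSE with dispersion (sd).
#' @export
study_means <- function(study) {
  s <- study[study$model != "error", ]
  s$theta_key <- ifelse(is.na(s$theta), -1, s$theta)
  agg <- stats::aggregate(rmse ~ isi + sigma_psi2 + model + theta_key,
                          data = s, FUN = function(z)
                            c(mean = mean(z), sd = stats::sd(z)))
  out <- data.frame(agg[, 1:4], rmse = agg$rmse[, "mean"],
                    sd = agg$rmse[, "sd"])
  out$theta <- ifelse(out$theta_key < 0, NA_real_, out$theta_key)
  out$theta_key <- NULL
  out[order(out$isi, out$sigma_psi2, out$model, out$theta), ]
}
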