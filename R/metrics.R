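#' Classification / choice accuracy
#' @param pred predicted labels.
#' @param y true labels.
#' @return fraction of agreements.
#' @export
accuracy <- function(pred, y) {
  if (length(pred) != length(y)) stop("`pred` and `y` must have equal length")
  if (length(y) == 0) stop("empty vectors")
  mean(pred == y)
}

#' Normalized Shannon entropy of a weight vector
#'
#' Diagnoses how compensatory a solution is. Each weight is mapped to
#' `wt_j = |w_j| / (||w||_1 * phi^{r_j})` and the entropy
#' `-sum wt_j log2 wt_j` (with `0 log 0 := 0`) is divided by `log2 m`.
#' With `phi = 1` the `wt_j` sum to one and the measure lies in `[0, 1]`,
#' peaking at 1 when the predictive force of the weights is uniform
#' (fully compensatory) and 0 for a one-cue solution. With `phi = 2`
#' (the TTB-family reading, discounting each weight by its validity
#' rank) the `wt_j` are sub-normalized by construction; set
#' `renormalize = TRUE` to rescale them to a probability vector first.
#'
#' @param w fitted weight vector (not all zero).
#' @param ranks ascending validity ranks (default all zero).
#' @param phi geometric base: 1 for zero/TAL-family weights, 2 for TTB.
#' @param renormalize rescale the discounted weights to sum to one?
#' @return entropy value; `NA` (with a warning) for an all-zero `w`.
#' @export
normalized_entropy <- function(w, ranks = NULL, phi = 1, renormalize = FALSE) {
  m <- length(w)
  if (m < 2) stop("entropy needs at least 2 weights")
  if (is.null(ranks)) ranks <- rep(0, m)
  l1 <- sum(abs(w))
  if (l1 == 0) {
    warning("all-zero weight vector: entropy undefined", call. = FALSE)
    return(NA_real_)
  }
  wt <- abs(w) / (l1 * phi^ranks)
  if (renormalize) wt <- wt / sum(wt)
  nz <- wt > 0
  -sum(wt[nz] * log2(wt[nz])) / log2(m)
}

#' Default penalty grid
#'
#' `{0}` followed by log-spaced values and, by default, `Inf` as the
#' explicit limiting model (the prior itself). Including both endpoints
#' makes a sweep cover the full OLS-to-prior continuum.
#'
#' @param n total number of grid points.
#' @param min,max range of the log-spaced interior.
#' @param include_inf include the `Inf` endpoint?
#' @return numeric vector of penalties.
#' @export
theta_grid <- function(n = 32, min = 1e-2, max = 1e6, include_inf = TRUE) {
  n_int <- n - 1L - as.integer(include_inf)
  stopifnot(n_int >= 1)
  g <- c(0, 10^seq(log10(min), log10(max), length.out = n_int))
  if (include_inf) g <- c(g, Inf)
  g
}

# fit one family at one theta; returns list(fit, Xtest) in the right space
.fit_family <- function(family, theta, train, test, model, priors, engine) {
  prior <- priors[[family]]
  if (identical(prior$transform, "ttb")) {
    Xtr <- ttb_transform(train$X, prior$ranks, prior$phi)
    Xte <- ttb_transform(test$X, prior$ranks, prior$phi)
  } else {
    Xtr <- train$X
    Xte <- test$X
  }
  if (engine == "linear") {
    fit <- ridge_fit(Xtr, train$y, theta, prior)
    pred <- predict_choice(fit, Xte, task = "sign")
  } else {
    fit <- logistic_ridge_fit(Xtr, (train$y + 1) / 2, theta, prior)
    pred <- predict_choice(fit, Xte, task = "probability")
  }
  list(fit = fit, pred = pred)
}

.build_priors <- function(families, model, train, seed, engine, phi) {
  m <- ncol(train$X)
  y01 <- (train$y + 1) / 2
  priors <- list()
  for (fam in families) {
    priors[[fam]] <- switch(fam,
      zero = zero_prior(m),
      tal = if (engine == "logistic")
        fit_logistic_scale_prior(train$X, y01, model$directions)
      else tal_prior(model, train),
      ttb = if (engine == "logistic") {
        Xt <- ttb_transform(train$X, model$ranks, phi)
        fit_logistic_scale_prior(Xt, y01, model$directions,
                                 family = "logistic_ttb",
                                 phi = phi, ranks = model$ranks)
      } else ttb_prior(model, train, phi),
      ols_permuted = permuted_ols_prior(train$X, train$y, seed = seed),
      stop("unknown family: ", fam)
    )
  }
  priors
}

#' Penalty sweep over train/test iterations
#'
#' For each iteration: split the data, fit the heuristic and all priors
#' on the training rows, solve the penalized model for every family at
#' every penalty, and record test accuracy, the entropy diagnostic of
#' the fitted weights (with each family's `phi`: 2 for the TTB family,
#' 1 otherwise), and the prior scale. Optionally also records the raw
#' TAL/TTB heuristic accuracies on the same splits (`theta = NA` rows).
#'
#' @param data a `decision_dataset`.
#' @param families subset of `c("zero", "tal", "ttb", "ols_permuted")`.
#' @param thetas penalty grid (must contain 0; may contain `Inf`).
#' @param n_iterations number of train/test partitions.
#' @param n_train training rows per iteration.
#' @param seed master seed: splits, tie-breaks and permutations all
#'   derive from it.
#' @param engine `"linear"` (closed-form ridge on y in -1/+1, sign
#'   predictions) or `"logistic"` (penalized logistic on 0/1 labels,
#'   probability predictions).
#' @param phi geometric base of the TTB family.
#' @param include_heuristics add `heuristic_tal` / `heuristic_ttb` rows?
#' @return data frame of class `sweep_result` with columns `family`,
#'   `theta`, `iteration`, `accuracy`, `entropy`, `scale`.
#' @export
run_sweep <- function(data, families = c("zero", "tal", "ttb", "ols_permuted"),
                      thetas = theta_grid(), n_iterations = 100,
                      n_train = 50, seed = 1L,
                      engine = c("linear", "logistic"), phi = 2,
                      include_heuristics = FALSE) {
  engine <- match.arg(engine)
  if (length(thetas) == 0) stop("empty theta grid")
  if (!any(thetas == 0)) stop("theta grid must include 0")
  rows <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    sp <- split_train_test(data, n_train, seed = seed, iteration = it)
    model <- fit_heuristic(sp$train)
    priors <- .build_priors(families, model, sp$train,
                            seed = derive_seed(seed, it, 7L), engine, phi)
    set.seed(derive_seed(seed, it, 11L))  # tie-break stream
    recs <- list()
    for (fam in families) {
      fam_phi <- if (identical(priors[[fam]]$transform, "ttb")) phi else 1
      fam_ranks <- if (fam_phi > 1) model$ranks else NULL
      for (th in thetas) {
        res <- tryCatch(
          .fit_family(fam, th, sp$train, sp$test, model, priors, engine),
          error = function(e) e)
        if (inherits(res, "error")) {
          recs[[length(recs) + 1L]] <- data.frame(
            family = fam, theta = th, iteration = it,
            accuracy = NA_real_, entropy = NA_real_,
            scale = priors[[fam]]$scale, error = conditionMessage(res))
          next
        }
        ent <- if (sum(abs(res$fit$w)) == 0) NA_real_ else
          normalized_entropy(res$fit$w, ranks = fam_ranks, phi = fam_phi)
        recs[[length(recs) + 1L]] <- data.frame(
          family = fam, theta = th, iteration = it,
          accuracy = accuracy(res$pred, sp$test$y), entropy = ent,
          scale = priors[[fam]]$scale, error = NA_character_)
      }
    }
    if (include_heuristics) {
      recs[[length(recs) + 1L]] <- data.frame(
        family = "heuristic_tal", theta = NA_real_, iteration = it,
        accuracy = accuracy(predict_tal(model, sp$test$X), sp$test$y),
        entropy = NA_real_, scale = NA_real_, error = NA_character_)
      recs[[length(recs) + 1L]] <- data.frame(
        family = "heuristic_ttb", theta = NA_real_, iteration = it,
        accuracy = accuracy(predict_ttb(model, sp$test$X), sp$test$y),
        entropy = NA_real_, scale = NA_real_, error = NA_character_)
    }
    rows[[it]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  attr(out, "thetas") <- thetas
  attr(out, "n_iterations") <- n_iterations
  attr(out, "engine") <- engine
  class(out) <- c("sweep_result", class(out))
  out
}

#' Best/worst penalty summary
#'
#' Per family, the penalty maximizing and minimizing mean test accuracy
#' across iterations, with those means. Heuristic rows (no penalty) are
#' summarized by their single mean.
#'
#' @param sweep a `sweep_result`.
#' @return data frame with one row per family: `best_theta`,
#'   `best_accuracy`, `worst_theta`, `worst_accuracy`.
#' @export
best_worst_summary <- function(sweep) {
  if (nrow(sweep) == 0) stop("empty sweep")
  fams <- unique(sweep$family)
  out <- lapply(fams, function(fam) {
    s <- sweep[sweep$family == fam & !is.na(sweep$accuracy), ]
    if (all(is.na(s$theta))) {
      acc <- mean(s$accuracy)
      return(data.frame(family = fam, best_theta = NA_real_,
                        best_accuracy = acc, worst_theta = NA_real_,
                        worst_accuracy = acc))
    }
    means <- tapply(s$accuracy, s$theta, mean)
    ths <- as.numeric(names(means))
    data.frame(family = fam,
               best_theta = ths[which.max(means)],
               best_accuracy = max(means),
               worst_theta = ths[which.min(means)],
               worst_accuracy = min(means))
  })
  do.call(rbind, out)
}

#' Mean accuracy/entropy per family and penalty
#' @param sweep a `sweep_result`.
#' @return data frame with columns `family`, `theta`, `accuracy`, `entropy`.
#' @export
sweep_means <- function(sweep) {
  s <- sweep[!is.na(sweep$theta), ]
  acc <- stats::aggregate(accuracy ~ family + theta, data = s,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  ent <- stats::aggregate(entropy ~ family + theta, data = s,
                          FUN = function(z) mean(z, na.rm = TRUE),
                          na.action = NULL)
  agg <- merge(acc, ent, by = c("family", "theta"))
  agg[order(agg$family, agg$theta), ]
}
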