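#' Prior specification
#'
#' A prior weight vector together with the design transform it is valid
#' under. For the TTB family the transform is the geometric column
#' scaling `X -> X P` with `P = diag(phi^r)`; the fit must then be done
#' (and new data predicted) in the transformed space.
#'
#' @param w_prior length-m numeric prior weight vector.
#' @param family one of `"zero"`, `"tal"`, `"ttb"`, `"ols_permuted"`,
#'   `"logistic_tal"`, `"logistic_ttb"`, `"lss"`, `"custom"`.
#' @param scale fitted shared scalar (where applicable).
#' @param transform `"identity"` or `"ttb"`.
#' @param phi geometric base of the TTB transform.
#' @param ranks ascending validity ranks (TTB transform state).
#' @param diagnostics free-form list (e.g. `at_bound` for the logistic fit).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(w_prior, family = "custom", scale = NA_real_,
                       transform = "identity", phi = 1, ranks = NULL,
                       diagnostics = list()) {
  stopifnot(is.numeric(w_prior), all(is.finite(w_prior)))
  structure(
    list(w_prior = as.numeric(w_prior), family = family, scale = scale,
         transform = transform, phi = phi, ranks = ranks,
         diagnostics = diagnostics),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec family=%s transform=%s scale=%s>\n",
              x$family, x$transform, format(x$scale)))
  print(x$w_prior)
  invisible(x)
}

#' Zero prior (standard ridge)
#' @param m number of predictors.
#' @return a [prior_spec()] with `w_prior = 0`.
#' @export
zero_prior <- function(m) prior_spec(rep(0, m), family = "zero")

#' Geometric TTB design transform
#'
#' Scales column j of the design by `phi^r_j`, encoding the validity
#' ranking directly into the regressors as a geometric progression.
#' `phi = 1` returns the design unchanged (the TAL case).
#'
#' @param X design matrix.
#' @param ranks ascending ranks of absolute cue validities.
#' @param phi geometric base, `phi >= 1`.
#' @return transformed matrix with attribute `ttb_phi` recording the base.
#' @export
ttb_transform <- function(X, ranks, phi = 2) {
  stopifnot(phi >= 1, length(ranks) == ncol(X))
  out <- sweep(X, 2, phi^ranks, `*`)
  attr(out, "ttb_phi") <- phi
  out
}

#' Shared-scalar least-squares prior (TAL / TTB)
#'
#' Fits the single scalar `s` minimizing `||y - X_design (q s)||^2`, with
#' the weight vector constrained to the cue directions `q`. Solved in
#' closed form as the 1-D projection `s = (X q)' y / ||X q||^2`. With
#' `X_design = X` this is the TAL scale; with the [ttb_transform()]ed
#' design it is the TTB scale.
#'
#' @param X_design design matrix (possibly TTB-transformed).
#' @param y outcomes in \{-1, +1\}.
#' @param q cue directions (not all zero for a nonzero fit).
#' @param family prior family label.
#' @param phi,ranks transform state to record (TTB family).
#' @return a [prior_spec()] with `w_prior = q * s`.
#' @export
fit_scale_prior <- function(X_design, y, q, family = "tal",
                            phi = 1, ranks = NULL) {
  z <- drop(as.matrix(X_design) %*% q)
  denom <- sum(z^2)
  if (denom == 0) {
    warning("X_design %*% q is zero; prior scale set to 0", call. = FALSE)
    s <- 0
  } else {
    s <- sum(z * y) / denom
  }
  prior_spec(q * s, family = family, scale = s,
             transform = if (family == "ttb") "ttb" else "identity",
             phi = phi, ranks = ranks)
}

#' TAL prior from a fitted heuristic
#' @param model a `heuristic_model`.
#' @param train training `decision_dataset`.
#' @return a [prior_spec()] (family `"tal"`).
#' @export
tal_prior <- function(model, train) {
  fit_scale_prior(train$X, train$y, model$directions, family = "tal")
}

#' TTB prior from a fitted heuristic
#'
#' Fits the shared scalar on the geometrically transformed design
#' `X P`, `P = diag(phi^r)`; the returned spec carries the transform so
#' that ridge fits and predictions use the same space.
#'
#' @param model a `heuristic_model`.
#' @param train training `decision_dataset`.
#' @param phi geometric base (default 2).
#' @return a [prior_spec()] (family `"ttb"`).
#' @export
ttb_prior <- function(model, train, phi = 2) {
  Xt <- ttb_transform(train$X, model$ranks, phi)
  fit_scale_prior(Xt, train$y, model$directions, family = "ttb",
                  phi = phi, ranks = model$ranks)
}

#' Logistic shared-scalar prior
#'
#' Maximum-likelihood scalar for the logistic model with weights
#' constrained to `w q` (the direction vector), i.e. the 1-D problem
#' `max_w sum_i [y_i eta_i - log(1 + exp(eta_i))]` with `eta = X q w`.
#' The search is bounded to `|w| <= bound` to handle complete separation
#' (where the unconstrained MLE diverges); hitting the bound is flagged
#' in the diagnostics. The prior vector is `q |w|`.
#'
#' @param X design matrix.
#' @param y01 labels in \{0, 1\} (both classes present).
#' @param q cue directions.
#' @param bound box constraint on the scalar (default 50).
#' @param family prior family label.
#' @param phi,ranks transform state to record (TTB variant).
#' @return a [prior_spec()].
#' @export
fit_logistic_scale_prior <- function(X, y01, q, bound = 50,
                                     family = "logistic_tal",
                                     phi = 1, ranks = NULL) {
  if (length(unique(y01)) < 2) stop("both classes must be present in `y01`")
  stopifnot(all(y01 %in% c(0, 1)))
  z <- drop(as.matrix(X) %*% q)
  negll <- function(w) {
    eta <- z * w
    -sum(y01 * eta - log1pexp(eta))
  }
  opt <- stats::optimize(negll, interval = c(-bound, bound), tol = 1e-10)
  s <- opt$minimum
  at_bound <- abs(s) >= bound - 1e-4
  if (at_bound) s <- sign(s) * bound
  prior_spec(q * abs(s), family = family, scale = abs(s),
             transform = if (grepl("ttb", family)) "ttb" else "identity",
             phi = phi, ranks = ranks,
             diagnostics = list(at_bound = at_bound, negll = opt$objective))
}

#' Permuted-OLS control prior
#'
#' A non-zero but uninformative control: the OLS solution with its
#' entries randomly permuted (seeded). Keeps the magnitude profile of
#' OLS while destroying the cue-to-weight assignment.
#'
#' @param X design matrix.
#' @param y outcomes.
#' @param seed integer seed for the permutation.
#' @return a [prior_spec()] (family `"ols_permuted"`).
#' @export
permuted_ols_prior <- function(X, y, seed = 1L) {
  w <- ols_fit(X, y)
  set.seed(as.integer(seed %% 2147483647))
  prior_spec(sample(w), family = "ols_permuted")
}

#' Serialize a prior (and optionally its heuristic) to JSON
#' @param prior a [prior_spec()].
#' @param model optional `heuristic_model` to bundle.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
prior_to_json <- function(prior, model = NULL, path = NULL) {
  obj <- unclass(prior)
  if (!is.null(model)) obj$heuristic <- unclass(model)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
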