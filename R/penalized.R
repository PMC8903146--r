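#' Ordinary least squares (minimum-norm)
#'
#' Unpenalized least-squares weights via the singular value
#' decomposition, returning the minimum-norm solution when the design is
#' rank deficient.
#'
#' @param X design matrix.
#' @param y numeric outcome vector.
#' @return numeric weight vector of length `ncol(X)`.
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, ncol(X)))
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Generalized ridge regression with a non-zero prior
#'
#' Minimizes `||y - X w||^2 + theta ||w - w_prior||^2`. The solution is
#' the closed form `w = (X'X + theta I)^{-1} (X'y + theta w_prior)`,
#' obtained by zeroing the gradient. `theta = 0` reduces to OLS
#' (minimum-norm when rank deficient); `theta = Inf` is accepted as the
#' limiting model and returns `w_prior` exactly, so a penalty sweep can
#' include both endpoints of the OLS-to-prior continuum.
#'
#' @param X design matrix (already transformed for a TTB-family prior).
#' @param y numeric outcome vector.
#' @param theta penalty, `theta >= 0` (may be `Inf`).
#' @param prior a [prior_spec()], or `NULL` for the zero prior.
#' @return object of class `penalized_fit` with fields `w`, `theta`,
#'   `prior`, `solver_info`.
#' @export
ridge_fit <- function(X, y, theta, prior = NULL) {
  X <- as.matrix(X)
  if (is.null(prior)) prior <- zero_prior(ncol(X))
  w_prior <- prior$w_prior
  if (length(w_prior) != ncol(X)) stop("prior length must match ncol(X)")
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta < 0)
    stop("`theta` must be a single nonnegative number")
  if (is.infinite(theta)) {
    w <- w_prior
  } else if (theta == 0) {
    w <- ols_fit(X, y)
  } else {
    A <- crossprod(X)
    diag(A) <- diag(A) + theta
    w <- drop(solve(A, crossprod(X, y) + theta * w_prior))
  }
  structure(
    list(w = w, theta = theta, prior = prior, engine = "linear",
         solver_info = list(converged = TRUE, iterations = 0L)),
    class = "penalized_fit"
  )
}

#' Penalized logistic regression toward a non-zero prior
#'
#' Maximizes the logistic log-likelihood minus
#' `(theta/2) ||w - w_prior||^2` by damped Newton-Raphson:
#' `w <- w + (X'SX + theta I)^{-1} (X'(y - mu) - theta (w - w_prior))`
#' with `mu` the fitted probabilities and `S = diag(mu (1 - mu))`.
#' Iteration starts at the prior, halves the step while the objective
#' would decrease, and stops when the gradient infinity-norm falls below
#' `tol`. `theta = Inf` returns the prior exactly (the limiting model).
#'
#' @param X design matrix.
#' @param y01 labels in \{0, 1\}.
#' @param theta penalty, `>= 0` (may be `Inf`).
#' @param prior a [prior_spec()], or `NULL` for the zero prior.
#' @param tol convergence tolerance on the gradient infinity-norm.
#' @param max_iter maximum Newton iterations.
#' @return a `penalized_fit`; non-convergence is flagged in
#'   `solver_info$converged`, not fatal.
#' @export
logistic_ridge_fit <- function(X, y01, theta, prior = NULL,
                               tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  stopifnot(all(y01 %in% c(0, 1)))
  if (is.null(prior)) prior <- zero_prior(ncol(X))
  w_prior <- prior$w_prior
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta < 0)
    stop("`theta` must be a single nonnegative number")
  if (is.infinite(theta)) {
    return(structure(
      list(w = w_prior, theta = theta, prior = prior, engine = "logistic",
           solver_info = list(converged = TRUE, iterations = 0L,
                              grad_norm = 0)),
      class = "penalized_fit"))
  }
  objective <- function(w) {
    eta <- drop(X %*% w)
    sum(y01 * eta - log1pexp(eta)) - theta / 2 * sum((w - w_prior)^2)
  }
  w <- w_prior
  obj <- objective(w)
  if (!is.finite(obj)) stop("non-finite objective at initialization")
  converged <- FALSE
  it <- 0L
  grad_norm <- Inf
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% w)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y01 - mu)) - theta * (w - w_prior)
    grad_norm <- max(abs(grad))
    if (grad_norm <= tol) { converged <- TRUE; break }
    H <- crossprod(X * (mu * (1 - mu)), X)
    diag(H) <- diag(H) + theta + 1e-12
    step <- drop(solve(H, grad))
    # damp: halve until the objective does not decrease
    alpha <- 1
    repeat {
      w_new <- w + alpha * step
      obj_new <- objective(w_new)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-12) { w_new <- w; obj_new <- obj; break }
    }
    w <- w_new
    obj <- obj_new
  }
  if (!converged) {
    eta <- drop(X %*% w)
    mu <- stats::plogis(eta)
    grad_norm <- max(abs(drop(crossprod(X, y01 - mu)) - theta * (w - w_prior)))
    converged <- grad_norm <= tol
  }
  structure(
    list(w = w, theta = theta, prior = prior, engine = "logistic",
         solver_info = list(converged = converged, iterations = it,
                            grad_norm = grad_norm, objective = obj)),
    class = "penalized_fit"
  )
}

#' Predict choices or labels from a penalized fit
#'
#' Sign task: `sign(X w)`, with zero scores resolved by a fair coin from
#' the session RNG (the same tie rule the heuristics use) -- so an
#' all-zero weight vector yields chance predictions. Probability task:
#' the logistic mean thresholded at 0.5, returned on the \{-1, +1\}
#' scale. For a TTB-family prior the new data must already be in the
#' transformed space (apply [ttb_transform()] with the training ranks).
#'
#' @param fit a `penalized_fit`.
#' @param X_new matrix of new cases.
#' @param task `"sign"` or `"probability"`.
#' @return integer predictions in \{-1, +1\}.
#' @export
predict_choice <- function(fit, X_new, task = c("sign", "probability")) {
  task <- match.arg(task)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$w)) stop("X_new has wrong number of columns")
  if (!is.null(fit$prior) && identical(fit$prior$transform, "ttb") &&
      is.null(attr(X_new, "ttb_phi")))
    stop("fit uses a TTB-transformed design; pass X_new through ttb_transform()")
  score <- drop(X_new %*% fit$w)
  if (task == "probability") score <- stats::plogis(score) - 0.5
  .break_ties(as.integer(sign(score)), score)
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit engine=%s theta=%s prior=%s converged=%s>\n",
              x$engine, format(x$theta), x$prior$family,
              x$solver_info$converged))
  print(x$w)
  invisible(x)
}

#' Serialize a penalized fit to JSON
#' @param fit a `penalized_fit`.
#' @param path optional file path.
#' @return JSON string (invisibly if written).
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(w = fit$w, theta = fit$theta, engine = fit$engine,
              prior_family = fit$prior$family, solver_info = fit$solver_info)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
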