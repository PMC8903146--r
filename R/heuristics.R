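#' Cue validity
#'
#' The signed accuracy of a single cue among the rows where it
#' discriminates: `v = (R - W) / (R + W)`, where R counts rows with
#' `sign(x_i) == y_i` and W those with `sign(x_i) != y_i`; rows with
#' `x_i == 0` present no prediction and are ignored. A cue that never
#' discriminates gets validity 0.
#'
#' @param x ternary cue vector (entries in -1/0/+1).
#' @param y outcome vector (entries in -1/+1).
#' @return list with `v`, `R`, `W`.
#' @export
cue_validity <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  active <- x != 0
  R <- sum(active & sign(x) == y)
  W <- sum(active) - R
  v <- if (R + W > 0) (R - W) / (R + W) else 0
  list(v = v, R = R, W = W)
}

#' Fit the tallying / take-the-best heuristic state
#'
#' Estimates per-cue validities on a training set and derives the
#' quantities both heuristics run on: directions `q = sign(v)` and
#' ascending ranks of the absolute validities,
#' `r_j = #\{j' : |v_j'| < |v_j|\}` (ties share a rank; ranks lie in
#' `0 .. m-1`).
#'
#' @param train a `decision_dataset`.
#' @return object of class `heuristic_model` with fields `validities`,
#'   `directions`, `ranks`, `R`, `W`.
#' @export
fit_heuristic <- function(train) {
  X <- train$X
  y <- train$y
  if (nrow(X) == 0) stop("empty training set")
  m <- ncol(X)
  R <- W <- integer(m)
  v <- numeric(m)
  for (j in seq_len(m)) {
    cv <- cue_validity(X[, j], y)
    v[j] <- cv$v; R[j] <- cv$R; W[j] <- cv$W
  }
  ranks <- vapply(seq_len(m), function(j) sum(abs(v) < abs(v[j])), integer(1))
  structure(
    list(validities = v, directions = as.integer(sign(v)), ranks = ranks,
         R = R, W = W),
    class = "heuristic_model"
  )
}

#' @export
print.heuristic_model <- function(x, ...) {
  cat("<heuristic_model>\n")
  print(data.frame(validity = x$validities, direction = x$directions,
                   rank = x$ranks, R = x$R, W = x$W))
  invisible(x)
}

# resolve ties (score exactly 0) by a fair coin from the session RNG
.break_ties <- function(pred, score) {
  tie <- score == 0
  if (any(tie)) pred[tie] <- sample(c(-1L, 1L), sum(tie), replace = TRUE)
  pred
}

#' Tallying (TAL) prediction
#'
#' Majority vote of direction-corrected cues:
#' `yhat = sign(sum_j sign(v_j x_j))`. A zero tally is resolved by a fair
#' coin (each option with probability 0.5) drawn from the session RNG;
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param model a `heuristic_model`.
#' @param x ternary cue vector, or a matrix with one case per row.
#' @return integer vector of choices in \{-1, +1\}.
#' @export
predict_tal <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  score <- rowSums(sign(sweep(X, 2, model$validities, `*`)))
  .break_ties(as.integer(sign(score)), score)
}

#' Take-the-best (TTB) prediction
#'
#' Decides by the single discriminating cue (x_j != 0) of highest
#' absolute validity, applying its direction:
#' `yhat = sign(q_{j*} x_{j*})`. Ties in |v| among discriminating cues
#' are broken by the lowest column index. When no cue discriminates (all
#' x_j = 0) the choice is a fair coin from the session RNG.
#'
#' @inheritParams predict_tal
#' @return integer vector of choices in \{-1, +1\}.
#' @export
predict_ttb <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  ord <- order(-abs(model$validities), seq_along(model$validities))
  Xo <- X[, ord, drop = FALSE]
  nz <- Xo != 0
  any_nz <- rowSums(nz) > 0
  first <- max.col(nz, ties.method = "first")  # meaningless where !any_nz
  q <- model$directions[ord]
  score <- q[first] * Xo[cbind(seq_len(nrow(Xo)), first)]
  score[!any_nz] <- 0
  .break_ties(as.integer(sign(score)), score)
}
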