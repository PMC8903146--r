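#' Raw tabular decision data
#'
#' Bundles a real-valued criterion with an object-by-attribute matrix.
#' Rows containing missing values (in the criterion or any attribute) are
#' dropped listwise and the drop count recorded, since all downstream
#' coding assumes complete cases.
#'
#' @param attributes numeric matrix or data frame, one row per object.
#' @param criterion numeric vector, one value per object.
#' @param names optional attribute labels (defaults to column names).
#' @return an object of class `raw_dataset` with fields `attributes`,
#'   `criterion`, `names` and attribute `n_dropped`.
#' @export
raw_dataset <- function(attributes, criterion, names = NULL) {
  attributes <- as.matrix(attributes)
  storage.mode(attributes) <- "double"
  criterion <- as.numeric(criterion)
  if (nrow(attributes) != length(criterion))
    stop("`attributes` and `criterion` must have the same number of rows")
  keep <- stats::complete.cases(attributes) & !is.na(criterion)
  n_dropped <- sum(!keep)
  attributes <- attributes[keep, , drop = FALSE]
  criterion <- criterion[keep]
  if (nrow(attributes) < 2) stop("need at least 2 complete objects")
  if (ncol(attributes) < 1) stop("need at least 1 attribute")
  nm <- names %||% colnames(attributes) %||% paste0("cue", seq_len(ncol(attributes)))
  colnames(attributes) <- nm
  structure(
    list(attributes = attributes, criterion = criterion, names = nm),
    n_dropped = n_dropped,
    class = "raw_dataset"
  )
}

#' Read a raw decision dataset from CSV
#'
#' Expects a header row, one criterion column (named), and the remaining
#' columns as attributes. Rows with missing cells are dropped listwise.
#'
#' @param path CSV file path (UTF-8, comma-separated).
#' @param criterion_col name of the criterion column.
#' @return a [raw_dataset()].
#' @export
read_raw_csv <- function(path, criterion_col) {
  df <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (!criterion_col %in% names(df))
    stop("criterion column '", criterion_col, "' not found in ", path)
  raw_dataset(df[setdiff(names(df), criterion_col)], df[[criterion_col]])
}

#' Median-split coding of attributes
#'
#' Codes each attribute column relative to its median. The binary scheme
#' marks strictly-above-median values 1 (ties at the median get 0); the
#' ternary scheme codes below/at/above the median as -1/0/+1. A constant
#' column carries no information and codes to all zeros, with a warning.
#'
#' @param raw a [raw_dataset()] or numeric matrix.
#' @param scheme `"binary"` or `"ternary"`.
#' @return coded integer matrix of the same shape as the attributes.
#' @export
median_split <- function(raw, scheme = c("binary", "ternary")) {
  scheme <- match.arg(scheme)
  x <- if (inherits(raw, "raw_dataset")) raw$attributes else as.matrix(raw)
  med <- apply(x, 2, stats::median)
  coded <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    if (max(x[, j]) == min(x[, j])) {
      warning("constant column '", colnames(x)[j] %||% j,
              "' coded to all 0", call. = FALSE)
      next
    }
    if (scheme == "binary") {
      coded[, j] <- as.integer(x[, j] > med[j])
    } else {
      coded[, j] <- as.integer(sign(x[, j] - med[j]))
    }
  }
  attr(coded, "medians") <- med
  attr(coded, "scheme") <- scheme
  coded
}

#' Paired-comparison dataset
#'
#' Builds the signed-difference design for two-alternative choice: one row
#' per unordered object pair with unequal criterion values, in a seeded
#' random left/right orientation. Cue j of a pair is
#' `coded[right, j] - coded[left, j]` in {-1, 0, +1}; the outcome is +1
#' when the right object has the larger criterion. Pairs tied on the
#' criterion are dropped (their count is recorded).
#'
#' @param coded binary (0/1) coded matrix from [median_split()].
#' @param criterion numeric criterion per object.
#' @param seed integer seed for the orientation randomization.
#' @return an object of class `decision_dataset` with fields `X`
#'   (n x m, entries in -1/0/+1), `y` (entries in -1/+1), `mode`,
#'   and attribute `n_tied_dropped`.
#' @export
make_paired_comparisons <- function(coded, criterion, seed = 1L) {
  coded <- as.matrix(coded)
  if (!all(coded %in% c(0, 1))) stop("`coded` must be a 0/1 matrix")
  N <- nrow(coded)
  if (N < 2) stop("need at least 2 objects to form pairs")
  if (length(criterion) != N) stop("criterion length must match rows of `coded`")
  pairs <- utils::combn(N, 2)
  tied <- criterion[pairs[1, ]] == criterion[pairs[2, ]]
  pairs <- pairs[, !tied, drop = FALSE]
  n <- ncol(pairs)
  if (n == 0) stop("all pairs are tied on the criterion")
  set.seed(as.integer(seed %% 2147483647))
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  left <- ifelse(swap, pairs[2, ], pairs[1, ])
  right <- ifelse(swap, pairs[1, ], pairs[2, ])
  X <- coded[right, , drop = FALSE] - coded[left, , drop = FALSE]
  y <- ifelse(criterion[right] > criterion[left], 1L, -1L)
  structure(
    list(X = X, y = y, mode = "paired_comparison"),
    n_tied_dropped = sum(tied),
    class = "decision_dataset"
  )
}

#' Classification dataset
#'
#' Wraps an already-coded (ternary) design with binary labels; no pairwise
#' construction is performed. Labels given as 0/1 are remapped to -1/+1
#' with a message.
#'
#' @param coded ternary coded matrix (entries in -1/0/+1).
#' @param labels vector in \{-1, +1\} (or \{0, 1\}, remapped).
#' @return a `decision_dataset` with `mode = "classification"`.
#' @export
make_classification <- function(coded, labels) {
  coded <- as.matrix(coded)
  if (length(labels) != nrow(coded))
    stop("`labels` length must match rows of `coded`")
  if (length(labels) == 0) stop("empty label vector")
  if (!all(coded %in% c(-1, 0, 1))) stop("`coded` must be ternary (-1/0/+1)")
  if (all(labels %in% c(0, 1))) {
    message("labels coded {0,1}; remapping to {-1,+1}")
    labels <- ifelse(labels == 1, 1L, -1L)
  }
  if (!all(labels %in% c(-1, 1))) stop("labels must be in {-1,+1} or {0,1}")
  structure(
    list(X = coded, y = as.integer(labels), mode = "classification"),
    class = "decision_dataset"
  )
}

#' Synthetic multi-cue decision task
#'
#' Generates an object-by-attribute benchmark task in the shape of the
#' classical multi-cue prediction datasets: standard-normal attributes and
#' a linear criterion with a chosen cue-weight profile. `"compensatory"`
#' gives equal absolute weights (many weak cues can jointly overturn any
#' one), `"noncompensatory"` doubles each successive weight (|beta_j|
#' proportional to 2^j, so the top cue dominates), and `"mixed"` draws
#' log-spaced magnitudes at random. Weight signs are random.
#'
#' @param m number of cues (>= 2).
#' @param N number of objects (>= 10).
#' @param validity_profile `"compensatory"`, `"noncompensatory"` or `"mixed"`.
#' @param noise_sd standard deviation of the criterion noise.
#' @param seed integer seed; generation is fully reproducible.
#' @return a [raw_dataset()] with attribute `beta` carrying the true weights.
#' @export
generate_synthetic_task <- function(m = 5, N = 60,
                                    validity_profile = c("compensatory",
                                                         "noncompensatory",
                                                         "mixed"),
                                    noise_sd = 0.5, seed = 1L) {
  validity_profile <- match.arg(validity_profile)
  stopifnot(m >= 2, N >= 10)
  set.seed(as.integer(seed %% 2147483647))
  A <- matrix(stats::rnorm(N * m), N, m,
              dimnames = list(NULL, paste0("cue", seq_len(m))))
  mag <- switch(validity_profile,
    compensatory    = rep(1, m),
    noncompensatory = 2^seq_len(m),
    mixed           = 2^stats::runif(m, 0, m - 1)
  )
  beta <- mag * sample(c(-1, 1), m, replace = TRUE)
  criterion <- drop(A %*% beta) + stats::rnorm(N, 0, noise_sd)
  out <- raw_dataset(A, criterion)
  attr(out, "beta") <- beta
  out
}

#' Train/test split of a decision dataset
#'
#' Samples `n_train` rows without replacement (seeded by `seed` and
#' `iteration`, so successive iterations give different but reproducible
#' partitions); the complement is the test set.
#'
#' @param data a `decision_dataset`.
#' @param n_train number of training rows, `1 <= n_train < n`.
#' @param seed master integer seed.
#' @param iteration iteration index (>= 1).
#' @return list with elements `train` and `test`, both `decision_dataset`s.
#' @export
split_train_test <- function(data, n_train, seed = 1L, iteration = 1L) {
  n <- nrow(data$X)
  if (n_train >= n) stop("`n_train` must be smaller than the number of rows")
  if (n_train < 1) stop("`n_train` must be at least 1")
  set.seed(derive_seed(seed, iteration))
  idx <- sample.int(n, n_train)
  subset_dd <- function(d, i) {
    structure(list(X = d$X[i, , drop = FALSE], y = d$y[i], mode = d$mode),
              class = "decision_dataset")
  }
  list(train = subset_dd(data, idx), test = subset_dd(data, setdiff(seq_len(n), idx)))
}

#' @export
print.decision_dataset <- function(x, ...) {
  cat(sprintf("<decision_dataset: %d rows, %d cues, mode=%s>\n",
              nrow(x$X), ncol(x$X), x$mode))
  invisible(x)
}

#' Read and clean a breast-cancer style UCI table
#'
#' Reads a comma-separated file with an id column, nine integer-valued cue
#' columns and a class column (2 = benign, 4 = malignant in the UCI
#' convention). Rows with missing cue values (coded `?`) are removed and
#' the remaining table returned as a [raw_dataset()]-like pair: ternary
#' median-split cues plus labels in \{-1, +1\} (-1 = malignant, +1 = benign).
#'
#' @param path file path.
#' @param header does the file carry a header row?
#' @return list with `coded` (ternary matrix), `labels`, `n_dropped`, `n`.
#' @export
read_uci_bcw <- function(path, header = FALSE) {
  df <- utils::read.csv(path, header = header, na.strings = "?",
                        stringsAsFactors = FALSE)
  if (ncol(df) != 11)
    stop("expected 11 columns (id, 9 cues, class); got ", ncol(df))
  cues <- as.matrix(df[, 2:10])
  storage.mode(cues) <- "double"
  cls <- df[, 11]
  keep <- stats::complete.cases(cues)
  n_dropped <- sum(!keep)
  cues <- cues[keep, , drop = FALSE]
  cls <- cls[keep]
  coded <- median_split(cues, scheme = "ternary")
  labels <- ifelse(cls == 4, -1L, 1L)
  list(coded = coded, labels = labels, n_dropped = n_dropped, n = nrow(coded))
}
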