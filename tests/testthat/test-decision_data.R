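test_that("median split codes columns relative to their medians", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  expect_equal(as.vector(median_split(x, "ternary")), c(-1, -1, 0, 1, 1))
  expect_equal(as.vector(median_split(matrix(c(10, 20), ncol = 1), "binary")),
               c(0, 1))
  # ties at the median are 0 in both schemes (strictly-above rule)
  xm <- matrix(c(1, 2, 2, 3), ncol = 1)
  expect_equal(as.vector(median_split(xm, "binary")), c(0, 0, 0, 1))
  expect_warning(out <- median_split(matrix(rep(7, 4), ncol = 1), "binary"),
                 "constant")
  expect_true(all(out == 0))
})

test_that("paired comparisons code signed attribute differences", {
  # two objects; whichever orientation is drawn, x and y stay consistent
  coded <- rbind(a = c(1, 0), b = c(0, 0))
  for (seed in 1:5) {
    dd <- make_paired_comparisons(coded, criterion = c(2, 1), seed = seed)
    expect_equal(nrow(dd$X), 1)
    expect_true(all(dd$X[1, ] %in% c(-1, 0, 1)))
    # y = -1 must coincide with x = (-1, 0) (right = b), y = +1 with (1, 0)
    if (dd$y == -1) expect_equal(unname(dd$X[1, ]), c(-1, 0))
    else expect_equal(unname(dd$X[1, ]), c(1, 0))
  }
  # all-distinct criteria: N(N-1)/2 rows; tied pairs are dropped and counted
  coded4 <- matrix(rbinom(12, 1, 0.5), 4, 3)
  dd4 <- make_paired_comparisons(coded4, c(4, 1, 3, 2), seed = 1)
  expect_equal(nrow(dd4$X), 6)
  dd_tied <- make_paired_comparisons(matrix(0, 3, 2), c(5, 5, 7), seed = 1)
  expect_equal(nrow(dd_tied$X), 2)
  expect_equal(attr(dd_tied, "n_tied_dropped"), 1)
  expect_error(make_paired_comparisons(matrix(0, 1, 2), 1), "at least 2")
})

test_that("decision datasets satisfy their value-set invariants", {
  for (seed in 1:10) {
    raw <- generate_synthetic_task(m = 4, N = 15, seed = seed,
                                   noise_sd = runif(1, 0, 2))
    dd <- make_paired_comparisons(median_split(raw, "binary"),
                                  raw$criterion, seed = seed)
    expect_true(all(dd$X %in% c(-1, 0, 1)))
    expect_true(all(dd$y %in% c(-1, 1)))
  }
})

test_that("classification wrapper validates and remaps labels", {
  coded <- matrix(sample(c(-1L, 0L, 1L), 27, replace = TRUE), 9, 3)
  lab01 <- rep(c(0, 1), length.out = 9)
  expect_message(dd <- make_classification(coded, lab01), "remapping")
  expect_equal(sort(unique(dd$y)), c(-1L, 1L))
  expect_equal(dd$mode, "classification")
  expect_identical(dd$X, coded)
  expect_error(make_classification(coded, c(1, -1)), "length")
  expect_error(make_classification(coded[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("synthetic task generation is seeded and structured", {
  a <- generate_synthetic_task(m = 4, N = 30, seed = 42)
  b <- generate_synthetic_task(m = 4, N = 30, seed = 42)
  expect_identical(a$attributes, b$attributes)
  expect_identical(a$criterion, b$criterion)
  expect_false(identical(
    a$criterion, generate_synthetic_task(m = 4, N = 30, seed = 43)$criterion))

  # noiseless compensatory task: TAL on the full dataset beats chance
  raw <- generate_synthetic_task(m = 5, N = 40, "compensatory",
                                 noise_sd = 0, seed = 7)
  dd <- make_paired_comparisons(median_split(raw, "binary"),
                                raw$criterion, seed = 7)
  hm <- fit_heuristic(dd)
  set.seed(1)
  expect_gt(accuracy(predict_tal(hm, dd$X), dd$y), 0.5)

  # noiseless noncompensatory m=2: the top-weight cue decides whenever it
  # discriminates
  raw2 <- generate_synthetic_task(m = 2, N = 30, "noncompensatory",
                                  noise_sd = 0, seed = 3)
  beta <- attr(raw2, "beta")
  top <- which.max(abs(beta))
  dd2 <- make_paired_comparisons(median_split(raw2, "binary"),
                                 raw2$criterion, seed = 3)
  disc <- dd2$X[, top] != 0
  pred_top <- sign(beta[top]) * dd2$X[disc, top]
  expect_true(mean(pred_top == dd2$y[disc]) > 0.9)
})

test_that("train/test splits are seeded, disjoint and exhaustive", {
  dd <- make_test_decision_data(N = 16)
  n <- nrow(dd$X)
  sp <- split_train_test(dd, 50, seed = 5, iteration = 1)
  expect_equal(nrow(sp$train$X), 50)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), n)
  sp2 <- split_train_test(dd, 50, seed = 5, iteration = 1)
  expect_identical(sp$train$X, sp2$train$X)
  sp3 <- split_train_test(dd, 50, seed = 5, iteration = 2)
  expect_false(identical(sp$train$X, sp3$train$X))
  expect_error(split_train_test(dd, n, seed = 1), "smaller")
})

test_that("raw datasets drop incomplete rows and report the count", {
  A <- matrix(rnorm(20), 10, 2)
  A[3, 1] <- NA
  crit <- rnorm(10); crit[7] <- NA
  raw <- raw_dataset(A, crit)
  expect_equal(attr(raw, "n_dropped"), 2)
  expect_equal(nrow(raw$attributes), 8)
})

test_that("UCI-format reader cleans missing rows and maps labels", {
  # synthetic fixture in the UCI breast-cancer file layout
  tf <- withr::local_tempfile(fileext = ".csv")
  set.seed(2)
  n <- 30
  rows <- data.frame(id = 1000 + seq_len(n))
  for (j in 1:9) rows[[paste0("c", j)]] <- sample(1:10, n, replace = TRUE)
  rows$class <- sample(c(2, 4), n, replace = TRUE)
  rows$c3[c(4, 9)] <- "?"
  utils::write.table(rows, tf, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  out <- read_uci_bcw(tf)
  expect_equal(out$n_dropped, 2)
  expect_equal(out$n, n - 2)
  expect_true(all(out$coded %in% c(-1, 0, 1)))
  expect_true(all(out$labels %in% c(-1, 1)))
  # malignant (class 4) maps to -1
  expect_equal(out$labels[rows$class[-c(4, 9)] == 4][1], -1L)
})
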