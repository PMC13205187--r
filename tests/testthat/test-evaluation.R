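test_that("stratified_split preserves proportions and partitions the data", {
  labels <- rep(c("a", "b", "c"), each = 100)
  sp <- stratified_split(labels, train_frac = 0.85, val_frac_of_train = 0,
                         seed = 1)
  per_class_test <- table(labels[sp$test])
  expect_true(all(per_class_test == 15))

  sp2 <- stratified_split(labels, train_frac = 0.85, val_frac_of_train = 0,
                          seed = 1)
  expect_identical(sp, sp2)

  spv <- stratified_split(labels, 0.85, 0.20, seed = 3)
  all_idx <- sort(c(spv$train, spv$validation, spv$test))
  expect_equal(all_idx, seq_along(labels))
  expect_equal(length(intersect(spv$train, spv$test)), 0L)
  expect_equal(length(intersect(spv$train, spv$validation)), 0L)

  # stratification error at most 1 per class on awkward sizes
  lab2 <- rep(c("a", "b", "c"), times = c(17, 9, 23))
  s3 <- stratified_split(lab2, 0.85, 0, seed = 2)
  for (cl in c("a", "b", "c")) {
    n_cl <- sum(lab2 == cl)
    got <- sum(lab2[s3$train] == cl)
    expect_lte(abs(got - 0.85 * n_cl), 1)
  }
  expect_error(stratified_split(c("a", "a", "b"), 0.85, 0, 1), ">= 3")
})

test_that("confusion counts truth rows against prediction columns", {
  cm <- confusion(c(0, 1), c(1, 0), levels = c(0, 1))
  expect_equal(unname(cm), rbind(c(0L, 1L), c(1L, 0L)))
  perfect <- confusion(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(perfect), diag(3L) * 1L, ignore_attr = TRUE)
  set.seed(8)
  y <- sample(c("a", "b", "c"), 50, replace = TRUE)
  p <- sample(c("a", "b", "c"), 50, replace = TRUE)
  cm2 <- confusion(y, p)
  expect_equal(unname(rowSums(cm2)), unname(as.vector(table(y))))
  expect_error(confusion(c("a", "d"), c("a", "a"), levels = c("a", "b")),
               "outside")
  expect_error(confusion(c("a"), c("a", "b")), "equal length")
})

test_that("macro_report reproduces the external-validation arithmetic", {
  # 72 independently graded fruits: per-class correct 30/30, 15/19, 23/23;
  # the 4 misses of the slight class land in the healthy column.
  cm <- rbind(healthy = c(30L, 0L, 0L),
              slight = c(4L, 15L, 0L),
              severe = c(0L, 0L, 23L))
  colnames(cm) <- rownames(cm)
  rep_ <- macro_report(cm)
  expect_equal(round(100 * rep_$accuracy, 2), 94.44)
  expect_equal(round(100 * rep_$per_class$recall[2], 1), 78.9)
  expect_equal(rep_$per_class$recall[c(1, 3)], c(1, 1))
})

test_that("macro_report matches a hand oracle on random matrices", {
  perfect <- macro_report(diag(c(5L, 3L, 7L)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(sample(0:20, 9, replace = TRUE), 3, 3)
    if (sum(m) == 0) next
    got <- suppressWarnings(macro_report(m))
    want <- naive_macro(m)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$macro_precision, want$precision)
    expect_equal(got$macro_recall, want$recall)
    expect_equal(got$macro_f1, want$f1)
    expect_equal(got$accuracy, sum(diag(m)) / sum(m))
  }
  expect_error(macro_report(matrix(0, 3, 3)), "empty")
})

test_that("mcnemar computes discordant counts and the corrected statistic", {
  y <- rep(1, 20)
  a <- c(rep(1, 10), rep(0, 10))  # a right on 1..10
  b <- c(rep(0, 10), rep(1, 10))  # b right on 11..20
  r <- mcnemar(y, a, b, correction = FALSE)
  expect_equal(r$b, 10L); expect_equal(r$c, 10L)
  expect_equal(r$chi_square, 0)

  y2 <- rep(1, 30)
  a2 <- c(rep(1, 10), rep(1, 20))
  b2 <- c(rep(0, 10), rep(1, 20))
  r2 <- mcnemar(y2, a2, b2, correction = TRUE)
  expect_equal(r2$b, 10L); expect_equal(r2$c, 0L)
  expect_equal(r2$chi_square, (abs(10 - 0) - 1)^2 / 10)  # 8.1
  expect_equal(r2$chi_square, 8.1)

  r3 <- mcnemar(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(r3$chi_square, 0)
  expect_equal(r3$p_value, 1)
})
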