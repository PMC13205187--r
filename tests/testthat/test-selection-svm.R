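test_that("F statistic separates discriminative from noise wavelengths", {
  X <- cbind(c(1, 1.1, 2, 2.1, 3, 3.1),
             c(0.2, -0.1, 0.1, 0.05, -0.2, 0.15))
  y <- c("a", "a", "b", "b", "c", "c")
  f <- f_statistic_scores(X, y)
  expect_gt(f[1], f[2])

  all_ident <- matrix(5, 6, 3)
  expect_equal(f_statistic_scores(all_ident, y), rep(0, 3))
})

test_that("F scores match a sum-of-squares oracle and are affine invariant", {
  set.seed(7)
  X <- matrix(rnorm(300), 30, 10)
  y <- rep(c("a", "b", "c"), each = 10)
  f <- f_statistic_scores(X, y)
  # hand-rolled SS decomposition
  oracle <- vapply(seq_len(10), function(j) {
    v <- X[, j]
    gm <- tapply(v, y, mean)
    ssb <- sum(table(y) * (gm - mean(v))^2)
    ssw <- sum((v - gm[y])^2)
    (ssb / 2) / (ssw / 27)
  }, numeric(1))
  expect_equal(f, oracle, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f_statistic_scores(3 * X + 17, y), f, tolerance = 1e-9)
  expect_error(f_statistic_scores(X, rep("a", 30)), "2 classes")
  expect_error(f_statistic_scores(X[1:11, ], c(rep("a", 10), "b")), ">= 2 samples")
})

test_that("select_top_k keeps the K largest scores with index tie-break", {
  expect_equal(select_top_k(c(3, 1, 2), 2L)$selected_indices, c(1L, 3L))
  expect_equal(sort(select_top_k(c(3, 1, 2), 3L)$selected_indices), 1:3)
  expect_equal(select_top_k(c(2, 5, 5, 1), 2L)$selected_indices, c(2L, 3L))
  expect_error(select_top_k(1:3, 4L), "between 1")
})

test_that("rf importances recover an injected wavelength, sum to 1, and are seeded", {
  set.seed(9)
  X <- matrix(rnorm(90 * 40), 90, 40)
  y <- rep(c("a", "b", "c"), each = 30)
  X[, 17] <- X[, 17] + 2 * as.integer(factor(y))
  imp <- rf_importance_scores(X, y, n_trees = 200L, seed = 2)
  expect_equal(which.max(imp), 17L)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))
  expect_identical(imp, rf_importance_scores(X, y, n_trees = 200L, seed = 2))
})

test_that("the OvO RBF-SVM separates blobs and votes by majority", {
  set.seed(15)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(40, 0, 0.4), 20, 2), 2, centers[k, ], "+")
  }))
  y <- rep(c("a", "b", "c"), each = 20)
  model <- train_svm(X, y, C = 1.0)
  expect_equal(mean(predict(model, X) == y), 1)
  expect_identical(predict(model, X[1, , drop = FALSE]), "a")

  votes <- predict(model, X[c(1, 21, 41), ], type = "votes")
  expect_equal(unname(votes[1, "a"]), 2)  # wins both of its pairs

  expect_identical(ovo_vote(c("a", "a", "b"), c("a", "b", "c")), "a")
  expect_identical(predict(model, X[0, , drop = FALSE]), character(0))
  expect_error(predict(model, X[, 1, drop = FALSE]), "feature count")
  expect_error(train_svm(X, rep("a", 60)), "2 classes")
  expect_error(train_svm(X, y, C = -1), "positive")
})

test_that("the gamma heuristic matches 1/(p * var) and is overridable", {
  set.seed(20)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("a", "b"), each = 10)
  model <- train_svm(X, y)
  v <- mean((X - mean(X))^2)
  expect_equal(model$gamma, 1 / (2 * v), tolerance = 1e-12)
  expect_equal(train_svm(X, y, bandwidth_mode = 0.5)$gamma, 0.5)
})

test_that("selection feeding the SVM reaches high held-out accuracy", {
  ds <- make_small_dataset(n_per_class = 20, n_wavelengths = 200,
                           noise_sd = 0.01, seed = 55)
  m <- spectra_matrix(ds)
  sp <- stratified_split(m$labels, train_frac = 0.7, val_frac_of_train = 0,
                         seed = 55)
  f <- f_statistic_scores(m$X[sp$train, ], m$labels[sp$train])
  sel <- select_top_k(f, 50L)$selected_indices
  model <- train_svm(m$X[sp$train, sel], m$labels[sp$train])
  acc <- mean(predict(model, m$X[sp$test, sel]) == m$labels[sp$test])
  expect_gte(acc, 0.95)
})
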