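test_that("paa takes non-overlapping window means and drops the remainder", {
  expect_equal(paa(1:10, 5L), c(3, 8))
  expect_length(paa(rnorm(1044), 5L), 208L)
  expect_equal(paa(rep(2.5, 17), 5L), rep(2.5, 3))
  expect_error(paa(1:10, 0L), "window_size")
})

test_that("quantile_discretize assigns equal-frequency rank states", {
  expect_equal(quantile_discretize(1:6, 3L)$states, c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(quantile_discretize(sort(rnorm(12)), 12L)$states, 0:11)
  expect_error(quantile_discretize(1:5, 6L), "shorter than q")
  expect_error(quantile_discretize(1:20, 1L), "q must be")
  # occupancy balance and rank-oracle agreement on distinct values
  for (n in c(24, 25, 35)) {
    set.seed(2 + n)
    x <- rnorm(n)
    st <- quantile_discretize(x, 12L)$states
    occ <- tabulate(st + 1L, 12L)
    expect_lte(max(occ) - min(occ), 1L)
    expect_equal(st, naive_states(x, 12L))
  }
})

test_that("transition_matrix counts adjacent pairs and normalizes rows", {
  tm <- transition_matrix(c(0L, 0L, 1L, 1L, 2L, 2L), q = 3L)
  expect_equal(tm$W, rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0, 0, 1)))
  tm_const <- transition_matrix(rep(1L, 6), q = 3L)
  expect_equal(tm_const$W[2, 2], 1)
  expect_equal(rowSums(tm_const$W), c(0, 1, 0))
  set.seed(5)
  st <- sample(0:3, 40, replace = TRUE)
  W <- transition_matrix(st, q = 4L)$W
  rs <- rowSums(W)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})

test_that("mtf_expand is an elementwise transition lookup", {
  tm <- structure(list(W = rbind(c(.5, .5), c(0, 1)), q = 2L),
                  class = "transition_model")
  M <- mtf_expand(c(0L, 0L, 1L, 1L), tm)
  expect_equal(M, rbind(c(.5, .5, .5, .5), c(.5, .5, .5, .5),
                        c(0, 0, 1, 1), c(0, 0, 1, 1)))
  tm1 <- structure(list(W = matrix(1, 1, 1), q = 1L), class = "transition_model")
  expect_equal(mtf_expand(rep(0L, 3), tm1), matrix(1, 3, 3))
  expect_true(all(M %in% tm$W))
  expect_error(mtf_expand(c(0L, 2L), tm), "out of range")
})

test_that("W and M match brute-force pair counting on longer series", {
  set.seed(17)
  for (n in c(20, 41, 60)) {
    x <- rnorm(n)
    ss <- quantile_discretize(x, 5L)
    tm <- transition_matrix(ss)
    expect_equal(tm$W, naive_transition(ss$states, 5L))
    expect_equal(mtf_expand(ss, tm), naive_mtf(ss$states, tm$W))
  }
})

test_that("pyramids reconstruct exactly and halve sides by ceiling", {
  const <- matrix(0.7, 32, 32)
  pc <- build_pyramids(const)
  for (L in pc$laplacian) expect_equal(L, matrix(0, nrow(L), ncol(L)),
                                       tolerance = 1e-12)

  set.seed(23)
  img <- matrix(runif(64 * 64), 64, 64)
  st <- build_pyramids(img)
  recon <- st$gaussian[[4]]
  for (k in 3:1) {
    recon <- st$laplacian[[k]] +
      pearspec:::.bilinear_resize(st$gaussian[[k + 1]],
                                  nrow(st$gaussian[[k]]),
                                  ncol(st$gaussian[[k]]))
    expect_equal(recon, st$gaussian[[k]], tolerance = 1e-10)
  }

  st208 <- build_pyramids(matrix(rnorm(208^2), 208, 208))
  expect_equal(vapply(st208$gaussian, nrow, integer(1)), c(208L, 104L, 52L, 26L))
  expect_error(build_pyramids(matrix(1, 4, 4), levels = 3L), "too small")
})

test_that("fuse_pyramid validates weights and lands exactly in [0,1]", {
  set.seed(31)
  st <- build_pyramids(matrix(runif(40 * 40), 40, 40))
  expect_error(fuse_pyramid(st, c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(fuse_pyramid(st, c(1, 0, 0)), "4 non-negative")

  fused <- fuse_pyramid(st)
  expect_equal(min(fused), 0, tolerance = 1e-12)
  expect_equal(max(fused), 1, tolerance = 1e-12)

  # degenerate weights isolate the rescaled first Laplacian layer
  l0 <- fuse_pyramid(st, c(1, 0, 0, 0))
  l0_direct <- st$laplacian[[1]]
  l0_direct <- (l0_direct - min(l0_direct)) / diff(range(l0_direct))
  expect_equal(l0, l0_direct, tolerance = 1e-12)
})

test_that("the full LPMTF pipeline yields the documented sides", {
  s <- generate_spectrum(spectrum_sim_config(seed = 12, class_label = "severe"))
  img <- lpmtf(s)
  expect_equal(img$side, 208L)
  expect_true(all(img$matrix >= 0 & img$matrix <= 1))

  expect_equal(lpmtf(s, q = 6L)$side, 208L)       # ablation parameter variant
  expect_equal(lpmtf(s, window_size = 10L)$side, 104L)

  expect_identical(lpmtf(s)$matrix, img$matrix)   # determinism
  expect_error(lpmtf(rnorm(30), q = 12L, window_size = 5L), "too short")
})
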