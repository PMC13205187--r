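#' One-way ANOVA F statistic per wavelength
#'
#' For each wavelength (column of `X`) the between-class mean square over
#' the within-class mean square across the label groups: large F means the
#' wavelength separates the classes well relative to its within-class
#' scatter.
#'
#' @param X Numeric samples x wavelengths matrix.
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @return Numeric vector of F values, one per wavelength (0 when the
#'   within-class variance is 0 and the between-class variance is 0 too;
#'   `Inf` for a perfectly separating constant-within wavelength).
#' @export
f_statistic_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2L)) stop("every class needs >= 2 samples", call. = FALSE)
  n <- nrow(X); k <- length(counts)
  grand <- colMeans(X)
  group_sums <- rowsum(X, y)                 # k x p
  group_means <- group_sums / as.numeric(counts)
  ssb <- colSums(as.numeric(counts) * (sweep(group_means, 2, grand))^2)
  ssw <- colSums((X - group_means[as.integer(y), , drop = FALSE])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  f[msb == 0 & msw == 0] <- 0
  f
}

#' Select the K top-scoring wavelengths
#'
#' @param scores Per-wavelength statistic (F value or importance).
#' @param K Number of wavelengths to keep (default 100).
#' @return A `selection_result`: list with `selected_indices` (1-based,
#'   sorted by descending score, ties broken by lower index), `scores`, `K`.
#' @export
select_top_k <- function(scores, K = 100L) {
  K <- as.integer(K)
  if (K < 1L || K > length(scores)) {
    stop("K must be between 1 and the number of wavelengths", call. = FALSE)
  }
  ord <- order(-scores, seq_along(scores))
  structure(
    list(selected_indices = ord[seq_len(K)], scores = scores, K = K),
    class = "selection_result"
  )
}

# ---- random forest importance (CART, Gini) -------------------------------

# Best Gini split of one feature: returns c(threshold, impurity_decrease)
# or NULL. Tie-break: first (lowest) threshold.
.best_split_feature <- function(x, y_int, n_classes) {
  ord <- order(x)
  xs <- x[ord]; ys <- y_int[ord]
  n <- length(xs)
  cum <- matrix(0, n, n_classes)
  cum[cbind(seq_len(n), ys)] <- 1
  cum <- apply(cum, 2, cumsum)
  tot <- cum[n, ]
  cut_ok <- which(diff(xs) > 0)  # split between positions i and i+1
  if (!length(cut_ok)) return(NULL)
  n_l <- cut_ok
  n_r <- n - n_l
  left <- cum[cut_ok, , drop = FALSE]
  right <- matrix(tot, length(cut_ok), n_classes, byrow = TRUE) - left
  gini_l <- 1 - rowSums((left / n_l)^2)
  gini_r <- 1 - rowSums((right / n_r)^2)
  gini_p <- 1 - sum((tot / n)^2)
  dec <- gini_p - (n_l / n) * gini_l - (n_r / n) * gini_r
  best <- which.max(dec)
  c(threshold = (xs[cut_ok[best]] + xs[cut_ok[best] + 1L]) / 2,
    decrease = dec[best])
}

# Grow one tree on (X, y_int); accumulates weighted impurity decreases into
# an importance vector (no tree structure is retained -- only importances
# are needed by the selector).
.grow_tree_importance <- function(X, y_int, n_classes, mtry, min_split = 2L,
                                  max_depth = 30L) {
  p <- ncol(X)
  imp <- numeric(p)
  n_total <- nrow(X)
  recurse <- function(idx, depth) {
    n <- length(idx)
    if (n < min_split || depth >= max_depth ||
        length(unique(y_int[idx])) == 1L) return(invisible())
    feats <- sample.int(p, mtry)
    best_dec <- 0; best_f <- NA_integer_; best_t <- NA_real_
    for (f in feats) {
      s <- .best_split_feature(X[idx, f], y_int[idx], n_classes)
      if (!is.null(s) && s[["decrease"]] > best_dec + 1e-15) {
        best_dec <- s[["decrease"]]; best_f <- f; best_t <- s[["threshold"]]
      }
    }
    if (is.na(best_f)) return(invisible())
    imp[best_f] <<- imp[best_f] + (n / n_total) * best_dec
    go_left <- X[idx, best_f] <= best_t
    recurse(idx[go_left], depth + 1L)
    recurse(idx[!go_left], depth + 1L)
  }
  recurse(seq_len(n_total), 0L)
  imp
}

#' Random-forest (Gini impurity) wavelength importances
#'
#' Bootstrapped CART trees with random feature subsets
#' (`mtry = floor(sqrt(p))`); importance of a wavelength is its
#' node-size-weighted Gini impurity decrease, averaged over trees and
#' normalized to sum 1.
#'
#' @param X Numeric samples x wavelengths matrix.
#' @param y Class labels.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed (forest is deterministic given seed).
#' @param mtry Features tried per node, default `floor(sqrt(p))`.
#' @return Numeric importance vector (non-negative, sums to 1).
#' @export
rf_importance_scores <- function(X, y, n_trees = 500L, seed = 1L,
                                 mtry = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2L)) stop("every class needs >= 2 samples", call. = FALSE)
  y_int <- as.integer(y)
  n_classes <- length(counts)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  set.seed(seed)
  total <- numeric(p)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
    imp <- .grow_tree_importance(X[boot, , drop = FALSE], y_int[boot],
                                 n_classes, mtry)
    s <- sum(imp)
    if (s > 0) total <- total + imp / s
  }
  if (sum(total) == 0) return(rep(1 / p, p))
  total / sum(total)
}
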