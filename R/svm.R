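# One-vs-one RBF support vector machine. No SVM library is assumed: each
# pairwise binary sub-problem (soft-margin hinge loss, Gaussian kernel) is
# solved by sequential minimal optimization with deterministic working-set
# selection, and the multiclass decision is a majority vote over the pairs.

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# SMO for one binary problem. y in {-1, +1}. Deterministic: the first index
# is scanned in order, the partner maximizes |E_i - E_j|.
.smo_fit <- function(K, y, C, tol = 1e-3, max_passes = 30L, max_iter = 5000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  f_cache <- function() as.numeric(K %*% (alpha * y)) + b
  E <- f_cache() - y
  passes <- 0L; iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      iter <- iter + 1L
      ri <- E[i] * y[i]
      if ((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)) {
        cand <- setdiff(order(-abs(E - E[i])), i)
        for (j in cand[seq_len(min(8L, length(cand)))]) {
          if (y[i] != y[j]) {
            L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
          } else {
            L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj_new <- alpha[j] - y[j] * (E[i] - E[j]) / eta
          aj_new <- min(max(aj_new, L), H)
          if (abs(aj_new - alpha[j]) < 1e-7) next
          ai_new <- alpha[i] + y[i] * y[j] * (alpha[j] - aj_new)
          b1 <- b - E[i] - y[i] * (ai_new - alpha[i]) * K[i, i] -
            y[j] * (aj_new - alpha[j]) * K[i, j]
          b2 <- b - E[j] - y[i] * (ai_new - alpha[i]) * K[i, j] -
            y[j] * (aj_new - alpha[j]) * K[j, j]
          db <- if (ai_new > 0 && ai_new < C) b1 - b
                else if (aj_new > 0 && aj_new < C) b2 - b
                else (b1 + b2) / 2 - b
          dai <- ai_new - alpha[i]; daj <- aj_new - alpha[j]
          E <- E + dai * y[i] * K[, i] + daj * y[j] * K[, j] + db
          alpha[i] <- ai_new; alpha[j] <- aj_new; b <- b + db
          changed <- changed + 1L
          break
        }
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

#' Train a one-vs-one RBF-SVM classifier
#'
#' Gaussian-kernel soft-margin SVMs are fit for every pair of classes
#' (sequential minimal optimization); prediction is by majority vote over
#' the pairwise decisions. The kernel bandwidth follows the "scale"
#' heuristic `gamma = 1 / (n_features * var(X))` where `var(X)` is the
#' variance of all training feature values.
#'
#' @param X Numeric samples x features matrix.
#' @param y Class labels (>= 2 classes).
#' @param C Soft-margin penalty, default 1.
#' @param bandwidth_mode `"variance-scaled"` (the gamma heuristic above) or
#'   a positive numeric gamma.
#' @return An `svm_model`: per-pair support coefficients and bias, training
#'   data reference, `gamma`, `C`, class levels.
#' @export
train_svm <- function(X, y, C = 1.0, bandwidth_mode = "variance-scaled") {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  y <- as.factor(y)
  levels_y <- levels(droplevels(y))
  if (length(levels_y) < 2L) stop("need at least 2 classes", call. = FALSE)
  gamma <- if (is.numeric(bandwidth_mode)) {
    if (bandwidth_mode <= 0) stop("gamma must be positive", call. = FALSE)
    bandwidth_mode
  } else {
    v <- stats::var(as.numeric(X)) * (length(X) - 1) / length(X)  # population var
    if (v <= 0) stop("zero-variance features: gamma heuristic undefined",
                     call. = FALSE)
    1 / (ncol(X) * v)
  }
  pairs_idx <- utils::combn(length(levels_y), 2)
  fits <- vector("list", ncol(pairs_idx))
  for (p in seq_len(ncol(pairs_idx))) {
    a <- levels_y[pairs_idx[1, p]]; bcl <- levels_y[pairs_idx[2, p]]
    sel <- y %in% c(a, bcl)
    Xs <- X[sel, , drop = FALSE]
    ys <- ifelse(y[sel] == a, 1, -1)  # +1 = first class of the pair
    K <- .rbf_kernel(Xs, Xs, gamma)
    sm <- .smo_fit(K, ys, C)
    sv <- sm$alpha > 1e-8
    fits[[p]] <- list(
      pair = c(a, bcl),
      sv_X = Xs[sv, , drop = FALSE],
      sv_coef = (sm$alpha * ys)[sv],
      b = sm$b
    )
  }
  structure(
    list(fits = fits, gamma = gamma, C = C, levels = levels_y,
         n_features = ncol(X)),
    class = "svm_model"
  )
}

#' Predict classes with a one-vs-one vote
#'
#' Each pairwise machine casts one vote per sample
#' (`sign(sum_i alpha_i y_i K(x_i, x) + b)`); the class with the most votes
#' wins. Vote ties are broken by the summed signed margins, then by class
#' order.
#'
#' @param object An `svm_model`.
#' @param newdata Numeric samples x features matrix (feature count must
#'   match training).
#' @param type `"class"` (default) for labels, `"votes"` for the per-class
#'   vote matrix, `"confidence"` for normalized vote shares.
#' @param ... Unused.
#' @return Character label vector (or a matrix for
#'   `type = "votes"` / `"confidence"`).
#' @export
predict.svm_model <- function(object, newdata, type = "class", ...) {
  type <- match.arg(type, c("class", "votes", "confidence"))
  X <- as.matrix(newdata)
  if (nrow(X) == 0L) {
    return(if (type == "class") character(0)
           else matrix(0, 0, length(object$levels),
                       dimnames = list(NULL, object$levels)))
  }
  if (ncol(X) != object$n_features) {
    stop("feature count does not match training data", call. = FALSE)
  }
  votes <- matrix(0, nrow(X), length(object$levels),
                  dimnames = list(NULL, object$levels))
  margin <- votes
  for (f in object$fits) {
    dec <- as.numeric(.rbf_kernel(X, f$sv_X, object$gamma) %*% f$sv_coef) + f$b
    win <- ifelse(dec >= 0, f$pair[1], f$pair[2])
    for (r in seq_len(nrow(X))) votes[r, win[r]] <- votes[r, win[r]] + 1
    margin[, f$pair[1]] <- margin[, f$pair[1]] + dec
    margin[, f$pair[2]] <- margin[, f$pair[2]] - dec
  }
  if (type == "votes") return(votes)
  if (type == "confidence") return(votes / rowSums(votes))
  apply(votes + 1e-9 * margin, 1, function(v) object$levels[which.max(v)])
}

#' Majority vote over pairwise outcomes
#'
#' The one-vs-one decision rule in isolation: given the winning class of
#' every pairwise contest, return the class with the most wins (ties ->
#' first class in `levels` order).
#'
#' @param pair_winners Character vector of pairwise winners.
#' @param levels Class levels defining tie-break order.
#' @return Winning class label.
#' @export
ovo_vote <- function(pair_winners, levels = sort(unique(pair_winners))) {
  counts <- table(factor(pair_winners, levels = levels))
  levels[which.max(counts)]
}
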