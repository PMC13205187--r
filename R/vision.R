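#' Patch tokenization arithmetic
#'
#' A square image is partitioned into non-overlapping `patch_size` x
#' `patch_size` tiles (remainder pixels cropped), each becoming one
#' transformer token: a 224-side image yields 14 x 14 = 196 tokens, a
#' 208-side image 13 x 13 = 169.
#'
#' @param image_side Image side in pixels (>= `patch_size`).
#' @param patch_size Patch side, default 16.
#' @return A `patch_grid`: list with `image_side`, `patch_size`,
#'   `tokens_per_side`, `token_count`.
#' @export
patch_tokens <- function(image_side, patch_size = 16L) {
  image_side <- as.integer(image_side)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("patch_size must be >= 1", call. = FALSE)
  if (image_side < patch_size) {
    stop("image_side must be >= patch_size", call. = FALSE)
  }
  tps <- image_side %/% patch_size
  structure(
    list(image_side = image_side, patch_size = patch_size,
         tokens_per_side = tps, token_count = tps * tps),
    class = "patch_grid"
  )
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`, softmax applied
#' row-wise; every attention-weight row sums to 1.
#'
#' @param Q Query matrix (tokens x d_k).
#' @param K Key matrix (source tokens x d_k).
#' @param V Value matrix (source tokens x d_v).
#' @param return_weights Also return the weight matrix (default `FALSE`).
#' @return Output matrix (tokens x d_v), or a list `(output, weights)`.
#' @export
attention <- function(Q, K, V, return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must share the token count", call. = FALSE)
  scores <- tcrossprod(Q, K) / sqrt(ncol(K))
  scores <- scores - apply(scores, 1, max)  # stabilized softmax
  w <- exp(scores)
  w <- w / rowSums(w)
  out <- w %*% V
  if (return_weights) list(output = out, weights = w) else out
}

#' Multi-head attention
#'
#' Q, K, V are split column-wise into `h` heads, scaled dot-product
#' attention runs per head, and the concatenated head outputs are linearly
#' projected by `W_o`.
#'
#' @param Q,K,V Token matrices with a common model dimension divisible by
#'   `h`.
#' @param h Number of heads.
#' @param W_o Output projection (model_dim x model_dim); identity by
#'   default.
#' @return Output matrix, same shape as `Q`.
#' @export
multi_head <- function(Q, K, V, h, W_o = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d <- ncol(Q)
  if (ncol(K) != d || ncol(V) != d) {
    stop("Q, K, V must share the model dimension", call. = FALSE)
  }
  if (d %% h != 0L) stop("model dimension not divisible by head count", call. = FALSE)
  if (is.null(W_o)) W_o <- diag(d)
  dh <- d %/% h
  heads <- lapply(seq_len(h), function(i) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
              V[, cols, drop = FALSE])
  })
  do.call(cbind, heads) %*% W_o
}

#' Depthwise-separable convolution cost ratio
#'
#' Standard convolution costs `D_K^2 M N D_F^2` multiply-adds; the
#' depthwise + pointwise factorization costs
#' `D_K^2 M D_F^2 + M N D_F^2`, a reduction factor of
#' `1/N + 1/D_K^2`.
#'
#' @param D_K Kernel side, `M_in` input channels, `N_out` output channels,
#'   `D_F` feature-map side; all positive integers.
#' @param M_in,N_out,D_F See `D_K`.
#' @return List: `cost_standard`, `cost_dsc`, `ratio`.
#' @export
dsc_cost_ratio <- function(D_K, M_in, N_out, D_F) {
  v <- c(D_K, M_in, N_out, D_F)
  if (any(v <= 0) || any(v != round(v))) {
    stop("all arguments must be positive integers", call. = FALSE)
  }
  cost_std <- D_K^2 * M_in * N_out * D_F^2
  cost_dsc <- D_K^2 * M_in * D_F^2 + M_in * N_out * D_F^2
  list(cost_standard = cost_std, cost_dsc = cost_dsc,
       ratio = 1 / N_out + 1 / D_K^2)
}

# ---- toy attention classifier -------------------------------------------

# Flatten an image into per-patch feature rows (token_count x patch_dim).
.patchify <- function(img, patch_size) {
  side <- nrow(img)
  tps <- side %/% patch_size
  out <- matrix(0, tps * tps, patch_size * patch_size)
  k <- 0L
  for (py in seq_len(tps)) {
    for (px in seq_len(tps)) {
      k <- k + 1L
      rows <- ((py - 1L) * patch_size + 1L):(py * patch_size)
      cols <- ((px - 1L) * patch_size + 1L):(px * patch_size)
      out[k, ] <- as.numeric(img[rows, cols])
    }
  }
  out
}

# Token features for one image, flattened for the linear head: the
# residual attention-mixed tokens E + Attention(EWq, EWk, EWv) when
# attention is enabled, the bare per-patch embeddings E when disabled
# (no mixing across tokens -- the patch-wise-only ablation).
.toy_features <- function(img, proj, use_attention) {
  P <- .patchify(img, proj$patch_size)
  E <- tanh(P %*% proj$W_embed)      # token_count x d
  if (use_attention) {
    E <- E + attention(E %*% proj$W_q, E %*% proj$W_k, E %*% proj$W_v)
  }
  as.numeric(E)
}

# Multinomial logistic head trained by batch gradient descent.
.fit_softmax_head <- function(F_mat, y_int, n_classes, lr = 0.5,
                              epochs = 300L, l2 = 1e-4) {
  n <- nrow(F_mat); d <- ncol(F_mat)
  W <- matrix(0, d + 1L, n_classes)
  Xb <- cbind(1, F_mat)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y_int)] <- 1
  for (e in seq_len(epochs)) {
    Z <- Xb %*% W
    Z <- Z - apply(Z, 1, max)
    Pm <- exp(Z); Pm <- Pm / rowSums(Pm)
    G <- t(Xb) %*% (Pm - Y) / n + l2 * rbind(0, W[-1, , drop = FALSE])
    W <- W - lr * G
  }
  W
}

#' Train a desk-scale attention classifier on encoded images
#'
#' A deliberately small stand-in for a full vision transformer: fixed
#' seeded random patch embedding and Q/K/V projections, one scaled
#' dot-product attention block with a residual connection, and a
#' multinomial logistic head over the flattened token features trained by
#' gradient descent. `use_attention = FALSE` removes the attention mixing
#' (the head then sees per-patch features only), giving the
#' attention-ablation variant.
#'
#' @param images List of square numeric matrices (all the same side).
#' @param labels Class labels, one per image (>= 2 classes).
#' @param patch_size Patch side, default 16.
#' @param d_model Per-token embedding dimension, default 8 (the head sees
#'   `token_count * d_model` features).
#' @param use_attention Include the attention block (default `TRUE`).
#' @param seed Integer seed for the random projections.
#' @param epochs,lr Head-training schedule.
#' @return A `toy_vit_model` with a `predict` method.
#' @export
toy_attention_classifier <- function(images, labels, patch_size = 16L,
                                     d_model = 8L, use_attention = TRUE,
                                     seed = 1L, epochs = 300L, lr = 0.5) {
  y <- as.factor(labels)
  if (length(levels(droplevels(y))) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (length(images) != length(y)) stop("one label per image", call. = FALSE)
  side <- nrow(images[[1L]])
  if (side < patch_size) stop("image smaller than one patch", call. = FALSE)
  pdim <- patch_size * patch_size
  set.seed(seed)
  proj <- list(
    patch_size = patch_size,
    W_embed = matrix(stats::rnorm(pdim * d_model, 0, 1 / sqrt(pdim)),
                     pdim, d_model),
    W_q = matrix(stats::rnorm(d_model^2, 0, 1 / sqrt(d_model)), d_model, d_model),
    W_k = matrix(stats::rnorm(d_model^2, 0, 1 / sqrt(d_model)), d_model, d_model),
    W_v = matrix(stats::rnorm(d_model^2, 0, 1 / sqrt(d_model)), d_model, d_model)
  )
  tok <- (side %/% patch_size)^2
  F_mat <- t(vapply(images, .toy_features, numeric(tok * d_model),
                    proj = proj, use_attention = use_attention))
  # centered but deliberately not variance-scaled: rescaling near-constant
  # token features amplifies noise and destabilizes the linear head
  mu <- colMeans(F_mat)
  W <- .fit_softmax_head(sweep(F_mat, 2, mu), as.integer(y),
                         length(levels(y)), lr = lr, epochs = epochs)
  structure(
    list(proj = proj, W = W, levels = levels(y), feat_mean = mu,
         use_attention = use_attention, d_model = d_model,
         n_features = ncol(F_mat), seed = seed),
    class = "toy_vit_model"
  )
}

#' @export
predict.toy_vit_model <- function(object, images, ...) {
  F_mat <- t(vapply(images, .toy_features, numeric(object$n_features),
                    proj = object$proj, use_attention = object$use_attention))
  Z <- cbind(1, sweep(F_mat, 2, object$feat_mean)) %*% object$W
  object$levels[max.col(Z, ties.method = "first")]
}
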