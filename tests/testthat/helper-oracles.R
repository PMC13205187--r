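# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity in the most naive way possible (double loops,
# direct counting) so they share no code path with the implementation.

naive_gasf <- function(x) {
  phi <- acos(x)
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) m[i, j] <- cos(phi[i] + phi[j])
  m
}

naive_gadf <- function(x) {
  phi <- acos(x)
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) m[i, j] <- sin(phi[i] - phi[j])
  m
}

naive_igaf <- function(x) {
  gd <- naive_gadf(x); gs <- naive_gasf(x)
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- if (i <= j) gd[i, j] else gs[i, j]
  }
  m
}

# Transition matrix by direct pair counting.
naive_transition <- function(states, q) {
  W <- matrix(0, q, q)
  for (k in seq_len(length(states) - 1L)) {
    W[states[k] + 1L, states[k + 1L] + 1L] <-
      W[states[k] + 1L, states[k + 1L] + 1L] + 1
  }
  for (i in seq_len(q)) {
    s <- sum(W[i, ])
    if (s > 0) W[i, ] <- W[i, ] / s
  }
  W
}

naive_mtf <- function(states, W) {
  n <- length(states)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- W[states[i] + 1L, states[j] + 1L]
  }
  m
}

# Equal-frequency states via explicit rank/ceiling arithmetic.
naive_states <- function(x, q) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(q * r / n) - 1L)
}

# Two-loop softmax attention.
naive_attention <- function(Q, K, V) {
  n_q <- nrow(Q); n_k <- nrow(K)
  out <- matrix(0, n_q, ncol(V))
  for (i in seq_len(n_q)) {
    s <- numeric(n_k)
    for (j in seq_len(n_k)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(K))
    w <- exp(s - max(s)); w <- w / sum(w)
    for (j in seq_len(n_k)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# Recursive flood-fill component counter (8-connectivity).
naive_component_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c <- p[2]
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
      if (!mask[r, c] || seen[r, c]) next
      seen[r, c] <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr || dc) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
      }
    }
  }
  count
}

# Macro metrics recomputed class by class from first principles.
naive_macro <- function(m) {
  k <- nrow(m); tot <- sum(m)
  prec <- rec <- f1 <- numeric(k)
  for (c_ in seq_len(k)) {
    tp <- m[c_, c_]
    fp <- sum(m[, c_]) - tp
    fn <- sum(m[c_, ]) - tp
    prec[c_] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c_] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c_] <- if (prec[c_] + rec[c_] > 0)
      2 * prec[c_] * rec[c_] / (prec[c_] + rec[c_]) else 0
  }
  list(accuracy = sum(diag(m)) / tot, precision = mean(prec),
       recall = mean(rec), f1 = mean(f1))
}

# Small labeled synthetic dataset shared by several tests.
make_small_dataset <- function(n_per_class = 12, n_wavelengths = 200,
                               noise_sd = 0.01, seed = 101) {
  generate_dataset(rep(n_per_class, 3),
                   spectrum_sim_config(n_wavelengths = n_wavelengths,
                                       noise_sd = noise_sd),
                   seed = seed)
}
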