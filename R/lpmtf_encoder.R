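#' Piecewise aggregate approximation
#'
#' Non-overlapping window means: element k of the output is the mean of
#' points `(k-1)*w + 1 .. k*w`. A trailing remainder shorter than the
#' window is dropped, so a 1044-point spectrum with the default window 5
#' reduces to 208 points (and hence a 208-side field, i.e. a 13 x 13 grid
#' of 16-pixel patches, 169 tokens).
#'
#' @param x Numeric vector (or `pear_spectrum` / `normalized_series`).
#' @param window_size Positive integer window, default 5.
#' @return Numeric vector of length `floor(length(x) / window_size)`.
#' @export
paa <- function(x, window_size = 5L) {
  if (inherits(x, "pear_spectrum")) x <- x$intensities
  if (inherits(x, "normalized_series")) x <- x$values
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) {
    stop("window_size must be >= 1", call. = FALSE)
  }
  n_out <- length(x) %/% window_size
  if (n_out < 1L) stop("series shorter than one window", call. = FALSE)
  colMeans(matrix(x[seq_len(n_out * window_size)], nrow = window_size))
}

#' Equal-frequency quantile discretization
#'
#' Assigns each point a state in `0..q-1` by rank: state of the r-th
#' smallest of n points is `ceiling(q * r / n) - 1`. Ties are broken by
#' original order (stable), so bin occupancies differ by at most one when
#' values are distinct.
#'
#' @param x Numeric vector, length >= `q`.
#' @param q Number of quantile bins, default 12.
#' @return A `state_sequence`: list with `states` (integer vector in
#'   `0..q-1`), `q`, and `bin_edges` (upper value boundary of each bin).
#' @export
quantile_discretize <- function(x, q = 12L) {
  q <- as.integer(q)
  if (is.na(q) || q < 2L) stop("q must be >= 2", call. = FALSE)
  n <- length(x)
  if (n < q) stop("series shorter than q: equal-frequency bins undefined",
                  call. = FALSE)
  r <- rank(x, ties.method = "first")
  states <- as.integer(ceiling(q * r / n) - 1L)
  xs <- sort(x)
  edges <- xs[ceiling(seq_len(q) * n / q)]
  structure(list(states = states, q = q, bin_edges = edges),
            class = "state_sequence")
}

#' First-order Markov transition matrix over quantile states
#'
#' `W[i, j]` is the probability of moving from state i to state j between
#' adjacent time points: observed i->j transitions divided by transitions
#' leaving i. States with no outgoing observation get an all-zero row.
#'
#' @param states A `state_sequence` or integer vector of states in
#'   `0..q-1`.
#' @param q Number of states (taken from the `state_sequence` if given).
#' @return A `transition_model`: list with `W` (q x q row-stochastic
#'   matrix, zero rows allowed) and `q`.
#' @export
transition_matrix <- function(states, q = NULL) {
  if (inherits(states, "state_sequence")) {
    q <- states$q
    states <- states$states
  }
  q <- as.integer(q)
  states <- as.integer(states)
  if (length(states) < 2L) stop("need at least 2 states", call. = FALSE)
  if (any(states < 0L | states >= q)) stop("state out of range", call. = FALSE)
  from <- states[-length(states)]
  to <- states[-1L]
  W <- matrix(0, q, q)
  for (k in seq_along(from)) W[from[k] + 1L, to[k] + 1L] <-
      W[from[k] + 1L, to[k] + 1L] + 1
  rs <- rowSums(W)
  nz <- rs > 0
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  structure(list(W = W, q = q), class = "transition_model")
}

#' Expand states and transition matrix into a Markov transition field
#'
#' `M[i, j] = W[s_i, s_j]` for every pair of time indices, giving an
#' N' x N' image whose texture encodes the transition structure of the
#' series.
#'
#' @param states A `state_sequence` or integer state vector.
#' @param model A `transition_model` (from [transition_matrix()]).
#' @return Numeric N' x N' matrix with entries in `[0, 1]`.
#' @export
mtf_expand <- function(states, model) {
  if (inherits(states, "state_sequence")) states <- states$states
  stopifnot(inherits(model, "transition_model"))
  states <- as.integer(states)
  if (any(states < 0L | states >= model$q)) {
    stop("state out of range for transition model", call. = FALSE)
  }
  n <- length(states)
  matrix(model$W[cbind(rep(states + 1L, times = n),
                       rep(states + 1L, each = n))],
         nrow = n)
}

#' Build a Gaussian/Laplacian pyramid
#'
#' Gaussian levels are produced by 5-tap binomial blur followed by factor-2
#' decimation (side of level k+1 = ceil(side_k / 2)); band-pass Laplacian
#' levels are `L_k = G_k - upsample(G_{k+1})` with bilinear upsampling, so
#' `G_k = L_k + upsample(G_{k+1})` reconstructs exactly by construction.
#'
#' @param image Square numeric matrix, side >= `2^levels`.
#' @param levels Number of Laplacian levels, default 3 (stack L0, L1, L2,
#'   G3).
#' @return A `pyramid_stack`: list with `gaussian` (levels G0..G_levels)
#'   and `laplacian` (L0..L_{levels-1}).
#' @export
build_pyramids <- function(image, levels = 3L) {
  stopifnot(is.matrix(image))
  if (nrow(image) != ncol(image)) stop("image must be square", call. = FALSE)
  if (nrow(image) < 2^levels) stop("image too small for pyramid depth",
                                   call. = FALSE)
  G <- vector("list", levels + 1L)
  G[[1L]] <- image
  for (k in seq_len(levels)) {
    blurred <- .binomial_blur(G[[k]])
    G[[k + 1L]] <- blurred[seq(1L, nrow(blurred), by = 2L),
                           seq(1L, ncol(blurred), by = 2L), drop = FALSE]
  }
  L <- vector("list", levels)
  for (k in seq_len(levels)) {
    up <- .bilinear_resize(G[[k + 1L]], nrow(G[[k]]), ncol(G[[k]]))
    L[[k]] <- G[[k]] - up
  }
  structure(list(gaussian = G, laplacian = L, levels = levels),
            class = "pyramid_stack")
}

#' Weighted fusion of a Laplacian pyramid stack
#'
#' Upsamples every layer (L0..L_{levels-1} and the residual Gaussian top)
#' to the base side, combines them as a weighted sum, and min-max rescales
#' the result to `[0, 1]`.
#'
#' @param stack A `pyramid_stack`.
#' @param weights Non-negative weights, one per layer (L0..L2, G_top),
#'   summing to 1 (within 1e-9). Default equal weights.
#' @return Numeric matrix, base side, values in `[0, 1]`.
#' @export
fuse_pyramid <- function(stack, weights = NULL) {
  stopifnot(inherits(stack, "pyramid_stack"))
  n_layers <- stack$levels + 1L
  if (is.null(weights)) weights <- rep(1 / n_layers, n_layers)
  if (length(weights) != n_layers || any(weights < 0)) {
    stop(sprintf("need %d non-negative weights", n_layers), call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("fusion weights must sum to 1", call. = FALSE)
  }
  side <- nrow(stack$gaussian[[1L]])
  layers <- c(stack$laplacian, stack$gaussian[n_layers])
  fused <- matrix(0, side, side)
  for (k in seq_len(n_layers)) {
    fused <- fused + weights[k] * .bilinear_resize(layers[[k]], side, side)
  }
  lo <- min(fused); hi <- max(fused)
  if (hi > lo) (fused - lo) / (hi - lo) else matrix(0, side, side)
}

#' Laplacian pyramid Markov transition field encoding
#'
#' Full pipeline: `[0,1]` min-max normalization -> PAA (window means) ->
#' equal-frequency quantile discretization -> Markov transition matrix ->
#' field expansion -> 3-level Laplacian pyramid -> weighted layer fusion ->
#' `[0,1]` image of side `floor(N / window_size)`.
#'
#' @param x Numeric vector or `pear_spectrum`.
#' @param q Quantile bin count, default 12.
#' @param window_size PAA window, default 5.
#' @param weights Fusion weights (see [fuse_pyramid()]), default equal.
#' @param levels Pyramid depth, default 3.
#' @return List of class `lpmtf_image`: `matrix` (side x side in `[0,1]`),
#'   `side`, and the parameters used.
#' @export
lpmtf <- function(x, q = 12L, window_size = 5L, weights = NULL, levels = 3L) {
  if (inherits(x, "pear_spectrum")) x <- x$intensities
  if (length(x) < q * window_size) {
    stop("series too short for the requested q and window_size", call. = FALSE)
  }
  xn <- minmax_normalize(x, "[0,1]")$values
  agg <- paa(xn, window_size)
  ss <- quantile_discretize(agg, q)
  tm <- transition_matrix(ss)
  M <- mtf_expand(ss, tm)
  stack <- build_pyramids(M, levels)
  fused <- fuse_pyramid(stack, weights)
  structure(
    list(matrix = fused, side = nrow(fused), q = q,
         window_size = window_size,
         weights = if (is.null(weights)) rep(1 / (levels + 1), levels + 1)
                   else weights,
         levels = levels),
    class = "lpmtf_image"
  )
}

#' @export
print.lpmtf_image <- function(x, ...) {
  cat(sprintf("<lpmtf_image> %dx%d (q=%d, window=%d)\n",
              x$side, x$side, x$q, x$window_size))
  invisible(x)
}
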