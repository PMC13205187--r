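# Shared low-level image primitives (no image-processing package is
# assumed): bilinear resize, separable binomial blur with reflect padding,
# connected-component labeling, flood fill. All matrices are row-major
# conceptually: row = y (origin top-left), column = x.

# Bilinear interpolation of `img` (matrix) to out_h x out_w, using the
# align-corners-free pixel-center convention (matches common CV resizers).
.bilinear_resize <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  if (out_h == in_h && out_w == in_w) return(img)
  sy <- in_h / out_h; sx <- in_w / out_w
  yc <- (seq_len(out_h) - 0.5) * sy - 0.5
  xc <- (seq_len(out_w) - 0.5) * sx - 0.5
  y0 <- pmin(pmax(floor(yc), 0), in_h - 1)
  x0 <- pmin(pmax(floor(xc), 0), in_w - 1)
  y1 <- pmin(y0 + 1, in_h - 1)
  x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(yc - y0, 0), 1)
  wx <- pmin(pmax(xc - x0, 0), 1)
  A <- img[y0 + 1, x0 + 1, drop = FALSE]
  B <- img[y0 + 1, x1 + 1, drop = FALSE]
  C <- img[y1 + 1, x0 + 1, drop = FALSE]
  D <- img[y1 + 1, x1 + 1, drop = FALSE]
  Wy <- matrix(wy, length(yc), length(xc))
  Wx <- matrix(wx, length(yc), length(xc), byrow = TRUE)
  (1 - Wy) * ((1 - Wx) * A + Wx * B) + Wy * ((1 - Wx) * C + Wx * D)
}

# Reflect-pad a matrix by k pixels on every side (edge mirror without
# repeating the border pixel is not required here; simple reflection).
.reflect_pad <- function(m, k) {
  n_r <- nrow(m); n_c <- ncol(m)
  ri <- c(rev(seq_len(min(k, n_r))), seq_len(n_r),
          n_r - seq_len(min(k, n_r)) + 1L)
  ci <- c(rev(seq_len(min(k, n_c))), seq_len(n_c),
          n_c - seq_len(min(k, n_c)) + 1L)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with an odd-length 1D kernel, reflect padding.
.sep_conv <- function(m, kern) {
  k <- (length(kern) - 1L) / 2L
  p <- .reflect_pad(m, k)
  # rows pass
  acc <- matrix(0, nrow(p), ncol(m))
  for (j in seq_along(kern)) {
    acc <- acc + kern[j] * p[, (j - 1L) + seq_len(ncol(m)), drop = FALSE]
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kern)) {
    out <- out + kern[j] * acc[(j - 1L) + seq_len(nrow(m)), , drop = FALSE]
  }
  out
}

# 5-tap binomial (Burt-Adelson) blur.
.binomial_blur <- function(m) .sep_conv(m, c(1, 4, 6, 4, 1) / 16)

# Shift a matrix by (dy, dx), padding with `fill`.
.shift_mat <- function(m, dy, dx, fill = 0) {
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(fill, n_r, n_c)
  sr <- max(1, 1 + dy):min(n_r, n_r + dy)
  sc <- max(1, 1 + dx):min(n_c, n_c + dx)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

#' Label connected components under 8-connectivity
#'
#' Pure vectorized label propagation: every foreground pixel starts with a
#' unique label and repeatedly takes the minimum label over its 8-neighbors
#' until a fixed point; labels are then compacted to 1..n_components.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @return List: `labels` (integer matrix, 0 = background), `areas`
#'   (integer vector of per-component pixel counts, label order),
#'   `n_components`.
#' @export
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  n_r <- nrow(mask); n_c <- ncol(mask)
  lab <- matrix(Inf, n_r, n_c)
  lab[mask] <- which(mask)
  if (!any(mask)) {
    return(list(labels = matrix(0L, n_r, n_c), areas = integer(0),
                n_components = 0L))
  }
  nbr <- expand.grid(dy = -1:1, dx = -1:1)
  nbr <- nbr[!(nbr$dy == 0 & nbr$dx == 0), ]
  repeat {
    new <- lab
    for (k in seq_len(nrow(nbr))) {
      new <- pmin(new, .shift_mat(lab, nbr$dy[k], nbr$dx[k], fill = Inf))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[mask]))
  out <- matrix(0L, n_r, n_c)
  out[mask] <- match(lab[mask], ids)
  areas <- tabulate(out[mask], nbins = length(ids))
  list(labels = out, areas = as.integer(areas),
       n_components = length(ids))
}

# One 3x3 (8-neighborhood) binary dilation.
.dilate3 <- function(mask) {
  out <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out | .shift_mat(mask, dy, dx, FALSE)
  }
  out
}

# One 3x3 (8-neighborhood) binary erosion.
.erode3 <- function(mask) !.dilate3(!mask)

# Flood fill (4-connectivity) of `open` pixels reachable from the image
# border, via iterative dilation; returns logical reachable mask.
.flood_from_border <- function(open) {
  n_r <- nrow(open); n_c <- ncol(open)
  reach <- matrix(FALSE, n_r, n_c)
  reach[1, ] <- open[1, ]; reach[n_r, ] <- open[n_r, ]
  reach[, 1] <- open[, 1]; reach[, n_c] <- open[, n_c]
  repeat {
    grown <- reach |
      .shift_mat(reach, 1L, 0L, FALSE) | .shift_mat(reach, -1L, 0L, FALSE) |
      .shift_mat(reach, 0L, 1L, FALSE) | .shift_mat(reach, 0L, -1L, FALSE)
    grown <- grown & open
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}
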