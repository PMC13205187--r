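#' Split an RGB image into channel planes
#'
#' @param image H x W x 3 numeric array.
#' @return List with matrices `R`, `G`, `B` (lossless).
#' @export
split_channels <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  list(R = image[, , 1], G = image[, , 2], B = image[, , 3])
}

# Canny edge detector: binomial smoothing, Sobel gradients, 4-direction
# non-maximum suppression, median-derived double threshold, hysteresis.
.canny_edges <- function(gray, low = NULL, high = NULL) {
  g <- .binomial_blur(gray)
  # 3-tap passes along columns (vertical) / rows (horizontal), reflect-padded
  vpass <- function(m, k) {
    p <- .reflect_pad(m, 1L)
    k[1] * p[1:nrow(m), 2:(ncol(m) + 1)] +
      k[2] * p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] +
      k[3] * p[3:(nrow(m) + 2), 2:(ncol(m) + 1)]
  }
  hpass <- function(m, k) {
    p <- .reflect_pad(m, 1L)
    k[1] * p[2:(nrow(m) + 1), 1:ncol(m)] +
      k[2] * p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] +
      k[3] * p[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  }
  gx <- vpass(hpass(g, c(-1, 0, 1)), c(1, 2, 1))  # Sobel x
  gy <- hpass(vpass(g, c(-1, 0, 1)), c(1, 2, 1))  # Sobel y
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)  # radians

  # quantize direction into 0, 45, 90, 135 degrees
  d <- ((round(ang / (pi / 4)) %% 4) + 4) %% 4
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  # (dy, dx) along the gradient for buckets 0/45/90/135 degrees
  dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (k in 0:3) {
    sel <- d == k
    off <- dirs[[k + 1L]]
    n1 <- .shift_mat(mag, off[1], off[2], 0)
    n2 <- .shift_mat(mag, -off[1], -off[2], 0)
    keep[sel] <- (mag >= n1 & mag >= n2)[sel]
  }
  thin <- mag * keep

  # auto thresholds from the smoothed-image median (8-bit convention)
  scale255 <- if (max(g) <= 1.5) 255 else 1
  med <- stats::median(g) * scale255
  if (is.null(low)) low <- max(0.66 * med, 1e-6)
  if (is.null(high)) high <- max(1.33 * med, 2e-6)
  thin255 <- thin * scale255
  strong <- thin255 >= high
  weak <- thin255 >= low

  # hysteresis: keep weak edges 8-connected to a strong edge
  reach <- strong
  repeat {
    grown <- reach
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | .shift_mat(reach, dy, dx, FALSE)
    }
    grown <- grown & weak
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

.to_gray <- function(image) {
  if (length(dim(image)) == 3L) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    image
  }
}

#' Extract the cross-section region from a photograph
#'
#' Canny edges are traced, the area enclosed by edges (not reachable from
#' the image border) is filled, and the largest 8-connected filled region
#' is taken as the fruit cross-section.
#'
#' @param image Grayscale matrix or H x W x 3 RGB array.
#' @return List: `mask` (logical matrix), `S2` (cross-section pixel area).
#' @export
cross_section_mask <- function(image) {
  gray <- .to_gray(image)
  edges <- .canny_edges(gray)
  if (!any(edges)) stop("no closed contour found", call. = FALSE)
  # Thin Canny chains are 8-connected: dilate once so the 4-connected
  # border flood cannot leak through diagonal gaps.
  edges_d <- .dilate3(edges)
  background <- .flood_from_border(!edges_d)
  filled <- !background  # enclosed interiors plus their edge bands
  comp <- label_components_8(filled)
  if (comp$n_components == 0L || max(comp$areas) < 9L) {
    stop("no closed contour found", call. = FALSE)
  }
  biggest <- comp$labels == which.max(comp$areas)
  # The filled region overshoots the contour by the dilated edge band
  # (~2 px); erode back so the mask stops at the traced contour.
  mask <- .erode3(.erode3(biggest))
  if (!any(mask)) stop("no closed contour found", call. = FALSE)
  list(mask = mask, S2 = sum(mask))
}

#' Ridler-Calvard (isodata) iterative threshold
#'
#' Starting from the grand mean, T is updated to the midpoint of the means
#' of the two classes it induces (`values <= T` vs `values > T`) until the
#' update is below `tol` (0.5 on an 8-bit intensity scale, rescaled for
#' other ranges).
#'
#' @param plane Numeric vector or matrix of intensities (non-constant).
#' @param tol Convergence tolerance; default 0.5 scaled by
#'   `range/255`.
#' @param max_iter Iteration cap, default 100.
#' @return Converged threshold value.
#' @export
iterative_threshold <- function(plane, tol = NULL, max_iter = 100L) {
  v <- as.numeric(plane)
  rng <- range(v)
  if (!(rng[2] > rng[1])) stop("constant plane: threshold undefined",
                               call. = FALSE)
  if (is.null(tol)) tol <- max(0.5 * (rng[2] - rng[1]) / 255, 1e-12)
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t_cur]; hi <- v[v > t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Grade a moldy-core percentage
#'
#' `S <= healthy_eps` -> healthy; `healthy_eps < S <= 10` -> slight
#' (boundary inclusive); `S > 10` -> severe. `healthy_eps` (default 0.1
#' percentage point) absorbs pixel noise around the literal S = 0 class
#' boundary; set it to 0 for the exact rule.
#'
#' @param S Moldy area percentage in `[0, 100]`.
#' @param healthy_eps Tolerance on the healthy boundary, default 0.1.
#' @return One of `"healthy"`, `"slight"`, `"severe"`.
#' @export
grade <- function(S, healthy_eps = 0.1) {
  if (is.na(S) || S < 0 || S > 100) stop("S must be in [0, 100]", call. = FALSE)
  if (S <= healthy_eps) "healthy" else if (S <= 10) "slight" else "severe"
}

#' Quantify moldy-core extent from a cross-section photograph
#'
#' Pipeline: cross-section contour mask (Canny + fill) -> iterative
#' thresholding of the blue channel inside the mask (browning darkens the
#' blue channel, so mold = below-threshold pixels) -> 8-connectivity
#' component labeling -> small-component suppression -> moldy area S1,
#' ratio `S = S1 / S2 * 100`, and grade.
#'
#' A threshold is only applied when the two induced class means are
#' separated by more than `min_separation` (in plane intensity units);
#' otherwise the section is treated as mold-free, which keeps pure sensor
#' noise from being split into a phantom mold class.
#'
#' @param image H x W x 3 RGB array (values in `[0,1]` or 8-bit).
#' @param min_area Minimum component area in pixels (default 20).
#' @param healthy_eps Healthy-grade tolerance in percentage points
#'   (default 0.1).
#' @param min_separation Minimum between-class mean separation for the
#'   threshold to count as evidence of mold; default 0.1 for unit-scaled
#'   images (25.5 on an 8-bit scale).
#' @return A `mold_quant_result`: list with `S1`, `S2`, `S`, `grade`,
#'   `component_count`, `threshold`, `mold_mask`, `section_mask`.
#' @export
quantify <- function(image, min_area = 20L, healthy_eps = 0.1,
                     min_separation = NULL) {
  ch <- split_channels(image)
  cs <- cross_section_mask(image)
  # Threshold strictly inside the contour: the first few pixels at the rim
  # are background/flesh mixels whose low blue values would masquerade as
  # mold on a healthy section.
  inner <- .erode3(.erode3(.erode3(cs$mask)))
  if (!any(inner)) inner <- cs$mask
  b_in <- ch$B[inner]
  if (is.null(min_separation)) {
    min_separation <- if (max(ch$B) <= 1.5) 0.1 else 25.5
  }
  S1 <- 0L; n_comp <- 0L; thr <- NA_real_
  mold_mask <- matrix(FALSE, nrow(ch$B), ncol(ch$B))
  if (diff(range(b_in)) > 0) {
    thr <- iterative_threshold(b_in)
    sep <- mean(b_in[b_in > thr]) - mean(b_in[b_in <= thr])
    if (is.finite(sep) && sep >= min_separation) {
      cand <- inner & ch$B < thr
      comp <- label_components_8(cand)
      keep <- which(comp$areas >= min_area)
      n_comp <- length(keep)
      if (n_comp > 0L) {
        mold_mask <- matrix(comp$labels %in% keep,
                            nrow(comp$labels), ncol(comp$labels))
        S1 <- sum(comp$areas[keep])
      }
    }
  }
  S <- S1 / cs$S2 * 100
  structure(
    list(S1 = as.integer(S1), S2 = as.integer(cs$S2), S = S,
         grade = grade(S, healthy_eps), component_count = n_comp,
         threshold = thr, mold_mask = mold_mask, section_mask = cs$mask),
    class = "mold_quant_result"
  )
}

#' @export
print.mold_quant_result <- function(x, ...) {
  cat(sprintf("<mold_quant_result> S1=%d px, S2=%d px, S=%.2f%%, grade=%s (%d component%s)\n",
              x$S1, x$S2, x$S, x$grade, x$component_count,
              if (x$component_count == 1L) "" else "s"))
  invisible(x)
}
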