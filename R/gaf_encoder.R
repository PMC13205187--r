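#' Map a normalized series to polar angles
#'
#' The Gramian angular encodings represent each normalized value as the
#' angle `phi_i = arccos(x_i)`, so the series must lie in `[-1, 1]`
#' (see [minmax_normalize()]). Values are clipped to the domain only within
#' a 1e-12 rounding slack.
#'
#' @param x Numeric vector in `[-1, 1]`, or a `normalized_series` in
#'   `"[-1,1]"` mode.
#' @return Angle vector in radians, each in `[0, pi]`.
#' @export
to_polar <- function(x) {
  if (inherits(x, "normalized_series")) {
    if (x$range_mode != "[-1,1]") {
      stop("polar mapping requires a [-1,1]-normalized series", call. = FALSE)
    }
    x <- x$values
  }
  if (any(x < -1 - 1e-12) || any(x > 1 + 1e-12)) {
    stop("values outside [-1, 1]: normalize before polar mapping", call. = FALSE)
  }
  acos(pmin(pmax(x, -1), 1))
}

.as_unit_series <- function(x) {
  if (inherits(x, "pear_spectrum")) x <- minmax_normalize(x, "[-1,1]")
  if (inherits(x, "normalized_series")) {
    if (x$range_mode != "[-1,1]") {
      stop("Gramian encodings require [-1,1] normalization", call. = FALSE)
    }
    x <- x$values
  }
  if (length(x) < 2L) stop("series must have length >= 2", call. = FALSE)
  as.numeric(x)
}

.gaf_image <- function(m, variant) {
  structure(list(matrix = m, variant = variant, side = nrow(m)),
            class = "gaf_image")
}

#' @export
print.gaf_image <- function(x, ...) {
  cat(sprintf("<gaf_image> %s %dx%d, range [%.3f, %.3f]\n", x$variant,
              x$side, x$side, min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Gramian angular summation field
#'
#' `GASF[i, j] = cos(phi_i + phi_j)`: a symmetric N x N image encoding
#' pairwise angular sums of the polar-mapped series. Equals the algebraic
#' form `x' x - sqrt(1 - x^2)' sqrt(1 - x^2)`.
#'
#' @param x Series accepted by [to_polar()] (vector, `normalized_series`,
#'   or `pear_spectrum` which is normalized internally).
#' @return A `gaf_image` (variant `"GASF"`), entries in `[-1, 1]`.
#' @export
gasf <- function(x) {
  phi <- to_polar(.as_unit_series(x))
  .gaf_image(cos(outer(phi, phi, `+`)), "GASF")
}

#' Gramian angular difference field
#'
#' `GADF[i, j] = sin(phi_i - phi_j)`: antisymmetric with a zero diagonal.
#'
#' @inheritParams gasf
#' @return A `gaf_image` (variant `"GADF"`), entries in `[-1, 1]`.
#' @export
gadf <- function(x) {
  phi <- to_polar(.as_unit_series(x))
  m <- sin(outer(phi, phi, `-`))
  diag(m) <- 0  # sin(0), kill rounding residue
  .gaf_image(m, "GADF")
}

#' Improved (fused) Gramian angular field
#'
#' Both GASF and GADF are redundant across their diagonal, so the fused
#' IGAF keeps the GADF on the upper triangle including the diagonal
#' (`i <= j`, hence a zero diagonal) and the GASF on the strict lower
#' triangle (`i > j`), capturing angular differences and sums in one image.
#'
#' @inheritParams gasf
#' @return A `gaf_image` (variant `"IGAF"`), entries in `[-1, 1]`,
#'   zero diagonal.
#' @export
igaf <- function(x) {
  s <- .as_unit_series(x)
  gd <- gadf(s)$matrix
  gs <- gasf(s)$matrix
  m <- gd
  low <- lower.tri(m, diag = FALSE)  # row index i > column index j
  m[low] <- gs[low]
  .gaf_image(m, "IGAF")
}

#' Resize a square image by bilinear interpolation
#'
#' Used to present an encoded image at a model input side (e.g. a
#' 1044 x 1044 IGAF at 224 so a 16-pixel patch grid yields 14 x 14 = 196
#' tokens). Output values are clamped to the input range.
#'
#' @param image Square numeric matrix or a `gaf_image`.
#' @param target_side Positive integer output side.
#' @param method Only `"bilinear"` is implemented.
#' @return Same type as the input, resized.
#' @export
resize_square <- function(image, target_side, method = "bilinear") {
  method <- match.arg(method, "bilinear")
  is_gaf <- inherits(image, "gaf_image")
  m <- if (is_gaf) image$matrix else image
  stopifnot(is.matrix(m))
  if (nrow(m) != ncol(m)) stop("input image must be square", call. = FALSE)
  if (target_side < 1) stop("target_side must be >= 1", call. = FALSE)
  out <- .bilinear_resize(m, target_side, target_side)
  out <- pmin(pmax(out, min(m)), max(m))
  if (is_gaf) .gaf_image(out, image$variant) else out
}
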