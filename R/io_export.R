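# Export conventions shared by both encoders: 8-bit grayscale PNG (affine
# value-range map to [0,255]), lossless float matrix CSV, metadata JSON.

#' Write an encoded image to PNG + float matrix + metadata
#'
#' @param img A `gaf_image`, `lpmtf_image`, or plain matrix.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.png`, `<prefix>.csv`, `<prefix>.json`.
#' @param value_range Affine source range mapped to `[0, 255]` for the
#'   PNG; defaults to `[-1, 1]` for Gramian images, `[0, 1]` otherwise.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_encoded_image <- function(img, path_prefix, value_range = NULL) {
  meta <- list(package = "pearspec",
               version = as.character(utils::packageVersion("pearspec")))
  if (inherits(img, "gaf_image")) {
    m <- img$matrix
    meta$method <- img$variant
    if (is.null(value_range)) value_range <- c(-1, 1)
  } else if (inherits(img, "lpmtf_image")) {
    m <- img$matrix
    meta$method <- "LPMTF"
    meta$q <- img$q
    meta$window_size <- img$window_size
    meta$weights <- img$weights
    if (is.null(value_range)) value_range <- c(0, 1)
  } else {
    m <- as.matrix(img)
    meta$method <- "matrix"
    if (is.null(value_range)) value_range <- range(m)
  }
  meta$side <- nrow(m)
  meta$value_range <- value_range
  u <- (m - value_range[1]) / max(value_range[2] - value_range[1], 1e-300)
  png_path <- paste0(path_prefix, ".png")
  png::writePNG(pmin(pmax(u, 0), 1), png_path)
  csv_path <- paste0(path_prefix, ".csv")
  utils::write.table(format(m, digits = 17), csv_path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  json_path <- paste0(path_prefix, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png = png_path, csv = csv_path, json = json_path))
}

#' Read an RGB image (PNG or JPEG)
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array in `[0, 1]` (grayscale input is
#'   replicated across channels; alpha is dropped).
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE)) {
      stop("the 'jpeg' package is required for JPEG input", call. = FALSE)
    }
    jpeg::readJPEG(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB array as PNG
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
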