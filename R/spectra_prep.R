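#' Construct a spectrum object
#'
#' A spectrum is a single Vis/NIR transmission measurement: an ascending
#' wavelength grid (nm) with one intensity per wavelength, an optional sample
#' identifier and an optional mold-severity class label.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param intensities Numeric vector of intensities, same length, all finite.
#' @param sample_id Optional character scalar.
#' @param label Optional class label, one of `"healthy"`, `"slight"`,
#'   `"severe"` (or `NA`).
#' @return An object of class `pear_spectrum`: a list with fields
#'   `wavelengths`, `intensities`, `sample_id`, `label`.
#' @export
spectrum <- function(wavelengths, intensities, sample_id = NA_character_,
                     label = NA_character_) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 1L) stop("empty spectrum", call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (!is.na(label)) label <- match.arg(label, mold_classes())
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         sample_id = as.character(sample_id), label = label),
    class = "pear_spectrum"
  )
}

#' The three mold-severity classes, in increasing severity order
#' @return `c("healthy", "slight", "severe")`
#' @export
mold_classes <- function() c("healthy", "slight", "severe")

#' @export
print.pear_spectrum <- function(x, ...) {
  cat(sprintf(
    "<pear_spectrum> %s: %d points, %.0f-%.0f nm, label=%s\n",
    x$sample_id, length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), x$label
  ))
  invisible(x)
}

#' Stack a list of spectra into a samples-by-wavelengths matrix
#'
#' @param spectra List of `pear_spectrum` objects on identical grids.
#' @return List with `X` (n x N intensity matrix), `wavelengths`, `labels`
#'   (character vector), `sample_ids`.
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(wl) ||
        any(abs(s$wavelengths - wl) > 1e-9)) {
      stop("spectra are not on a common wavelength grid", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  list(
    X = X, wavelengths = wl,
    labels = vapply(spectra, `[[`, character(1), "label"),
    sample_ids = vapply(spectra, `[[`, character(1), "sample_id")
  )
}

#' Read a spectra table from delimited text
#'
#' Expected layout: header row of numeric wavelengths plus a final `label`
#' column (and optionally a leading `sample_id` column); one sample per row.
#'
#' @param path Path to a CSV file.
#' @return List of `pear_spectrum` objects.
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cn <- names(df)
  id_col <- which(cn == "sample_id")
  label_col <- which(cn == "label")
  wl_cols <- setdiff(seq_along(cn), c(id_col, label_col))
  wl <- suppressWarnings(as.numeric(cn[wl_cols]))
  if (any(is.na(wl))) {
    stop("non-numeric wavelength header column(s): ",
         paste(cn[wl_cols][is.na(wl)], collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- suppressWarnings(as.numeric(df[i, wl_cols]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric intensity cell in row %d", i), call. = FALSE)
    }
    out[[i]] <- spectrum(
      wl, vals,
      sample_id = if (length(id_col)) df[i, id_col] else sprintf("s%04d", i),
      label = if (length(label_col)) df[i, label_col] else NA_character_
    )
  }
  out
}

#' Write a spectra collection as delimited text
#'
#' Inverse of [read_spectra_table()]: round trip preserves intensities to
#' better than 1e-12 (full double precision is written).
#'
#' @param spectra List of `pear_spectrum` objects on a common grid.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  m <- spectra_matrix(spectra)
  df <- as.data.frame(m$X, check.names = FALSE)
  names(df) <- format(m$wavelengths, digits = 15, trim = TRUE,
                      scientific = FALSE)
  df <- cbind(sample_id = m$sample_ids, df, label = m$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate scans of one sample
#'
#' Each fruit is scanned several times (rotated about the stem-calyx axis)
#' and the arithmetic mean spectrum is used downstream.
#'
#' @param scans List of `pear_spectrum` objects on identical grids
#'   (typically 3 replicates).
#' @return A single averaged `pear_spectrum`; `sample_id` and `label` are
#'   taken from the first scan.
#' @export
average_replicates <- function(scans) {
  m <- spectra_matrix(scans)
  spectrum(m$wavelengths, colMeans(m$X),
           sample_id = scans[[1L]]$sample_id, label = scans[[1L]]$label)
}

#' Flag outlying spectra by mean absolute z-score
#'
#' A reproducible, automated stand-in for manual screening of abnormal
#' acquisitions: for each sample the wavelength-wise z-score against the
#' collection mean/SD is computed, and samples whose mean absolute z exceeds
#' `z_threshold` are flagged. Data are never mutated.
#'
#' @param spectra List of `pear_spectrum` (>= 3 samples).
#' @param z_threshold Positive scalar, default 3.
#' @return Logical vector, `TRUE` = flagged.
#' @export
flag_outliers <- function(spectra, z_threshold = 3) {
  m <- spectra_matrix(spectra)
  if (nrow(m$X) < 3L) stop("need at least 3 samples", call. = FALSE)
  mu <- colMeans(m$X)
  sd <- apply(m$X, 2, stats::sd)
  sd[sd == 0] <- 1  # constant wavelengths carry no deviation signal
  z <- abs(sweep(sweep(m$X, 2, mu), 2, sd, "/"))
  rowMeans(z) > z_threshold
}

#' Min-max normalize a series
#'
#' Rescales to `[-1, 1]` (for Gramian angular encoding, whose arccos step
#' requires that range) or `[0, 1]` (for the Markov transition branch).
#' Endpoints map exactly to the range bounds; the source min/max are stored
#' so the map is invertible.
#'
#' @param x Numeric vector or a `pear_spectrum` (its intensities are used).
#' @param range_mode `"[-1,1]"` (default) or `"[0,1]"`.
#' @return Object of class `normalized_series`: list with `values`,
#'   `range_mode`, `source_min`, `source_max`.
#' @export
minmax_normalize <- function(x, range_mode = c("[-1,1]", "[0,1]")) {
  range_mode <- match.arg(range_mode)
  if (inherits(x, "pear_spectrum")) x <- x$intensities
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (!(hi > lo)) {
    stop("constant series: min-max normalization (and the arccos mapping) is undefined",
         call. = FALSE)
  }
  u <- (x - lo) / (hi - lo)
  v <- if (range_mode == "[-1,1]") 2 * u - 1 else u
  structure(
    list(values = v, range_mode = range_mode, source_min = lo, source_max = hi),
    class = "normalized_series"
  )
}

#' Invert a min-max normalization
#' @param ns A `normalized_series`.
#' @return Numeric vector on the original intensity scale.
#' @export
denormalize <- function(ns) {
  stopifnot(inherits(ns, "normalized_series"))
  u <- if (ns$range_mode == "[-1,1]") (ns$values + 1) / 2 else ns$values
  u * (ns$source_max - ns$source_min) + ns$source_min
}
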