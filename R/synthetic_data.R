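#' Configuration for synthetic Vis/NIR pear spectra
#'
#' The generator emulates the qualitative structure of transmission spectra
#' of pears with moldy core: the transmitted signal is concentrated in a
#' 600-900 nm absorption-window peak complex whose amplitude decreases with
#' mold severity (enzymatic browning absorbs more light), sitting on a small
#' smooth stray-light shoulder outside that window. Amplitudes are free
#' choices, not claims about real fruit.
#'
#' @param n_wavelengths Number of grid points (default 1044).
#' @param wavelength_range Length-2 nm range, default `c(350, 1150)`.
#' @param class_label One of `"healthy"`, `"slight"`, `"severe"`.
#' @param peak_band Length-2 nm band holding the transmission peaks,
#'   default `c(600, 900)`.
#' @param severity_attenuation Named factors scaling the peak complex,
#'   strictly ordered healthy > slight > severe.
#' @param noise_sd SD of additive i.i.d. Gaussian noise (intensity units).
#'   Default 0.005, small relative to the O(1) peak, mirroring a high-SNR
#'   (1000:1) spectrometer.
#' @param seed Integer seed.
#' @return A `spectrum_sim_config` list.
#' @export
spectrum_sim_config <- function(n_wavelengths = 1044L,
                                wavelength_range = c(350, 1150),
                                class_label = "healthy",
                                peak_band = c(600, 900),
                                severity_attenuation = c(healthy = 1.0,
                                                         slight = 0.7,
                                                         severe = 0.4),
                                noise_sd = 0.005,
                                seed = 1L) {
  class_label <- match.arg(class_label, mold_classes())
  if (n_wavelengths < 2L) stop("n_wavelengths must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  att <- severity_attenuation[mold_classes()]
  if (any(is.na(att)) || !(att[1] > att[2] && att[2] > att[3])) {
    stop("severity_attenuation must be named and strictly ordered healthy > slight > severe",
         call. = FALSE)
  }
  structure(
    list(n_wavelengths = as.integer(n_wavelengths),
         wavelength_range = as.numeric(wavelength_range),
         class_label = class_label,
         peak_band = as.numeric(peak_band),
         severity_attenuation = att,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "spectrum_sim_config"
  )
}

# Peak complex: three Gaussians inside the peak band, positioned/scaled
# relative to the band so any band choice yields the same shape family.
.peak_complex <- function(wl, band) {
  ctr <- band[1] + c(0.27, 0.55, 0.80) * diff(band)
  sig <- c(0.12, 0.15, 0.10) * diff(band)
  amp <- c(0.6, 1.0, 0.5)
  out <- numeric(length(wl))
  for (k in seq_along(ctr)) {
    out <- out + amp[k] * exp(-0.5 * ((wl - ctr[k]) / sig[k])^2)
  }
  out
}

# Stray-light shoulder: low-order polynomial, cosine-tapered to exactly zero
# inside the peak band so the band amplitude is governed purely by the
# class attenuation factor.
.baseline_shoulder <- function(wl, band, range) {
  t <- (wl - range[1]) / diff(range)
  poly <- 0.05 + 0.04 * t - 0.03 * t^2
  taper_frac <- 0.35
  w <- numeric(length(wl))
  left <- wl < band[1]
  right <- wl > band[2]
  lw <- taper_frac * (band[1] - range[1])
  rw <- taper_frac * (range[2] - band[2])
  dl <- pmin((band[1] - wl[left]) / lw, 1)
  dr <- pmin((wl[right] - band[2]) / rw, 1)
  w[left] <- 0.5 - 0.5 * cos(pi * dl)
  w[right] <- 0.5 - 0.5 * cos(pi * dr)
  poly * w
}

#' Generate one synthetic spectrum
#'
#' Intensity = stray-light shoulder (zero inside `peak_band`) +
#' class-attenuated Gaussian peak complex + i.i.d. Gaussian noise.
#' Deterministic for a fixed config (including seed).
#'
#' @param config A [spectrum_sim_config()].
#' @return A [spectrum()] labeled with the config class.
#' @export
generate_spectrum <- function(config) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  wl <- seq(config$wavelength_range[1], config$wavelength_range[2],
            length.out = config$n_wavelengths)
  att <- config$severity_attenuation[[config$class_label]]
  base <- .baseline_shoulder(wl, config$peak_band, config$wavelength_range)
  peak <- att * .peak_complex(wl, config$peak_band)
  noise <- if (config$noise_sd > 0) {
    set.seed(config$seed)
    stats::rnorm(length(wl), 0, config$noise_sd)
  } else 0
  spectrum(wl, base + peak + noise,
           sample_id = sprintf("sim_%s_%d", config$class_label, config$seed),
           label = config$class_label)
}

#' Generate a labeled synthetic dataset
#'
#' Per-sample seeds are drawn (without replacement) from the master seed so
#' the whole dataset is reproducible while samples stay independent.
#'
#' @param n_per_class Integer vector of class sizes, named or in
#'   healthy/slight/severe order.
#' @param config Template [spectrum_sim_config()]; `class_label` and `seed`
#'   are overridden per sample.
#' @param seed Master integer seed.
#' @return List of [spectrum()] objects (grouped by class).
#' @export
generate_dataset <- function(n_per_class = c(healthy = 10, slight = 10, severe = 10),
                             config = spectrum_sim_config(),
                             seed = 1L) {
  cls <- mold_classes()
  if (is.null(names(n_per_class))) names(n_per_class) <- cls
  if (any(n_per_class < 1L)) stop("n_per_class must be >= 1 each", call. = FALSE)
  n_tot <- sum(n_per_class)
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  out <- vector("list", n_tot)
  k <- 0L
  for (cl in cls) {
    for (i in seq_len(n_per_class[[cl]])) {
      k <- k + 1L
      cfg <- config
      cfg$class_label <- cl
      cfg$seed <- sample_seeds[k]
      out[[k]] <- generate_spectrum(cfg)
      out[[k]]$sample_id <- sprintf("sim_%s_%03d", cl, i)
    }
  }
  out
}

#' Configuration for synthetic pear cross-section images
#'
#' @param image_size Side of the square RGB image in pixels (default 256).
#' @param fruit_radius Semi-major axis of the elliptical flesh region in
#'   pixels (default 100); must fit inside the image.
#' @param mold_fraction_true Target moldy area as a percentage of the
#'   cross-section area, in `[0, 100]`.
#' @param seed Integer seed.
#' @return A `cross_section_sim_config` list.
#' @export
cross_section_sim_config <- function(image_size = 256L, fruit_radius = 100L,
                                     mold_fraction_true = 0, seed = 1L) {
  if (mold_fraction_true < 0 || mold_fraction_true > 100) {
    stop("mold_fraction_true must be in [0, 100]", call. = FALSE)
  }
  if (fruit_radius >= image_size / 2) {
    stop("fruit must fit inside the image", call. = FALSE)
  }
  structure(
    list(image_size = as.integer(image_size),
         fruit_radius = as.numeric(fruit_radius),
         mold_fraction_true = as.numeric(mold_fraction_true),
         seed = as.integer(seed)),
    class = "cross_section_sim_config"
  )
}

#' Generate a synthetic cross-section photograph
#'
#' Bright elliptical flesh on a dark background with one dark blob of mold
#' (low blue channel, emulating enzymatic browning) whose pixel-counted area
#' equals `mold_fraction_true` percent of the flesh area up to one-pixel
#' quantization. The blob is grown as the nearest flesh pixels (under a
#' random anisotropic metric) around a random interior seed point, so its
#' area is exact and it always lies inside the flesh.
#'
#' @param config A [cross_section_sim_config()].
#' @return List: `image` (H x W x 3 array in `[0,1]`), `mold_fraction_true`,
#'   `flesh_mask`, `mold_mask` (logical matrices).
#' @export
generate_cross_section <- function(config) {
  stopifnot(inherits(config, "cross_section_sim_config"))
  n <- config$image_size
  set.seed(config$seed)
  cx <- n / 2 + stats::runif(1, -2, 2)
  cy <- n / 2 + stats::runif(1, -2, 2)
  a <- config$fruit_radius
  b <- 0.88 * config$fruit_radius
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  flesh <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1

  mold <- matrix(FALSE, n, n)
  target_px <- round(config$mold_fraction_true / 100 * sum(flesh))
  if (target_px > 0) {
    theta <- stats::runif(1, 0, 2 * pi)
    r0 <- stats::runif(1, 0, 0.35)
    sx <- cx + r0 * a * cos(theta)
    sy <- cy + r0 * b * sin(theta)
    phi <- stats::runif(1, 0, pi)
    stretch <- stats::runif(1, 1.0, 1.8)
    dx <- xs - sx; dy <- ys - sy
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    d <- (u / stretch)^2 + (v * stretch)^2
    d[!flesh] <- Inf
    ord <- order(d)[seq_len(target_px)]
    mold[ord] <- TRUE
  }

  flesh_rgb <- c(0.93, 0.88, 0.74)
  mold_rgb <- c(0.42, 0.30, 0.12)
  bg_rgb <- c(0.07, 0.07, 0.09)
  img <- array(0, dim = c(n, n, 3))
  tex <- matrix(stats::rnorm(n * n, 0, 0.012), n, n)
  for (ch in 1:3) {
    plane <- matrix(bg_rgb[ch], n, n)
    plane[flesh] <- flesh_rgb[ch]
    plane[mold] <- mold_rgb[ch]
    img[, , ch] <- pmin(pmax(plane + tex, 0), 1)
  }
  list(image = img, mold_fraction_true = config$mold_fraction_true,
       flesh_mask = flesh, mold_mask = mold)
}
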