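test_that("peak-band amplitude tracks mold severity", {
  cfg <- function(cl) spectrum_sim_config(class_label = cl, noise_sd = 0, seed = 4)
  band_mean <- function(s) {
    sel <- s$wavelengths >= 600 & s$wavelengths <= 900
    mean(s$intensities[sel])
  }
  h <- generate_spectrum(cfg("healthy"))
  sl <- generate_spectrum(cfg("slight"))
  sv <- generate_spectrum(cfg("severe"))
  expect_gt(band_mean(h), band_mean(sl))
  expect_gt(band_mean(sl), band_mean(sv))
})

test_that("spectrum generation is deterministic and scales by the closed-form bump factor", {
  cfg <- spectrum_sim_config(class_label = "slight", noise_sd = 0.01, seed = 77)
  expect_identical(generate_spectrum(cfg)$intensities,
                   generate_spectrum(cfg)$intensities)

  att <- c(healthy = 1.0, slight = 0.7, severe = 0.4)
  h <- generate_spectrum(spectrum_sim_config(class_label = "healthy",
                                             severity_attenuation = att,
                                             noise_sd = 0, seed = 1))
  sv <- generate_spectrum(spectrum_sim_config(class_label = "severe",
                                              severity_attenuation = att,
                                              noise_sd = 0, seed = 1))
  band <- h$wavelengths >= 600 & h$wavelengths <= 900
  ratio <- max(h$intensities[band]) / max(sv$intensities[band])
  expect_equal(ratio, 1.0 / 0.4, tolerance = 1e-9)
})

test_that("spectrum config validates its invariants", {
  expect_error(spectrum_sim_config(class_label = "rotten"), "should be one of")
  expect_error(spectrum_sim_config(noise_sd = -1), "noise_sd")
  expect_error(spectrum_sim_config(
    severity_attenuation = c(healthy = 0.4, slight = 0.7, severe = 1.0)),
    "ordered")
})

test_that("generate_dataset conserves counts and is reproducible", {
  ds <- generate_dataset(c(healthy = 10, slight = 10, severe = 10), seed = 8)
  labels <- vapply(ds, `[[`, character(1), "label")
  expect_length(ds, 30L)
  expect_equal(unname(table(labels)[mold_classes()]),
               array(c(10L, 10L, 10L)), ignore_attr = TRUE)
  ds2 <- generate_dataset(c(healthy = 10, slight = 10, severe = 10), seed = 8)
  expect_identical(lapply(ds, `[[`, "intensities"),
                   lapply(ds2, `[[`, "intensities"))
  # the study's training composition is representable directly
  big <- generate_dataset(c(healthy = 540, slight = 186, severe = 326),
                          spectrum_sim_config(n_wavelengths = 8), seed = 1)
  expect_equal(sum(vapply(big, `[[`, character(1), "label") == "slight"), 186L)
  expect_length(big, 1052L)
})

test_that("class-mean band amplitude decreases with severity across seeds", {
  for (seed in c(2, 31, 97)) {
    vals <- vapply(mold_classes(), function(cl) {
      s <- generate_spectrum(spectrum_sim_config(class_label = cl,
                                                 noise_sd = 0, seed = seed))
      sel <- s$wavelengths >= 600 & s$wavelengths <= 900
      mean(s$intensities[sel])
    }, numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("cross-section generator hits the requested mold fraction", {
  cs0 <- generate_cross_section(cross_section_sim_config(mold_fraction_true = 0,
                                                         seed = 5))
  expect_false(any(cs0$mold_mask))

  cs25 <- generate_cross_section(
    cross_section_sim_config(mold_fraction_true = 25, seed = 5))
  frac <- sum(cs25$mold_mask) / sum(cs25$flesh_mask) * 100
  expect_gte(frac, 24); expect_lte(frac, 26)
  expect_true(all(cs25$flesh_mask[cs25$mold_mask]))  # mold inside flesh

  cs25b <- generate_cross_section(
    cross_section_sim_config(mold_fraction_true = 25, seed = 5))
  expect_identical(cs25$image, cs25b$image)

  expect_error(cross_section_sim_config(mold_fraction_true = 101), "\\[0, 100\\]")
  expect_error(cross_section_sim_config(image_size = 100, fruit_radius = 60),
               "fit inside")
})
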