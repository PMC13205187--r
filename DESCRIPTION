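Package: pearspec
Title: Vis/NIR Spectrum Image Encoding and Moldy-Core Grading for Pear Fruit
Version: 0.1.0
Authors@R:
    person("pearspec", "developers", email = "pearspec@example.org", role = c("aut", "cre"))
Description: Tools for nondestructive internal-defect analysis of pear fruit
    from visible/near-infrared transmission spectra and cross-section
    photographs. Implements two spectrum-to-image encodings -- the improved
    Gramian angular field (IGAF), which fuses the Gramian angular difference
    field upper triangle with the summation field lower triangle, and the
    Laplacian pyramid Markov transition field (LPMTF), which combines
    piecewise aggregate approximation, equal-frequency quantile
    discretization, a first-order Markov transition field, and weighted
    Laplacian-pyramid fusion. Also provides moldy-core quantification from
    cross-section images (Canny contour extraction, iterative thresholding,
    8-connectivity labeling, area-fraction grading), characteristic-wavelength
    selection (one-way ANOVA F statistic and random-forest importance), a
    one-vs-one RBF support vector machine baseline, macro-averaged evaluation
    metrics with McNemar's test, minimal vision-transformer primitives (patch
    tokenization, scaled dot-product attention), and a synthetic-data
    generator so the whole pipeline is testable without any measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
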