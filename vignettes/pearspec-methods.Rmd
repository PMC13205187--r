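---
title: "pearspec: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pearspec: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearspec)
```

## The problem

Moldy core is an internal fungal infection of pear fruit that leaves the
skin intact, so it cannot be graded visually. Two measurement channels
carry the signal:

* **Vis/NIR transmission spectra** (350–1150 nm, 1044 points). Healthy
  flesh scatters light through air-filled intercellular spaces; browning
  of infected core tissue absorbs it. The transmitted energy concentrates
  in a 600–900 nm window, and its amplitude falls as severity rises.
* **Cross-section photographs** taken after cutting, which define the
  ground-truth grade: the moldy area S1 relative to the section area S2,
  S = S1/S2 × 100, with S = 0 % healthy, 0 < S ≤ 10 % slight, S > 10 %
  severe.

`pearspec` implements the spectral encodings that turn spectra into
images for vision models, the photographic quantification pipeline, a
classical selection + SVM baseline, evaluation utilities, and a synthetic
generator that stands in for the (unavailable) measured data.

## Spectrum-to-image encodings

### Gramian angular fields and IGAF

A spectrum is min–max normalized to x̃ ∈ [−1, 1] and mapped to polar
angles φᵢ = arccos(x̃ᵢ) ∈ [0, π]. The two Gramian fields are

* GADF[i, j] = sin(φᵢ − φⱼ)  (antisymmetric, zero diagonal),
* GASF[i, j] = cos(φᵢ + φⱼ)  (symmetric),

and each is redundant across its diagonal. The fused IGAF keeps the GADF
for i ≤ j and the GASF for i > j, so one image carries both angular
differences and sums. Its diagonal is sin(0) = 0 by the i ≤ j convention
— we follow that literal reading rather than assigning the diagonal to
the GASF branch.

Normalization is **per spectrum**, because each sample is encoded into an
image independently; a constant spectrum is an error rather than a
silently chosen angle, since arccos gives no preferred value there.
Inputs are clipped to [−1, 1] only within a 1e-12 rounding slack; larger
excursions raise an error.

The encoders are validated against naive double-loop trigonometric
oracles (≤ 1e-12) and against the algebraic form
x̃ᵀx̃ − √(1−x̃²)ᵀ√(1−x̃²) (≤ 1e-10).

### Presentation side for IGAF

A 1044-point spectrum gives a 1044 × 1044 IGAF, but the downstream token
arithmetic (196 tokens of 16 × 16 pixels) implies a 224-side input. The
encoding is computed at full resolution and bilinearly resized; whether
the original work resized or aggregated before encoding is not stated, so
the resize is exposed as a parameter (`resize_square`) and flagged as an
interpretation, not a reproduction.

### LPMTF

The Laplacian pyramid Markov transition field composes six stages, each
exported and tested separately:

1. **[0, 1] normalization**, then **PAA** with window 5: non-overlapping
   window means, trailing remainder dropped, 1044 → ⌊1044/5⌋ = 208. The
   drop-remainder convention is the only one consistent with the 169-token
   count downstream (208 = 13 × 16).
2. **Equal-frequency quantile discretization**, q = 12: the r-th smallest
   of n points gets state ⌈q·r/n⌉ − 1; ties break by original order, so
   occupancies differ by at most 1 for distinct values. q = 12 and
   window 5 are the calibrated defaults of the procedure this package
   implements; q = 6 and window 10 variants are exercised as ablation
   settings.
3. **Transition matrix** W[i, j] = #(i→j among adjacent pairs) / #(pairs
   leaving i). States never left give an all-zero row — no probability is
   redistributed, which keeps W interpretable and leaves every M lookup
   defined.
4. **Field expansion** M[i, j] = W[sᵢ, sⱼ] — an N′ × N′ image in [0, 1].
5. **Laplacian pyramid**, 3 levels: Gaussian levels by 5-tap binomial
   (Burt–Adelson) blur with reflect padding and factor-2 decimation
   (side ⌈s/2⌉); Lₖ = Gₖ − upsample(Gₖ₊₁) with factor-2 bilinear
   upsampling. Because L is defined against the same upsampler,
   reconstruction Gₖ = Lₖ + upsample(Gₖ₊₁) is exact (tested ≤ 1e-10).
   The original description says only "Gaussian pyramid"; the binomial
   kernel is the standard choice and is documented as ours.
6. **Weighted fusion**: L0, L1, L2 and the residual top G3 are upsampled
   to the base side and combined with non-negative weights summing to 1
   (equal by default — the fusion weights are unspecified upstream, so
   they are a configurable parameter, not a claim), then min–max mapped
   to [0, 1]. The affine map is our mechanism for the stated [0, 1]
   output range.

W and M are checked against brute-force pair counting, and the pipeline
is deterministic: same series and parameters, same image bit for bit.

## Moldy-core quantification

The photographic pipeline mirrors the classical procedure: Canny edges →
section contour → blue-channel iterative threshold → 8-connectivity
labeling → area ratio → grade.

Numerical choices that the procedure's description leaves open, all
configurable:

* **Canny thresholds** derive from the smoothed-image median (0.66·m,
  1.33·m on the 8-bit scale), the common auto-threshold rule; hysteresis
  keeps weak edges 8-connected to strong ones. Thin Canny chains are
  8-connected, so the edge map is dilated once before the border flood
  fill that separates background from section — otherwise the fill leaks
  through diagonal pixel chains. The filled component is eroded back by
  the same margin, and validated on synthetic disks to within 2 % of
  πr².
* **Iterative threshold** (Ridler–Calvard/isodata): T starts at the grand
  mean and moves to the midpoint of the two class means it induces until
  the update is below 0.5 on an 8-bit scale (rescaled for unit-range
  planes). A threshold is only *believed* when the two class means
  separate by at least `min_separation` (default 0.1 in unit intensity):
  on a mold-free section the isodata split would otherwise bisect sensor
  noise and invent a phantom mold class.
* **Thresholding domain**: within the section contour only (eroded a few
  pixels, because rim mixels are dark in the blue channel and would
  masquerade as mold). Whether the original ran on the full plane or
  within the contour is unstated; within-contour is our documented
  choice.
* **Mold polarity**: mold = blue channel *below* threshold — browning
  darkens blue.
* **min_area = 20 px** suppresses speckle components; **healthy_eps =
  0.1 percentage points** absorbs pixel noise at the literal S = 0
  boundary (set 0 for the exact rule). The grade boundary at 10 % is
  inclusive on the slight side.

## Wavelength selection and the SVM baseline

The F statistic is the one-way ANOVA ratio per wavelength; selection
keeps the K = 100 largest with ties broken by lower index (determinism).
Random-forest importance uses bootstrapped CART trees, Gini impurity,
mtry = ⌊√p⌋, and node-size-weighted impurity decreases normalized to sum
1; tree count defaults to 500 and the importance type (impurity rather
than permutation) is a documented choice. Because no SVM or tree package
is assumed, the soft-margin RBF-SVM is solved in-package by sequential
minimal optimization with deterministic working-set selection; the
one-vs-one vote and the γ = 1/(p · Var X) "scale" heuristic are explicit
code paths with their own tests. Vote ties break by summed signed
margins, then class order. Prediction confidence is exposed as
normalized vote shares; full Platt-scaled probabilities are not
reproduced.

## Evaluation

Multi-class accuracy is trace/total — the reading consistent with the
68/72 = 94.44 % external-validation arithmetic — rather than the binary
TP/TN form. Macro metrics are unweighted class means; a class never
predicted (or absent) contributes 0 to the affected metric with a
warning. McNemar's test uses the continuity correction by default
((|b−c|−1)²/(b+c)); b + c = 0 returns statistic 0, p = 1. Stratified
splitting preserves per-class proportions within one sample and is
seed-deterministic.

## Vision primitives and the desk-scale classifier

Patch tokenization, scaled dot-product attention and multi-head
attention are implemented exactly and checked against two-loop oracles;
non-divisible image sides are cropped (floor), matching 208 → 169. The
depthwise-separable cost identity (cost ratio = 1/N + 1/D²_K) is exposed
with both absolute costs.

A full 12-layer ViT is deliberately **not** trained here. The
`toy_attention_classifier` is a desk-scale stand-in: fixed seeded random
patch embedding and Q/K/V projections, one attention block with a
residual connection, and a multinomial logistic head over the flattened
token features trained by gradient descent (the only trained component —
keeping the model deterministic and inside a CPU-minutes budget). The
`use_attention = FALSE` ablation removes token mixing, leaving patch-wise
processing only, and is asserted never to *outperform* the enabled model
on the same seeds — the directional analogue of the attention ablation;
the dramatic magnitude of the original drop is out of scope. Token
features are centered but not variance-scaled before the head:
per-feature standardization amplifies near-constant noisy features and
destabilizes the comparison.

## The synthetic world

`generate_spectrum` builds intensity = stray-light shoulder + class
attenuation × Gaussian peak complex + i.i.d. Gaussian noise:

* the peak complex is three Gaussians positioned inside 600–900 nm;
* the shoulder is a low-order polynomial cosine-tapered to exactly zero
  inside the peak band, so the band amplitude is governed purely by the
  class factor (healthy 1.0 > slight 0.7 > severe 0.4 by default) — this
  makes amplitude ratios closed-form testable;
* noise_sd defaults to 0.005 against an O(1) peak, reflecting a
  high-SNR (1000:1) spectrometer.

No public amplitudes exist for real pears, so these are generator knobs,
not claims; they were chosen once and the acceptance thresholds were not
tuned against them. `generate_cross_section` plants an exact-area mold
blob (nearest flesh pixels around a seed point under a random anisotropic
metric) inside an elliptical flesh region, so recovery error is pure
pipeline error.

What a green test therefore establishes: the encodings, quantification
arithmetic, selectors, solver and metrics are correct on data whose
ground truth is known exactly, and the pipeline's qualitative behaviors
(severity ordering, ablation direction, fraction recovery within ±2
points) hold in that world. What it does not establish: classification
accuracy on real fruit, robustness to illumination/geometry, or the
original study's headline numbers, which require the private dataset and
GPU-trained networks.

## Known limitations

* The automated z-score outlier rule is a reproducible stand-in for a
  manual screening step whose criterion is unrecorded; it is off by
  default.
* The SMO solver targets desk-scale problems (hundreds of samples); it is
  not tuned for large-n training.
* Canny parameters are auto-derived; photographs with poor contrast may
  need explicit thresholds.
* The toy classifier trains only its head; it is a smoke-test vehicle,
  not a ViT replacement.
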