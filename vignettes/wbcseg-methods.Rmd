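---
title: "Methods: ensemble nucleus segmentation and logit cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble nucleus segmentation and logit cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcseg)
```

## The problem

In stained blood-smear micrographs the white blood cell (leukocyte) nucleus
is the region that carries most of the morphological signal used to grade
acute lymphoblastic leukemia. Segmenting it reliably across acquisitions is
hard because staining, illumination and camera differ between laboratories.
`wbcseg` implements an ensemble segmenter built from two complementary
parts, plus the evaluation and analysis tools around it.

## Handcrafted pipeline

The handcrafted segmenter is a deterministic color-space pipeline:

1. **Color constancy.** Every RGB channel is rescaled by
   `gray_mean / channel_mean`, where the grayscale mean uses configurable
   luma weights. We default to ITU-R BT.601 (0.299, 0.587, 0.114): the
   definition of "grayscale" is a genuinely open choice, and BT.601 is the
   convention most imaging libraries use for 8-bit micrographs. After
   rescaling, values are clamped to [0, 255] and rounded half-up; the
   unclipped transform conserves each channel mean exactly, which is how the
   operation is unit-tested.
2. **Channel extraction.** The CMYK Magenta channel uses the naive device
   conversion (`K = 1 - max(r, g, b)`, `M = (max - g)/max`); no ICC profile
   is involved. The HSV Saturation channel is `(max - min)/max`. Both are
   high precisely on purple, strongly chromatic pixels — the stained
   nucleus.
3. **Hadamard product.** Elementwise `M * S`. Red cells (pinkish: moderate M,
   low S) and plasma background (near-achromatic) are suppressed; the
   product is bounded by the smaller factor everywhere.
4. **Bilateral smoothing.** A classic bilateral filter (disk support,
   diameter 9 px; range sigma 0.1 on the [0, 1] scale; spatial sigma 5 px)
   removes pixel noise while preserving the nucleus boundary. These defaults
   are our own: the stages upstream produce values in [0, 1], and a range
   sigma of 0.1 is well below the nucleus/background contrast (about 0.5 on
   the product channel) so edges survive, while typical sensor noise
   (about 0.01–0.05) is averaged out.
5. **Otsu binarization.** A single global threshold on the 256-bin histogram
   maximizing between-class variance; ties break to the lowest maximizing
   bin and foreground is the population above the threshold. We deliberately
   implement the global variant only — the pipeline applies one threshold
   per image — and verify it against an exhaustive search oracle.
6. **Morphological refinement.** Closing with a disk of radius 3 px, filling
   of all holes (background components not touching the border), and removal
   of 8-connected components below `min_area`. `min_area` defaults to 0.1 %
   of the image pixels rather than an absolute count, so behaviour is stable
   across the very different image sizes this kind of data comes in
   (120×120 up to 640×480).

Degenerate inputs are handled explicitly: an all-zero channel makes the
color-constancy weight undefined and raises an error naming the channel; a
constant channel has no Otsu threshold and yields an empty mask with a
warning.

## Deep segmenter

The second segmenter is a five-level U-Net: strided 3×3 convolutions
(strides 1, 2, 2, 2, 2, a 16-fold bottleneck reduction), instance
normalization, the Mish activation `x * tanh(softplus(x))`, dropout, skip
connections concatenated at matching resolutions, nearest-neighbour
upsampling in the decoder, and a 1×1 sigmoid head. The default widths are
32→512; narrower widths are used throughout the tests.

The engine behind it is written in R: convolutions are im2col gathers
followed by one BLAS matrix multiply per layer, and every backward pass is
hand-derived and verified against central finite differences (agreement to
~1e-11 on random small networks). This keeps the package free of any deep
learning framework dependency while remaining fast enough for the problem
sizes the package targets.

Training minimizes the **Unified Focal Loss**
`λ·L_focal + (1-λ)·L_focalTversky` with δ = 0.6, γ = 0.5, λ = 0.5 by
default. The focal term is the pixel mean of
`δ (1 - p_t)^{1-γ} (-log p_t)`; we implement the exponent `1-γ` exactly as
specified, and expose `focal_exponent = "conventional"` for the usual
`(1-p_t)^γ` focusing, because the two conventions disagree in the
literature. The region term sums `(1 - mTI)^γ` over foreground and
background soft counts with the Tversky index
`TP/(TP + δ·FN + (1-δ)·FP)`. Soft counts are computed on raw probabilities
(so a hard perfect prediction has exactly zero loss); probabilities are
clamped to `[1e-6, 1-1e-6]` only inside gradients to keep them finite.

Optimization uses Adam (lr 1e-3, batch 8) with halving of the learning rate
after 10 epochs without improvement. The 10-fold cross-validation harness
shuffles, partitions into folds whose sizes differ by at most one, trains on
nine folds and scores the tenth, recording per-epoch loss/IoU curves for
both sets. On-the-fly augmentation applies vertical/horizontal flips,
90° rotations and transposition with probability 0.5 and random gamma,
CLAHE and Gaussian noise with probability 0.2, plus a deterministic resize;
validation samples get only the resize.

## Ensemble fusion

The two masks are merged by pixelwise logical AND followed by an area
opening (default threshold equal to the handcrafted `min_area`). AND can
only remove pixels, so against any ground truth the fused mask's false
positives are bounded by the smaller of the two inputs' — the property the
ensemble exists for. The unavoidable cost is recall: a pixel missed by
either segmenter is missed by the ensemble. That trade-off is designed
behaviour, not something the package tries to compensate.

## Segmentation metrics

From the pixel confusion counts the package derives accuracy, precision,
recall, specificity, Dice (DSC) and IoU exactly as conventionally defined,
with `DSC = 2·IoU/(1+IoU)` holding as an identity. Ratios with zero
denominator are reported as 0 and flagged `undefined` rather than NA, since
batch aggregation (unweighted mean over images) must stay numeric.

## Logit cluster separability

For a three-class classifier, the `(L1, L2, L3)` logits of test samples are
centered and projected onto the top two principal components (sample
covariance, n−1; component signs fixed by making the largest-magnitude
loading positive so results are reproducible). Within this plane the
package computes per-class centroids, the three pairwise centroid
distances and their total, a per-class spread
`sd_c = sqrt(sd(PC1)² + sd(PC2)²)`, the total spread
`sqrt(Σ sd_c²)`, and the 3:1-weighted separability statistic

```
ratio = 3 · dist_total / sd_total .
```

Root-sum-of-squares was chosen as the per-class combiner because it is the
Euclidean norm of the component spreads and reproduces published worked
examples of this statistic from their per-cluster columns; a plain mean of
the two SDs does not. Distances are measured after projection, matching the
visualization the statistic accompanies. The ratio is invariant under
rigid motions and under global rescaling of the logit cloud, and increases
with true centroid separation at fixed spread — all property-tested.

## Synthetic data generators

`make_smear()` emulates exactly the features the pipeline keys on: a
pinkish/yellowish background, anti-aliased pink red-cell disks (low
Magenta×Saturation product), and purple nucleus blobs (high product) drawn
last as radial-frequency-perturbed ellipses, so that closing and hole
filling do non-trivial work. The ground truth is the exact blob union
before anti-aliasing and noise. Defaults: 128×128 canvas, 1 nucleus of
radius 14–22 px, 12 red cells, per-object color jitter SD 8, pixel noise
SD 3 — chosen once to mimic the single-leukocyte crops common in public
smear datasets. A `hard_mode` preset washes the nucleus out toward the
background for stress testing. `make_logits()` draws isotropic Gaussian
clouds around three specified centroids.

What the generator does **not** emulate: chromatin texture, cytoplasm,
touching/overlapping leukocytes, uneven illumination fields and staining
artefacts. Passing the synthetic end-to-end bar (IoU ≥ 0.9) therefore
demonstrates the pipeline's internal correctness and robustness to additive
noise and color jitter — not clinical-grade performance on real smears.

## Problem sizes and numerical choices

The test-suite problem sizes are our own scaling choices: the learnability
check overfits eight 64×64 smears for 200 epochs with a narrow
(8–128 channel) spec, dropout and augmentation off, because its purpose is
to demonstrate gradient correctness and capacity, not regularized
generalization; cross-validation is exercised with 3 folds on 6 tiny images
to test the harness contract. Determinism is part of the contract
everywhere: generators are pure functions of their seed, a fit is fully
reproduced by its seed, and the handcrafted pipeline is bit-identical on
identical input.

Known limitations: only binary nucleus/background segmentation (no
cytoplasm, no nucleus typing, no stain deconvolution); the deep engine is
CPU-only and intended for the scaled-down problem sizes above; images with
multiple classes of strongly purple objects will confound the color prior
of the handcrafted stage.
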