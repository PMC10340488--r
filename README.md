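# wbcseg

Ensemble segmentation of white blood cell (leukocyte) nuclei in stained
blood-smear micrographs, with the evaluation metrics and logit-space
cluster-separability analysis that go with it.

## What it does, and for whom

Grading acute lymphoblastic leukemia from smear images starts with finding
the leukocyte nucleus. `wbcseg` is for image-analysis researchers who need a
reproducible, dependency-light nucleus segmenter and its surrounding
toolbox:

- a **handcrafted pipeline**: color constancy (per-channel rescaling by
  `gray_mean / channel_mean`), extraction of the CMYK Magenta (M) and HSV
  Saturation (S) channels, their Hadamard product `M ⊙ S` which lights up
  the purple nucleus, bilateral smoothing, global Otsu thresholding, and
  morphological refinement (closing, hole filling, area filter);
- a **U-Net segmenter** (strided-convolution encoder, instance norm, Mish
  activation `x·tanh(softplus(x))`, skip connections) trained with the
  Unified Focal Loss `λ·L_F + (1−λ)·L_FT`, where the focal term is
  `mean[δ(1−p_t)^{1−γ}(−log p_t)]` and the region term sums `(1−mTI)^γ`
  over classes with the Tversky index `TP/(TP + δFN + (1−δ)FP)`. The CNN
  engine is pure R (im2col + BLAS) — no deep-learning framework required;
- the **ensemble**: pixelwise logical AND of the two masks plus an area
  opening, which provably never increases false positives;
- the six pixel metrics (accuracy, precision, recall, specificity, DSC,
  IoU, with `DSC = 2·IoU/(1+IoU)`);
- a **cluster separability analysis** of 3-class classifier logits: PCA to
  (PC1, PC2), per-class centroids and spreads, and the 3:1-weighted
  statistic `ratio = 3·dist_total/sd_total`;
- deterministic **synthetic generators** of smear-like images with exact
  ground truth and of Gaussian logit clouds, so everything is testable
  without external databases.

## Worked example

```r
library(wbcseg)

sm  <- make_smear(smear_params(seed = 42))   # synthetic smear + ground truth
seg <- segment_handcrafted(sm$image)         # handcrafted pipeline
evaluate_masks(seg$mask, sm$mask)
#> Pixel confusion: TP 1008  TN 15348  FP 0  FN 28
#>    accuracy   precision      recall specificity         dsc         iou
#>      0.9983      1.0000      0.9730      1.0000      0.9863      0.9730
```

The report reads: of the 1036 true nucleus pixels, 1008 were recovered
(recall 0.973) with no false positives (precision 1), giving a Dice score
of 0.986 and an intersection-over-union of 0.973 for this image.

Training the deep segmenter and fusing:

```r
fx   <- lapply(1:8, function(i) make_smear(smear_params(
          image_size = 64, n_rbc = 5, nucleus_radius_range = c(8, 12), seed = i)))
fit  <- wbc_unet(lapply(fx, `[[`, "image"), lapply(fx, `[[`, "mask"),
                 spec = unet_spec(channels = c(8, 16, 32, 64, 128), dropout_p = 0),
                 epochs = 200, seed = 7)
deep  <- predict(fit, fx[[1]]$image)
fused <- fuse_masks(segment_handcrafted(fx[[1]]$image)$mask, deep)
```

Cluster separability of classifier logits (CSV with columns
`L1, L2, L3, label` also accepted via `cluster_analysis(path)`):

```r
lg <- make_logits(logit_sim_params(n_per_class = 200, seed = 42))
summarize_clusters(project_logits(lg))
#> Logit cluster separability (PCA space)
#>   pairwise centroid distances: 11.25, 11.33, 11.25 (total 33.82)
#>   per-cluster SD: 1.42, 1.43, 1.43 (total 2.47)
#>   Dist/SD ratio (3:1 weighted): 41.13
```

Larger ratios mean tighter, better-separated class clusters — the
statistic used to compare classifiers' logit spaces.

A thin CLI over the same functions lives at `inst/cli/wbcseg`
(subcommands `segment`, `fuse`, `evaluate`, `cluster-report`,
`make-fixtures`, `train-unet`, `predict`).

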