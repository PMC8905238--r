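---
title: "Methods: watershed segmentation and two-pathway classification of corn seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: watershed segmentation and two-pathway classification of corn seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cornseed` implements an end-to-end pipeline for detecting phenotypic defects
(mold, insect or mechanical damage, discoloration) in corn seeds imaged as
4-channel multispectral scenes: 8-bit R, G, B plus a near-infrared (NIR)
plane, nominally 1296 x 964 pixels, acquired over a bright backlit panel.
This vignette explains the models and procedures, every tunable that matters,
the synthetic data the package tests itself on, and the numerical choices
made where the underlying design was open.

## 1. Marker-based watershed segmentation

Seeds on the tray touch each other, so plain connected-component labeling
under-counts. The pipeline separates touching seeds in five steps, all
operating on the blue channel, which gives the strongest contrast between the
yellow-orange seeds and the bright background:

1. **Binarization.** An Otsu threshold is computed on the 256-bin histogram
   of the B plane; with `invert = TRUE` (the default — seeds are darker than
   the backlit background) pixels at or below the threshold become
   foreground. The threshold maximizes between-class variance; the
   implementation works directly on the integer histogram so that inverting
   the image and toggling `invert` yields the identical mask, and
   constant-intensity input raises an explicit error rather than returning an
   arbitrary cut.
2. **Cleaning.** Morphological opening (`open_iterations` erosions then as
   many dilations with a disc of radius `open_kernel`, defaults 2 and 3)
   removes binarization specks smaller than the element while changing large
   components by well under 15%.
3. **Sure background.** The cleaned mask is dilated `dilate_iterations`
   times (default 3); the complement of the dilation is certainly background.
4. **Markers.** The Euclidean distance transform of the cleaned mask is
   thresholded at `dist_frac` (default 0.5) of each connected component's
   *own* maximum. Per-component normalization matters: a global threshold
   would let large seeds suppress the cores of small ones. The thresholded
   cores are labeled by 8-connected components; for convex seed shapes each
   seed contributes exactly one core, and two touching seeds contribute two
   (the distance transform dips at the contact neck).
5. **Flooding.** Meyer's flooding runs on the inverted distance transform,
   restricted to the dilated foreground, starting from the markers. Every
   foreground pixel — including watershed ridge pixels — is assigned to the
   basin whose front reaches it first; with the FIFO tie-break on equal
   altitudes that is the basin of the nearer marker, so instance masks tile
   the cleaned foreground with no unlabeled pixels. Instances smaller than
   `min_area` (200 px at nominal scale, rescaled by scene area otherwise)
   are discarded; IDs are ordered by centroid.

Conventions fixed across the package: 8-connectivity everywhere, 0-based
half-open bounding boxes, and bbox-cropped masks as the storage form for
per-seed rasters (equivalent to scene-sized masks at a fraction of the
memory; `cornseed:::instances_to_label_matrix()` materializes the full
raster when needed).

Chips for classification are cut with the instance bounding box applied to
all four channels at identical coordinates (the NIR plane is segmented by
the RGB-derived coordinates, not re-segmented), out-of-mask pixels are
replaced by the scene's per-channel background median so a neighboring seed
inside the box cannot leak label information (`fill = "none"` disables
this), and the crop is resampled to 224 x 224 per channel with bilinear
interpolation aligned on pixel centers (exact identity when the crop is
already 224 x 224).

## 2. The two-pathway classifier

Each 224 x 224 x 4 chip is classified good/bad by a network with two
parallel feature extraction branches whose embeddings are concatenated:

* **VGG16-style branch** — 13 stacked 3 x 3 convolutions with five 2 x 2
  max-pools (64-64 / 128-128 / 256-256-256 / 512-512-512 / 512-512-512
  channels), producing a 7 x 7 x 512 map. The original VGG16 fully connected
  head (25088 -> 4096 -> 4096, ~119.6 M parameters) is replaced by a 7 x 7
  *valid* convolution with 512 channels followed by two 512-unit fully
  connected layers (~13.4 M parameters) — an order of magnitude fewer
  parameters for the same 512-dimensional embedding.
* **ResNet50-style branch** — a 7 x 7 stride-2 stem, 3 x 3 stride-2
  max-pool, then bottleneck residual blocks in the classic 3-4-6-3
  configuration (each 1x1 -> 3x3 -> 1x1 with batch normalization and a
  shortcut that adds the block input to the transformed output; projection
  shortcuts where shape changes), global average pooling, and one 512-unit
  fully connected layer. Counting the stem, the 48 block convolutions and
  the final fully connected layer gives the familiar 50 weighted layers;
  the 4 projection convolutions sit outside that count.

The two 512-vectors are concatenated into a 1,024-dimensional fused feature,
mapped by one fully connected layer to 2 classes and a softmax
`y_m = exp(z_m) / sum_k exp(z_k)` (computed with max-subtraction). The loss
is categorical cross-entropy `L = -sum_i log y_{i,true}` with natural
logarithms and probabilities clipped at 1e-12; training behavior is
invariant to the logarithm base up to a constant factor absorbed by the
learning rate.

**Engine.** No deep-learning framework is available to R in this
environment, so the package carries its own compact CNN engine
(`src/nnet.cpp`): single-precision im2col convolutions executed as BLAS
`sgemm`, batch normalization with running statistics, max-pooling, global
average pooling, dense layers, SGD-with-momentum and Adam. He-normal
initialization throughout, seeded; training is deterministic for a fixed
seed and BLAS thread count. Chips enter scaled to `[0, 1]` (divide by 255);
no per-channel standardization is applied.

**Tunables.** `width_multiplier` scales every channel count (embeddings
included) so reduced models train on one CPU in minutes; 1.0 reproduces the
printed architecture, and the architecture audit in the test suite runs at
full width. Training defaults follow the reference configuration: SGD,
momentum 0.9, initial learning rate 0.001, batch size 32, and halving of the
learning rate when the test loss stops improving — the patience is 3 epochs
(the reference procedure states the trigger but not a patience). The batch
loss is mean-reduced by default, the convention frameworks pair with
published learning rates; `loss_reduction = "sum"` applies the printed
batch-sum formula, identical up to a factor of the batch size on the
learning rate. With random (non-pretrained) initialization the summed loss
at batch 32 corresponds to a 32x effective step and can diverge, which is
why the mean convention is the default.

**Pretrained initialization.** The package never downloads weights. When
3-channel pretrained first-layer kernels are available locally,
`adapt_pretrained_first_layer()` copies R, G, B unchanged and initializes
the NIR kernel as their mean — one concrete reading of reusing an
RGB-pretrained first layer for a 4-channel input without changing any other
layer's parameter count; all remaining layers are copied unchanged via
`set_first_conv()`.

## 3. Hand-crafted baselines

Five classical descriptor families feed an RBF-SVM baseline. The reference
description names the families and the six GLCM statistics but none of the
geometric parameters; the package fixes one parameterization and keeps it
centralized:

| family | dimension | parameters |
|---|---|---|
| MC (morphology) | 5 | perimeter/equivalent-diameter, equivalent diameter, eccentricity, axis ratio, extent |
| Color histogram | 48 | 16 bins per R, G, B over mask pixels, each channel normalized |
| HOG | 26,244 | 9 unsigned orientations, 8x8 cells, 2x2 blocks, L2-hys |
| GLCM | 24 | 32 gray levels, distance 1, angles 0/45/90/135, symmetric; contrast, dissimilarity, homogeneity, energy, correlation, ASM per angle |
| LBP | 10 | rotation-invariant uniform patterns, 8 neighbors at radius 1 |

The perimeter uses a Crofton-style estimator (pi/4 times the exposed
4-neighbor edge count), which is exact for digital disks — the
boundary-pixel counts common in image libraries misestimate the
perimeter-to-diameter ratio of a circle by 10-15%. Features are computed
over mask pixels where a mask exists, over the full chip otherwise. The SVM
standardizes features with training statistics and uses an RBF kernel with
`C = 1`, `gamma = 1/(d * var(X))`.

## 4. Evaluation

Per class, precision `100 tp/(tp+fp)`, recall `100 tp/(tp+fn)` and accuracy
`100 correct/total` are computed from confusion counts; macro values are
unweighted class means, and **F1 is the harmonic mean of the macro precision
and macro recall** — recomputing the bundled reference tables confirms this
convention (not the mean of per-class F1s) reproduces every derivable
printed summary cell to ±0.01. Printed values round half away from zero to
two decimals (95.625 -> 95.63). A zero denominator yields `NA` with a
warning and drops the class from macro averages.

Detections are matched one-to-one to truth seeds greedily by descending mask
Jaccard with a 0.5 acceptance threshold (the reference procedure states no
matching rule; an exhaustive optimal matcher is kept as a test oracle, and
the greedy counts coincide with it on small scenes). Equal labels in a
matched pair give a TP; unequal labels an FP for the prediction plus an FN
for the truth; unmatched detections are FPs, unmatched truth seeds FNs —
so classification errors and segmentation misses are both covered.

One bundled reference row is internally inconsistent: its per-class
precisions average to 92.905 while the printed average is 91.96 (the printed
F1 agrees with 91.96, pointing at a typo in a per-class cell). That cell and
the F1 derived from it are carried with `note = "inconsistent_avg_p"` and
excluded from the ±0.01 assertion; everything else is asserted.

## 5. The synthetic scene generator

The original seed images are not publicly deposited, so the package
generates scenes with known per-seed ground truth and tests itself against
them. A scene is a bright background (default level 230) carrying convex
kernel-shaped seeds: ellipses with semi-axes drawn from 22-34 px (areas
~1,500-3,600 px², comfortably above the 200 px minimum-area filter),
randomly oriented, and truncated flat at one end with probability 0.5 to
mimic the kernel base. RGB inside the mask is a yellow-orange base
(R≈210, G≈168, B≈92) with radial shading and band-limited texture.

Defects emulate discoloration and mold as a *chromatic and textural* event:
1-3 blotches collapse the blue band to 5-20% of its base value (a drop of
60+ levels in B) while leaving the luminance-heavy R and G bands at their
normal level; a correlated fine-roughness field (amplitude 4, correlation
~2 px) covers the defective seed; and a boundary notch appears with
probability 0.4. Healthy kernels are not featureless either: 70% of them
carry 1-2 benign luminance markings (mild proportional darkening of all
bands to 80-95%), emulating tip caps, scratches and shading spots. This
split of signal matters for the baseline comparison: coarsely quantized
luminance co-occurrence statistics (GLCM) cannot separate benign markings
from defect roughness, while sign-based local binary patterns resolve the
roughness and the B/NIR channels carry the unambiguous class signal — the
mechanism by which the texture baselines end up ranked LBP over GLCM, as in
the published comparison, with neither ranking hard-coded anywhere.

The NIR plane is `clip(0.45 R + 0.1 G + 0.45 B)` inside the mask, further
attenuated to 55% inside blotches — so the fourth channel carries defect
signal beyond what RGB provides, mirroring the finding that the NIR band
improves classification. Additive Gaussian noise (sigma 3) is applied to all
four channels and clipped.

**Adhesion.** With probability `adhesion_prob` a seed is slid along a random
direction toward an existing seed until their masks share an 8-connected
border, accepted only if the overlap stays below 10% of its area *and* the
contact interface is shorter than 0.7 of its minor axis. The cap encodes
what "touching" means here: point/edge contact between vibration-separated
seeds. Without it, two flat truncated faces can meet face-on and fuse into a
near-convex union whose distance transform has a single core — a
configuration that is unresolvable from the binary mask alone and does not
represent seeds that merely touch. Non-adherent seeds keep a 2-px clearance
so pixel noise cannot bridge them, which also underwrites the
watershed-equals-connected-components oracle at `adhesion_prob = 0`.

**What the generator does not emulate:** real lens blur and chromatic
effects, spectral signatures of specific defect types (mold color vs.
mechanical damage), variety-dependent seed shape, specular highlights, and
stacked (occluding) seeds. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as designed on data with
known structure — not that the reported field accuracies transfer to any
particular camera or seed lot.

**Blotch statistics are artifact choices.** The reference material gives no
quantitative description of defect appearance; the blotch depth/size ranges
above were chosen once so that a trivial darkness-fraction threshold
separates the classes with ≥90% accuracy (verified in the test suite),
guaranteeing the learning stages have signal, and were not revisited.

## 6. Scaled-down study conditions

CPU-sized problem sizes used by the test suite and `scripts/acceptance.R`,
chosen as the package's own desk-scale conditions:

* segmentation recovery: 100 scenes at full 1296 x 964 resolution, 15 seeds,
  `adhesion_prob = 0.3`, default parameters; the count must match truth in
  at least 95 scenes with median matched Jaccard ≥ 0.9;
* end-to-end learning: `width_multiplier = 0.25`, 400 training / 100
  held-out chips, 5 epochs, batch 16. The Adam optimizer (learning rate
  0.001) is used for this short-budget run — it is one of the reference
  training configurations and reaches high accuracy within the ~125
  optimization steps available, where SGD at the same budget is still
  converging (measured: 55% vs 100% held-out accuracy); the default
  configuration for full-scale training remains SGD with momentum at batch
  32. Batch 16 is used here because the width-0.25 working set at batch 32
  sits past the single-CPU cache knee and trains ~40% slower per sample
  with no accuracy benefit. Held-out accuracy must reach 90%, and the full
  detect pipeline on 20 fresh scenes must reach macro F1 ≥ 90% against
  generator truth;
* baseline ordering: LBP+SVM must outperform GLCM+SVM on a 1,000-chip split
  — the qualitative ranking of the texture baselines, not their absolute
  published scores, which depend on the undeposited dataset.

## 7. Known limitations

* The watershed stage targets touching seeds; stacked or heavily occluded
  seeds are out of scope (the acquisition rig's vibration module is assumed
  to have separated them).
* Single-marker-per-seed relies on approximately convex seed shapes; deeply
  concave debris would over-segment.
* The CNN engine is single-threaded except for BLAS and trades generality
  for auditability: fixed layer vocabulary, no autograd, no GPU.
* Bit-for-bit training reproducibility holds for a fixed BLAS thread count;
  across different thread counts results agree only statistically.
* `input_size` other than 224 is rejected at width 1.0 because the VGG head
  requires a 7 x 7 terminal map.
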