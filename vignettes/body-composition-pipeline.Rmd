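---
title: "Automated CT body composition at L1 and L3: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CT body composition at L1 and L3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Opportunistic body-composition analysis extracts quantitative tissue
measurements from CT scans acquired for other clinical reasons. Two axial
levels carry most of the clinically validated information: the slice through
the **first lumbar vertebra (L1)**, whose trabecular density in Hounsfield
units (HU) is a bone-mineral-density surrogate, and the slice through the
**third lumbar vertebra (L3)**, where the cross-sectional areas of skeletal
muscle (SMA), visceral adipose tissue (VAT) and subcutaneous adipose tissue
(SAT) are measured. Doing this manually requires a reader to find both
vertebrae and outline several tissue regions; `bodycomp` automates the three
stages:

1. **Localization** — find the axial slices intersecting L1 and L3;
2. **Segmentation** — label the relevant tissue classes on those slices;
3. **Quantification** — compute seven body-composition indices.

## Stage 1: vertebra localization as heatmap regression

The 3D problem is reduced to 2D. The volume is reoriented to a fixed
anatomical frame (right-left, anterior-posterior, inferior-superior, with
the slice index increasing toward the head), resampled to isotropic voxels
(1 mm by default), and collapsed into a sagittal projection by a
maximum-intensity projection over the central half of the right-left extent.
The slab restriction suppresses ribs and arms while keeping the vertebral
column conspicuous; a mean projection is available by configuration.

Three HU windows — [1000, 2000], [400, 500], [800, 1900] — are applied as
channels (`clip((HU - lo)/(hi - lo), 0, 1)`), and the result is resized to a
128 x 256 grid (anterior-posterior x inferior-superior; SI is the long axis
of a thoraco-abdominal scan). The resize transform is retained so any grid
pixel maps back to a physical mm position.

The training target is an image in which each vertebral centre is a Gaussian
blob of width sigma = 15 pixels. Blobs are composed by element-wise maximum
— the usual convention in landmark-heatmap generation — so each centre
remains an exact argmax of the map at any separation; for centres at least
3 sigma apart this differs from a Gaussian-filtered delta image by less than
`exp(-9/2)`. The map is normalized to a global maximum of 1, matching the
convention that centre pixels carry value 1.

A **MultiResUNet** regresses this heatmap from the windowed projection: a
4-level encoder-decoder of MultiRes blocks (three chained 3x3 convolutions
factorizing the 5x5 and 7x7 receptive fields, concatenated, with a 1x1
residual shortcut) whose skip connections pass through Res Paths with 4, 3,
2 and 1 residual convolution blocks at successive depths, and a final 1x1
convolution with sigmoid activation. At inference, local maxima above 10% of
the global maximum and at least 2 sigma apart are ranked by intensity; the
two strongest are kept and assigned anatomically — the superior peak is L1 —
never by intensity order. Fewer than two acceptable peaks is a hard
detection-failure error, not a silent fallback.

```{r}
library(bodycomp)
cfg <- phantom_scale_config()
ds <- generate_dataset(80, seed = 11)
loc <- train_localizer(ds[1:64], cfg)
predict_centers(loc, ds[[65]]$volume, cfg)$pred
```

## Stage 2: slice segmentation

Two plain U-Nets (4 double-convolution blocks per side, nearest-neighbour
upsampling, skip concatenation, per-pixel softmax) segment the selected
slices on a fixed 512 x 512 grid (slices are centre-padded with air at
-1024 HU, or centre-cropped). Each level has its own contrast preparation:

* **L1**: one bone window [-1024, 500]; classes background / trabecular /
  cortical. Only trabecular contributes to the indices — the cortical shell
  is segmented but feeds no quantity.
* **L3**: three windows stacked as channels — full contrast [-1024, 2048],
  adipose [-190, -30], muscle [40, 100]; classes background / SMA / VAT /
  SAT.

Classes are mutually exclusive (single softmax, argmax decoding with exact
ties broken toward the lower class index). The loss is cross-entropy plus
soft Dice, a combination robust to the severe class imbalance between the
small cortical region and the background. No morphological post-processing
is applied in the clinical default configuration; an optional modal
(3x3 majority-vote) label smoothing is available behind
`config$postprocess$modal_iterations` and is enabled in the phantom-scale
configuration, where a single-pixel boundary wart is a proportionally much
larger fraction of a region than on a 512 grid.

## Stage 3: the seven indices

From the L1 slice: trabecular density mean and standard deviation (HU) and
trabecular area (cm²). From the L3 slice: SAT area, SMA, VAT area (cm²) and
SAT density standard deviation (HU). Areas are
`pixel count x spacing_x x spacing_y / 100`; density statistics are always
computed from the original HU values of the resampled slice that was
segmented, never from windowed intensities. The standard deviation uses the
population convention (divide by N) throughout the package — for regions of
hundreds of pixels the difference from the sample convention is negligible,
but a single convention keeps every reported number well defined. An empty
region yields an explicit undefined-statistic error rather than a silent
zero.

## Evaluation protocol

* Localization: mean absolute error along the superior-inferior axis in mm
  (the quantity that determines slice selection), the absolute slice error,
  and the percentage of cases with error strictly under 10 mm.
* Segmentation: Dice coefficient `2|P n T| / (|P| + |T|)` per class, with
  the both-empty case defined as 1 (perfect agreement on absence).
* Indices: percentage relative error `|pred - truth|/|truth| x 100`
  aggregated as mean +/- sd over subjects, ordinary least-squares regression
  of predicted on reference values with Pearson r (two-sided p) and r², and
  Bland–Altman bias with 1.96-sd limits of agreement.
* Model selection: subject-level k-fold cross-validation (k = 5 by default,
  unstratified, seeded partition), with a final retraining on the complete
  dataset for external testing.

## The phantom generator

Real training data cannot ship with the package, so every stage is
exercised on synthetic CT phantoms with exact ground truth. A phantom is an
elliptical torso: a subcutaneous fat ring, a muscle wall, a soft-tissue
interior with randomly placed visceral fat blobs, and a lumbar column of
cylindrical vertebral bodies (trabecular core ~N(160, 30) HU inside a
cortical shell ~N(1200, 50) HU, separated by intervertebral discs). Fat is
drawn from N(-100, 20) truncated to the adipose window [-190, -30], muscle
from N(55, 12); global acquisition noise of sd 10 HU is added last. The most
superior vertebra of the column is L1 and the third is L3; the column top
varies across subjects so the localization task cannot be solved by a fixed
offset. Body radii, fat-ring thickness, muscle thickness, visceral fat and
the column position are sampled per subject; a single integer seed makes a
dataset bitwise reproducible.

What the phantoms deliberately do **not** model: organs, bowel gas, ribs and
arms, spinal curvature, fractures, implants, contrast phases, or transitional
lumbosacral anatomy. Passing the recovery tests therefore demonstrates that
the pipeline's machinery — geometry, windowing, training, peak extraction,
mask decoding, index arithmetic — is correct and learnable end-to-end; it
does not certify clinical performance on patient data, which requires the
full-scale setting (205 training scans in the original protocol).

## Problem sizes and numerical choices

The package trains on one CPU, so the phantom-scale configuration
(`phantom_scale_config()`) reduces the default geometry: 96 x 96 x 120
volumes at 2 mm isotropic spacing, a 96-pixel segmentation grid, and a
64 x 128 projection grid with sigma = 7.5 — the clinical grid and sigma
halved together so the blob subtends the same fraction of the image. The
clinical defaults (`default_config()`) are untouched: sigma 15, 128 x 256
and 512 x 512 grids, the six HU windows above, k = 5. The recovery tests
train on 64 phantoms and evaluate on 16 held-out phantoms in roughly a
quarter of an hour.

Training choices that mattered in practice:

* **Output-bias prior initialization.** Both tasks are heavily imbalanced
  (a heatmap that is mostly zero; segmentation that is mostly background).
  With zero-initialized output biases, the first optimizer steps chase the
  global class imbalance through shared weights, silence the ReLU pathways,
  and the network collapses onto a constant predictor it never escapes. The
  heatmap model therefore starts its output bias at `logit(0.05)` and the
  U-Nets at the log class frequencies of the training masks, after which
  optimization is stable across seeds. Gradient correctness of the engine
  itself is verified against finite differences in the test suite.
* **Optimizer.** Adam (lr 1e-3 for the localizer, 3e-4 for the U-Nets,
  batch 8), mean-squared error on heatmaps, cross-entropy + soft-Dice for
  segmentation, early stopping on a seeded 10% validation split. All
  shuffling, splits and initializations derive from configuration seeds; a
  fit is bitwise reproducible.
* **Batch normalization** is omitted: at these widths (4-8 base filters) the
  prior-initialized networks train stably without it, and inference is
  exactly deterministic.
* **Interpolation.** Volume resampling is trilinear; projection resizing is
  bilinear with a Gaussian pre-blur when downscaling (anti-aliasing).
  Resampling preserves physical extent to within one voxel; constants are
  preserved exactly.
* **Tie-breaks.** Peak ranking breaks intensity ties toward the superior
  position; mask argmax breaks probability ties toward the lower class
  index; both rules are pinned by tests.

## Why the density-SD indices are fragile at phantom scale

The five area/mean indices are recovered on held-out phantoms with mean
percentage relative errors of roughly 4-15%. The two standard-deviation
indices (trabecular density SD, SAT density SD) are not, and the reason is
worth stating precisely because it is a property of the metric, not of any
one component.

A region's measured SD is corrupted by pixels that cross a tissue
interface: including a fraction `f` of wrong-side pixels at an interface
with HU contrast `D` inflates the SD of a tissue with intrinsic spread `s`
by roughly `f * D^2 / (2 s^2)` in relative terms. The phantoms have
razor-sharp interfaces — air to fat is ~900 HU, trabecular to cortical is
~1000 HU — and small regions (a 2 mm-grid SAT ring is ~900 pixels, a
trabecular core ~80). One single air pixel inside a predicted SAT region
roughly doubles its measured SD. Trained U-Nets place boundaries to about
plus or minus one pixel — the predicted contour wanders in short arcs on
either side of the truth — and neither longer training, nor re-weighting
the Dice term, nor majority-vote smoothing (which removes isolated warts
but not shifted arcs) changes that. On clinical 512-grid slices the same
one-pixel imprecision is diluted by regions 30x larger and softened by
partial-volume ramps at every interface, which is why density-SD indices
are reported as the weakest but still usable at full scale. At phantom
scale the corresponding recovery test is expected to fail for these two
indices, and does; the area and mean indices pass.

## Known limitations

* The DICOM reader covers uncompressed little-endian single-frame CT series
  (explicit or implicit VR) — the common export for abdominal CT — not
  compressed transfer syntaxes or multiframe objects; NIfTI is the primary
  interchange format.
* The segmentation models operate on a single axial slice per level;
  no 3D context is used.
* "Volumetric" Dice is computed on the selected slice's mask, the only mask
  the pipeline produces per level.
* Phantom-scale results quantify machinery, not clinical accuracy (see
  above); the cortical class is reported but held to no recovery threshold,
  mirroring its known difficulty at full scale.
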