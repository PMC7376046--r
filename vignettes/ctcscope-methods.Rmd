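---
title: "Methods: label-free CTC detection from bright-field images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free CTC detection from bright-field images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctcscope` detects and counts circulating tumor cells (CTCs) among white
blood cells (WBCs) from bright-field microscopy alone. This vignette is the
package's account of the method: the model behind each stage, the
parameters that matter, what the synthetic data generator does and does not
emulate, the numerical choices, and the known limitations.

## Why label-free

Fluorescence-based CTC enumeration depends on epithelial surface markers
that some carcinomas (notably renal cell carcinoma) underexpress, and
staining compromises cell viability for downstream culture. The
alternative implemented here uses paired fluorescence only once — to label
training crops — and classifies unseen cells from bright-field appearance.
The working assumption is that CTCs and WBCs differ in bright-field
texture (rim contrast, interior granularity) even where their size
distributions overlap: both classes average ≈11.5 µm in diameter, so size
alone cannot separate them, and the classifier must exploit appearance.

## Segmentation model

A bright-field cell under slight defocus appears as a dark rim around a
brighter interior on a mid-gray background. The segmentation stage turns
that appearance into one labelled region per cell:

1. **Brightness cap** (`cap_brightness`, default 99.5th percentile,
   inverse-ECDF definition). Otsu thresholding fails when rare, very bright
   cells stretch the histogram: the threshold lands between the bright
   cells and everything else instead of between cells and background.
   Clipping at a high percentile removes that failure mode reproducibly;
   the percentile is the automated replacement for a manual brightness
   adjustment.
2. **Edge detection** (`edge_mask`). Otsu's threshold (256-bin histogram,
   maximizing between-class variance, ties to the lower threshold) is
   applied to the Gaussian-smoothed gradient magnitude, not the raw
   intensity: cells are both darker (rim) and brighter (interior) than
   background, so intensity thresholding is ambiguous while the rim's edge
   response forms closed rings. Intensity mode remains available as
   `edge_mode = "intensity"`.
3. **Hole filling** (`fill_holes`). Background components not connected to
   the image border become foreground. In the composed pipeline the
   background is labelled with the connectivity *complementary* to the
   foreground's (4-connected holes for 8-connected rims): with matching
   connectivities, background leaks diagonally through the junctions of a
   visually closed ring and cell interiors fail to fill — a classical
   digital-topology duality. `fill_holes` itself takes the connectivity as
   an argument, so both conventions are testable.
4. **Opening + area filter** (`open_and_filter`). Morphological opening
   with an explicit disk offset set (radius 2 px by default) removes
   debris-scale specks; connected components outside [120, 2000] px are
   dropped. The bounds bracket the ≈500 px area of an 11.5 µm cell at
   0.46 µm/px by roughly 0.25–4×.
5. **Watershed** (`watershed_split`). Markers are the regional maxima of
   the Gaussian-smoothed Euclidean distance transform; maxima closer than
   the opening radius merge (the deeper survives). The negated distance
   surface is flooded from the markers inside the mask, so touching cells
   split along the distance valley. Boundary ties go to the lower label
   id; every foreground pixel receives exactly one label.
6. **Measurement** (`extract_regions`): centroid, half-open bounding box,
   area, solidity (pixel count over convex-hull lattice-point count, via
   Pick's theorem — always ≤ 1), eccentricity from second central moments.

Coordinates are 0-based `(row, col)` and boxes half-open throughout.

A known residual failure mode: a cell whose inner rim edge does not close
produces a horseshoe-shaped mask whose distance ridge carries several
maxima, so the watershed emits small fragments. These fall below the
minimum region area and are rejected by the downstream quality rules; they
do not contaminate the dataset, but they do inflate the raw region count
for such frames.

## From regions to a labeled dataset

* **Crops**: 30 × 30 patches centered at the rounded centroid, edge
  replication at frame borders, source coordinates recorded verbatim (they
  re-appear in the final count report).
* **Label transfer**: mean channel signal in a disk (radius = crop
  side / 4) at the centroid, minus the channel median, scaled by the
  channel MAD; a label requires SNR ≥ 3 (default) and dominance over the
  other channel, otherwise the crop stays UNLABELED (kept for prediction,
  excluded from training). Exact ties stay UNLABELED.
* **Quality rules** replace manual single-cell selection with explicit,
  reproducible criteria, applied in order: area in [120, 2000] px,
  solidity ≥ 0.85, eccentricity ≤ 0.8, centroid ≥ 16 px from the border,
  bounding-box overlap with any other region ≤ 0.3 (fraction of own box).
  Each rejection names the first failed rule. This is a deliberate,
  documented deviation from a manual step: it makes the training set a
  deterministic function of the input.
* **Normalization**: a least-squares plane fitted to the outer 3-px border
  ring is subtracted from the whole patch (cells near a well edge sit on a
  sloped, cloudy background), then the patch is standardized to mean 0,
  sd 1. Because the plane fit includes a constant term and is a projection
  on the ring, the operator is exactly idempotent.
* **Augmentation** to a fixed per-class count (default 1000 CTCs + 1000
  WBCs): uniform rotation (±180°), shear (±0.2), horizontal/vertical
  flips, bilinear interpolation with edge padding. Originals are included
  first, then transforms of uniformly resampled sources. Rotation range
  and flips are natural symmetries of isolated round cells; the shear
  range is kept small so shape identity is preserved. Every augmented
  crop's `origin_id` points at its source original — the provenance that
  the cross-validation harness partitions on.

## Classifier

The reference architecture is transfer learning: a pretrained ResNet-50
backbone used as a frozen feature extractor on 34 × 34 inputs (bilinearly
resized from the 30 px crops), followed by a trainable head — fully
connected + ReLU, dropout 0.6, 2-way softmax — optimized with Adam at
learning rate 10⁻⁴ on cross-entropy, mini-batches of 16. ImageNet weights
are not shipped; without them `build_model` raises an explicit error
directing to the scratch backbone.

The `small-scratch-cnn` backbone is a compact network implemented natively
in R (im2col convolution, 2 × 2 max pooling, global average pooling): three
3 × 3 convolution blocks of 8/16/32 channels feeding the same head. It
trains on a CPU in seconds-to-minutes and is the backbone all tests use.
Unstated-by-design quantities were fixed once: head width 256, epoch cap
50 with early stopping on validation loss (patience 10). Dropout is active
only in training; inference is deterministic, and argmax ties resolve to
WBC — the non-rare class — so a coin-flip never calls a CTC. Training is
balanced by augmentation (equal per-class targets), so no loss
re-weighting is used. Training and validation sets must be disjoint by
`origin_id`; violation is a hard error, not a warning.

## Evaluation protocol

`make_folds` shuffles originals within class (seeded) and deals them
round-robin into k = 5 folds: a stratified partition with sizes differing
by at most one (95 originals → five folds of 19). Stratification is an
addition over a plain shuffle: with few CTC originals, an unstratified
split can produce a training set with a single class.

`run_cv` then, per fold: augments the other folds' originals, splits the
augmented pool 80/20 into training/validation *at the origin level* (an
image-level split of augmented copies would put near-duplicates of the
same cell on both sides), trains, and predicts the held fold's original
crops only. Augmented copies never cross the fold boundary; the harness
asserts origin-disjointness at runtime and fails hard otherwise. Metrics:
per-fold and pooled confusion matrices, accuracy, precision/recall/F-score
(positive class CTC), ROC by threshold sweep with trapezoidal AUC (equal
to the normalized Mann–Whitney U), and both aggregations of AUC — pooled
over concatenated folds and the mean of per-fold values — reported under
those explicit names. The mean learning history across folds supports the
learning-curve plot.

t-SNE (perplexity 50, learning rate 100) is computed by an exact O(n²)
implementation with per-point bandwidth calibration, early exaggeration
and momentum descent, operating on flattened normalized pixels (a
CNN-feature embedding would require committing to one trained model;
pixels keep the visualization model-free). Its contract is shape and
seeded reproducibility — t-SNE geometry is not otherwise stable.

## The synthetic study conditions

The generator emulates the imaging conditions the pipeline targets:
480 × 640 8-bit frames at 0.46 µm/px (so a mean 11.5 µm cell covers
≈500 px), mid-gray background with Gaussian noise, a radial vignette and a
smooth low-frequency "cloudy" field, cells rendered as dark rim + brighter
textured interior, 5% of cells near saturation (to exercise the brightness
cap), 10% placed as touching pairs (to exercise the watershed), and bright
sub-cell-size debris specks (to exercise the opening). Diameters: WBC
N(11.5, 0.8) µm, CTC N(11.5, 1.8) µm, both truncated at ±3σ — equal means,
wider CTC spread. The class-dependent appearance difference (deeper/wider
rim and stronger interior texture for CTCs) is the label-free signal the
classifier learns; its exact amplitudes are configuration, not contract.
Fluorescence ground truth is rendered as Gaussian blobs in the
class-matching channel only, assumed perfectly registered with the bright
field — bit depth and registration error of real rigs are deliberately not
modelled.

What the generator does *not* emulate: real optics (no point-spread
function or focal stacks), red blood cells and platelets (post-enrichment
samples), cell clumps beyond pairs, staining artifacts, and — most
importantly — the true morphological variability of patient CTCs. Passing
the synthetic study therefore demonstrates that the pipeline's mechanics
are correct (segmentation recovers known cells, labels transfer without
error, augmentation and cross-validation are leakage-free, the classifier
can learn a texture difference of realistic magnitude); it does not
certify clinical accuracy, which depends on data no generator can stand in
for.

## Problem sizes and numerical choices

Tests run the study at desk scale, chosen as the smallest sizes at which
each property is meaningful: segmentation quality over ten 50-cell frames;
label-transfer fidelity over ten 30-cell frames; oracle equivalence on
10⁴ random ≤ 8 × 8 masks (hole filling and opening), 100 histograms
(Otsu), 100 score sets (AUC) and all 2 × 2 confusion matrices with entries
≤ 6 (F-score); and five-fold cross-validation over ~70 originals per class
augmented to 150 per class per fold. The acceptance script draws 1000
cells per class — the augmented-dataset scale — across 25 frames, since a
single frame cannot hold 2000 cells at the configured spacing.

Numerical conventions, fixed once: Otsu ties break to the lower threshold
(a bimodal sample with an empty gap between modes ties across the whole
gap, so the reported threshold is the lowest separating value); the
brightness-cap percentile uses the inverse-ECDF (type-1) quantile so the
cap is always an observed intensity; watershed boundary ties go to the
lower label; max-pooling ties route gradients to the first window position
in a fixed order; degenerate F-scores (no positive predictions or truths)
return 0 with a `degenerate` flag rather than NA; constant crops and
exact-plane crops are normalization errors, not silent zeros. All
randomness flows through explicit integer seeds and the package restores
the caller's RNG state.

## Limitations

* The pretrained-backbone path is defined but not exercisable without
  ImageNet weights; the scratch backbone is smaller than ResNet-50 and is
  a CPU-scale stand-in for the architecture family, not a replica.
* Segmentation assumes roughly round, sparsely touching cells; heavy
  clumps, debris larger than cells, or non-rim-like appearances (e.g.
  phase contrast) are out of scope.
* The quality rules are tuned for round single cells and will discard
  genuinely irregular CTCs; on real data this trades recall for label
  purity exactly as the manual selection it replaces did.
* UNLABELED crops are excluded from training but still classified and
  counted at prediction time; the count report tallies them separately.
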