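---
title: "Identifying fungal colonies from plate photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying fungal colonies from plate photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyid)
```

## The problem

Many culturable fungi announce their identity chromatically: grown on a
standard medium, each species lays down a characteristic palette of
pigments, often in concentric zones — a centre colour grading into a
differently coloured margin. `colonyid` turns that observation into an
automated identification pipeline for top-down photographs of culture
plates:

1. **find the dish** — a Hough circle transform over a gradient-magnitude
   edge map locates the circular plate rim;
2. **crop it** — the best-fitting circle's bounding square is cropped and
   resized to the classifier's input size;
3. **name the species** — a convolutional network with a softmax head
   converts the crop into per-species probabilities.

Around this sit the standard evaluation protocol (stratified 70/30 split,
stratified 5-fold cross-validation, confusion matrices, seven per-species
metrics, one-vs-rest ROC-AUC) and a command-line interface with
`simulate`, `train`, `test` and `evaluate` modes.

## Plate detection

### Edge map

Each RGB channel is Gaussian-blurred (default kernel 9 px, sigma 2 px) and
differentiated with 3×3 Sobel operators; the three per-channel gradient
magnitudes are combined by root-sum-of-squares and min-max-normalized to
[0, 255]. Computing gradients per channel rather than on a grey
conversion keeps edges that live in only one channel — a coloured colony
margin on grey agar, say — at full strength. Root-sum-of-squares was
chosen over a per-pixel max because it is rotationally symmetric in colour
space and favours no channel; the difference is rarely decisive, but the
choice has to be fixed somewhere. Replicate-padding is used at the image
border so the frame itself does not ring as an edge, and the
normalization returns an all-zero map when the dynamic range is below
1e-6 intensity units, rather than amplifying numerical noise on constant
images.

### Hough circle transform

The detector is the classical two-stage gradient-voting scheme. Edge
pixels at or above `param1` (default 100 on the normalized 0-255 scale)
cast votes along their gradient direction, in both senses, at every
radius in `[min_radius, max_radius]`; votes accumulate in a centre array
at `1/dp` resolution. Local maxima above `param2` (default 50 votes)
become centre candidates, greedily accepted in descending vote order
subject to a `min_dist` spacing. Each candidate's radius is the mode of a
1 px histogram of edge-pixel distances. Two refinements give sub-pixel
output: the centre is the vote-weighted centroid of the accumulator peak's
3×3 neighbourhood, and centre and radius are then polished by an
algebraic least-squares circle fit to the edge pixels lying within 3 px
of the hypothesised ring (two passes, accepting only local adjustments of
at most 5 px). The refinement is what brings translation equivariance
inside ±2 px; the raw accumulator is quantised to whole pixels.

Defaults scale with the image: `min_dist = min_dim/4`,
`min_radius = min_dim/8`, `max_radius = min_dim/2`. All six parameters are
user-overridable, from R or as CLI flags, because real photograph sets
differ in plate scale far more than in any other respect. Edge maps carry
the per-pixel gradient direction of the locally strongest channel as
attributes; if a caller supplies a bare magnitude matrix instead, the
detector estimates directions by Sobel on the magnitude raster itself —
for an annular ridge those directions are radial, which is exactly what
centre voting needs, though with more noise than the true image gradient.

Among multiple detections, the plate is taken to be the circle fully
inside the frame with the highest vote score; ties break to the larger
radius (a dish rim beats a colony margin of equal evidence), then to the
smaller row, then column coordinate. The tie-break chain is arbitrary but
total, so results are reproducible.

## The classifier

The default backbone, `small_cnn`, is three blocks of 3×3 convolution +
ReLU + 2×2 max pooling with 16, 32 and 64 filters, followed by global
average pooling, a 64-unit ReLU dense layer and a softmax output; inputs
are 64×64 RGB crops scaled to [0, 1]. This is deliberately small: the
network trains from scratch on a laptop CPU in minutes and needs no
downloaded weights, which keeps every experiment in this package fully
self-contained. A `vgg16` backbone (the classical 13-convolution
configuration, optionally frozen) is constructible through the same
layer stack for users who want the deeper architecture; without
pretrained weights it is a large random-init network, so it is not the
default. The convolution and pooling kernels are implemented in C++
(im2col + BLAS GEMM); everything else — global average pooling, dense
layers, softmax, Adam — is plain R matrix algebra.

Training minimises mean cross-entropy with Adam (learning rate 1e-3,
batch 16 by default; both recorded in the configuration so runs are
reproducible). Each mini-batch is augmented with label-preserving random
transforms — rotation up to 20°, shifts up to 10%, zoom up to 10%, both
flips, brightness scaling up to 10% — composed into a single bilinear
affine warp. The magnitudes are conventional for natural-image
augmentation; a plate photographed from above genuinely can appear at any
rotation and either flip, so the geometric family is well matched to the
domain. A stratified fraction (default 20%) of the training data is held
out; validation loss is monitored per epoch for early stopping (default
patience `min(10, epochs)`) and the weights with the lowest validation
loss seen are what the caller gets back — and what lands in the HDF5
checkpoint file, together with the class-label list and architecture
metadata. One integer seed drives weight initialisation, shuffling,
validation splitting and augmentation draws, so histories are bitwise
reproducible.

## Evaluation protocol

The split and fold operations are stratified: the 70/30 split gives each
class `floor(0.7 n_c)` training images and tops up to the overall
`round(0.7 n)` by largest fractional part; folds are assigned by a global
round-robin over shuffled within-class ids, so fold sizes differ by at
most one *and* every class spreads as evenly as possible (269 items in 5
folds gives sizes 54, 54, 54, 54, 53). Classes smaller than `k` degrade
to the same round-robin with a warning. Subsets are strictly disjoint —
if two subsets shared images, every downstream metric would be
optimistically biased, so "minimal overlap" is implemented as none.

Cross-validation trains one fresh model per fold (fold-specific seeds
derived from the master seed) and stores, for every test image, the full
probability vector and argmax label; a failed run is recorded without
aborting the rest. Confusion matrices are oriented rows-predicted ×
columns-actual. Per-species one-vs-rest counts give the seven metrics:
sensitivity, specificity, accuracy, PPV, NPV (percentages), F1 and MCC
(dimensionless). A zero denominator makes a metric *undefined* and it is
reported as missing, never coerced to 0 — coercion would silently drag
down averages. The summary table's bottom line is the unweighted mean
over species (skipping missing entries with a warning), with half-up
rounding to two decimals.

ROC curves are one-vs-rest per species over the pooled predictions of all
cross-validation runs — pooling, rather than averaging per-run curves, is
the simplest construction that uses every prediction exactly once. The
AUC is the trapezoidal area, which equals the Mann–Whitney probability
that a random positive outscores a random negative with ties counting
one half; the test suite checks that identity exhaustively on small
inputs and against an independent ROC implementation.

`reconstruct_counts()` inverts a printed metrics row back to integer
(TP, FN, FP, TN) by constrained search, verifying that all seven printed
values are mutually consistent at their printed precision. It exists
because published tables give rounded percentages, not counts, and the
package's own metric identities can then be exercised against such a
table exactly.

## The synthetic plate generator

No public image corpus accompanies this problem, so the package ships a
seeded generator whose defaults emulate the documented imaging set-up: a
512×512 canvas; a plate of radius 16–33% of the canvas placed uniformly
at random (10 px margin); light (tone 190) or dark (tone 30) backdrop
with equal probability; a thin bright rim annulus (3 px, tone 250) —
the circular edge a real dish presents and the detector keys on; a cream
agar disc; and a colony disc whose colour grades radially from the
species' centre colour to its ring colour (colony radius 50–85% of the
plate, standing in for developmental stage), softened over the outer 15%
of its radius, with zero-mean correlated mottling (sd 8, correlation
length 8 px) and independent per-pixel Gaussian sensor noise (sd 5,
clipped to [0, 255]). Species palettes are drawn by rejection sampling
with a 60-unit RGB distance floor between centre colours, the package's
definition of "chromatically distinct species".

What the generator does *not* model is equally important for reading the
test results: hyphal texture, irregular colony margins, specular
highlights, perspective and lens distortion, uneven illumination and
inter-replicate biological variation are all absent. Passing the bundled
experiments therefore demonstrates that the pipeline's machinery —
detection geometry, training dynamics, the evaluation algebra — is
correct and that the classifier can exploit chromatic separation; it does
not certify field accuracy on real photographs, which the authors of any
retraining must establish on their own images.

## Problem sizes and numerical choices

The bundled experiments use a 4-species × 30-image study (chance accuracy
0.25) at 64×64 input resolution, 25 training epochs, and 100 rendered
plates for detection-recovery measurements; these sizes give stable
statistics while keeping a full run in the minutes range on one CPU core.
Detection accepts a plate as recovered within ±5 px in centre and radius.
Ties in the softmax argmax resolve to the earlier label in sorted order;
ROC threshold sweeps group tied scores; probabilities are clamped at
1e-12 inside the cross-entropy; Adam uses the standard bias correction
with epsilon 1e-8. Degenerate inputs are rejected with specific errors:
fewer than two classes, an empty class, an unreadable file, a circle
outside the canvas, an even blur kernel, inverted radius bounds.

## Known limitations

* The synthetic generator's realism gap, discussed above.
* The `vgg16` backbone is architecture-only; no pretrained weights are
  bundled, so transfer learning in the strict sense requires the user to
  supply weights.
* Plates are assumed circular in the image (top-down photography);
  ellipse fitting for oblique views is out of scope.
* The detector returns at most one plate per `min_dist` neighbourhood;
  touching dishes closer than `min_dist` merge into one detection.
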