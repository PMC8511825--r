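---
title: "Dilated fully convolutional networks for thoracic organ-at-risk segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dfcn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiotherapy planning requires delineating organs at risk (OARs) — lungs,
heart, esophagus, trachea, spinal cord — on every axial slice of a planning
CT. Manual contouring is slow and inter-observer variability is large,
especially for small, low-contrast structures such as the collapsed
esophagus. This package implements a fully convolutional network (FCN)
approach in which the classic VGG16-based FCN family is improved by *atrous
(dilated) convolution*: the strides of the deepest pooling layers are
removed and the following convolutions are dilated by the product of the
removed strides, so the network keeps its receptive field while producing a
score map at 4-16 pixel resolution instead of 32. We refer to the dilated
variants as D-FCN 16s/8s/4s, by their output stride.

## Model

### Window-adjustment input layer

CT intensities are Hounsfield units (HU): air at -1000, water at 0, bone
far above 0. Networks pre-trained on RGB images expect three input
channels; instead of triplicating the grey-scale slice, the first
(parameter-free) layer of every network maps the HU range `[-300, 600]`
onto three channels, each channel applying one of the three equal
sub-windows of width 300 HU (levels -150, 150, 450):

```
out = clamp((HU - (level - width/2)) / width, 0, 1)
```

Values below/above a channel's sub-window saturate at 0/1, so the three
channels jointly encode the full soft-tissue range at three operating
points, mimicking how radiologists review CT at different display windows.
Design choices the protocol leaves open, decided here once:

* output scale is `[0, 1]` (framework-neutral; a gain can be applied when
  loading externally trained weights that expect 0-255);
* the layer is fixed, not learnable — nothing in the protocol suggests
  trainable window parameters;
* out-of-range HU saturate (standard display-window semantics), they are
  not masked;
* channels are ordered by ascending HU sub-window.

### FCN family and the dilation conversion

`build_fcn()` constructs the standard VGG16 FCN: five convolution blocks
(2, 2, 3, 3, 3 convolutions of 3x3; 64-512 channels), each followed by a
2-stride max pool, then 7x7 and 1x1 convolutions of 4096 channels and a 1x1
score layer with one map per class (7 by default: background + 6 OARs).
FCN 16s and 8s fuse zero-initialized pool4/pool3 scores with 2x upsampled
deeper scores. All convolutions use "same" zero padding; the original
FCN's 100-pixel input pad is not used, so shape arithmetic is exact and
only border behaviour differs.

`convert_to_dfcn()` applies the stride-removal rule to an FCN 32s
architecture: walking the backbone, the deepest pools (pool5, then pool4,
then pool3) become stride-1; each converted pool is dilated by the running
factor accumulated so far, the factor then doubles and dilates every
subsequent convolution. For D-FCN 4s the backbone dilations per block are
(1, 1, 1, 2, 4, 8). Two properties are designed in and tested:

* **receptive-field conservation** — the layer recurrence
  `rf <- rf + (k_eff - 1) * jump; jump <- jump * stride` gives identical
  receptive fields for FCN 32s and all three D-FCN variants;
* **a trous equivalence** — with shared weights and fusion disabled, the
  D-FCN score map subsampled at stride `32 / output_stride` reproduces the
  FCN 32s score map. In this implementation the equality is bit-exact,
  because convolution sums are accumulated in the same order and the
  padding conventions coincide on the sub-grid. Note one consequence the
  protocol's data model does not anticipate: a pool that *follows* an
  earlier converted pool must itself be dilated (D-FCN 8s pool5 carries
  dilation 2; D-FCN 4s pool4/pool5 carry 2/4), otherwise the equivalence
  breaks. Unconverted pools keep dilation 1.

Two points the source protocol leaves ambiguous, resolved here and
recorded: D-FCN variants use **no skip fusion** (dilation already preserves
the resolution that skips compensate for), and the final upsampling is a
cascade of two learnable, bilinear-initialized transposed convolutions
(2x2 for D-FCN 4s, 2x4 for 8s, 4x4 for 16s), reconciling the "2x and 4x"
staging of the original diagram. Both are configurable in the architecture
builder rather than asserted as the original authors' intent.

The `width_multiplier` (not part of the original design) scales every
channel count so that desk-scale experiments can run a 1/4- or 1/8-width
network on one CPU; it defaults to 1.

### Engine and initialization

No deep-learning framework is assumed: convolution (with dilation),
transposed convolution, 2x2 max pooling and softmax cross-entropy are
implemented with im2col + BLAS kernels (Rcpp/RcppArmadillo), in float32
(training fast path) and float64 (default inference). `init_network()` is
deterministic given a seed: He (fan-in) normal weights for convolutions,
zeros for score layers (so an untrained network predicts background
everywhere), exact bilinear kernels for upsampling layers. Externally
supplied backbone weights can be injected with `copy_matching_weights()`;
none are shipped.

## Dice evaluation

For structure class `c`, `Dice = 2|X ^ Y| / (|X| + |Y|)` over predicted and
reference pixel sets. The **global** Dice is the micro average (pooled
counts over all foreground classes); a union-of-foreground Dice would
credit cross-class confusions (esophagus predicted as trachea), so it is
not used. Per-case Dice pools all slices of a case (3-D counts from 2-D
predictions); cohort values average per-case values. `0/0` (structure
absent from prediction *and* reference) is reported as `NA` and excluded
from averages, with exclusion counts surfaced — silently scoring it 1.0
would inflate small-structure results. Whether the original protocol's
global Dice is micro, macro or per-case averaged is not stated; micro +
per-case averaging is this package's recorded choice.

## Training protocol

`split_dataset()` assigns cases uniformly at random to train/validation/
test (the reference corpus used 70/30/20 of 120 cases). `train_network()`
runs SGD with momentum and weight decay on per-pixel softmax cross-entropy,
snapshotting a checkpoint every `checkpoint_interval` iterations (5000 in
the full-scale protocol; scaled proportionally at desk scale).
`validate_checkpoints()` scores every checkpoint on the validation cohort,
producing the Dice curve; `select_optimal()` picks the maximum, breaking
ties toward the earliest iteration. No smoothing or monotonicity is
assumed of the curve.

The protocol names its hyperparameters but publishes no values; defaults
here are the FCN-standard choices, all overridable: initial learning rate
`1e-3`, step decay x0.1 at 50% and 75% of the iteration budget, batch size
4, momentum 0.9, weight decay `5e-4`, no augmentation (left-right flips
available behind a flag). The loss is unweighted by default;
`class_weights = "inverse_freq"` enables inverse-frequency weights (capped
at 100x background) to counter the small-organ imbalance that the original
study identifies as its main weakness.

## Synthetic phantom

The clinical dataset behind the reference results is private, so the
package ships a parametric thoracic phantom: a soft-tissue body ellipse
containing two lung ellipses (-700 +/- 60 HU), a heart between them
(45 +/- 15), a tracheal lumen (-950 +/- 30) splitting into bronchi on
inferior slices, an esophagus (40 +/- 15) behind the trachea, and a
vertebral ring (400 +/- 100, part of the background class) around the cord
(35 +/- 10); global Gaussian noise sigma 10 HU. The HU table is
anatomically plausible and deliberately exercises the `[-300, 600]`
window: lungs saturate below it, vertebra above it, and heart/esophagus/
cord differ by only 5 HU so the network must use spatial context, not
intensity alone. Small structures occupy under 2% of body pixels,
preserving the class-imbalance difficulty. Organ centers drift smoothly
across the slices of a case, so per-case 3-D Dice pooling is meaningful.

What the phantom does *not* emulate: CT physics (beam hardening,
reconstruction kernels, partial-volume effects), pathology, contacting
organ boundaries with realistic texture, or inter-observer contour noise.
A green desk-scale test therefore establishes that the implementation
learns and ranks architectures as designed on well-posed geometry — not
that it reproduces clinical Dice levels; the reference study's clinical
tables are explicitly not reproduction targets.

Determinism: a case is a pure function of (config, case seed); dataset
case seeds derive from the master seed as
`(master + 7919 * i) mod (2^31 - 1)`. Geometry draws violating the
construction constraints (all structures present, tubular structures >= 2
pixels across) are retried a bounded number of times, then fail loudly
naming the constraint.

## Numerical and format choices

* Inference and all equivalence checks run in float64; training runs in
  float32 for speed on one CPU. The two paths agree to ~1e-5 on score
  maps.
* `predict_labels()` breaks score ties toward the lowest class index, so
  all-zero scores decode to background.
* Inputs must be divisible by 32; `pad = TRUE` zero-pads (air) on the
  bottom/right and crops the output back.
* Volumes/masks are single-file NIfTI-1 (int16 HU, uint8 masks, pixdim in
  mm, optional gzip), implemented in-package because no NIfTI reader is
  available in the offline dependency set; DICOM/DICOM-RT are out of scope
  (convert externally).
* Contours are 0.5-level iso-lines of the class indicator on a zero-padded
  grid (marching squares via `grDevices::contourLines`): vertices at
  half-integer pixel-edge positions, outer boundaries counter-clockwise,
  holes clockwise as separate polygons; `rasterize_contours()` is the
  even-odd fill used as the round-trip oracle.
* The run configuration file is JSON (sections `data`, `window`, `model`,
  `training`, `evaluation`) rather than YAML: the target environment has
  no YAML parser, and jsonlite is part of the dependency set.

## Desk-scale convergence experiment

The package's stochastic acceptance property mirrors the reference
convergence claim at desk scale: a width-1/4 D-FCN 4s trained from scratch
on ~205 synthetic 96x96 slices (34 cases) reaches a held-out cohort global
Dice of at least 0.80 within the 2000-iteration budget (500 are used:
batch size 1, initial rate 0.01, inverse-frequency weights), and an FCN 32s
given the identical budget does not beat it by more than 0.02. This is a
non-inferiority smoke test of the ranking *direction* — the coarse
32-stride decoder cannot delineate 2-3-pixel structures, the dilated
4-stride decoder can — not a reproduction of the clinical ranking.

## Known limitations

* Single-CPU training limits practical experiments to reduced-width
  networks and small phantoms; the full-width 500k-iteration protocol is
  out of reach by design.
* Dropout is omitted (the reference protocol does not mention
  regularization beyond weight decay; deterministic training is favoured).
* The 7x7 fc6 kernel under dilation 8 has an effective extent of 55
  pixels; it is kept (the conversion rule dilates without shrinking
  kernels), which makes fc6 the dominant compute cost of D-FCN 4s.
* Bootstrap confidence intervals and surface-distance metrics are not
  implemented (out of scope).
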