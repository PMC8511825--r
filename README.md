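# dfcn — dilated fully convolutional networks for chest-CT organ segmentation

`dfcn` is an R package for training and evaluating semantic-segmentation
networks that automatically delineate thoracic organs at risk (left and
right lung, heart, esophagus, trachea, spinal cord) on axial chest-CT
slices, the contouring task that dominates radiotherapy planning time. It
is aimed at medical-image-analysis researchers who want a dependency-light,
fully reproducible reference implementation of the FCN → D-FCN (dilated
FCN) construction and its evaluation protocol, runnable end to end on a
single CPU.

## What it implements

* **HU window-adjustment input layer.** A CT slice arrives as one channel
  of Hounsfield units. The input layer splits the window `[-300, 600]` HU
  into three equal sub-windows (level/width `(-150, 300)`, `(150, 300)`,
  `(450, 300)`) and maps each onto one network channel via
  `out = clamp((HU - (level - width/2)) / width, 0, 1)`.
* **The six architectures.** VGG16-based FCN 32s/16s/8s (skip fusion of
  pool4/pool3 scores), and D-FCN 16s/8s/4s derived from FCN 32s by
  removing the strides of the deepest pools and dilating every downstream
  convolution by the product of removed strides. Receptive field is
  conserved (404 px for all variants); the output stride — the "s" in the
  name — improves from 32 to 4. With shared weights, a D-FCN score map
  subsampled at `32/output_stride` reproduces the FCN 32s score map
  exactly (the "à trous" equivalence, tested to machine precision).
* **A CPU engine.** Dilated convolution, transposed convolution, max
  pooling and softmax cross-entropy as im2col + BLAS kernels
  (Rcpp/RcppArmadillo), float32 for training and float64 for inference,
  with deterministic seeded initialization (He weights, zero score layers,
  exact bilinear upsampling kernels).
* **Dice evaluation.** Per-structure Dice `2|X∩Y|/(|X|+|Y|)`, global
  (micro-averaged) Dice over all foreground structures, per-case pooling
  over slices, cohort aggregation with explicit handling of the 0/0 case.
* **The training protocol.** Random 70/30/20-style case splits, SGD with
  momentum/weight decay, checkpoints every N iterations, validation Dice
  curves, optimal-checkpoint selection (earliest iteration on ties), and
  test-set reporting — every step deterministic given its seeds.
* **A thoracic CT phantom.** Paired (HU slice, label mask) generator with
  anatomically plausible geometry and HU statistics, so the whole pipeline
  is trainable and testable with no data download.
* **IO + CLI.** Minimal NIfTI-1 volumes/masks, CSV manifests,
  mask-to-contour extraction (marching squares, oriented polygons, JSON
  export), and a `dfcn` command line
  (`simulate | train | validate | predict | evaluate | arch-info`).

## Worked example

```r
library(dfcn)

# synthetic cohort: 34 training cases (~205 slices of 96x96), 6 held out
pc     <- phantom_config()
train  <- generate_phantom_dataset(pc, 34, master_seed = 101)$cases
val    <- generate_phantom_dataset(pc, 6,  master_seed = 505)$cases

# width-1/4 D-FCN 4s, trained from scratch for 500 iterations
cfg <- training_config(initial_lr = 0.01, batch_size = 1,
                       max_iterations = 500, checkpoint_interval = 100,
                       seed = 7, class_weights = "inverse_freq")
net   <- init_network(build_arch("dfcn4s", n_classes = 7,
                                 width_multiplier = 1/4), seed = 7)
ckpts <- train_network(net, train, cfg)
curve <- validate_checkpoints(ckpts, val)
as.data.frame(curve)
#>   iteration global_dice
#> 1       100   0.6990602
#> 2       200   0.7452637
#> 3       300   0.8049237
#> 4       400   0.8114352
#> 5       500   0.8159654
select_optimal(curve)$iteration
#> [1] 500
```

The curve is the validation **global Dice** (micro-average over the six
structures, pooled per case, averaged over cases) of each checkpoint; the
selected model is the curve's argmax. 0.82 after 500 single-slice
iterations means the network has learned the large structures well and the
2–3-pixel tubular structures partially — the same small-organ difficulty
profile reported for clinical data. An FCN 32s trained with the identical
budget reaches 0.8045: the coarse 32-stride decoder is the limiting
factor, which is exactly what the dilated conversion removes.

Architecture inspection:

```text
$ dfcn arch-info --variant dfcn4s
dfcn4s: output stride 4, receptive field 404 px
   name  kind   input kernel stride dilation effective_kernel ...
  pool3  pool conv3_3      2      1        1                2
conv4_1  conv   pool3      3      1        2                5
...
```

## Layout

* `R/`, `src/` — windowing, architectures, engine, metrics, training
  harness, phantom, IO/contours, CLI
* `tests/testthat/` — unit + property tests and `test-acceptance.R`
* `vignettes/dfcn-methods.Rmd` — model, assumptions, design decisions,
  phantom scope, limitations
* `scripts/acceptance.R` — acceptance report (above)
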