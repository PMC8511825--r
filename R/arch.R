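#' @name architectures
#' @title FCN and D-FCN network architectures
#'
#' @description
#' The package builds six VGG16-backbone variants for semantic segmentation:
#' the classic skip-architecture family (`fcn32s`, `fcn16s`, `fcn8s`) and the
#' dilated family (`dfcn16s`, `dfcn8s`, `dfcn4s`) obtained from `fcn32s` by
#' removing the stride of the deepest pooling layers and compensating every
#' downstream convolution with an equal dilation, so the receptive field is
#' preserved while the score-map resolution (the *output stride*, the "s" in
#' the variant name) improves from 32 down to 4.
#'
#' An architecture is an ordered list of layer descriptions (kind, kernel,
#' stride, dilation, channels, data-flow edges).  All convolutions use
#' "same"-style zero padding, so the output stride alone controls resolution.
NULL

VGG_BLOCKS <- list(n_convs = c(2L, 2L, 3L, 3L, 3L),
                   channels = c(64L, 128L, 256L, 512L, 512L))

scaled_ch <- function(base, mult) max(1L, as.integer(round(base * mult)))

layer_spec <- function(name, kind, input, kernel = 1L, stride = 1L,
                       dilation = 1L, in_channels = NA_integer_,
                       out_channels = NA_integer_, activation = "none",
                       zero_init = FALSE, factor = NA_integer_, aux = NA_character_) {
  list(name = name, kind = kind, input = input, kernel = as.integer(kernel),
       stride = as.integer(stride), dilation = as.integer(dilation),
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels), activation = activation,
       zero_init = zero_init, factor = as.integer(factor), aux = aux)
}

# Shared VGG16 backbone (conv blocks + pool layers + fc-convs + score layer).
vgg_backbone <- function(n_classes, mult, in_channels = 3L) {
  layers <- list()
  prev <- "input"
  cin <- as.integer(in_channels)
  for (b in seq_along(VGG_BLOCKS$n_convs)) {
    cout <- scaled_ch(VGG_BLOCKS$channels[b], mult)
    for (i in seq_len(VGG_BLOCKS$n_convs[b])) {
      nm <- sprintf("conv%d_%d", b, i)
      layers[[nm]] <- layer_spec(nm, "conv", prev, kernel = 3L,
                                 in_channels = cin, out_channels = cout,
                                 activation = "relu")
      prev <- nm
      cin <- cout
    }
    nm <- sprintf("pool%d", b)
    layers[[nm]] <- layer_spec(nm, "pool", prev, kernel = 2L, stride = 2L,
                               in_channels = cin, out_channels = cin)
    prev <- nm
  }
  fc_ch <- scaled_ch(4096L, mult)
  layers[["fc6"]] <- layer_spec("fc6", "conv", prev, kernel = 7L,
                                in_channels = cin, out_channels = fc_ch,
                                activation = "relu")
  layers[["fc7"]] <- layer_spec("fc7", "conv", "fc6", kernel = 1L,
                                in_channels = fc_ch, out_channels = fc_ch,
                                activation = "relu")
  layers[["score_fr"]] <- layer_spec("score_fr", "conv", "fc7", kernel = 1L,
                                     in_channels = fc_ch,
                                     out_channels = n_classes,
                                     zero_init = TRUE)
  layers
}

upsample_layer <- function(name, input, factor, n_classes) {
  layer_spec(name, "upsample", input, kernel = 2L * factor, stride = factor,
             in_channels = n_classes, out_channels = n_classes,
             factor = factor)
}

new_arch <- function(variant, layers, n_classes, mult, window) {
  structure(list(variant = variant, n_classes = as.integer(n_classes),
                 width_multiplier = mult, window = window,
                 layers = layers, output = layers[[length(layers)]]$name),
            class = "dfcn_arch")
}

#' Build an FCN 32s / 16s / 8s architecture
#'
#' Constructs the standard VGG16-based fully convolutional network: five
#' convolution blocks (2, 2, 3, 3, 3 convolutions of 3x3; 64, 128, 256, 512,
#' 512 channels, scaled by `width_multiplier`), each followed by a 2-stride
#' max pool; then a 7x7 convolution and a 1x1 convolution of 4096 x
#' `width_multiplier` channels and a 1x1 score layer with `n_classes` maps.
#' `fcn16s` fuses a zero-initialized pool4 score with the 2x-upsampled deep
#' score; `fcn8s` additionally fuses a pool3 score.  A final learnable,
#' bilinear-initialized upsampling restores input resolution.
#'
#' @param variant one of `"fcn32s"`, `"fcn16s"`, `"fcn8s"`
#' @param n_classes number of output maps (background + structures), `>= 2`.
#'   The default 7 covers background + left lung, right lung, heart,
#'   esophagus, trachea, spinal cord.
#' @param width_multiplier positive scale applied to every channel count
#'   (e.g. `1/4` for a desk-scale network); default 1
#' @param window the HU [window_spec()] of the parameter-free input layer
#' @return a `dfcn_arch` object
#' @seealso [convert_to_dfcn()], [build_arch()], [output_stride()],
#'   [receptive_field()]
#' @export
build_fcn <- function(variant = c("fcn32s", "fcn16s", "fcn8s"),
                      n_classes = 7L, width_multiplier = 1,
                      window = window_spec()) {
  variant <- match.arg(variant)
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) {
    stop_dfcn("build_fcn: n_classes must be >= 2 (background + structures)")
  }
  if (!is.numeric(width_multiplier) || width_multiplier <= 0) {
    stop_dfcn("build_fcn: width_multiplier must be positive")
  }
  layers <- vgg_backbone(n_classes, width_multiplier,
                         in_channels = window$n_channels)
  if (variant == "fcn32s") {
    layers[["upscore32"]] <- upsample_layer("upscore32", "score_fr", 32L, n_classes)
  } else {
    layers[["upscore2"]] <- upsample_layer("upscore2", "score_fr", 2L, n_classes)
    layers[["score_pool4"]] <- layer_spec(
      "score_pool4", "conv", "pool4", kernel = 1L,
      in_channels = layers[["pool4"]]$out_channels,
      out_channels = n_classes, zero_init = TRUE)
    layers[["fuse_pool4"]] <- layer_spec(
      "fuse_pool4", "fuse", "upscore2", aux = "score_pool4",
      in_channels = n_classes, out_channels = n_classes)
    if (variant == "fcn16s") {
      layers[["upscore16"]] <- upsample_layer("upscore16", "fuse_pool4", 16L, n_classes)
    } else {
      layers[["upscore_pool4"]] <- upsample_layer("upscore_pool4", "fuse_pool4", 2L, n_classes)
      layers[["score_pool3"]] <- layer_spec(
        "score_pool3", "conv", "pool3", kernel = 1L,
        in_channels = layers[["pool3"]]$out_channels,
        out_channels = n_classes, zero_init = TRUE)
      layers[["fuse_pool3"]] <- layer_spec(
        "fuse_pool3", "fuse", "upscore_pool4", aux = "score_pool3",
        in_channels = n_classes, out_channels = n_classes)
      layers[["upscore8"]] <- upsample_layer("upscore8", "fuse_pool3", 8L, n_classes)
    }
  }
  new_arch(variant, layers, n_classes, width_multiplier, window)
}

# Decoder staging of the dilated variants: the final upsampling factor
# (= output stride) is realized as a cascade of two bilinear-initialized
# learnable stages (4 = 2x2, 8 = 2x4, 16 = 4x4).
DFCN_STAGES <- list(`16` = c(4L, 4L), `8` = c(2L, 4L), `4` = c(2L, 2L))

#' Convert FCN 32s into a dilated D-FCN variant
#'
#' Applies the stride-removal / dilation-compensation rule: walking the
#' backbone, the deepest pools (pool5, then pool4, then pool3) have their
#' stride removed (2 -> 1) until the output stride reaches `target_stride`.
#' Each converted pool is itself dilated by the running factor accumulated so
#' far, the factor then doubles, and every subsequent convolution carries a
#' dilation equal to the current factor (d-1 zeros are inserted between
#' kernel elements).  This preserves the receptive field exactly while the
#' score map keeps a finer resolution; with the weights shared, the converted
#' network reproduces the FCN 32s scores on the coincident sub-grid (the
#' "a trous" equivalence).
#'
#' The dilated variants use no skip fusion -- dilation already preserves the
#' resolution the skips were compensating for -- and the final upsampling is
#' a cascade of two learnable bilinear-initialized stages (2x2, 2x4 or 4x4).
#'
#' @param arch an `fcn32s` architecture from [build_fcn()]
#' @param target_stride one of 16, 8, 4
#' @return a `dfcn_arch` with variant `dfcn16s`, `dfcn8s` or `dfcn4s`
#' @export
convert_to_dfcn <- function(arch, target_stride) {
  if (!inherits(arch, "dfcn_arch") || arch$variant != "fcn32s") {
    stop_dfcn("convert_to_dfcn: arch must be an fcn32s architecture")
  }
  target_stride <- as.integer(target_stride)
  if (!target_stride %in% c(16L, 8L, 4L)) {
    stop_dfcn("convert_to_dfcn: target_stride must be one of 16, 8, 4")
  }
  n_remove <- as.integer(log2(32 / target_stride))
  convert <- paste0("pool", seq(6L - n_remove, 5L))
  layers <- arch$layers[setdiff(names(arch$layers), "upscore32")]
  f <- 1L
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (l$kind == "pool" && nm %in% convert) {
      l$stride <- 1L
      l$dilation <- f
      f <- f * 2L
    } else if (l$kind == "conv") {
      l$dilation <- l$dilation * f
    }
    layers[[nm]] <- l
  }
  stages <- DFCN_STAGES[[as.character(target_stride)]]
  layers[["up1"]] <- upsample_layer("up1", "score_fr", stages[1], arch$n_classes)
  layers[["up2"]] <- upsample_layer("up2", "up1", stages[2], arch$n_classes)
  new_arch(sprintf("dfcn%ds", target_stride), layers, arch$n_classes,
           arch$width_multiplier, arch$window)
}

#' Build any of the six supported architectures by name
#'
#' Convenience dispatcher: FCN variants go through [build_fcn()]; D-FCN
#' variants are built as `fcn32s` and passed through [convert_to_dfcn()].
#'
#' @inheritParams build_fcn
#' @param variant one of `"fcn32s"`, `"fcn16s"`, `"fcn8s"`, `"dfcn16s"`,
#'   `"dfcn8s"`, `"dfcn4s"`
#' @return a `dfcn_arch`
#' @export
build_arch <- function(variant, n_classes = 7L, width_multiplier = 1,
                       window = window_spec()) {
  variant <- match.arg(variant, c("fcn32s", "fcn16s", "fcn8s",
                                  "dfcn16s", "dfcn8s", "dfcn4s"))
  if (startsWith(variant, "fcn")) {
    return(build_fcn(variant, n_classes, width_multiplier, window))
  }
  base <- build_fcn("fcn32s", n_classes, width_multiplier, window)
  convert_to_dfcn(base, as.integer(sub("^dfcn(\\d+)s$", "\\1", variant)))
}

# Backbone path: conv/pool layers feeding score_fr (input -> ... -> score_fr).
backbone_layers <- function(arch) {
  upto <- which(names(arch$layers) == "score_fr")
  if (length(upto) == 0) upto <- length(arch$layers)
  arch$layers[seq_len(upto)]
}

effective_kernel <- function(k, d) k + (k - 1L) * (d - 1L)

#' Output stride of an architecture
#'
#' Ratio between the input resolution and the resolution of the score map
#' that feeds the final upsampling (the "s" in FCN 32s / D-FCN 4s):
#' the product of the layer strides along the path to that score map,
#' divided by any decoder upsampling already applied before skip fusion
#' (FCN 16s/8s fuse pool scores at 2x stages).
#'
#' @param arch a `dfcn_arch`
#' @return integer
#' @export
output_stride <- function(arch) {
  stopifnot(inherits(arch, "dfcn_arch"))
  num <- 1L
  den <- 1L
  nm <- score_layer_name(arch)
  while (!identical(nm, "input")) {
    l <- arch$layers[[nm]]
    if (l$kind %in% c("conv", "pool")) num <- num * l$stride
    if (l$kind == "upsample") den <- den * l$factor
    nm <- l$input
  }
  as.integer(num / den)
}

#' Receptive field of one score-map unit
#'
#' Computed by the standard layer recurrence
#' `rf <- rf + (effective_kernel - 1) * jump; jump <- jump * stride`
#' walked along the backbone, where the effective kernel extent of a
#' dilated kernel is `k + (k - 1)(d - 1)`.  The dilated variants preserve
#' the FCN 32s receptive field exactly.
#'
#' @param arch a `dfcn_arch`
#' @return integer, in input pixels
#' @export
receptive_field <- function(arch) {
  stopifnot(inherits(arch, "dfcn_arch"))
  rf <- 1L
  jump <- 1L
  for (l in backbone_layers(arch)) {
    rf <- rf + (effective_kernel(l$kernel, l$dilation) - 1L) * jump
    jump <- jump * l$stride
  }
  rf
}

#' Per-layer architecture table
#'
#' @param arch a `dfcn_arch`
#' @return data.frame with one row per layer: name, kind, data-flow source,
#'   kernel, stride, dilation, effective kernel extent, channels
#' @export
arch_summary <- function(arch) {
  stopifnot(inherits(arch, "dfcn_arch"))
  do.call(rbind, lapply(arch$layers, function(l) {
    data.frame(name = l$name, kind = l$kind, input = l$input,
               kernel = l$kernel, stride = l$stride, dilation = l$dilation,
               effective_kernel = effective_kernel(l$kernel, l$dilation),
               in_channels = l$in_channels, out_channels = l$out_channels,
               row.names = NULL)
  }))
}

#' @export
print.dfcn_arch <- function(x, ...) {
  cat(sprintf("<dfcn_arch> %s: %d classes, width x%s\n", x$variant,
              x$n_classes, format(x$width_multiplier)))
  cat(sprintf("  output stride %d, receptive field %d px, %d layers\n",
              output_stride(x), receptive_field(x), length(x$layers)))
  invisible(x)
}

# Dilation sequence of the backbone blocks (block1..block5, fc-convs), used
# for bookkeeping checks; takes the dilation of the last conv of each block.
backbone_dilations <- function(arch) {
  picks <- c("conv1_2", "conv2_2", "conv3_3", "conv4_3", "conv5_3", "fc6")
  vapply(picks, function(nm) arch$layers[[nm]]$dilation, integer(1))
}
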