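#' @name engine
#' @title CPU forward/backward engine
#' @description
#' Networks are evaluated on the CPU with im2col + BLAS convolution kernels.
#' Two numeric precisions are supported: `"double"` (default for inference
#' and all equivalence checks) and `"single"` (float32, the training fast
#' path).  Both are deterministic for a fixed parameter set and input.
NULL

conv_pad <- function(k, d) as.integer(d * (k - 1L) / 2L)

# Separable bilinear interpolation kernel for an upsampling factor f
# (length 2f); the factor-2 kernel is (0.25, 0.75, 0.75, 0.25).
bilinear_kernel <- function(factor) {
  i <- seq_len(2L * factor) - 1L
  1 - abs(i + 0.5 - factor) / factor
}

init_layer_params <- function(l) {
  if (l$kind == "conv") {
    n <- l$kernel * l$kernel * l$in_channels * l$out_channels
    w <- if (l$zero_init) rep(0, n) else {
      rnorm(n, sd = sqrt(2 / (l$kernel * l$kernel * l$in_channels)))
    }
    dim(w) <- c(l$kernel, l$kernel, l$in_channels, l$out_channels)
    list(w = w, b = rep(0, l$out_channels))
  } else if (l$kind == "upsample") {
    v <- bilinear_kernel(l$factor)
    w <- array(0, dim = c(l$kernel, l$kernel, l$out_channels, l$in_channels))
    for (c in seq_len(min(l$in_channels, l$out_channels))) {
      w[, , c, c] <- outer(v, v)
    }
    list(w = w, b = rep(0, l$out_channels))
  } else {
    NULL
  }
}

#' Instantiate a network from an architecture
#'
#' Parameter shapes are fully determined by the architecture; values are
#' deterministic given `(arch, seed)`.  Convolutions use fan-in-scaled
#' He-normal initialization, score layers are zero-initialized, and
#' upsampling layers start as exact bilinear interpolation kernels.
#'
#' @param arch a `dfcn_arch` from [build_arch()]
#' @param seed integer controlling the weight draws
#' @return a `dfcn_network` (architecture + per-layer parameter arrays)
#' @export
init_network <- function(arch, seed = 0L) {
  stopifnot(inherits(arch, "dfcn_arch"))
  params <- with_seed(seed, {
    p <- lapply(arch$layers, init_layer_params)
    p[!vapply(p, is.null, logical(1))]
  })
  structure(list(arch = arch, params = params, init_seed = as.integer(seed)),
            class = "dfcn_network")
}

#' @export
print.dfcn_network <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$w) + length(p$b),
                      numeric(1)))
  cat(sprintf("<dfcn_network> %s, %s parameters (init seed %d)\n",
              x$arch$variant, format(n_par, big.mark = ","), x$init_seed))
  invisible(x)
}

#' Copy parameters between networks by layer name
#'
#' Every parameter array in `dst` whose layer name and shape match one in
#' `src` is overwritten with the `src` values.  Used to share a backbone
#' between an FCN 32s and its dilated conversions (the layer names and
#' parameter shapes are unchanged by [convert_to_dfcn()]), and as the hook
#' for loading externally supplied backbone weights.
#'
#' @param src,dst `dfcn_network` objects
#' @return `dst` with the matching parameters replaced
#' @export
copy_matching_weights <- function(src, dst) {
  stopifnot(inherits(src, "dfcn_network"), inherits(dst, "dfcn_network"))
  for (nm in names(dst$params)) {
    sp <- src$params[[nm]]
    if (!is.null(sp) && identical(dim(sp$w), dim(dst$params[[nm]]$w))) {
      dst$params[[nm]] <- sp
    }
  }
  dst
}

# Name of the score activation at the network's output stride (the input of
# the final upsampling chain).
score_layer_name <- function(arch) {
  switch(arch$variant,
         fcn16s = "fuse_pool4",
         fcn8s = "fuse_pool3",
         "score_fr")
}

# Layers that participate in the decoder after the score map (per variant).
prepare_input <- function(net, x, pad) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != net$arch$window$n_channels) {
      stop_dfcn("forward: 3-d input must have one plane per window channel")
    }
    stack <- x
  } else {
    stack <- window_transform(as.matrix(x), net$arch$window)
  }
  H <- dim(stack)[1]; W <- dim(stack)[2]
  ph <- (32L - H %% 32L) %% 32L
  pw <- (32L - W %% 32L) %% 32L
  if ((ph > 0L || pw > 0L) && !pad) {
    stop_dfcn(sprintf(
      "forward: input %dx%d is not divisible by 32; enable pad = TRUE", H, W))
  }
  if (ph > 0L || pw > 0L) {
    big <- array(0, dim = c(H + ph, W + pw, dim(stack)[3]))
    big[seq_len(H), seq_len(W), ] <- stack
    stack <- big
  }
  list(stack = stack, H = H, W = W)
}

run_forward <- function(net, stack, precision, keep_acts = FALSE,
                        stop_at = NULL) {
  single <- identical(precision, "single")
  acts <- new.env(parent = emptyenv())
  idxs <- new.env(parent = emptyenv())
  assign("input", stack, envir = acts)
  for (l in net$arch$layers) {
    x_in <- get(l$input, envir = acts)
    y <- switch(l$kind,
      conv = cpp_conv_fwd(x_in, net$params[[l$name]]$w,
                          net$params[[l$name]]$b, l$stride, l$dilation,
                          conv_pad(l$kernel, l$dilation),
                          identical(l$activation, "relu"), single),
      pool = {
        r <- cpp_maxpool_fwd(x_in, l$kernel, l$stride, l$dilation)
        assign(l$name, r$idx, envir = idxs)
        r$y
      },
      upsample = cpp_tconv_fwd(x_in, net$params[[l$name]]$w,
                               net$params[[l$name]]$b, l$stride,
                               l$factor %/% 2L, single),
      fuse = x_in + get(l$aux, envir = acts),
      stop_dfcn("forward: unknown layer kind ", l$kind))
    assign(l$name, y, envir = acts)
    if (!is.null(stop_at) && identical(l$name, stop_at)) break
  }
  out <- get(if (is.null(stop_at)) net$arch$output else stop_at, envir = acts)
  if (keep_acts) list(out = out, acts = acts, idxs = idxs) else out
}

#' Forward evaluation
#'
#' Runs the network on one axial slice.  A plain H x W matrix is interpreted
#' as Hounsfield units and passed through the window-adjustment input layer;
#' an H x W x C array is taken as an already windowed stack.  Spatial
#' dimensions must be divisible by 32 unless `pad = TRUE`, in which case the
#' input is zero-padded (air) on the bottom/right and the output cropped
#' back.
#'
#' @param net a `dfcn_network`
#' @param x H x W HU matrix or H x W x C windowed array
#' @param upsample if `FALSE`, return the score map at the network's output
#'   stride (before the final upsampling chain) instead of at input
#'   resolution
#' @param precision `"double"` (default) or `"single"` (float32 fast path)
#' @param pad zero-pad inputs not divisible by 32
#' @return numeric array of class score maps: H x W x n_classes when
#'   `upsample = TRUE`, else (H/os) x (W/os) x n_classes
#' @export
forward <- function(net, x, upsample = TRUE, precision = c("double", "single"),
                    pad = FALSE) {
  stopifnot(inherits(net, "dfcn_network"))
  precision <- match.arg(precision)
  pin <- prepare_input(net, x, pad)
  stop_at <- if (upsample) NULL else score_layer_name(net$arch)
  out <- run_forward(net, pin$stack, precision, stop_at = stop_at)
  if (upsample && (dim(out)[1] != pin$H || dim(out)[2] != pin$W)) {
    out <- out[seq_len(pin$H), seq_len(pin$W), , drop = FALSE]
  }
  out
}

# Backpropagate grad_out (at the final output) through cached activations.
# Returns list(grads = per-layer list(w, b), ...); the input layer gets no
# gradient (the window layer is fixed).
run_backward <- function(net, fw, grad_out, precision) {
  single <- identical(precision, "single")
  gacc <- new.env(parent = emptyenv())
  assign(net$arch$output, grad_out, envir = gacc)
  grads <- list()
  for (l in rev(net$arch$layers)) {
    if (!exists(l$name, envir = gacc)) next
    g <- get(l$name, envir = gacc)
    push <- function(nm, gi) {
      if (identical(nm, "input")) return(invisible())
      if (exists(nm, envir = gacc)) {
        assign(nm, get(nm, envir = gacc) + gi, envir = gacc)
      } else {
        assign(nm, gi, envir = gacc)
      }
    }
    if (l$kind == "conv") {
      if (identical(l$activation, "relu")) {
        g <- g * (get(l$name, envir = fw$acts) > 0)
      }
      res <- cpp_conv_bwd(get(l$input, envir = fw$acts),
                          net$params[[l$name]]$w, g, l$stride, l$dilation,
                          conv_pad(l$kernel, l$dilation),
                          !identical(l$input, "input"), single)
      grads[[l$name]] <- list(w = res$gw, b = res$gb)
      if (!identical(l$input, "input")) push(l$input, res$gx)
    } else if (l$kind == "pool") {
      din <- dim(get(l$input, envir = fw$acts))
      push(l$input, cpp_maxpool_bwd(get(l$name, envir = fw$idxs), g,
                                    din[1], din[2], din[3]))
    } else if (l$kind == "upsample") {
      res <- cpp_tconv_bwd(get(l$input, envir = fw$acts),
                           net$params[[l$name]]$w, g, l$stride,
                           l$factor %/% 2L, single)
      grads[[l$name]] <- list(w = res$gw, b = res$gb)
      push(l$input, res$gz)
    } else if (l$kind == "fuse") {
      push(l$input, g)
      push(l$aux, g)
    }
  }
  grads
}

# One supervised sample: forward + per-pixel weighted softmax cross-entropy
# + backward.  labels: H x W integers in 0..n_classes-1.
network_loss_grad <- function(net, x, labels, class_weights, precision) {
  pin <- prepare_input(net, x, pad = FALSE)
  fw <- run_forward(net, pin$stack, precision, keep_acts = TRUE)
  lab <- as.integer(labels)
  dim(lab) <- dim(labels)
  sm <- cpp_softmax_xent(fw$out, lab, class_weights)
  grads <- run_backward(net, fw, sm$grad, precision)
  list(loss = sm$loss, grads = grads)
}

#' Decode score maps into a label mask
#'
#' Per-pixel argmax over the class score maps; ties break toward the lowest
#' class index, so an all-zero score map decodes to all-background.
#'
#' @param scores H x W x C numeric array
#' @return H x W integer matrix of class ids `0..C-1`
#' @export
predict_labels <- function(scores) {
  d <- dim(scores)
  if (length(d) != 3L) stop_dfcn("predict_labels: scores must be H x W x C")
  m <- matrix(scores, nrow = d[1] * d[2], ncol = d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Segment one slice
#'
#' Convenience wrapper: [forward()] then [predict_labels()].
#'
#' @inheritParams forward
#' @return H x W integer label mask
#' @export
predict_mask <- function(net, x, precision = "double", pad = FALSE) {
  predict_labels(forward(net, x, precision = precision, pad = pad))
}
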