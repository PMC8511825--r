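#' Hounsfield-unit window specification
#'
#' Defines an HU range `[lo, hi]` that is tiled by `channels` equal-width
#' sub-windows, one per input channel of the network.  A CT display window is
#' conventionally described by its *level* (the HU value mapped to
#' mid-intensity) and its *width* (the HU span mapped onto the full intensity
#' range); [partition_window()] derives the per-channel (level, width) pairs.
#'
#' The default, `[-300, 600]` split into three parts, covers the soft-tissue
#' range of a chest CT: lung parenchyma (about -700 HU) saturates below it and
#' cortical bone (above 600 HU) saturates above it.
#'
#' @param lo,hi lower / upper HU bound, `lo < hi`
#' @param channels number of equal sub-windows (one per network input channel)
#' @return an object of class `window_spec`
#' @examples
#' ws <- window_spec(-300, 600, 3)
#' partition_window(ws)
#' @export
window_spec <- function(lo = -300, hi = 600, channels = 3L) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1 ||
      !is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop_dfcn("window_spec: need finite numeric bounds with lo < hi")
  }
  channels <- as.integer(channels)
  if (is.na(channels) || channels < 1L) {
    stop_dfcn("window_spec: channels must be a positive integer")
  }
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi),
                 n_channels = channels),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> [%g, %g] HU in %d equal sub-window(s)\n",
              x$lo, x$hi, x$n_channels))
  p <- partition_window(x)
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  channel %d: level %g HU, width %g HU\n",
                i, p$level[i], p$width[i]))
  }
  invisible(x)
}

#' Partition an HU window into per-channel (level, width) pairs
#'
#' Splits `[lo, hi]` into `n_channels` contiguous sub-ranges of equal width
#' `(hi - lo) / n_channels`; each sub-range becomes one display window whose
#' level is its midpoint.  Sub-ranges are ordered ascending.
#'
#' @param spec a [window_spec()]
#' @return data.frame with columns `level` and `width`, one row per channel
#' @export
partition_window <- function(spec) {
  if (!inherits(spec, "window_spec")) spec <- do.call(window_spec, as.list(spec))
  w <- (spec$hi - spec$lo) / spec$n_channels
  i <- seq_len(spec$n_channels)
  data.frame(level = spec$lo + (i - 0.5) * w, width = rep(w, spec$n_channels))
}

#' Apply one display window to an HU raster
#'
#' Linearly maps the HU interval `[level - width/2, level + width/2]` onto
#' `[0, 1]` and clamps (saturates) outside it:
#' `out = clamp((HU - level + width/2) / width, 0, 1)`.  The map is monotone
#' non-decreasing in HU.
#'
#' @param x numeric array of HU values (any shape)
#' @param level window level (HU mapped to 0.5)
#' @param width window width in HU, `> 0`
#' @return array of the same shape with values in `[0, 1]`
#' @export
apply_window <- function(x, level, width) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0) {
    stop_dfcn("apply_window: width must be a positive finite number")
  }
  out <- (x - (level - width / 2)) / width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Window-adjustment input transform
#'
#' Converts a single-channel HU slice into the multi-channel stack the
#' network consumes: channel `i` is [apply_window()] with the i-th
#' (level, width) pair of [partition_window()].  This is the "window
#' adjustment layer" -- the parameter-free first layer of every network
#' variant; it replaces the naive triplication of a grey-scale slice into a
#' faux RGB image by giving each channel its own HU window.
#'
#' @param x numeric matrix of HU values (H x W)
#' @param spec a [window_spec()]
#' @return numeric array H x W x n_channels with values in `[0, 1]`
#' @export
window_transform <- function(x, spec = window_spec()) {
  if (!inherits(spec, "window_spec")) stop_dfcn("window_transform: spec must be a window_spec")
  x <- as.matrix(x)
  p <- partition_window(spec)
  out <- array(0, dim = c(nrow(x), ncol(x), spec$n_channels))
  for (i in seq_len(spec$n_channels)) {
    out[, , i] <- apply_window(x, p$level[i], p$width[i])
  }
  out
}
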