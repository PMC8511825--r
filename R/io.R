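#' @name nifti-io
#' @title Minimal NIfTI-1 volume input/output
#' @description
#' Self-contained single-file NIfTI-1 (`.nii`, optionally gzipped `.nii.gz`)
#' reading and writing, covering what the package needs for clinical-style
#' interchange: 2-D/3-D volumes, uint8/int16/int32/float32/float64 data,
#' little-endian encoding, pixdim spacing in mm, and scl_slope/scl_inter
#' rescaling on read.  HU volumes are stored as int16 (HU are integral on
#' clinical scanners), masks as uint8; integer masks round-trip losslessly.
#' DICOM and DICOM-RT are deliberately unsupported; convert externally.
NULL

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)
NIFTI_BITS <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

write_nifti <- function(data, path, spacing = c(1, 1, 1), datatype = "int16") {
  d <- dim(data)
  if (is.null(d)) d <- length(data)
  if (length(d) > 3) stop_dfcn("write_nifti: only 2-D/3-D volumes supported")
  dims <- c(length(d), d, rep(1L, 7 - length(d)))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop_dfcn("write_nifti: unsupported datatype ", datatype)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                               # sizeof_hdr
  writeBin(raw(36), con)                    # data_type..dim_info (unused)
  wi(dims, 2)                               # dim[0..7]
  writeBin(raw(14), con)                    # intent_p1..intent_code
  wi(dt, 2)                                 # datatype
  wi(NIFTI_BITS[[as.character(dt)]], 2)     # bitpix
  wi(0L, 2)                                 # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))             # pixdim[0..7]
  wf(352)                                   # vox_offset
  wf(1); wf(0)                              # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con)          # slice_end, slice_code
  writeBin(as.raw(2L), con)                 # xyzt_units = mm
  wf(0); wf(0); wf(0)                       # cal_max, cal_min, slice_duration
  wf(0); wi(0L, 4); wi(0L, 4)               # toffset, glmax, glmin
  writeBin(raw(80 + 24), con)               # descrip, aux_file
  wi(0L, 2); wi(0L, 2)                      # qform_code, sform_code
  wf(rep(0, 6))                             # quatern b,c,d; qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))                # srow_x
  wf(c(0, spacing[2], 0, 0))                # srow_y
  wf(c(0, 0, spacing[3], 0))                # srow_z
  writeBin(raw(16), con)                    # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                     # magic terminator
  writeBin(raw(4), con)                     # no extensions
  v <- as.vector(data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    lim <- switch(datatype, uint8 = c(0, 255), int16 = c(-32768, 32767),
                  int32 = c(-2147483647, 2147483647))
    v <- pmin(pmax(round(v), lim[1]), lim[2])
    writeBin(as.integer(v), con,
             size = switch(datatype, uint8 = 1, int16 = 2, int32 = 4),
             endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = if (datatype == "float32") 4 else 8,
             endian = "little")
  }
  invisible(path)
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop_dfcn("read_nifti: no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop_dfcn("read_nifti: truncated header in ", path)
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (ri(0, 4) != 348L) {
    stop_dfcn("read_nifti: not a little-endian NIfTI-1 file: ", path)
  }
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  if (nd < 1 || nd > 3) stop_dfcn("read_nifti: only 1..3 dims supported")
  shape <- dims[2:(1 + nd)]
  dt <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  seek(con, vox_offset)
  n <- prod(shape)
  v <- switch(as.character(dt),
    `2` = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                  endian = "little"),
    `4` = readBin(con, "integer", n = n, size = 2, endian = "little"),
    `8` = readBin(con, "integer", n = n, size = 4, endian = "little"),
    `16` = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    `64` = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop_dfcn("read_nifti: unsupported datatype code ", dt))
  if (length(v) < n) stop_dfcn("read_nifti: truncated data in ", path)
  if (slope != 0 && !(slope == 1 && inter == 0)) v <- v * slope + inter
  arr <- array(v, dim = shape)
  list(data = arr, spacing = pixdim[2:(1 + nd)])
}

#' Read / write HU volumes and label masks
#'
#' `read_volume()`/`write_volume()` handle Hounsfield-unit rasters (stored
#' as int16); `read_mask()`/`write_mask()` handle integer label rasters
#' (stored as uint8, lossless round-trip).  Files are single-file NIfTI-1,
#' gzipped if the path ends in `.gz`; anisotropic pixel spacing is
#' preserved.
#'
#' @param path file path (`.nii` or `.nii.gz`)
#' @param data 2-D or 3-D numeric array (HU) or integer array (mask)
#' @param spacing voxel spacing in mm (recycled to length 3)
#' @return `read_*` return a list with `data` and `spacing`; `write_*`
#'   return the path invisibly
#' @export
read_volume <- function(path) read_nifti(path)

#' @rdname read_volume
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1)) {
  write_nifti(data, path, spacing, datatype = "int16")
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  out <- read_nifti(path)
  if (any(out$data != round(out$data)) || any(out$data < 0)) {
    stop_dfcn("read_mask: ", path, " does not contain non-negative integers")
  }
  out$data <- array(as.integer(out$data), dim = dim(out$data))
  out
}

#' @rdname read_volume
#' @export
write_mask <- function(data, path, spacing = c(1, 1, 1)) {
  if (any(data != round(data)) || any(data < 0) || any(data > 255)) {
    stop_dfcn("write_mask: mask values must be integers in 0..255")
  }
  write_nifti(data, path, spacing, datatype = "uint8")
}

#' Dataset manifest handling
#'
#' A manifest is a CSV with columns `case_id`, `image`, `mask` and an
#' optional `split` tag; one row per case.  `read_manifest()` checks that
#' case ids are unique and the referenced files exist.
#' `load_manifest_dataset()` reads every case into memory as a list of
#' per-slice HU matrices and mask matrices, validating that image and mask
#' shapes agree.
#'
#' @param path manifest CSV path
#' @return `read_manifest()`: the manifest data.frame;
#'   `load_manifest_dataset()`: list of cases, each with `case_id`,
#'   `slices`, `masks`, `spacing`
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_dfcn("read_manifest: no such file: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "image", "mask")
  if (!all(need %in% names(m))) {
    stop_dfcn("read_manifest: manifest needs columns ",
              paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$case_id)) stop_dfcn("read_manifest: duplicate case ids")
  base <- dirname(path)
  for (col in c("image", "mask")) {
    m[[col]] <- ifelse(file.exists(m[[col]]), m[[col]],
                       file.path(base, basename(m[[col]])))
    missing <- !file.exists(m[[col]])
    if (any(missing)) {
      stop_dfcn("read_manifest: missing ", col, " file(s): ",
                paste(m[[col]][missing], collapse = ", "))
    }
  }
  m
}

#' @rdname read_manifest
#' @param manifest manifest data.frame (or path to one)
#' @export
load_manifest_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_volume(manifest$image[i])
    msk <- read_mask(manifest$mask[i])
    if (!identical(dim(img$data)[1:2], dim(msk$data)[1:2]) ||
        !identical(dim(img$data), dim(msk$data))) {
      stop_dfcn("load_manifest_dataset: image/mask shape mismatch for case ",
                manifest$case_id[i])
    }
    ns <- if (length(dim(img$data)) == 3) dim(img$data)[3] else 1L
    sl <- function(a, s) if (length(dim(a)) == 3) a[, , s] else a
    list(case_id = manifest$case_id[i],
         slices = lapply(seq_len(ns), function(s) sl(img$data, s)),
         masks = lapply(seq_len(ns), function(s) {
           m <- sl(msk$data, s); storage.mode(m) <- "integer"; m
         }),
         spacing = img$spacing)
  })
}
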