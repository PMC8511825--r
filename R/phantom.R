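#' @name phantom
#' @title Synthetic thoracic CT phantom
#' @description
#' Generates paired (HU slice, label mask) axial chest phantoms: an
#' elliptical soft-tissue body containing two air-filled lungs, a heart
#' between them, a tracheal lumen that splits into two bronchi on inferior
#' slices, an esophagus posterior to the trachea, and a high-attenuation
#' vertebra ring enclosing the spinal cord.  Structures are rasterized with
#' the priority order cord > trachea > esophagus > heart > lungs > body, so
#' label masks never overlap; Hounsfield units are drawn per pixel from
#' per-structure Gaussians plus global Gaussian noise.  Organ centers follow
#' smooth per-case trajectories across slices so per-case 3-D Dice pooling
#' is meaningful.  All geometry is jittered per case, deterministically in
#' the case seed.
NULL

#' Structure table of the default phantom
#'
#' Class ids follow the reporting order left lung, right lung, heart,
#' esophagus, trachea, spinal cord (1..6; 0 is background, which includes
#' body soft tissue, vertebra and outside air).
#'
#' @return data.frame with columns `structure`, `class_id`, `hu_mean`, `hu_sd`
#' @export
phantom_structures <- function() {
  data.frame(
    structure = c("lung_l", "lung_r", "heart", "esophagus", "trachea", "cord"),
    class_id = 1:6,
    hu_mean = c(-700, -700, 45, 40, -950, 35),
    hu_sd = c(60, 60, 15, 15, 30, 10))
}

#' Phantom generation configuration
#'
#' @param image_size integer (H, W) in pixels; the defaults (96 for tests,
#'   256 for demos) are multiples of 32 as the networks require
#' @param pixel_spacing in-plane spacing in mm/pixel (scalar or length 2)
#' @param organs structure table as in [phantom_structures()] (class ids
#'   must be unique and positive)
#' @param body_hu,body_sd soft-tissue HU statistics of the body ellipse
#' @param vertebra_hu,vertebra_sd HU statistics of the vertebral ring
#'   (background class, above the default display window)
#' @param background_hu HU of air outside the body
#' @param noise_sigma global additive Gaussian noise, HU
#' @param slices_per_case inclusive integer range (min, max) of axial slices
#'   drawn per case
#' @param jitter relative geometric jitter of organ centers/axes per case
#' @return a `phantom_config`
#' @export
phantom_config <- function(image_size = c(96L, 96L), pixel_spacing = 3.5,
                           organs = phantom_structures(),
                           body_hu = 40, body_sd = 15,
                           vertebra_hu = 400, vertebra_sd = 100,
                           background_hu = -1000, noise_sigma = 10,
                           slices_per_case = c(4L, 8L), jitter = 0.02) {
  image_size <- as.integer(rep(image_size, length.out = 2))
  if (any(image_size < 32L)) stop_dfcn("phantom_config: image_size must be >= 32")
  if (anyDuplicated(organs$class_id) || any(organs$class_id < 1)) {
    stop_dfcn("phantom_config: class ids must be unique positive integers")
  }
  slices_per_case <- as.integer(rep(slices_per_case, length.out = 2))
  if (slices_per_case[1] < 1L || slices_per_case[2] < slices_per_case[1]) {
    stop_dfcn("phantom_config: invalid slices_per_case range")
  }
  structure(list(image_size = image_size,
                 pixel_spacing = rep(as.numeric(pixel_spacing), length.out = 2),
                 organs = organs, body_hu = body_hu, body_sd = body_sd,
                 vertebra_hu = vertebra_hu, vertebra_sd = vertebra_sd,
                 background_hu = background_hu, noise_sigma = noise_sigma,
                 slices_per_case = slices_per_case, jitter = jitter),
            class = "phantom_config")
}

# Indicator of a rotated ellipse over the pixel-center grid (relative coords).
ellipse_mask <- function(H, W, cy, cx, ry, rx, theta = 0) {
  y <- (seq_len(H) - 0.5) / H
  x <- (seq_len(W) - 0.5) / W
  Y <- matrix(y, H, W) - cy
  X <- matrix(x, H, W, byrow = TRUE) - cx
  u <- cos(theta) * Y + sin(theta) * X
  v <- -sin(theta) * Y + cos(theta) * X
  (u / ry)^2 + (v / rx)^2 <= 1
}

# Per-case geometry draw (relative units). Row axis runs anterior (top) to
# posterior (bottom); columns run patient-right to patient-left.
draw_case_geometry <- function(cfg) {
  j <- function(x) x + runif(length(x), -cfg$jitter, cfg$jitter)
  s <- function(x) x * runif(length(x), 0.92, 1.08)
  list(
    body = list(c = j(c(0.50, 0.50)), r = s(c(0.40, 0.45)),
                th = runif(1, -0.08, 0.08)),
    lung_l = list(c = j(c(0.46, 0.70)), r = s(c(0.24, 0.13)),
                  th = runif(1, -0.15, 0.05)),
    lung_r = list(c = j(c(0.46, 0.30)), r = s(c(0.24, 0.13)),
                  th = runif(1, -0.05, 0.15)),
    heart = list(c = j(c(0.58, 0.52)), r = s(c(0.115, 0.125)),
                 th = runif(1, -0.2, 0.2)),
    trachea = list(c = j(c(0.38, 0.50)), r = s(c(0.033, 0.033))),
    esophagus = list(c = j(c(0.52, 0.515)), r = s(c(0.026, 0.026))),
    vertebra = list(c = j(c(0.80, 0.50)), r = s(c(0.065, 0.065))),
    cord = list(r = s(c(0.026, 0.026))),
    # smooth per-case drift of organ centers along the slice direction
    drift_amp = runif(2, 0, 0.015), drift_phase = runif(1, 0, 2 * pi),
    bronchi_split = runif(1, 0.45, 0.6))
}

rasterize_slice <- function(cfg, geo, z_frac) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  drift <- geo$drift_amp * sin(2 * pi * z_frac + geo$drift_phase)
  em <- function(g, scale = 1) {
    ellipse_mask(H, W, g$c[1] + drift[1], g$c[2] + drift[2],
                 g$r[1] * scale, g$r[2] * scale,
                 if (is.null(g$th)) 0 else g$th)
  }
  # lungs taper toward the ends of the scanned range
  taper <- 1 - 0.25 * (2 * z_frac - 1)^2
  body <- em(geo$body)
  lung_l <- em(geo$lung_l, taper) & body
  lung_r <- em(geo$lung_r, taper) & body
  heart <- em(geo$heart) & body
  eso <- em(geo$esophagus) & body
  vert <- em(geo$vertebra) & body
  cord <- ellipse_mask(H, W, geo$vertebra$c[1] + drift[1],
                       geo$vertebra$c[2] + drift[2],
                       geo$cord$r[1], geo$cord$r[2]) & body
  if (z_frac <= geo$bronchi_split) {
    trach <- em(geo$trachea)
  } else {
    g <- geo$trachea
    trach <- ellipse_mask(H, W, g$c[1] + drift[1], g$c[2] + drift[2] - 0.055,
                          g$r[1] * 0.8, g$r[2] * 0.8) |
             ellipse_mask(H, W, g$c[1] + drift[1], g$c[2] + drift[2] + 0.055,
                          g$r[1] * 0.8, g$r[2] * 0.8)
    trach <- trach & body
  }
  ids <- stats::setNames(cfg$organs$class_id, cfg$organs$structure)
  mask <- matrix(0L, H, W)
  mask[body] <- 0L
  mask[lung_l] <- ids[["lung_l"]]
  mask[lung_r] <- ids[["lung_r"]]
  mask[heart] <- ids[["heart"]]
  mask[eso] <- ids[["esophagus"]]
  mask[trach] <- ids[["trachea"]]
  mask[cord] <- ids[["cord"]]

  hu <- matrix(rnorm(H * W, cfg$background_hu, 5), H, W)
  fill <- function(region, mean, sd) {
    n <- sum(region)
    if (n > 0) hu[region] <<- rnorm(n, mean, sd)
  }
  fill(body, cfg$body_hu, cfg$body_sd)
  fill(vert, cfg$vertebra_hu, cfg$vertebra_sd)
  tab <- cfg$organs
  for (i in seq_len(nrow(tab))) {
    fill(mask == tab$class_id[i], tab$hu_mean[i], tab$hu_sd[i])
  }
  hu <- hu + rnorm(H * W, 0, cfg$noise_sigma)
  list(hu = hu, mask = mask)
}

check_case_geometry <- function(cfg, slices) {
  present <- Reduce(union, lapply(slices, function(s) unique(as.vector(s$mask))))
  missing <- setdiff(cfg$organs$class_id, present)
  if (length(missing) > 0) {
    return(sprintf("structure class(es) %s absent from every slice",
                   paste(missing, collapse = ", ")))
  }
  # tubular structures must keep a diameter of >= 2 pixels on every slice
  tubes <- cfg$organs$class_id[cfg$organs$structure %in%
                                 c("trachea", "esophagus", "cord")]
  for (s in slices) {
    for (cid in tubes) {
      if (sum(s$mask == cid) < 4) {
        return(sprintf("tubular structure %d thinner than 2 pixels", cid))
      }
    }
  }
  NULL
}

#' Generate one synthetic phantom case
#'
#' Deterministic in `(cfg, case_seed)`.  Geometry draws that violate the
#' construction constraints (every structure present, tubular structures at
#' least 2 pixels across) are retried a bounded number of times before
#' raising an error naming the violated constraint.
#'
#' @param cfg a [phantom_config()]
#' @param case_seed integer seed for this case
#' @param case_id optional case identifier (defaults to `case<seed>`)
#' @return a `phantom_case`: list with `case_id`, `slices` (list of H x W HU
#'   matrices), `masks` (list of H x W integer matrices), `spacing`, `seed`
#' @export
generate_phantom_case <- function(cfg, case_seed, case_id = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  case_seed <- as.integer(case_seed)
  if (is.null(case_id)) case_id <- sprintf("case%04d", case_seed)
  for (attempt in 0:19) {
    out <- with_seed(case_seed + 100000L * attempt, {
      geo <- draw_case_geometry(cfg)
      n_slices <- sample(seq(cfg$slices_per_case[1], cfg$slices_per_case[2]), 1)
      zf <- if (n_slices == 1) 0.5 else (seq_len(n_slices) - 1) / (n_slices - 1)
      lapply(zf, function(z) rasterize_slice(cfg, geo, z))
    })
    problem <- check_case_geometry(cfg, out)
    if (is.null(problem)) {
      return(structure(list(case_id = case_id,
                            slices = lapply(out, `[[`, "hu"),
                            masks = lapply(out, `[[`, "mask"),
                            spacing = cfg$pixel_spacing,
                            seed = case_seed),
                       class = "phantom_case"))
    }
  }
  stop_dfcn("generate_phantom_case: geometry constraint unsatisfiable after ",
            "20 retries: ", problem)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: %d slice(s) of %dx%d (seed %d)\n",
              x$case_id, length(x$slices), nrow(x$slices[[1]]),
              ncol(x$slices[[1]]), x$seed))
  invisible(x)
}

# Per-case seed derivation from the master seed (kept below 2^31).
derive_case_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Generate a phantom dataset
#'
#' Case seeds are derived from `master_seed` as
#' `(master_seed + 7919 * i) mod (2^31 - 1)` for case index `i`, so the
#' dataset is reproducible case by case.  With `out_dir` set, each case is
#' written as a NIfTI HU volume and mask volume plus a `manifest.csv`;
#' re-running overwrites the same files with identical bytes.
#'
#' @param cfg a [phantom_config()]
#' @param n_cases number of cases, `>= 1`
#' @param master_seed integer master seed
#' @param out_dir optional output directory; created if missing
#' @return invisibly, a list with `cases` (list of `phantom_case`, only when
#'   `out_dir` is `NULL`) and `manifest` (data.frame of case id, paths, seed)
#' @export
generate_phantom_dataset <- function(cfg, n_cases, master_seed = 1L,
                                     out_dir = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) {
    stop_dfcn("generate_phantom_dataset: n_cases must be >= 1")
  }
  rows <- list()
  cases <- vector("list", n_cases)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_len(n_cases)) {
    cid <- sprintf("case%03d", i)
    cs <- generate_phantom_case(cfg, derive_case_seed(master_seed, i), cid)
    if (is.null(out_dir)) {
      cases[[i]] <- cs
      rows[[i]] <- data.frame(case_id = cid, image = NA_character_,
                              mask = NA_character_, seed = cs$seed)
    } else {
      img <- file.path(out_dir, paste0(cid, "_ct.nii"))
      msk <- file.path(out_dir, paste0(cid, "_mask.nii"))
      write_volume(case_array(cs$slices), img, spacing = cfg$pixel_spacing)
      write_mask(case_array(cs$masks), msk, spacing = cfg$pixel_spacing)
      rows[[i]] <- data.frame(case_id = cid, image = img, mask = msk,
                              seed = cs$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(list(cases = if (is.null(out_dir)) cases else NULL,
                 manifest = manifest))
}

# Stack a list of H x W matrices into an H x W x S array.
case_array <- function(slices) {
  arr <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (s in seq_along(slices)) arr[, , s] <- slices[[s]]
  arr
}
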