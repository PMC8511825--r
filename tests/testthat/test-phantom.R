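test_that("phantom generation is deterministic in (config, seed)", {
  cfg <- phantom_config()
  a <- generate_phantom_case(cfg, 7)
  b <- generate_phantom_case(cfg, 7)
  expect_identical(a$slices, b$slices)
  expect_identical(a$masks, b$masks)
  c2 <- generate_phantom_case(cfg, 8)
  expect_false(identical(a$masks, c2$masks))
})

test_that("every configured structure appears and shapes are consistent", {
  cfg <- phantom_config()
  for (seed in c(1, 23, 99)) {
    cs <- generate_phantom_case(cfg, seed)
    expect_equal(length(cs$slices), length(cs$masks))
    expect_true(all(vapply(cs$slices, function(s)
      identical(dim(s), cfg$image_size), logical(1))))
    present <- Reduce(union, lapply(cs$masks, function(m) unique(as.vector(m))))
    expect_true(all(cfg$organs$class_id %in% present))
    expect_true(all(present %in% c(0L, cfg$organs$class_id)))
  }
})

test_that("per-structure HU statistics match the configured table", {
  # pool several cases: the tubular structures cover only tens of pixels per
  # slice, and the structure means are as close as 5 HU apart by design
  cfg <- phantom_config(image_size = c(128, 128))
  cases <- generate_phantom_dataset(cfg, 3, master_seed = 31)$cases
  hu <- unlist(lapply(cases, function(cs) dfcn:::case_array(cs$slices)))
  mask <- unlist(lapply(cases, function(cs) dfcn:::case_array(cs$masks)))
  tab <- cfg$organs
  for (i in seq_len(nrow(tab))) {
    v <- hu[mask == tab$class_id[i]]
    n <- length(v)
    expect_gt(n, 0)
    # sample mean within 3 standard errors (per-pixel sd + global noise)
    se <- sqrt(tab$hu_sd[i]^2 + cfg$noise_sigma^2) / sqrt(n)
    expect_lt(abs(mean(v) - tab$hu_mean[i]), 3 * se + 1e-9)
    # median HU closer to own configured mean than to any other structure's
    # (the two lungs share one mean, so compare distinct means only)
    others <- setdiff(tab$hu_mean[-i], tab$hu_mean[i])
    expect_true(all(abs(stats::median(v) - tab$hu_mean[i]) <
                      abs(stats::median(v) - others)))
  }
})

test_that("small structures stay rare, preserving the class imbalance", {
  cfg <- phantom_config()
  cs <- generate_phantom_case(cfg, 17)
  mask <- dfcn:::case_array(cs$masks)
  hu <- dfcn:::case_array(cs$slices)
  body_px <- sum(hu > -500)   # body approximated by non-air attenuation
  small <- sum(mask %in% cfg$organs$class_id[cfg$organs$structure %in%
                                               c("trachea", "esophagus", "cord")])
  expect_lt(small / body_px, 0.02)
})

test_that("windowing interacts with the phantom as designed", {
  cfg <- phantom_config()
  cs <- generate_phantom_case(cfg, 3)
  ws <- window_spec(-300, 600, 3)
  st <- window_transform(cs$slices[[1]], ws)
  m <- cs$masks[[1]]
  lungs <- m == 1L | m == 2L
  expect_gt(sum(lungs), 0)
  # lung parenchyma saturates the lowest window
  expect_lt(mean(st[, , 1][lungs]), 0.05)
  # soft tissue (heart) saturates channel 1 high and sits inside channel 2
  heart <- m == 3L
  expect_gt(mean(st[, , 1][heart]), 0.9)
  ch2 <- mean(st[, , 2][heart])
  expect_gt(ch2, 0.05)
  expect_lt(ch2, 0.5)
})

test_that("dataset generation is reproducible and sized correctly", {
  cfg <- phantom_config(image_size = c(64, 64), slices_per_case = c(2, 3))
  d1 <- generate_phantom_dataset(cfg, 3, master_seed = 1)
  d2 <- generate_phantom_dataset(cfg, 3, master_seed = 1)
  expect_identical(lapply(d1$cases, `[[`, "masks"),
                   lapply(d2$cases, `[[`, "masks"))
  expect_equal(nrow(d1$manifest), 3L)
  expect_error(generate_phantom_dataset(cfg, 0), "n_cases")

  # on-disk round trip: byte-identical re-run, readable manifest
  out1 <- file.path(tempdir(), "phantom_a")
  out2 <- file.path(tempdir(), "phantom_b")
  generate_phantom_dataset(cfg, 2, master_seed = 5, out_dir = out1)
  generate_phantom_dataset(cfg, 2, master_seed = 5, out_dir = out2)
  f1 <- list.files(out1, pattern = "\\.nii$")
  expect_length(f1, 4L)
  for (f in f1) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
  cases <- load_manifest_dataset(file.path(out1, "manifest.csv"))
  expect_length(cases, 2L)
  mem <- generate_phantom_dataset(cfg, 2, master_seed = 5)$cases
  expect_equal(cases[[1]]$masks, mem[[1]]$masks)
  # HU stored as int16: round trip within rounding precision
  expect_lt(max(abs(cases[[1]]$slices[[1]] - mem[[1]]$slices[[1]])), 0.5 + 1e-9)
})
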