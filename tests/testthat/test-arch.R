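VARIANTS <- c("fcn32s", "fcn16s", "fcn8s", "dfcn16s", "dfcn8s", "dfcn4s")

test_that("the six variants have the nominal output strides", {
  os <- vapply(VARIANTS, function(v) output_stride(build_arch(v, 7, 1 / 8)),
               integer(1))
  expect_equal(unname(os), c(32L, 16L, 8L, 16L, 8L, 4L))
})

test_that("receptive field is conserved by the dilated conversions", {
  rf <- vapply(VARIANTS, function(v) receptive_field(build_arch(v, 7, 1 / 8)),
               integer(1))
  expect_true(all(rf[c("dfcn16s", "dfcn8s", "dfcn4s")] == rf[["fcn32s"]]))
})

test_that("receptive field follows the layer recurrence on known stacks", {
  # single 3x3 conv -> 3; two stacked -> 5 (hand recurrence)
  a <- build_arch("fcn32s", 2, 1 / 16)
  a$layers <- a$layers["conv1_1"]
  expect_equal(receptive_field(structure(a, class = "dfcn_arch")), 3L)
  a2 <- build_arch("fcn32s", 2, 1 / 16)
  a2$layers <- a2$layers[c("conv1_1", "conv1_2")]
  expect_equal(receptive_field(structure(a2, class = "dfcn_arch")), 5L)
  # independent recurrence over the full backbone table
  tab <- arch_summary(build_arch("dfcn4s", 7, 1))
  tab <- tab[seq_len(which(tab$name == "score_fr")), ]
  rf <- 1; jump <- 1
  for (i in seq_len(nrow(tab))) {
    rf <- rf + (tab$effective_kernel[i] - 1) * jump
    jump <- jump * tab$stride[i]
  }
  expect_equal(receptive_field(build_arch("dfcn4s", 7, 1)), rf)
})

test_that("an arch with no strided layer has output stride 1", {
  a <- build_arch("fcn32s", 2, 1 / 16)
  a$layers <- a$layers[c("conv1_1", "conv1_2", "fc7", "score_fr")]
  a$layers$fc7$input <- "conv1_2"
  a$layers$fc7$in_channels <- a$layers$conv1_2$out_channels
  expect_equal(output_stride(structure(a, class = "dfcn_arch")), 1L)
})

test_that("dilation bookkeeping of the dilated variants is exact", {
  dil <- function(v) dfcn:::backbone_dilations(build_arch(v, 7, 1 / 8))
  expect_equal(unname(dil("dfcn4s")), c(1L, 1L, 1L, 2L, 4L, 8L))
  expect_equal(unname(dil("dfcn8s")), c(1L, 1L, 1L, 1L, 2L, 4L))
  expect_equal(unname(dil("dfcn16s")), c(1L, 1L, 1L, 1L, 1L, 2L))
  expect_equal(unname(dil("fcn32s")), rep(1L, 6))
  # converted pools: stride removed, dilation = accumulated factor
  a8 <- build_arch("dfcn8s", 7, 1 / 8)
  expect_equal(a8$layers$pool4[c("stride", "dilation")], list(stride = 1L, dilation = 1L))
  expect_equal(a8$layers$pool5[c("stride", "dilation")], list(stride = 1L, dilation = 2L))
  expect_equal(a8$layers$pool3[c("stride", "dilation")], list(stride = 2L, dilation = 1L))
})

test_that("build_fcn validates inputs and applies the width multiplier", {
  expect_error(build_fcn("fcn32s", n_classes = 1), "n_classes")
  expect_error(build_fcn("fcn32s", width_multiplier = 0), "width_multiplier")
  expect_error(build_arch("unet"), "arg")
  expect_error(convert_to_dfcn(build_arch("fcn16s"), 8), "fcn32s")
  expect_error(convert_to_dfcn(build_arch("fcn32s"), 12), "target_stride")

  a <- build_fcn("fcn32s", 7, 1 / 4)
  tab <- arch_summary(a)
  ch <- tab$out_channels[match(c("conv1_1", "conv2_1", "conv3_1", "conv4_1",
                                 "conv5_1", "fc6", "fc7"), tab$name)]
  expect_equal(ch, c(16L, 32L, 64L, 128L, 128L, 1024L, 1024L))
  expect_equal(tab$out_channels[tab$name == "score_fr"], 7L)
})

test_that("skip-fusion wiring matches the variant", {
  a32 <- build_arch("fcn32s", 7, 1 / 8)
  expect_false(any(vapply(a32$layers, function(l) l$kind == "fuse", logical(1))))
  a16 <- build_arch("fcn16s", 7, 1 / 8)
  expect_equal(a16$layers$fuse_pool4$aux, "score_pool4")
  expect_equal(a16$layers$score_pool4$input, "pool4")
  a8 <- build_arch("fcn8s", 7, 1 / 8)
  expect_setequal(names(Filter(function(l) l$kind == "fuse", a8$layers)),
                  c("fuse_pool4", "fuse_pool3"))
  # dilated variants carry no fusion; decoder factors multiply to the stride
  for (v in c("dfcn16s", "dfcn8s", "dfcn4s")) {
    a <- build_arch(v, 7, 1 / 8)
    expect_false(any(vapply(a$layers, function(l) l$kind == "fuse", logical(1))))
    ups <- Filter(function(l) l$kind == "upsample", a$layers)
    expect_equal(prod(vapply(ups, function(l) l$factor, integer(1))),
                 output_stride(a))
  }
})
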