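test_that("init_network is deterministic and follows the stated schemes", {
  arch <- tiny_arch("dfcn4s")
  n1 <- init_network(arch, 42)
  n2 <- init_network(arch, 42)
  expect_identical(n1$params, n2$params)
  n3 <- init_network(arch, 43)
  expect_false(identical(n1$params, n3$params))

  # score layer zero-initialized
  expect_true(all(n1$params$score_fr$w == 0))
  # upsampling starts as the closed-form bilinear kernel
  expect_equal(dfcn:::bilinear_kernel(2), c(0.25, 0.75, 0.75, 0.25))
  v <- dfcn:::bilinear_kernel(2)
  expect_equal(n1$params$up1$w[, , 1, 1], outer(v, v))
  expect_true(all(n1$params$up1$w[, , 1, 2] == 0))
  # parameter shapes are determined by the arch
  expect_equal(dim(n1$params$conv1_1$w),
               c(3L, 3L, 3L, arch$layers$conv1_1$out_channels))
})

test_that("forward obeys the shape contract and padding policy", {
  net <- init_network(tiny_arch("dfcn4s", n_classes = 5), 1)
  x <- random_hu(64)
  s <- forward(net, x)
  expect_equal(dim(s), c(64L, 64L, 5L))
  slow <- forward(net, x, upsample = FALSE)
  expect_equal(dim(slow), c(16L, 16L, 5L))  # output stride 4
  expect_error(forward(net, random_hu(60)), "divisible by 32")
  expect_equal(dim(forward(net, random_hu(60), pad = TRUE)), c(60L, 60L, 5L))
})

test_that("a bilinearly initialized upsampling layer interpolates exactly", {
  # factor-2 transposed conv with the bilinear kernel doubles a ramp
  net <- init_network(tiny_arch("dfcn4s", n_classes = 2), 1)
  z <- array(0, dim = c(6, 6, 2))
  z[, , 1] <- outer(seq_len(6), rep(1, 6))
  up <- dfcn:::cpp_tconv_fwd(z, net$params$up1$w, net$params$up1$b, 2L, 1L, FALSE)
  expect_equal(dim(up), c(12L, 12L, 2L))
  # interior of channel 1 is the linear interpolation of the ramp
  expect_equal(up[4, 6, 1], 2.25)   # between rows 2 and 3: 0.75*2 + 0.25*3
  expect_equal(up[5, 6, 1], 2.75)
  expect_true(all(up[, , 2] == 0))
})

test_that("constant input yields spatially constant interior responses", {
  # translation invariance of the (dilated) convolution and pool primitives:
  # away from the border margin, a constant input maps to a constant output
  set.seed(2)
  x <- array(0.7, dim = c(20, 20, 3))
  w <- array(stats::rnorm(3 * 3 * 3 * 5, sd = 0.2), c(3, 3, 3, 5))
  y <- dfcn:::cpp_conv_fwd(x, w, stats::rnorm(5), 1L, 2L, 2L, TRUE, FALSE)
  interior <- y[3:18, 3:18, , drop = FALSE]
  for (c in 1:5) expect_lt(diff(range(interior[, , c])), 1e-12)
  p <- dfcn:::cpp_maxpool_fwd(y, 2L, 2L, 1L)$y
  expect_lt(diff(range(p[2:9, 2:9, 1])), 1e-12)
})

test_that("predict_labels takes the argmax with background-favoring ties", {
  sc <- array(0, dim = c(1, 2, 2))
  sc[1, 1, ] <- c(0.1, 0.9)
  sc[1, 2, ] <- c(0.5, 0.5)
  expect_equal(predict_labels(sc), matrix(c(1L, 0L), 1, 2))
  expect_true(all(predict_labels(array(0, dim = c(4, 4, 3))) == 0L))
})

test_that("dilated variants reproduce fcn32s scores on the sub-grid", {
  base <- init_network(tiny_arch("fcn32s", n_classes = 4), 11)
  set.seed(12)
  x <- matrix(stats::rnorm(96 * 96, 0, 350), 96, 96)
  s32 <- forward(base, x, upsample = FALSE)
  for (v in c("dfcn16s", "dfcn8s", "dfcn4s")) {
    net <- copy_matching_weights(base, init_network(tiny_arch(v, 4), 11))
    sv <- forward(net, x, upsample = FALSE)
    sub <- 32L / output_stride(net$arch)
    ss <- sv[seq(1, dim(sv)[1], by = sub), seq(1, dim(sv)[2], by = sub), ,
             drop = FALSE]
    expect_lt(max(abs(ss - s32)), 1e-6)
  }
})

test_that("analytic gradients match finite differences", {
  arch <- tiny_arch("dfcn4s", n_classes = 3)
  net <- init_network(arch, 5)
  set.seed(6)
  net$params$score_fr$w[] <- stats::rnorm(length(net$params$score_fr$w),
                                          sd = 0.1)
  x <- random_hu(32, seed = 7)
  y <- random_mask(32, 32, k = 3, seed = 8)
  cw <- c(1, 2, 0.5)
  lg <- dfcn:::network_loss_grad(net, x, y, cw, "double")
  eps <- 1e-5
  set.seed(9)
  for (nm in c("conv2_1", "fc6", "up2")) {
    for (rep in 1:2) {
      i <- sample(length(net$params[[nm]]$w), 1)
      up <- net; up$params[[nm]]$w[i] <- up$params[[nm]]$w[i] + eps
      dn <- net; dn$params[[nm]]$w[i] <- dn$params[[nm]]$w[i] - eps
      gnum <- (dfcn:::network_loss_grad(up, x, y, cw, "double")$loss -
               dfcn:::network_loss_grad(dn, x, y, cw, "double")$loss) / (2 * eps)
      gana <- lg$grads[[nm]]$w[i]
      expect_equal(gana, gnum, tolerance = 1e-3)
    }
  }
})

test_that("single and double precision agree to float tolerance", {
  net <- init_network(tiny_arch("dfcn8s", n_classes = 3), 3)
  set.seed(4)
  net$params$score_fr$w[] <- stats::rnorm(length(net$params$score_fr$w),
                                          sd = 0.05)
  x <- random_hu(64, seed = 5)
  sd_ <- forward(net, x, precision = "double")
  ss_ <- forward(net, x, precision = "single")
  expect_lt(max(abs(sd_ - ss_)), 1e-4)
})
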