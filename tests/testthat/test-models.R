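test_that("model specs validate architecture constraints", {
  expect_error(model_spec("ResNet", kernel_edge = 4), "odd")
  expect_error(model_spec("ResNet", n_res_blocks = 0), ">= 1")
  expect_error(model_spec("cCNN", ccnn_channels = c(64, 32, 2)), "ending in 1")
  expect_error(model_spec("ResNet", input_edge = 1), ">=")
})

test_that("the plain CNN has three convolutions with the configured widths", {
  spec <- model_spec("cCNN")
  net <- build_ccnn(spec, seed = 1)
  sm <- model_summary(net)
  expect_equal(sm$n_conv_layers, 3L)
  widths <- vapply(net$layers, function(l) dim(l$W)[5], integer(1))
  expect_equal(unname(widths), c(64L, 32L, 1L))
  expect_true(all(vapply(net$layers, function(l) all(dim(l$W)[1:3] == 3L),
                         logical(1))))
  # shape contract: 21^3 single-channel in, 21^3 single-channel out
  x <- array(rnorm(21^3), dim = c(21, 21, 21, 1, 1))
  out <- voxsr:::net_forward(net, x)$out
  expect_identical(dim(out), c(21L, 21L, 21L, 1L, 1L))
})

test_that("the residual network matches its blueprint and global skip", {
  spec <- model_spec("ResNet")     # reference: 10 blocks, 64 channels
  net <- build_resnet(spec, seed = 1)
  sm <- model_summary(net)
  expect_equal(sm$n_res_blocks, 10L)
  # each block contributes exactly two convolutions
  blk <- grep("^block", names(net$layers), value = TRUE)
  expect_equal(length(blk), 20L)
  # zero-weight network is the identity map through the global skip
  small <- build_resnet(model_spec("ResNet", n_res_blocks = 2, channels = 4,
                                   input_edge = 7), seed = 1)
  for (nm in names(small$layers)) {
    small$layers[[nm]]$W[] <- 0
    small$layers[[nm]]$b[] <- 0
  }
  x <- array(rnorm(7^3), dim = c(7, 7, 7, 1, 1))
  expect_equal(voxsr:::net_forward(small, x)$out, x)
})

test_that("the GAN pairs a ResNet generator with a sigmoid discriminator", {
  spec <- model_spec("GAN", n_res_blocks = 2, channels = 4, input_edge = 7)
  nets <- build_gan(spec, seed = 2)
  gsum <- model_summary(nets$generator)
  rsum <- model_summary(build_resnet(spec, seed = 99))
  expect_identical(gsum$layer_names, rsum$layer_names)
  expect_identical(gsum$parameter_count, rsum$parameter_count)
  dsum <- model_summary(nets$discriminator)
  expect_equal(dsum$n_res_blocks, 2L)
  full <- build_gan(model_spec("GAN"), seed = 1)
  expect_equal(model_summary(full$discriminator)$n_res_blocks, 10L)
  # discriminator output strictly inside (0, 1) for arbitrary inputs
  for (s in 1:3) {
    x <- array(rnorm(7^3, sd = s), dim = c(7, 7, 7, 1, 1))
    p <- voxsr:::net_forward(nets$discriminator, x)$out
    expect_gt(p, 0); expect_lt(p, 1)
  }
})

test_that("all families are shape-preserving across patch sizes", {
  specR <- model_spec("ResNet", n_res_blocks = 1, channels = 3, input_edge = 5)
  netR <- build_resnet(specR, seed = 3)
  netC <- build_ccnn(model_spec("cCNN", ccnn_channels = c(4, 3, 1),
                                input_edge = 5), seed = 3)
  for (p in c(3L, 5L, 9L)) {
    x <- array(rnorm(p^3), dim = c(p, p, p, 1, 1))
    expect_identical(dim(voxsr:::net_forward(netR, x)$out), dim(x))
    expect_identical(dim(voxsr:::net_forward(netC, x)$out), dim(x))
  }
})

test_that("seeded initialization is reproducible bit for bit", {
  spec <- model_spec("ResNet", n_res_blocks = 2, channels = 4, input_edge = 7)
  expect_identical(build_resnet(spec, seed = 5)$layers,
                   build_resnet(spec, seed = 5)$layers)
  expect_false(identical(build_resnet(spec, seed = 5)$layers,
                         build_resnet(spec, seed = 6)$layers))
})

test_that("the convolution engine matches the definitional oracle", {
  set.seed(41)
  x <- array(rnorm(4^3 * 2 * 2), dim = c(4, 4, 4, 2, 2))
  W <- array(rnorm(27 * 2 * 3), dim = c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  expect_equal(voxsr:::.conv3d_forward(x, W, b, dim(x)),
               oracle_conv3d(x, W, b), tolerance = 1e-12)
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(42)
  spec <- model_spec("ResNet", n_res_blocks = 1, channels = 2, input_edge = 5)
  net <- build_resnet(spec, seed = 8)
  x <- array(rnorm(5^3), dim = c(5, 5, 5, 1, 1))
  tgt <- array(rnorm(5^3), dim = c(5, 5, 5, 1, 1))
  fwd <- voxsr:::net_forward(net, x, cache = TRUE)
  gy <- 2 * (fwd$out - tgt) / length(fwd$out)
  bk <- voxsr:::net_backward(net, fwd$cache, gy)
  lossf <- function(nt) mean((voxsr:::net_forward(nt, x)$out - tgt)^2)
  eps <- 1e-6
  for (nm in names(net$layers)) {
    for (i in c(1L, 7L)) {
      np <- net; np$layers[[nm]]$W[i] <- np$layers[[nm]]$W[i] + eps
      nm2 <- net; nm2$layers[[nm]]$W[i] <- nm2$layers[[nm]]$W[i] - eps
      num <- (lossf(np) - lossf(nm2)) / (2 * eps)
      expect_equal(bk$grads[[nm]]$W[i], num, tolerance = 1e-5)
    }
  }
})
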