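# Shared tiny fixture: patches from one small phantom pair.
tiny_patches <- function(n = 50L, seed = 51L, grid = 32L) {
  v <- generate_phantom(phantom_config(seed = seed, grid_size = grid))
  pair <- voxsr:::normalize_pair(make_lr_hr_pair(v, resample_plan(25, 50)))
  sample_patches(pair, p = 7, n = n, seed = seed)
}

tiny_spec <- model_spec("ResNet", n_res_blocks = 2, channels = 4,
                        input_edge = 7, scale_hint = "50->25um")

test_that("training config enforces its invariants", {
  expect_error(train_config(validation_fraction = 0.6), "0.5")
  expect_error(train_config(max_epochs = 10, early_stop_patience = 10),
               "below")
  expect_error(train_config(gan_adversarial_weight = -1), ">= 0")
})

test_that("training reduces the MSE and records a full history", {
  ps <- tiny_patches()
  tc <- train_config(max_epochs = 30, early_stop_patience = 10,
                     batch_size = 16, validation_fraction = 0.25, seed = 1)
  m <- train(build_resnet(tiny_spec, seed = 1), ps, tc)
  expect_s3_class(m, "voxsr_trained_model")
  expect_equal(nrow(m$history), m$stopped_epoch)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_true(all(is.finite(m$history$val_loss)))
})

test_that("a zero learning rate triggers early stopping within patience", {
  ps <- tiny_patches()
  tc <- train_config(learning_rate = 0, max_epochs = 50,
                     early_stop_patience = 5, batch_size = 16,
                     validation_fraction = 0.25, seed = 2)
  m <- train(build_resnet(tiny_spec, seed = 2), ps, tc)
  expect_lte(m$stopped_epoch, 6L)
})

test_that("the same seed reproduces identical final weights", {
  ps <- tiny_patches()
  tc <- train_config(max_epochs = 5, early_stop_patience = 3,
                     batch_size = 16, validation_fraction = 0.25, seed = 3)
  m1 <- train(build_resnet(tiny_spec, seed = 3), ps, tc)
  m2 <- train(build_resnet(tiny_spec, seed = 3), ps, tc)
  expect_identical(m1$network$layers, m2$network$layers)
})

test_that("training rejects degenerate inputs", {
  ps <- tiny_patches(n = 8)
  ps$targets <- NULL
  tc <- train_config(max_epochs = 3, early_stop_patience = 1, batch_size = 4,
                     validation_fraction = 0.25, seed = 1)
  expect_error(train(build_resnet(tiny_spec, seed = 1), ps, tc), "targets")
  ps2 <- tiny_patches(n = 4)
  expect_error(train(build_resnet(tiny_spec, seed = 1), ps2,
                     train_config(batch_size = 16, max_epochs = 3,
                                  early_stop_patience = 1, seed = 1)),
               "at least")
})

test_that("a GAN with zero adversarial weight reduces to MSE training", {
  ps <- tiny_patches()
  spec <- model_spec("GAN", n_res_blocks = 2, channels = 4, input_edge = 7)
  nets <- build_gan(spec, seed = 4)
  tc <- train_config(max_epochs = 4, early_stop_patience = 2, batch_size = 16,
                     validation_fraction = 0.25, seed = 4,
                     gan_adversarial_weight = 0)
  mg <- train_gan(nets$generator, nets$discriminator, ps, tc)
  mp <- train(build_resnet(spec, seed = 4), ps, tc)
  expect_identical(mg$network$layers, mp$network$layers)
})

test_that("adversarial training keeps discriminator scores in (0, 1)", {
  ps <- tiny_patches()
  spec <- model_spec("GAN", n_res_blocks = 2, channels = 4, input_edge = 7)
  nets <- build_gan(spec, seed = 5)
  tc <- train_config(max_epochs = 6, early_stop_patience = 3, batch_size = 16,
                     validation_fraction = 0.25, seed = 5,
                     gan_adversarial_weight = 1e-3)
  mg <- train_gan(nets$generator, nets$discriminator, ps, tc)
  expect_true(all(is.finite(mg$history$disc_loss)))
  # trained generator still improves over its start
  expect_lt(min(mg$history$val_loss), mg$history$val_loss[1] + 1e-12)
  p <- voxsr:::net_forward(mg$discriminator,
                           voxsr:::as_batch(ps$inputs[, , , 1:4]))$out
  expect_true(all(p > 0 & p < 1))
})

test_that("fine-tuning freezes everything but the declared tail layers", {
  ps <- tiny_patches()
  tc <- train_config(max_epochs = 6, early_stop_patience = 3, batch_size = 16,
                     validation_fraction = 0.25, seed = 6)
  base <- train(build_resnet(tiny_spec, seed = 6), ps, tc)
  ps_t <- tiny_patches(seed = 77)
  ft <- fine_tune(base, ps_t, 3, tc)
  nms <- names(base$network$layers)
  nl <- length(nms)
  frozen <- nms[seq_len(nl - 3L)]
  for (nm in frozen) {
    expect_identical(ft$network$layers[[nm]], base$network$layers[[nm]])
  }
  sm <- model_summary(ft$network)
  expect_equal(sum(!sm$trainable_flags), nl - 3L)
  expect_error(fine_tune(base, ps_t, nl + 1L, tc), "must be in")
})

test_that("fine-tuning every layer equals resumed training", {
  ps <- tiny_patches()
  tc <- train_config(max_epochs = 4, early_stop_patience = 2, batch_size = 16,
                     validation_fraction = 0.25, seed = 7)
  base <- train(build_resnet(tiny_spec, seed = 7), ps, tc)
  ps_t <- tiny_patches(seed = 78)
  ft_all <- fine_tune(base, ps_t, length(base$network$layers), tc)
  resumed <- train(base$network, ps_t, tc)
  expect_identical(ft_all$network$layers, resumed$network$layers)
})

test_that("whole-volume inference honours the identity network", {
  v <- generate_phantom(phantom_config(seed = 61, grid_size = 16))
  net <- build_resnet(tiny_spec, seed = 1)
  for (nm in names(net$layers)) {
    net$layers[[nm]]$W[] <- 0
    net$layers[[nm]]$b[] <- 0
  }
  model <- structure(list(network = net, spec = tiny_spec,
                          config = train_config(seed = 1),
                          history = data.frame(), stopped_epoch = 0L,
                          provenance = "test"),
                     class = "voxsr_trained_model")
  lr <- block_average(v, 2)           # 8^3 at 50 um
  sr <- apply_sr(model, lr, 2)
  cub <- cubic_upsample(lr, 2)
  expect_equal(sr$data, cub$data, tolerance = 1e-12)
  expect_identical(dim(sr), dim(v))
  expect_equal(sr$voxel_size_um, 25)
  # voxel-size mismatch with the training hint warns but proceeds
  lr_wrong <- lr; lr_wrong$voxel_size_um <- 100
  expect_warning(apply_sr(model, lr_wrong, 2), "resolution")
})

test_that("training-size growth does not hurt held-out accuracy", {
  # scaled-down analogue of the training-set size trend: more sampled
  # patches must not increase median held-out RMSE over seeds
  plan <- resample_plan(25, 50)
  meds <- sapply(c(60L, 300L), function(n_patch) {
    sapply(1:3, function(rep) {
      vtr <- generate_phantom(phantom_config(seed = 400 + rep, grid_size = 32))
      vte <- generate_phantom(phantom_config(seed = 500 + rep, grid_size = 32))
      pair <- voxsr:::normalize_pair(make_lr_hr_pair(vtr, plan))
      ps <- sample_patches(pair, p = 7, n = n_patch, seed = rep)
      tc <- train_config(max_epochs = 12, early_stop_patience = 6,
                         batch_size = 8, validation_fraction = 0.25,
                         seed = rep)
      m <- train(build_resnet(tiny_spec, seed = rep), ps, tc)
      trip <- voxsr:::test_triplet(vte, plan)
      voxsr:::eval_model(m, trip, plan)$rmse
    })
  })
  expect_lte(median(meds[, 2]), median(meds[, 1]))
})
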