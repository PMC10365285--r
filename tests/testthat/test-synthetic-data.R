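test_that("phantom generation is deterministic and in [0, 1]", {
  cfg <- phantom_config(seed = 1, grid_size = 32)
  v1 <- generate_phantom(cfg)
  v2 <- generate_phantom(cfg)
  expect_identical(v1$data, v2$data)
  expect_identical(v1$modality, "AF_like")
  expect_gte(min(v1$data), 0)
  expect_lte(max(v1$data), 1)
})

test_that("phantom config enforces its invariants", {
  expect_error(phantom_config(scale_lengths_um = c(100, 400)), "decreasing")
  expect_error(phantom_config(scale_lengths_um = c(400, 30)), "2 voxels")
  expect_error(phantom_config(target_cross_correlation = 1), "inside")
  expect_error(phantom_config(n_volumes = 0), ">= 1")
  # grid too small for the largest configured scale
  expect_error(generate_phantom(phantom_config(grid_size = 16,
                                               scale_lengths_um = c(1600, 100))),
               "too small")
})

test_that("phantoms carry genuine fine-scale structure", {
  cfg <- phantom_config(seed = 2, grid_size = 64, scale_lengths_um = c(400, 100))
  v <- generate_phantom(cfg)
  # radially averaged power above the Nyquist/4 band
  ps <- abs(fft(v$data - mean(v$data)))^2
  fr <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n / 2)
  d <- dim(v$data)
  rad <- sqrt(outer(outer(fr(d[1])^2, fr(d[2])^2, `+`), fr(d[3])^2, `+`))
  frac_high <- sum(ps[rad > 0.25]) / sum(ps[rad > 0])
  expect_gt(frac_high, 0.01)
  # coarsening such a phantom must lose information ...
  rt_multi <- rmse(cubic_upsample(block_average(v, 2), 2), v)
  expect_gt(rt_multi, 0.01)
  # ... while a single very coarse scale survives a factor-2 round trip
  cfg1 <- phantom_config(seed = 2, grid_size = 64, scale_lengths_um = 1600)
  v1 <- generate_phantom(cfg1)
  rt_single <- rmse(cubic_upsample(block_average(v1, 2), 2), v1)
  expect_lt(rt_single, 0.01)
  expect_lt(rt_single, rt_multi / 2)
})

test_that("derived modalities hit their target correlation", {
  af <- generate_phantom(phantom_config(seed = 3, grid_size = 32))
  t2 <- derive_modality(af, "T2w_like", 0.72, seed = 11)
  expect_identical(t2$modality, "T2w_like")
  r <- pearson_correlation(af, t2)$r
  expect_gte(r, 0.67); expect_lte(r, 0.77)
  fa <- derive_modality(af, "FA_like", -0.69, seed = 12)
  r2 <- pearson_correlation(af, fa)$r
  expect_gte(r2, -0.74); expect_lte(r2, -0.64)
  z <- derive_modality(af, "T2w_like", 0, seed = 13)
  expect_lt(abs(pearson_correlation(af, z)$r), 0.1)
  expect_error(derive_modality(af, "T2w_like", 1), "< 1")
  expect_error(derive_modality(t2, "FA_like", 0.5), "AF_like")
})

test_that("the FA-like contrast is not a pointwise function of the source", {
  af <- generate_phantom(phantom_config(seed = 4, grid_size = 32))
  fa <- derive_modality(af, "FA_like", -0.69, seed = 14)
  # a pointwise map would make FA nearly constant within narrow source bins
  s <- as.numeric(af$data); f <- as.numeric(fa$data)
  bin <- cut(s, quantile(s, seq(0, 1, 0.1)), include.lowest = TRUE)
  within_sd <- median(tapply(f, bin, sd))
  expect_gt(within_sd, 0.2 * sd(f))
})

test_that("dataset generation yields co-registered triples with a manifest", {
  cfg <- phantom_config(seed = 5, grid_size = 32, n_volumes = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds$volumes, 3)
  expect_equal(sum(lengths(ds$volumes)), 9)  # 9 volumes in total
  expect_length(ds$manifest$volumes, 3)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$manifest, ds2$manifest)
  # distinct phantoms differ
  expect_gt(rmse(ds$volumes[[1]]$AF_like, ds$volumes[[2]]$AF_like), 0)
  expect_gt(rmse(ds$volumes[[2]]$AF_like, ds$volumes[[3]]$AF_like), 0)
})

test_that("dataset export writes NIfTI volumes and refuses collisions", {
  cfg <- phantom_config(seed = 6, grid_size = 32, n_volumes = 1)
  dir <- file.path(tempdir(), "voxsr_ds_test")
  unlink(dir, recursive = TRUE)
  generate_dataset(cfg, out_dir = dir)
  files <- list.files(dir)
  expect_equal(sum(grepl("\\.nii\\.gz$", files)), 3)
  expect_error(generate_dataset(cfg, out_dir = dir), "overwrite")
  expect_silent(generate_dataset(cfg, out_dir = dir, overwrite = TRUE))
  unlink(dir, recursive = TRUE)
})
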