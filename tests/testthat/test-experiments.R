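# Micro-scale config: 2 seeds and a 3-epoch budget, just enough to exercise
# the harness logic (the scientific replicas run in the acceptance suite).
micro_cfg <- function(...) {
  args <- list(
    phantom = phantom_config(grid_size = 32L, scale_lengths_um = c(400, 100),
                             n_volumes = 3L),
    model_specs = list(
      ResNet = model_spec("ResNet", n_res_blocks = 1L, channels = 3L,
                          input_edge = 7L),
      cCNN = model_spec("cCNN", ccnn_channels = c(4L, 3L, 1L),
                        input_edge = 7L)),
    train = train_config(max_epochs = 3L, early_stop_patience = 2L,
                         batch_size = 8L, validation_fraction = 0.25),
    epochs_by_family = list(),
    n_seeds = 2L, n_train_volumes = 2L, n_test_volumes = 1L,
    n_patches = 48L, patch_edge = 7L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

test_that("the network comparison reports every method against cubic", {
  cfg <- micro_cfg()
  rep <- run_network_comparison(cfg)
  rows <- rep$rows
  # cubic baseline row present for every seed
  expect_equal(sum(rows$condition == "cubic"), cfg$n_seeds)
  expect_setequal(unique(rows$condition), c("cubic", "ResNet", "cCNN"))
  # improvement column follows its definition on identical test volumes
  for (s in unique(rows$seed)) {
    cub <- rows$rmse[rows$condition == "cubic" & rows$seed == s]
    for (mn in c("ResNet", "cCNN")) {
      r <- rows[rows$condition == mn & rows$seed == s, ]
      expect_equal(r$improvement_over_cubic, cub - r$rmse, tolerance = 1e-12)
    }
  }
  expect_named(rep$tests, c("ResNet_vs_cubic", "cCNN_vs_cubic",
                            "ResNet_vs_cCNN"))
})

test_that("experiment reports are deterministic given their config", {
  cfg <- micro_cfg(n_seeds = 1L)
  r1 <- run_network_comparison(cfg)
  r2 <- run_network_comparison(cfg)
  expect_identical(r1$rows, r2$rows)
})

test_that("resolution matching flags exactly one matched condition", {
  cfg <- micro_cfg(
    plans = list(resample_plan(25, 50), resample_plan(50, 100)),
    test_plan = resample_plan(50, 100))
  rep <- run_resolution_matching(cfg)
  rows <- rep$rows[rep$rows$condition != "cubic", ]
  per_seed <- split(rows, rows$seed)
  for (df in per_seed) expect_equal(sum(df$matched), 1L)
  expect_equal(unique(rows$condition[rows$matched]), "100->50um")
  expect_identical(rep$tests$anova_across_conditions$test_name,
                   "Welch's ANOVA")
  # a config whose plans do not contain the test pair is rejected
  bad <- micro_cfg(plans = list(resample_plan(25, 50), resample_plan(25, 75)),
                   test_plan = resample_plan(50, 100))
  expect_error(run_resolution_matching(bad), "match the test plan")
})

test_that("the transfer harness validates its preconditions", {
  cfg <- micro_cfg(transfer = list(source_modality = "AF_like",
                                   target_modality = "AF_like",
                                   n_target_volumes = 2L,
                                   n_trainable_tail_layers = 3L,
                                   finetune_epochs = 2L))
  expect_error(run_transfer(cfg), "must differ")
  cfg2 <- micro_cfg(transfer = list(source_modality = "AF_like",
                                    target_modality = "FA_like",
                                    n_target_volumes = 1L,
                                    n_trainable_tail_layers = 3L,
                                    finetune_epochs = 2L))
  expect_error(run_transfer(cfg2), ">= 2")
})

test_that("the transfer harness reports all five comparison arms", {
  cfg <- micro_cfg(n_seeds = 1L,
                   transfer = list(source_modality = "AF_like",
                                   target_modality = "FA_like",
                                   n_target_volumes = 2L,
                                   n_trainable_tail_layers = 2L,
                                   finetune_epochs = 2L,
                                   n_ft_patches = 48L,
                                   finetune_lr = 5e-4))
  rep <- run_transfer(cfg)
  expect_setequal(unique(rep$rows$condition),
                  c("cubic_FA", "direct_FA", "finetuned_FA",
                    "cubic_T2w", "direct_T2w"))
})

test_that("reports serialize to CSV with a provenance block", {
  cfg <- micro_cfg(n_seeds = 1L)
  rep <- run_network_comparison(cfg)
  dir <- file.path(tempdir(), "voxsr_report_test")
  unlink(dir, recursive = TRUE)
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "network_comparison.csv")))
  back <- utils::read.csv(file.path(dir, "network_comparison.csv"))
  expect_equal(nrow(back), nrow(rep$rows))
  unlink(dir, recursive = TRUE)
})
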