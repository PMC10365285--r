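#' Configure a seeded, scaled-down SR experiment
#'
#' Bundles everything the three study harnesses need: the phantom
#' generator settings, the resolution pairs, the network specifications, the
#' training regime, and the replication seeds.  Defaults are desk-scale
#' (small grids, 2-block / 8-channel networks, around 10^2 patches, tens of
#' epochs) so a full study runs in minutes on one CPU; the reference-scale
#' settings (10 blocks, 64 channels, 21-voxel patches, thousands of samples)
#' remain reachable through the same fields.
#'
#' @param phantom a [phantom_config()]; `n_volumes` must cover
#'   `n_train_volumes + n_test_volumes` (plus the transfer volumes for
#'   [run_transfer()]).
#' @param plans list of [resample_plan()]s (training resolution pairs).
#' @param test_plan the [resample_plan()] used for held-out evaluation.
#' @param model_specs named list of [model_spec()]s.
#' @param train train-config template ([train_config()]); its seed is
#'   re-derived per repetition.
#' @param n_seeds number of seeded repetitions.
#' @param n_train_volumes,n_test_volumes phantom split.
#' @param n_patches training patches sampled per repetition.
#' @param patch_edge training patch edge.
#' @param epochs_by_family named list of per-family epoch budgets overriding
#'   `train$max_epochs`; the plain CNN needs a much longer budget than the
#'   residual families because it must first learn the identity map that the
#'   ResNet's global skip provides for free.
#' @param transfer list with `source_modality`, `target_modality`,
#'   `n_target_volumes`, `n_trainable_tail_layers`, `finetune_epochs`,
#'   `n_ft_patches` and `finetune_lr` (a reduced step size, standard practice
#'   when adapting a converged network).
#' @return A `voxsr_experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(
                                grid_size = 48L,
                                scale_lengths_um = c(400, 100, 50),
                                n_volumes = 6L),
                              plans = list(resample_plan(25, 50)),
                              test_plan = plans[[1]],
                              model_specs = list(
                                ResNet = model_spec("ResNet", n_res_blocks = 2L,
                                                    channels = 8L,
                                                    input_edge = 7L),
                                cCNN = model_spec("cCNN",
                                                  ccnn_channels = c(8L, 4L, 1L),
                                                  input_edge = 7L)),
                              train = train_config(max_epochs = 150L,
                                                   early_stop_patience = 40L,
                                                   batch_size = 8L,
                                                   validation_fraction = 0.25),
                              epochs_by_family = list(cCNN = 150L,
                                                      ResNet = 30L,
                                                      GAN = 30L),
                              n_seeds = 5L,
                              n_train_volumes = 4L,
                              n_test_volumes = 2L,
                              n_patches = 400L,
                              patch_edge = 7L,
                              transfer = list(source_modality = "AF_like",
                                              target_modality = "FA_like",
                                              n_target_volumes = 6L,
                                              n_trainable_tail_layers = 3L,
                                              finetune_epochs = 40L,
                                              n_ft_patches = 600L,
                                              finetune_lr = 5e-4)) {
  for (pl in plans) {
    fc <- pl$source_voxel_um / phantom$voxel_size_um
    if (abs(fc - round(fc)) > 1e-9) {
      stopf("plan resolution %g um is not an integer multiple of the phantom voxel size",
            pl$source_voxel_um)
    }
  }
  structure(list(phantom = phantom, plans = plans, test_plan = test_plan,
                 model_specs = model_specs, train = train,
                 epochs_by_family = epochs_by_family,
                 n_seeds = as.integer(n_seeds),
                 n_train_volumes = as.integer(n_train_volumes),
                 n_test_volumes = as.integer(n_test_volumes),
                 n_patches = as.integer(n_patches),
                 patch_edge = as.integer(patch_edge),
                 transfer = transfer),
            class = "voxsr_experiment_config")
}

# Derived per-repetition seed, kept well inside 32-bit integer range.
#' @keywords internal
rep_seed <- function(base, rep) (as.integer(base) + 77003L * as.integer(rep)) %% 2000000011L

# Normalize a (lr_upsampled, hr) pair with the LR volume's [0,1] map, the
# same map apply_sr() inverts at inference time.
#' @keywords internal
normalize_pair <- function(pair) {
  nlr <- normalize_intensity(pair$lr_upsampled)
  nrm <- attr(nlr, "norm")
  rng <- nrm[["max"]] - nrm[["min"]]
  hr <- pair$hr
  hr$data <- if (rng > 0) (hr$data - nrm[["min"]]) / rng else hr$data * 0
  list(lr_upsampled = nlr, hr = hr)
}

# LR / HR / cubic-baseline triplet of a test volume under a plan.
#' @keywords internal
test_triplet <- function(v, plan) {
  f_hr <- as.integer(round(plan$source_voxel_um / v$voxel_size_um))
  hr <- block_average(v, f_hr)
  lr <- block_average(hr, plan$factor)
  cub <- cubic_upsample(lr, plan$factor)
  d <- dim(cub$data)
  hr$data <- hr$data[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  list(lr = lr, hr = hr, cubic = cub)
}

#' @keywords internal
scale_hint_of <- function(plan) {
  sprintf("%g->%gum", plan$target_voxel_um, plan$source_voxel_um)
}

#' @keywords internal
train_for_plan <- function(spec, volumes, plan, cfg, seed) {
  pairs <- lapply(volumes, function(v) normalize_pair(make_lr_hr_pair(v, plan)))
  ps <- sample_patches(pairs, p = cfg$patch_edge, n = cfg$n_patches, seed = seed)
  tc <- cfg$train; tc$seed <- seed
  ep <- cfg$epochs_by_family[[spec$family]]
  if (!is.null(ep)) {
    tc$max_epochs <- as.integer(ep)
    tc$early_stop_patience <- min(tc$early_stop_patience, tc$max_epochs - 1L)
  }
  spec$scale_hint <- scale_hint_of(plan)
  if (spec$family == "cCNN") {
    net <- build_ccnn(spec, seed = seed)
    train(net, ps, tc)
  } else if (spec$family == "GAN") {
    nets <- build_gan(spec, seed = seed)
    train_gan(nets$generator, nets$discriminator, ps, tc)
  } else {
    net <- build_resnet(spec, seed = seed)
    train(net, ps, tc)
  }
}

#' @keywords internal
eval_model <- function(model, trip, plan, with_decorr = FALSE) {
  sr <- suppressWarnings(apply_sr(model, trip$lr, plan$factor))
  d <- dim(trip$hr$data)
  sr$data <- sr$data[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  er <- if (with_decorr && min(d) >= 32) {
    effective_resolution(sr)$effective_resolution_um
  } else NA_real_
  list(rmse = rmse(sr, trip$hr), ssim = ssim(sr, trip$hr),
       effective_resolution = er)
}

#' @keywords internal
eval_cubic <- function(trip, with_decorr = FALSE) {
  d <- dim(trip$hr$data)
  er <- if (with_decorr && min(d) >= 32) {
    effective_resolution(trip$cubic)$effective_resolution_um
  } else NA_real_
  list(rmse = rmse(trip$cubic, trip$hr), ssim = ssim(trip$cubic, trip$hr),
       effective_resolution = er)
}

#' @keywords internal
new_report <- function(rows, tests, config, kind) {
  structure(list(rows = rows, tests = tests, config = config, kind = kind),
            class = "voxsr_report")
}

#' @export
print.voxsr_report <- function(x, ...) {
  cat(sprintf("<voxsr_report> %s: %d rows\n", x$kind, nrow(x$rows)))
  agg <- stats::aggregate(rmse ~ condition, data = x$rows, FUN = median)
  names(agg)[2] <- "median_rmse"
  print(agg, row.names = FALSE)
  for (tn in names(x$tests)) {
    tst <- x$tests[[tn]]
    cat(sprintf("  %s: %s statistic = %.3g, p = %.3g\n",
                tn, tst$test_name, tst$statistic, tst$p_value))
  }
  invisible(x)
}

#' Write an experiment report as CSV plus a YAML provenance block
#'
#' @param report a `voxsr_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$rows, file.path(dir, paste0(report$kind, ".csv")),
                   row.names = FALSE)
  prov <- list(kind = report$kind,
               phantom = unclass(report$config$phantom),
               n_seeds = report$config$n_seeds,
               tests = lapply(report$tests, function(t) {
                 list(test = t$test_name, statistic = t$statistic,
                      p = t$p_value)
               }))
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(prov, file.path(dir, paste0(report$kind, "_provenance.yaml")))
  }
  invisible(dir)
}

# Generate the phantoms of one repetition and split train/test.  The
# single-modality studies only need the structural volumes, so companion
# contrasts are derived only when `af_only` is FALSE.
#' @keywords internal
rep_phantoms <- function(cfg, rep, n_extra = 0L, af_only = FALSE) {
  ph <- cfg$phantom
  ph$n_volumes <- cfg$n_train_volumes + cfg$n_test_volumes + n_extra
  ph$seed <- rep_seed(ph$seed, rep)
  if (!af_only) return(generate_dataset(ph))
  seeds <- with_seed(ph$seed,
                     sample.int(.Machine$integer.max %/% 2L, 3L * ph$n_volumes))
  vols <- lapply(seq_len(ph$n_volumes), function(i) {
    af <- generate_phantom(ph, seed = seeds[3L * i - 2L],
                           id = sprintf("phantom%03d", i))
    list(AF_like = af)
  })
  list(volumes = vols,
       manifest = list(config = unclass(ph),
                       volumes = lapply(seq_len(ph$n_volumes), function(i)
                         list(id = sprintf("phantom%03d", i),
                              seeds = seeds[3L * i - 2L]))))
}

#' Compare SR network families at matched resolution
#'
#' A scaled-down replica of the network-family study: for each seeded
#' repetition, all configured families are trained on identical patches from
#' shared phantoms and evaluated on a held-out phantom against the cubic
#' interpolation baseline; paired t-tests compare each method with cubic and
#' the methods with each other across repetitions.
#'
#' @param cfg an [experiment_config()] with at least 2 model specs.
#' @return A `voxsr_report`; `rows` has one row per (condition, seed) with
#'   `rmse`, `ssim` and `improvement_over_cubic` (= cubic RMSE minus method
#'   RMSE on the same test volumes, positive = method better).
#' @export
run_network_comparison <- function(cfg) {
  if (length(cfg$model_specs) < 2L) stopf("need at least 2 model specs")
  plan <- cfg$test_plan
  rows <- NULL
  per_method <- list()
  for (rep in seq_len(cfg$n_seeds)) {
    ds <- rep_phantoms(cfg, rep, af_only = TRUE)
    vols <- lapply(ds$volumes, `[[`, "AF_like")
    train_vols <- vols[seq_len(cfg$n_train_volumes)]
    test_vols <- vols[cfg$n_train_volumes + seq_len(cfg$n_test_volumes)]
    trips <- lapply(test_vols, test_triplet, plan = plan)
    sseed <- rep_seed(cfg$train$seed, rep)
    cub <- lapply(trips, eval_cubic, with_decorr = TRUE)
    cub_rmse <- mean(vapply(cub, `[[`, numeric(1), "rmse"))
    rows <- rbind(rows, data.frame(
      condition = "cubic", seed = rep,
      rmse = cub_rmse, ssim = mean(vapply(cub, `[[`, numeric(1), "ssim")),
      effective_resolution = mean(vapply(cub, `[[`, numeric(1),
                                         "effective_resolution")),
      improvement_over_cubic = 0))
    per_method$cubic <- c(per_method$cubic, cub_rmse)
    for (mn in names(cfg$model_specs)) {
      model <- train_for_plan(cfg$model_specs[[mn]], train_vols, plan, cfg,
                              sseed)
      ev <- lapply(trips, eval_model, model = model, plan = plan,
                   with_decorr = TRUE)
      mr <- mean(vapply(ev, `[[`, numeric(1), "rmse"))
      rows <- rbind(rows, data.frame(
        condition = mn, seed = rep,
        rmse = mr, ssim = mean(vapply(ev, `[[`, numeric(1), "ssim")),
        effective_resolution = mean(vapply(ev, `[[`, numeric(1),
                                           "effective_resolution")),
        improvement_over_cubic = cub_rmse - mr))
      per_method[[mn]] <- c(per_method[[mn]], mr)
    }
  }
  tests <- list()
  if (cfg$n_seeds >= 2L) {
    for (mn in names(cfg$model_specs)) {
      tests[[paste0(mn, "_vs_cubic")]] <-
        paired_ttest(per_method$cubic, per_method[[mn]])
    }
    mns <- names(cfg$model_specs)
    for (i in seq_len(length(mns) - 1L)) {
      for (j in (i + 1L):length(mns)) {
        tests[[paste(mns[i], "vs", mns[j], sep = "_")]] <-
          paired_ttest(per_method[[mns[i]]], per_method[[mns[j]]])
      }
    }
  }
  new_report(rows, tests, cfg, "network_comparison")
}

#' Test whether training resolution must match the target resolution
#'
#' Trains one residual network per configured resolution pair and evaluates
#' all of them on one shared test set generated at `cfg$test_plan`; exactly
#' one pair must match the test plan and is flagged in the rows.  A Welch
#' ANOVA across conditions accompanies the per-seed results.
#'
#' @param cfg an [experiment_config()] whose `plans` contain the test plan.
#' @return A `voxsr_report` with a logical `matched` column.
#' @export
run_resolution_matching <- function(cfg) {
  if (length(cfg$plans) < 2L) stopf("need at least 2 resolution pairs")
  matched <- vapply(cfg$plans, function(pl) {
    pl$source_voxel_um == cfg$test_plan$source_voxel_um &&
      pl$target_voxel_um == cfg$test_plan$target_voxel_um
  }, logical(1))
  if (sum(matched) != 1L) {
    stopf("exactly one plan must match the test plan (found %d)", sum(matched))
  }
  spec <- cfg$model_specs[[which(vapply(cfg$model_specs, function(s)
    s$family == "ResNet", logical(1)))[1]]]
  if (is.null(spec)) stopf("a ResNet model spec is required")
  labels <- vapply(cfg$plans, scale_hint_of, character(1))
  rows <- NULL
  per_cond <- list()
  for (rep in seq_len(cfg$n_seeds)) {
    ds <- rep_phantoms(cfg, rep, af_only = TRUE)
    vols <- lapply(ds$volumes, `[[`, "AF_like")
    train_vols <- vols[seq_len(cfg$n_train_volumes)]
    test_vols <- vols[cfg$n_train_volumes + seq_len(cfg$n_test_volumes)]
    trips <- lapply(test_vols, test_triplet, plan = cfg$test_plan)
    sseed <- rep_seed(cfg$train$seed, rep)
    cub <- lapply(trips, eval_cubic, with_decorr = TRUE)
    cub_rmse <- mean(vapply(cub, `[[`, numeric(1), "rmse"))
    rows <- rbind(rows, data.frame(
      condition = "cubic", seed = rep, matched = FALSE, rmse = cub_rmse,
      ssim = mean(vapply(cub, `[[`, numeric(1), "ssim")),
      effective_resolution = mean(vapply(cub, `[[`, numeric(1),
                                         "effective_resolution")),
      improvement_over_cubic = 0))
    for (ci in seq_along(cfg$plans)) {
      model <- train_for_plan(spec, train_vols, cfg$plans[[ci]], cfg, sseed)
      ev <- lapply(trips, eval_model, model = model, plan = cfg$test_plan,
                   with_decorr = TRUE)
      mr <- mean(vapply(ev, `[[`, numeric(1), "rmse"))
      rows <- rbind(rows, data.frame(
        condition = labels[ci], seed = rep, matched = matched[ci], rmse = mr,
        ssim = mean(vapply(ev, `[[`, numeric(1), "ssim")),
        effective_resolution = mean(vapply(ev, `[[`, numeric(1),
                                           "effective_resolution")),
        improvement_over_cubic = cub_rmse - mr))
      per_cond[[labels[ci]]] <- c(per_cond[[labels[ci]]], mr)
    }
  }
  tests <- if (cfg$n_seeds >= 2L) {
    list(anova_across_conditions = welch_anova(per_cond))
  } else list()
  new_report(rows, tests, cfg, "resolution_matching")
}

#' Quantify cross-modality transfer learning
#'
#' Trains a residual network on the source modality, then compares three
#' routes to super-resolving held-out target-modality volumes: direct
#' application of the source-trained network, fine-tuning its last layers on
#' a few target-modality volumes, and the cubic baseline.  The companion
#' high-correlation contrast (`"T2w_like"`) is evaluated with direct
#' application as well.
#'
#' @param cfg an [experiment_config()]; `cfg$transfer` sets the modalities,
#'   the number of target fine-tuning volumes (>= 2) and how many tail
#'   layers stay trainable.
#' @return A `voxsr_report` with conditions `direct_FA`, `finetuned_FA`,
#'   `cubic_FA`, `direct_T2w`, `cubic_T2w` (for default modalities).
#' @export
run_transfer <- function(cfg) {
  tr <- cfg$transfer
  if (tr$source_modality == tr$target_modality) {
    stopf("source and target modalities must differ")
  }
  if (tr$n_target_volumes < 2L) stopf("`n_target_volumes` must be >= 2")
  plan <- cfg$test_plan
  spec <- cfg$model_specs[[which(vapply(cfg$model_specs, function(s)
    s$family == "ResNet", logical(1)))[1]]]
  short <- function(m) sub("_like$", "", m)
  rows <- NULL
  acc <- list()
  for (rep in seq_len(cfg$n_seeds)) {
    ds <- rep_phantoms(cfg, rep, n_extra = tr$n_target_volumes)
    n_tr <- cfg$n_train_volumes
    src_vols <- lapply(ds$volumes[seq_len(n_tr)], `[[`, tr$source_modality)
    tgt_idx <- n_tr + seq_len(tr$n_target_volumes)
    tgt_vols <- lapply(ds$volumes[tgt_idx], `[[`, tr$target_modality)
    test_idx <- n_tr + tr$n_target_volumes + seq_len(cfg$n_test_volumes)
    test_tgt <- lapply(ds$volumes[test_idx], `[[`, tr$target_modality)
    test_t2 <- lapply(ds$volumes[test_idx], `[[`, "T2w_like")
    sseed <- rep_seed(cfg$train$seed, rep)

    base <- train_for_plan(spec, src_vols, plan, cfg, sseed)
    tgt_pairs <- lapply(tgt_vols, function(v)
      normalize_pair(make_lr_hr_pair(v, plan)))
    ft_ps <- sample_patches(tgt_pairs, p = cfg$patch_edge,
                            n = tr$n_ft_patches %||% cfg$n_patches,
                            seed = sseed + 1L)
    ft_cfg <- cfg$train
    ft_cfg$seed <- sseed + 2L
    ft_cfg$max_epochs <- tr$finetune_epochs %||% cfg$train$max_epochs
    ft_cfg$early_stop_patience <- min(cfg$train$early_stop_patience,
                                      ft_cfg$max_epochs - 1L)
    ft_cfg$learning_rate <- tr$finetune_lr %||% ft_cfg$learning_rate
    tuned <- fine_tune(base, ft_ps, tr$n_trainable_tail_layers, ft_cfg)

    add_row <- function(cond, vols_, model_) {
      trips <- lapply(vols_, test_triplet, plan = plan)
      ev <- if (is.null(model_)) lapply(trips, eval_cubic, with_decorr = TRUE)
            else lapply(trips, eval_model, model = model_, plan = plan,
                        with_decorr = TRUE)
      mr <- mean(vapply(ev, `[[`, numeric(1), "rmse"))
      rows <<- rbind(rows, data.frame(
        condition = cond, seed = rep, rmse = mr,
        ssim = mean(vapply(ev, `[[`, numeric(1), "ssim")),
        effective_resolution = mean(vapply(ev, `[[`, numeric(1),
                                           "effective_resolution"))))
      acc[[cond]] <<- c(acc[[cond]], mr)
    }
    tg <- short(tr$target_modality)
    add_row(paste0("cubic_", tg), test_tgt, NULL)
    add_row(paste0("direct_", tg), test_tgt, base)
    add_row(paste0("finetuned_", tg), test_tgt, tuned)
    add_row("cubic_T2w", test_t2, NULL)
    add_row("direct_T2w", test_t2, base)
  }
  tg <- short(tr$target_modality)
  tests <- if (cfg$n_seeds >= 2L) list(
    finetuned_vs_direct = paired_ttest(acc[[paste0("direct_", tg)]],
                                       acc[[paste0("finetuned_", tg)]]),
    direct_vs_cubic_target = paired_ttest(acc[[paste0("cubic_", tg)]],
                                          acc[[paste0("direct_", tg)]]),
    direct_vs_cubic_T2w = paired_ttest(acc$cubic_T2w, acc$direct_T2w)) else list()
  new_report(rows, tests, cfg, "transfer")
}
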