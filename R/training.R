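#' Training configuration
#'
#' Houses the optimization regime: Adam with the reference hyper-parameters
#' (learning rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8), MSE loss, a
#' maximum epoch budget (reference 1000) with early stopping when the
#' validation loss has set no new strict minimum within `early_stop_patience`
#' epochs (reference 100), best-validation weights restored.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param max_epochs epoch budget.
#' @param early_stop_patience epochs without a new validation minimum before
#'   stopping; must be below `max_epochs`.
#' @param batch_size minibatch size.
#' @param validation_fraction fraction of patches held out for validation,
#'   in (0, 0.5); the split is by source volume whenever patches from more
#'   than one volume are present.
#' @param seed seed driving the split and all shuffling.
#' @param gan_adversarial_weight weight of the adversarial term in the GAN
#'   generator loss (relative to MSE); ignored by [train()].
#' @return A `voxsr_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, max_epochs = 1000L,
                         early_stop_patience = 100L, batch_size = 16L,
                         validation_fraction = 0.2, seed = 1L,
                         gan_adversarial_weight = 1e-3) {
  if (validation_fraction <= 0 || validation_fraction >= 0.5) {
    stopf("`validation_fraction` must lie in (0, 0.5)")
  }
  if (early_stop_patience >= max_epochs) {
    stopf("`early_stop_patience` must be below `max_epochs`")
  }
  if (gan_adversarial_weight < 0) stopf("`gan_adversarial_weight` must be >= 0")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 gan_adversarial_weight = gan_adversarial_weight),
            class = "voxsr_train_config")
}

# ---- Adam ---------------------------------------------------------------

#' @keywords internal
adam_init <- function(net) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(net$layers)) {
    st$m[[nm]] <- list(W = net$layers[[nm]]$W * 0, b = net$layers[[nm]]$b * 0)
    st$v[[nm]] <- st$m[[nm]]
  }
  if (!is.null(net$dense)) {
    st$m$dense <- list(W = net$dense$W * 0, b = 0)
    st$v$dense <- st$m$dense
  }
  st
}

#' @keywords internal
adam_step <- function(net, grads, st, cfg) {
  st$t <- st$t + 1L
  corr1 <- 1 - cfg$beta1^st$t
  corr2 <- 1 - cfg$beta2^st$t
  upd <- function(p, g, m, v) {
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    p <- p - cfg$learning_rate * (m / corr1) / (sqrt(v / corr2) + cfg$epsilon)
    list(p = p, m = m, v = v)
  }
  for (nm in names(grads)) {
    if (!isTRUE(net$trainable[[nm]])) next
    tgt <- if (nm == "dense") net$dense else net$layers[[nm]]
    for (par in c("W", "b")) {
      u <- upd(tgt[[par]], grads[[nm]][[par]], st$m[[nm]][[par]],
               st$v[[nm]][[par]])
      tgt[[par]] <- u$p; st$m[[nm]][[par]] <- u$m; st$v[[nm]][[par]] <- u$v
    }
    if (nm == "dense") net$dense <- tgt else net$layers[[nm]] <- tgt
  }
  list(net = net, state = st)
}

# ---- splits and loss ----------------------------------------------------

# Validation split: by source volume when several volumes contributed
# patches (no volume's overlapping patches straddle the split), otherwise by
# random patches.
#' @keywords internal
split_validation <- function(ps, fraction) {
  n <- n_patches(ps)
  vols <- unique(ps$volume_id)
  if (length(vols) > 1L) {
    vs <- sample(vols)
    counts <- cumsum(vapply(vs, function(v) sum(ps$volume_id == v), numeric(1)))
    k <- which(counts >= fraction * n)[1]
    val_vols <- vs[seq_len(k)]
    val <- which(ps$volume_id %in% val_vols)
  } else {
    val <- sample.int(n, max(1L, round(fraction * n)))
  }
  if (length(val) >= n) val <- val[-1L]
  list(train = setdiff(seq_len(n), val), val = sort(val))
}

#' @keywords internal
mse_loss <- function(pred, target) mean((pred - target)^2)

#' @keywords internal
eval_mse <- function(net, inputs, targets, idx, batch_size) {
  tot <- 0
  for (s in seq.int(1L, length(idx), by = batch_size)) {
    ii <- idx[s:min(s + batch_size - 1L, length(idx))]
    xb <- as_batch(inputs[, , , ii, drop = FALSE])
    pb <- net_forward(net, xb)$out
    tot <- tot + sum((pb - as_batch(targets[, , , ii, drop = FALSE]))^2)
  }
  tot / (length(idx) * prod(dim(inputs)[1:3]))
}

# ---- core loop ----------------------------------------------------------

# Shared epoch loop for train() and train_gan().  `gan` is NULL or
# list(discriminator, weight); with weight 0 no adversarial gradient is
# computed, so the generator trajectory is arithmetically identical to plain
# training (the discriminator is still updated).
#' @keywords internal
train_core <- function(net, ps, cfg, gan = NULL, provenance = "") {
  if (is.null(ps$targets)) stopf("training requires a patch set with targets")
  n <- n_patches(ps)
  if (n < cfg$batch_size) stopf("need at least `batch_size` (%d) patches, got %d",
                                cfg$batch_size, n)
  trn <- net$trainable[names(net$layers)]
  if (!any(trn)) stopf("no trainable layers")
  min_tr <- which(trn)[1]
  with_seed(cfg$seed, {
    sp <- split_validation(ps, cfg$validation_fraction)
    st <- adam_init(net)
    dst <- if (!is.null(gan)) adam_init(gan$discriminator)
    disc <- gan$discriminator
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), disc_loss = numeric())
    # epoch-0 baseline: the untrained (or pre-trained) weights compete too,
    # so early stopping can never return something worse than its start
    best_val <- eval_mse(net, ps$inputs, ps$targets, sp$val, cfg$batch_size)
    best_net <- net; best_epoch <- 0L; wait <- 0L
    warn_collapse <- FALSE
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(sp$train)
      ep_loss <- 0; ep_n <- 0; d_loss <- NA_real_
      for (s in seq.int(1L, length(ord), by = cfg$batch_size)) {
        ii <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        xb <- as_batch(ps$inputs[, , , ii, drop = FALSE])
        yb <- as_batch(ps$targets[, , , ii, drop = FALSE])
        fw <- net_forward(net, xb, cache = TRUE)
        pred <- fw$out
        loss <- mse_loss(pred, yb)
        if (!is.finite(loss)) stopf("training diverged (non-finite loss) at epoch %d", epoch)
        gy <- 2 * (pred - yb) / length(pred)
        if (!is.null(gan)) {
          # --- discriminator step: real HR vs generated, BCE ---
          nb <- length(ii)
          dx <- array(c(yb, pred), dim = c(dim(yb)[1:4], 2L * nb))
          lab <- c(rep(1, nb), rep(0, nb))
          dfw <- net_forward(disc, dx, cache = TRUE)
          pr <- pmin(pmax(dfw$out, 1e-12), 1 - 1e-12)
          d_loss <- -mean(lab * log(pr) + (1 - lab) * log(1 - pr))
          gyd <- (pr - lab) / (pr * (1 - pr)) / length(lab)   # d BCE / d p
          dbw <- net_backward(disc, dfw$cache, gyd)
          du <- adam_step(disc, dbw$grads, dst, cfg)
          disc <- du$net; dst <- du$state
          if (cfg$gan_adversarial_weight > 0) {
            # --- adversarial gradient for the generator: push D(G(x)) to 1
            gfw <- net_forward(disc, pred, cache = TRUE)
            pg <- pmin(pmax(gfw$out, 1e-12), 1 - 1e-12)
            gyg <- (-1 / pg) / length(pg)
            gbwd <- net_backward(disc, gfw$cache, gyg)
            gy <- gy + cfg$gan_adversarial_weight * gbwd$gx
            if (d_loss < 1e-3 && loss > 10 * best_val) warn_collapse <- TRUE
          }
        }
        bw <- net_backward(net, fw$cache, gy, min_trainable = min_tr)
        up <- adam_step(net, bw$grads, st, cfg)
        net <- up$net; st <- up$state
        ep_loss <- ep_loss + loss * length(ii); ep_n <- ep_n + length(ii)
      }
      val <- eval_mse(net, ps$inputs, ps$targets, sp$val, cfg$batch_size)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                  val_loss = val, disc_loss = d_loss))
      if (val < best_val) {
        best_val <- val; best_net <- net; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
    if (warn_collapse) {
      attr(history, "warning") <- "possible discriminator collapse"
    }
    structure(list(network = best_net, spec = net$spec, config = cfg,
                   history = history, stopped_epoch = nrow(history),
                   best_epoch = best_epoch,
                   discriminator = disc,
                   provenance = provenance),
              class = "voxsr_trained_model")
  })
}

#' Train an SR network on paired patches
#'
#' Adam optimization of the MSE between predicted and target patches, with a
#' volume-level validation split, early stopping on the validation loss and
#' restoration of the best-validation weights.  Fully seeded: the same seed
#' reproduces identical final weights.
#'
#' @param network a `voxsr_network` from [build_ccnn()] or [build_resnet()].
#' @param train_ps a `voxsr_patchset` with targets.
#' @param config a [train_config()].
#' @return A `voxsr_trained_model` with per-epoch `history`, `stopped_epoch`
#'   and the best-validation `network`.
#' @export
train <- function(network, train_ps, config = train_config()) {
  if (!inherits(network, "voxsr_network")) stopf("`network` must be a voxsr_network")
  if (network$family == "discriminator") stopf("cannot MSE-train a discriminator")
  train_core(network, train_ps, config, provenance = "train")
}

#' Train a GAN super-resolution model
#'
#' Alternating updates: the discriminator on binary cross-entropy between
#' real high-resolution patches and generator outputs, the generator on
#' MSE + `gan_adversarial_weight` x adversarial term.  With weight 0 the
#' generator trajectory reduces exactly to [train()].  The trained generator
#' is returned as the SR model.
#'
#' @param generator,discriminator networks from [build_gan()].
#' @param train_ps a `voxsr_patchset` with targets.
#' @param config a [train_config()]; `gan_adversarial_weight` sets the loss
#'   balance.
#' @return A `voxsr_trained_model` (the generator; the final discriminator
#'   rides along as `$discriminator`).
#' @export
train_gan <- function(generator, discriminator, train_ps,
                      config = train_config()) {
  if (discriminator$family != "discriminator") {
    stopf("`discriminator` must come from build_gan()")
  }
  train_core(generator, train_ps, config,
             gan = list(discriminator = discriminator,
                        weight = config$gan_adversarial_weight),
             provenance = "train_gan")
}

#' Fine-tune a trained model on a new domain
#'
#' Transfer learning: freezes all layers except the last
#' `n_trainable_tail_layers` (in forward order) and resumes training on the
#' target-domain patches; frozen weights are bit-identical afterwards.
#'
#' @param base a `voxsr_trained_model`.
#' @param target_ps target-domain `voxsr_patchset` with targets.
#' @param n_trainable_tail_layers how many trailing layers stay trainable
#'   (reference setting: the last three).
#' @param config a [train_config()] for the fine-tuning run.
#' @return A new `voxsr_trained_model`; `model_summary()` of its network
#'   records the freezing.
#' @export
fine_tune <- function(base, target_ps, n_trainable_tail_layers = 3L,
                      config = train_config()) {
  if (!inherits(base, "voxsr_trained_model")) {
    stopf("`base` must be a voxsr_trained_model")
  }
  net <- base$network
  nl <- length(net$layers)
  n_trainable_tail_layers <- as.integer(n_trainable_tail_layers)
  if (n_trainable_tail_layers < 1L || n_trainable_tail_layers > nl) {
    stopf("`n_trainable_tail_layers` must be in [1, %d]", nl)
  }
  net$trainable[] <- FALSE
  net$trainable[names(net$layers)[(nl - n_trainable_tail_layers + 1L):nl]] <- TRUE
  out <- train_core(net, target_ps, config, provenance = "fine_tune")
  out$provenance <- sprintf("fine_tune(last %d layers) of %s",
                            n_trainable_tail_layers, base$provenance)
  out
}

#' Super-resolve a whole volume
#'
#' The full inference chain: cubic up-sampling by `factor`, [0, 1]
#' normalization, patch extraction at the inference stride (default half the
#' patch edge), batched network prediction, overlap-averaged recombination,
#' and inversion of the normalization.
#'
#' @param model a `voxsr_trained_model`.
#' @param lr_volume low-resolution input `voxsr_volume`.
#' @param factor integer upsampling factor of the model's training plan.
#' @param patch_edge patch size for inference; defaults to the spec's
#'   `input_edge` (clipped to the volume).
#' @param stride inference stride; default `max(1, patch_edge %/% 2)` for
#'   seam suppression by overlap averaging.
#' @return The super-resolved `voxsr_volume` on the factor-upsampled grid.
#' @export
apply_sr <- function(model, lr_volume, factor, patch_edge = NULL,
                     stride = NULL) {
  if (!inherits(model, "voxsr_trained_model")) {
    stopf("`model` must be a voxsr_trained_model")
  }
  check_volume(lr_volume, "lr_volume")
  hint <- model$spec$scale_hint
  if (!is.null(hint)) {
    want <- suppressWarnings(as.numeric(sub("->.*$", "", hint)))
    if (is.finite(want) && abs(lr_volume$voxel_size_um - want) > 1e-6) {
      warning(sprintf(
        "voxel size %g um differs from the model's training resolution hint %s; SR quality degrades when resolutions are mismatched",
        lr_volume$voxel_size_um, hint), call. = FALSE)
    }
  }
  up <- cubic_upsample(lr_volume, as.integer(factor))
  p <- as.integer(patch_edge %||% min(model$spec$input_edge, min(dim(up$data))))
  stride <- as.integer(stride %||% max(1L, p %/% 2L))
  nv <- normalize_intensity(up)
  nrm <- attr(nv, "norm")
  ps <- extract_patches(nv, NULL, p = p, stride = stride)
  pred <- net_predict(model$network, ps$inputs)
  rec <- reconstruct_volume(ps, pred)
  out <- denormalize_intensity(rec, nrm)
  out$voxel_size_um <- up$voxel_size_um
  out$modality <- lr_volume$modality
  out$id <- paste0(lr_volume$id, "_sr")
  out
}
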