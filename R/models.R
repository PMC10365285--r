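#' Declare a super-resolution network architecture
#'
#' The three families mirror the classical SR lineage: a plain three-layer
#' convolutional network (`"cCNN"`), a residual network (`"ResNet"`) whose
#' global skip makes it learn the HR - LR difference, and a `"GAN"` whose
#' generator is that ResNet and whose discriminator is a residual trunk with
#' a sigmoid head.
#'
#' @param family `"cCNN"`, `"ResNet"` or `"GAN"`.
#' @param n_res_blocks residual blocks in the ResNet / GAN trunk (reference
#'   setting 10).
#' @param channels convolution channels (reference setting 64).
#' @param kernel_edge odd kernel edge (reference setting 3).
#' @param ccnn_channels channel widths of the three cCNN layers (reference
#'   setting 64, 32, 1; the last must be 1).
#' @param input_edge nominal training patch edge (reference setting 21).
#' @param scale_hint optional string recording the training resolution pair,
#'   e.g. `"200->100um"`; [apply_sr()] warns on a mismatch.
#' @return A `voxsr_model_spec`.
#' @export
model_spec <- function(family = c("ResNet", "cCNN", "GAN"),
                       n_res_blocks = 10L, channels = 64L, kernel_edge = 3L,
                       ccnn_channels = c(64L, 32L, 1L), input_edge = 21L,
                       scale_hint = NULL) {
  family <- match.arg(family)
  kernel_edge <- as.integer(kernel_edge)
  if (kernel_edge %% 2L == 0L) stopf("`kernel_edge` must be odd")
  if (input_edge < kernel_edge) stopf("`input_edge` must be >= `kernel_edge`")
  if (family != "cCNN" && n_res_blocks < 1L) stopf("`n_res_blocks` must be >= 1")
  if (length(ccnn_channels) != 3L || ccnn_channels[3] != 1L) {
    stopf("`ccnn_channels` must be three widths ending in 1")
  }
  structure(list(family = family, n_res_blocks = as.integer(n_res_blocks),
                 channels = as.integer(channels), kernel_edge = kernel_edge,
                 ccnn_channels = as.integer(ccnn_channels),
                 input_edge = as.integer(input_edge), scale_hint = scale_hint),
            class = "voxsr_model_spec")
}

# Glorot (Xavier) normal initialization for a k^3 conv kernel.
#' @keywords internal
glorot_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin; fan_out <- k^3 * cout
  array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (fan_in + fan_out))),
        dim = c(k, k, k, cin, cout))
}

#' @keywords internal
conv_layer <- function(k, cin, cout) {
  list(W = glorot_conv(k, cin, cout), b = numeric(cout))
}

#' @keywords internal
new_network <- function(family, spec, layers, dense = NULL) {
  structure(list(family = family, spec = spec, layers = layers,
                 dense = dense,
                 trainable = stats::setNames(rep(TRUE, length(layers) +
                                                   !is.null(dense)),
                                             c(names(layers),
                                               if (!is.null(dense)) "dense"))),
            class = "voxsr_network")
}

#' Build the three-layer plain CNN
#'
#' Three 3D convolutions (channel widths from `spec$ccnn_channels`, default
#' 64, 32, 1) with ReLU after the first two layers and a linear output;
#' mirror same-padding keeps a p^3 input at p^3.
#'
#' @param spec a [model_spec()] with `family == "cCNN"`.
#' @param seed integer seed for the Glorot-normal initialization.
#' @return A `voxsr_network`.
#' @export
build_ccnn <- function(spec, seed = 1L) {
  if (spec$family != "cCNN") stopf("`spec$family` must be cCNN")
  k <- spec$kernel_edge; ch <- spec$ccnn_channels
  with_seed(seed, {
    layers <- list(conv1 = conv_layer(k, 1L, ch[1]),
                   conv2 = conv_layer(k, ch[1], ch[2]),
                   conv3 = conv_layer(k, ch[2], ch[3]))
    new_network("ccnn", spec, layers)
  })
}

#' @keywords internal
resnet_layers <- function(spec) {
  k <- spec$kernel_edge; C <- spec$channels
  layers <- list(head = conv_layer(k, 1L, C))
  for (b in seq_len(spec$n_res_blocks)) {
    layers[[sprintf("block%02d_conv1", b)]] <- conv_layer(k, C, C)
    layers[[sprintf("block%02d_conv2", b)]] <- conv_layer(k, C, C)
  }
  layers$tail <- conv_layer(k, C, 1L)
  layers
}

#' Build the residual SR network
#'
#' Head convolution to `channels`, then `n_res_blocks` residual blocks
#' (conv - ReLU - conv, identity skip added, ReLU), then a tail convolution
#' back to one channel.  A global skip adds the network input to the output,
#' so the network learns the HR - LR residual and the all-zero-weight
#' network is exactly the identity.
#'
#' @param spec a [model_spec()] with `family` `"ResNet"` or `"GAN"`.
#' @param seed integer seed for the Glorot-normal initialization.
#' @return A `voxsr_network`.
#' @export
build_resnet <- function(spec, seed = 1L) {
  if (!spec$family %in% c("ResNet", "GAN")) {
    stopf("`spec$family` must be ResNet or GAN")
  }
  with_seed(seed, new_network("resnet", spec, resnet_layers(spec)))
}

#' Build the GAN generator and discriminator
#'
#' The generator is structurally identical to [build_resnet()].  The
#' discriminator is a residual convolutional trunk (same block count and
#' width), global average pooling, one dense unit and a sigmoid, so it maps
#' any p^3 patch to a realness score in (0, 1).
#'
#' @param spec a [model_spec()] with `family == "GAN"`.
#' @param seed integer seed; generator and discriminator draw from one
#'   seeded stream.
#' @return `list(generator, discriminator)` of `voxsr_network`s.
#' @export
build_gan <- function(spec, seed = 1L) {
  if (spec$family != "GAN") stopf("`spec$family` must be GAN")
  with_seed(seed, {
    gen <- new_network("resnet", spec, resnet_layers(spec))
    C <- spec$channels
    dlayers <- resnet_layers(spec)
    dlayers$tail <- NULL
    dense <- list(W = matrix(rnorm(C, sd = sqrt(2 / (C + 1))), C, 1L),
                  b = 0)
    disc <- new_network("discriminator", spec, dlayers, dense = dense)
    list(generator = gen, discriminator = disc)
  })
}

#' Summarize a network
#'
#' @param net a `voxsr_network`.
#' @return A `voxsr_model_summary`: ordered `layer_names`, per-layer
#'   `trainable_flags`, total `parameter_count`, and counts of residual
#'   blocks / convolution layers.
#' @export
model_summary <- function(net) {
  if (!inherits(net, "voxsr_network")) stopf("`net` must be a voxsr_network")
  nm <- names(net$layers)
  if (!is.null(net$dense)) nm <- c(nm, "dense")
  count <- sum(vapply(net$layers, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  if (!is.null(net$dense)) count <- count + length(net$dense$W) + 1
  structure(list(layer_names = nm,
                 trainable_flags = unname(net$trainable[nm]),
                 parameter_count = as.integer(count),
                 n_conv_layers = length(net$layers),
                 n_res_blocks = sum(grepl("_conv1$", names(net$layers)))),
            class = "voxsr_model_summary")
}

#' @export
print.voxsr_model_summary <- function(x, ...) {
  cat(sprintf("<voxsr_model_summary> %d layers, %d parameters, %d residual blocks\n",
              length(x$layer_names), x$parameter_count, x$n_res_blocks))
  frozen <- x$layer_names[!x$trainable_flags]
  if (length(frozen)) cat("  frozen:", paste(frozen, collapse = ", "), "\n")
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

#' @keywords internal
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 4L) dim(x) <- c(d[1:3], 1L, d[4])  # N patches, 1 chan
  x
}

#' @keywords internal
conv_fwd <- function(x, layer) .conv3d_forward(x, layer$W, layer$b, dim(x))

#' @keywords internal
relu <- function(x) { x[x < 0] <- 0; x }

# Forward pass.  x: [p, p, p, 1, N] batch.  When `cache = TRUE` the
# returned list carries every pre-activation needed by net_backward().
#' @keywords internal
net_forward <- function(net, x, cache = FALSE) {
  L <- net$layers
  cc <- if (cache) list(x0 = x) else NULL
  if (net$family == "ccnn") {
    a1 <- conv_fwd(x, L$conv1); r1 <- relu(a1)
    a2 <- conv_fwd(r1, L$conv2); r2 <- relu(a2)
    out <- conv_fwd(r2, L$conv3)
    if (cache) cc <- c(cc, list(a1 = a1, r1 = r1, a2 = a2, r2 = r2))
    return(list(out = out, cache = cc))
  }
  # residual trunk, shared by the ResNet and the discriminator
  h <- conv_fwd(x, L$head)
  if (cache) cc$head <- h
  nb <- sum(grepl("_conv1$", names(L)))
  for (b in seq_len(nb)) {
    n1 <- sprintf("block%02d_conv1", b); n2 <- sprintf("block%02d_conv2", b)
    a1 <- conv_fwd(h, L[[n1]]); r1 <- relu(a1)
    a2 <- conv_fwd(r1, L[[n2]])
    s <- a2 + h          # identity skip
    h2 <- relu(s)
    if (cache) {
      cc[[paste0(n1, "_in")]] <- h
      cc[[paste0(n1, "_a")]] <- a1
      cc[[paste0(n1, "_r")]] <- r1
      cc[[paste0(n2, "_s")]] <- s
    }
    h <- h2
  }
  if (net$family == "resnet") {
    out <- conv_fwd(h, L$tail) + x   # global skip: learn the residual image
    if (cache) cc$trunk <- h
    return(list(out = out, cache = cc))
  }
  # discriminator: global average pool over voxels -> dense -> sigmoid
  d <- dim(h)
  hm <- matrix(h, nrow = prod(d[1:3]))
  dim(hm) <- c(prod(d[1:3]), d[4], d[5])
  pooled <- apply(hm, c(2, 3), mean)          # C x N
  z <- drop(crossprod(pooled, net$dense$W)) + net$dense$b   # length N
  p <- 1 / (1 + exp(-z))
  if (cache) { cc$trunk <- h; cc$pooled <- pooled; cc$z <- z; cc$p <- p }
  list(out = p, cache = cc)
}

# Backward pass: gy is d(loss)/d(out).  Returns per-layer weight gradients
# (same shapes as the weights) and the gradient w.r.t. the network input.
# `min_trainable` (index into the forward layer order) lets fine-tuning skip
# the backward work below the earliest trainable layer; gx is NULL then.
#' @keywords internal
net_backward <- function(net, cc, gy, min_trainable = 1L) {
  L <- net$layers
  g <- list()
  if (net$family == "ccnn") {
    b3 <- .conv3d_backward(cc$r2, L$conv3$W, gy, dim(cc$r2))
    g$conv3 <- list(W = b3$gW, b = b3$gb)
    if (min_trainable > 2L) return(list(grads = g, gx = NULL))
    g2 <- b3$gx; g2[cc$a2 < 0] <- 0
    b2 <- .conv3d_backward(cc$r1, L$conv2$W, g2, dim(cc$r1))
    g$conv2 <- list(W = b2$gW, b = b2$gb)
    if (min_trainable > 1L) return(list(grads = g, gx = NULL))
    g1 <- b2$gx; g1[cc$a1 < 0] <- 0
    b1 <- .conv3d_backward(cc$x0, L$conv1$W, g1, dim(cc$x0))
    g$conv1 <- list(W = b1$gW, b = b1$gb)
    return(list(grads = g, gx = b1$gx))
  }
  nb <- sum(grepl("_conv1$", names(L)))
  if (net$family == "resnet") {
    bt <- .conv3d_backward(cc$trunk, L$tail$W, gy, dim(cc$trunk))
    g$tail <- list(W = bt$gW, b = bt$gb)
    gh <- bt$gx
    gx_global <- gy               # global skip path
  } else {
    # discriminator head: gy is d(loss)/d(p), length N
    p <- cc$p
    gz <- gy * p * (1 - p)                       # through sigmoid
    g$dense <- list(W = cc$pooled %*% matrix(gz, ncol = 1),
                    b = sum(gz))
    d <- dim(cc$trunk)
    nvox <- prod(d[1:3])
    gh <- array(0, dim = d)
    # d pooled / d h = 1/nvox; distribute dense gradient back over voxels
    for (n in seq_len(d[5])) {
      per_chan <- as.numeric(net$dense$W) * gz[n] / nvox
      gh[, , , , n] <- rep(per_chan, each = nvox)
    }
    gx_global <- 0
  }
  for (b in rev(seq_len(nb))) {
    # block b holds forward-order layer indices 2b and 2b + 1 (head is 1);
    # once every remaining layer below is frozen there is nothing to compute
    if (2L * b + 1L < min_trainable) return(list(grads = g, gx = NULL))
    n1 <- sprintf("block%02d_conv1", b); n2 <- sprintf("block%02d_conv2", b)
    s <- cc[[paste0(n2, "_s")]]
    gs <- gh; gs[s < 0] <- 0          # through the post-skip ReLU
    b2 <- .conv3d_backward(cc[[paste0(n1, "_r")]], L[[n2]]$W, gs,
                           dim(cc[[paste0(n1, "_r")]]))
    g[[n2]] <- list(W = b2$gW, b = b2$gb)
    gr <- b2$gx; gr[cc[[paste0(n1, "_a")]] < 0] <- 0
    b1 <- .conv3d_backward(cc[[paste0(n1, "_in")]], L[[n1]]$W, gr,
                           dim(cc[[paste0(n1, "_in")]]))
    g[[n1]] <- list(W = b1$gW, b = b1$gb)
    gh <- b1$gx + gs                  # identity-skip path
  }
  if (min_trainable > 1L) return(list(grads = g, gx = NULL))
  bh <- .conv3d_backward(cc$x0, L$head$W, gh, dim(cc$x0))
  g$head <- list(W = bh$gW, b = bh$gb)
  list(grads = g, gx = bh$gx + gx_global)
}

# Prediction on a 4D patch array, in batches to bound memory.
#' @keywords internal
net_predict <- function(net, patches, batch_size = 64L) {
  n <- dim(patches)[4L]
  out <- array(0, dim = dim(patches))
  for (s in seq.int(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    xb <- as_batch(patches[, , , idx, drop = FALSE])
    out[, , , idx] <- net_forward(net, xb)$out
  }
  out
}
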