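#' Min-max normalize a volume to [0, 1]
#'
#' Whole-volume normalization (never per patch, so patch recombination stays
#' scale-consistent).  The (min, max) actually used are attached as the
#' `"norm"` attribute so predictions can be mapped back with
#' [denormalize_intensity()].  A constant volume maps to all zeros.
#'
#' @param v a `voxsr_volume` with finite intensities.
#' @return A normalized `voxsr_volume` carrying attribute `norm = c(min, max)`.
#' @export
normalize_intensity <- function(v) {
  check_volume(v)
  lo <- min(v$data); hi <- max(v$data)
  out <- if (hi > lo) (v$data - lo) / (hi - lo) else array(0, dim = dim(v$data))
  res <- as_volume_like(out, v)
  attr(res, "norm") <- c(min = lo, max = hi)
  res
}

#' Invert a min-max normalization
#'
#' @param v normalized `voxsr_volume` (or any volume on the normalized scale,
#'   e.g. a network prediction).
#' @param norm the `c(min, max)` pair recorded by [normalize_intensity()].
#' @return A `voxsr_volume` on the original intensity scale.
#' @export
denormalize_intensity <- function(v, norm) {
  check_volume(v)
  as_volume_like(v$data * (norm[["max"]] - norm[["min"]]) + norm[["min"]], v)
}

# Clamped origin lattice along one axis: stride steps from 0, with a final
# origin forced to dim - p so the whole extent is covered. 0-based.
#' @keywords internal
clamped_lattice <- function(dim, p, stride) {
  o <- seq.int(0L, dim - p, by = stride)
  if (o[length(o)] != dim - p) o <- c(o, dim - p)
  as.integer(o)
}

#' Extract paired cubic patches from co-registered volumes
#'
#' Enumerates patch origins in raster order (first axis fastest) over a
#' stride lattice, clamping the final origin per axis to `dim - p` so the
#' whole volume is covered; target cubes (when a target volume is given) are
#' cut at identical origins.  Coordinates are 0-based, half-open
#' `[origin, origin + p)`.
#'
#' @param lr_up input `voxsr_volume` (typically cubic-upsampled LR).
#' @param hr optional co-registered target `voxsr_volume` of the same shape.
#' @param p patch edge length.
#' @param stride integer stride, one value or one per axis.
#' @return A `voxsr_patchset`: list with `inputs` (p x p x p x N array),
#'   `targets` (or NULL), `origins` (N x 3, 0-based), `patch_edge`,
#'   `source_shape`, `stride`, `volume_id`.
#' @export
extract_patches <- function(lr_up, hr = NULL, p, stride = p) {
  check_volume(lr_up, "lr_up")
  d <- dim(lr_up$data)
  p <- as.integer(p)
  stride <- as.integer(rep(stride, length.out = 3L))
  if (any(stride < 1L)) stopf("`stride` must be >= 1")
  if (any(p > d)) stopf("patch edge %d exceeds volume dimensions (%s)",
                        p, paste(d, collapse = "x"))
  if (!is.null(hr)) {
    check_volume(hr, "hr")
    if (!identical(dim(hr$data), d)) stopf("`hr` shape differs from `lr_up`")
  }
  lat <- lapply(1:3, function(ax) clamped_lattice(d[ax], p, stride[ax]))
  origins <- as.matrix(expand.grid(lat[[1]], lat[[2]], lat[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  dimnames(origins) <- NULL
  n <- nrow(origins)
  cut <- function(src) {
    out <- array(0, dim = c(p, p, p, n))
    for (i in seq_len(n)) {
      o <- origins[i, ]
      out[, , , i] <- src[(o[1] + 1):(o[1] + p), (o[2] + 1):(o[2] + p),
                          (o[3] + 1):(o[3] + p)]
    }
    out
  }
  structure(
    list(inputs = cut(lr_up$data),
         targets = if (!is.null(hr)) cut(hr$data) else NULL,
         origins = origins, patch_edge = p, source_shape = d,
         stride = stride, volume_id = rep.int(1L, n),
         voxel_size_um = lr_up$voxel_size_um),
    class = "voxsr_patchset"
  )
}

#' @export
print.voxsr_patchset <- function(x, ...) {
  cat(sprintf("<voxsr_patchset> %d patches of edge %d from a %s grid (%s targets)\n",
              n_patches(x), x$patch_edge, paste(x$source_shape, collapse = "x"),
              if (is.null(x$targets)) "no" else "with"))
  invisible(x)
}

#' Number of patches in a patch set
#' @param ps a `voxsr_patchset`.
#' @return Integer count.
#' @export
n_patches <- function(ps) dim(ps$inputs)[4L]

#' Randomly sample paired training patches
#'
#' Training patches are drawn at uniform random origins (the counts, not the
#' locations, are what the training protocol fixes).  Sampling from several
#' co-registered volume pairs records a `volume_id` per patch so validation
#' splits can be made at the volume level.
#'
#' @param pairs one `list(lr_upsampled, hr)` pair or a list of such pairs.
#' @param p patch edge length.
#' @param n total number of patches to draw.
#' @param seed integer seed.
#' @return A `voxsr_patchset` with targets.
#' @export
sample_patches <- function(pairs, p, n, seed = 1L) {
  if (!is.null(pairs$lr_upsampled)) pairs <- list(pairs)
  p <- as.integer(p); n <- as.integer(n)
  nv <- length(pairs)
  with_seed(seed, {
    vol_of <- sort(sample.int(nv, n, replace = TRUE))
    inputs <- array(0, dim = c(p, p, p, n))
    targets <- array(0, dim = c(p, p, p, n))
    origins <- matrix(0L, n, 3L)
    for (i in seq_len(n)) {
      pr <- pairs[[vol_of[i]]]
      d <- dim(pr$lr_upsampled$data)
      if (any(p > d)) stopf("patch edge %d exceeds volume dimensions", p)
      o <- vapply(d, function(dd) sample.int(dd - p + 1L, 1L) - 1L, integer(1))
      origins[i, ] <- o
      inputs[, , , i] <- pr$lr_upsampled$data[(o[1] + 1):(o[1] + p),
                                              (o[2] + 1):(o[2] + p),
                                              (o[3] + 1):(o[3] + p)]
      targets[, , , i] <- pr$hr$data[(o[1] + 1):(o[1] + p),
                                     (o[2] + 1):(o[2] + p),
                                     (o[3] + 1):(o[3] + p)]
    }
    structure(
      list(inputs = inputs, targets = targets, origins = origins,
           patch_edge = p, source_shape = dim(pairs[[1]]$lr_upsampled$data),
           stride = NA_integer_, volume_id = vol_of,
           voxel_size_um = pairs[[1]]$lr_upsampled$voxel_size_um),
      class = "voxsr_patchset"
    )
  })
}

#' Reassemble a volume from predicted patches
#'
#' Each voxel's value is the mean of all predicted patches covering it
#' (every voxel is covered at least once by the clamped extraction lattice).
#'
#' @param ps the `voxsr_patchset` the patches were extracted from.
#' @param predicted p x p x p x N array of predictions (defaults to
#'   `ps$inputs`, giving an exact round trip).
#' @return A `voxsr_volume` of shape `ps$source_shape`.
#' @export
reconstruct_volume <- function(ps, predicted = ps$inputs) {
  if (!inherits(ps, "voxsr_patchset")) stopf("`ps` must be a voxsr_patchset")
  pd <- dim(predicted)
  p <- ps$patch_edge
  if (length(pd) != 4L || any(pd[1:3] != p) || pd[4] != n_patches(ps)) {
    stopf("`predicted` must be a %d x %d x %d x %d array", p, p, p, n_patches(ps))
  }
  acc <- array(0, dim = ps$source_shape)
  cnt <- array(0, dim = ps$source_shape)
  for (i in seq_len(pd[4])) {
    o <- ps$origins[i, ]
    ix <- (o[1] + 1):(o[1] + p); iy <- (o[2] + 1):(o[2] + p)
    iz <- (o[3] + 1):(o[3] + p)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + predicted[, , , i]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  if (any(cnt == 0)) stopf("internal error: uncovered voxel in reconstruction")
  volume(acc / cnt, ps$voxel_size_um %||% 1, "other", "reconstructed")
}
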