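#' Configuration for the multi-scale phantom generator
#'
#' Describes a synthetic high-resolution structural ("AF-like") volume built
#' from band-limited Gaussian random fields at several correlation lengths
#' plus a piecewise-constant region map with sharp boundaries, so that
#' coarsening genuinely destroys fine detail.
#'
#' @param seed integer seed; identical seed + config reproduces identical
#'   volumes bit for bit.
#' @param grid_size voxels per axis (cubic grid).
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param scale_lengths_um strictly decreasing feature correlation lengths
#'   (micrometres); the smallest must be at least `2 * voxel_size_um` so the
#'   finest features are resolvable on the grid.
#' @param target_cross_correlation voxel-wise Pearson correlation in (-1, 1)
#'   targeted between the structural volume and its derived "T2w-like"
#'   companion contrast.
#' @param fa_cross_correlation correlation targeted for the "FA-like"
#'   companion contrast (typically negative).
#' @param n_volumes number of independent phantoms for [generate_dataset()].
#' @param n_regions number of piecewise-constant anatomical regions; default
#'   scales the reference density of about 30 cells on a 64-cube with grid
#'   volume.
#' @return A `voxsr_phantom_config` list.
#' @export
phantom_config <- function(seed = 1L,
                           grid_size = 64L,
                           voxel_size_um = 25,
                           scale_lengths_um = c(400, 100),
                           target_cross_correlation = 0.72,
                           fa_cross_correlation = -0.69,
                           n_volumes = 1L,
                           n_regions = NULL) {
  grid_size <- as.integer(grid_size)
  n_volumes <- as.integer(n_volumes)
  if (grid_size < 8L) stopf("`grid_size` must be at least 8")
  if (voxel_size_um <= 0) stopf("`voxel_size_um` must be positive")
  if (length(scale_lengths_um) < 1L || any(scale_lengths_um <= 0)) {
    stopf("`scale_lengths_um` must be positive")
  }
  if (is.unsorted(rev(scale_lengths_um), strictly = TRUE) &&
      length(scale_lengths_um) > 1L) {
    stopf("`scale_lengths_um` must be strictly decreasing")
  }
  if (min(scale_lengths_um) < 2 * voxel_size_um) {
    stopf("smallest scale length (%g um) is below 2 voxels (%g um): features would not be resolvable on the grid",
          min(scale_lengths_um), 2 * voxel_size_um)
  }
  if (abs(target_cross_correlation) >= 1 || abs(fa_cross_correlation) >= 1) {
    stopf("cross-correlation targets must lie strictly inside (-1, 1)")
  }
  if (n_volumes < 1L) stopf("`n_volumes` must be >= 1")
  n_regions <- as.integer(n_regions %||% max(8, round(30 * (grid_size / 64)^3)))
  structure(
    list(seed = as.integer(seed), grid_size = grid_size,
         voxel_size_um = as.numeric(voxel_size_um),
         n_structure_scales = length(scale_lengths_um),
         scale_lengths_um = as.numeric(scale_lengths_um),
         target_cross_correlation = target_cross_correlation,
         fa_cross_correlation = fa_cross_correlation,
         n_volumes = n_volumes, n_regions = n_regions),
    class = "voxsr_phantom_config"
  )
}

# Piecewise-constant region map from a seeded Voronoi partition of the grid:
# each voxel takes the random value of its nearest cell centre.  Edges are
# then softened with a Gaussian whose width tracks the finest configured
# scale, so a single very coarse scale yields an almost band-limited volume.
#' @keywords internal
voronoi_field <- function(grid, n_regions, edge_sigma_vox) {
  centers <- matrix(runif(3L * n_regions, 1, grid), ncol = 3L)
  values <- runif(n_regions)
  ax <- seq_len(grid)
  best_d2 <- array(Inf, dim = c(grid, grid, grid))
  lab_val <- array(0, dim = c(grid, grid, grid))
  dx2 <- outer(ax, centers[, 1L], function(a, c) (a - c)^2)
  dy2 <- outer(ax, centers[, 2L], function(a, c) (a - c)^2)
  dz2 <- outer(ax, centers[, 3L], function(a, c) (a - c)^2)
  for (i in seq_len(n_regions)) {
    d2 <- outer(outer(dx2[, i], dy2[, i], `+`), dz2[, i], `+`)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    lab_val[upd] <- values[i]
  }
  gauss_smooth_periodic(lab_val, edge_sigma_vox)
}

#' Generate a multi-scale structural phantom
#'
#' Produces an "AF-like" high-resolution volume: a sum of Gaussian random
#' fields (white noise convolved with Gaussian kernels at the configured
#' correlation lengths) and a piecewise-constant Voronoi region map whose
#' edge sharpness follows the finest scale.  Intensities are scaled to
#' [0, 1].
#'
#' @param config a [phantom_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param id identifier for the returned volume.
#' @return A `voxsr_volume` with modality `"AF_like"`.
#' @export
generate_phantom <- function(config, seed = NULL, id = "phantom") {
  if (!inherits(config, "voxsr_phantom_config")) {
    stopf("`config` must come from phantom_config()")
  }
  g <- config$grid_size
  sigmas <- config$scale_lengths_um / (2 * config$voxel_size_um)
  if (max(sigmas) > g / 2) {
    stopf("grid of %d voxels is too small for the largest scale (%g um)",
          g, max(config$scale_lengths_um))
  }
  with_seed(seed %||% config$seed, {
    # band-limited field per scale: difference of Gaussians concentrates the
    # energy of each scale in its own spectral band, so volumes carry
    # genuinely resolution-specific structure
    fields <- lapply(sigmas, function(s) {
      w <- array(rnorm(g^3), dim = c(g, g, g))
      f <- gauss_smooth_periodic(w, s) - gauss_smooth_periodic(w, 2 * s)
      f / sd(f)
    })
    # sharp anatomical boundaries only when fine scales are requested
    edge_sigma <- min(sigmas) / 4
    vor <- voronoi_field(g, config$n_regions, edge_sigma)
    vor <- (vor - mean(vor)) / max(sd(vor), 1e-12)
    x <- 1.0 * vor
    for (f in fields) x <- x + f * (0.8 / length(fields))
    x <- (x - min(x)) / (max(x) - min(x))
    volume(x, config$voxel_size_um, "AF_like", id)
  })
}

#' Derive a co-registered companion contrast
#'
#' Builds a second modality on the same grid whose voxel-wise Pearson
#' correlation with the source equals `target_corr` (exactly, up to the
#' affine [0, 1] rescale).  `"T2w_like"` combines a monotone intensity
#' transform of the source with independent structured noise; `"FA_like"`
#' additionally mixes in a local-gradient-orientation feature so that part
#' of its contrast is not a pointwise function of source intensity.
#'
#' @param source an `"AF_like"` `voxsr_volume`.
#' @param target_modality `"T2w_like"` or `"FA_like"`.
#' @param target_corr desired correlation, `|target_corr| < 1`.
#' @param seed integer seed for the structured noise.
#' @return A co-registered `voxsr_volume` of the requested modality.
#' @export
derive_modality <- function(source, target_modality = c("T2w_like", "FA_like"),
                            target_corr = 0.72, seed = 1L) {
  check_volume(source, "source")
  if (source$modality != "AF_like") stopf("`source` must be AF_like")
  target_modality <- match.arg(target_modality)
  if (abs(target_corr) >= 1) stopf("|target_corr| must be < 1")
  d <- dim(source$data)
  s <- as.numeric(source$data)
  s0 <- standardize(s)
  with_seed(seed, {
    noise <- gauss_smooth_periodic(array(rnorm(prod(d)), dim = d), 2)
    if (target_modality == "T2w_like") {
      z <- standardize(as.numeric(source$data)^1.5)   # monotone transform
      c1 <- cor(z, s0)
      if (abs(target_corr) >= abs(c1)) {
        stopf("target correlation %g exceeds what the monotone transform allows (%.3f)",
              target_corr, c1)
      }
      e <- standardize(orthogonalize(as.numeric(noise), list(s0, z)))
      a <- target_corr / c1
      t_raw <- a * z + sqrt(1 - a^2) * e
    } else {
      f <- orientation_feature(source$data)
      fp <- standardize(orthogonalize(as.numeric(f), list(s0)))
      e <- standardize(orthogonalize(as.numeric(noise), list(s0, fp)))
      resid <- sqrt(1 - target_corr^2)
      cf <- 0.6 * resid
      be <- sqrt(resid^2 - cf^2)
      t_raw <- target_corr * s0 + cf * fp + be * e
    }
    t_raw <- (t_raw - min(t_raw)) / (max(t_raw) - min(t_raw))
    volume(array(t_raw, dim = d), source$voxel_size_um, target_modality,
           paste0(source$id, "_", tolower(substr(target_modality, 1, 2))))
  })
}

# Orientation feature: magnitude of a directionally weighted intensity
# gradient (central differences), emulating contrast driven by local
# anisotropic organisation rather than by intensity itself.
#' @keywords internal
orientation_feature <- function(a) {
  d <- dim(a)
  grad <- function(axis) {
    ip <- reflect_index(seq_len(d[axis]) + 1L, d[axis])
    im <- reflect_index(seq_len(d[axis]) - 1L, d[axis])
    switch(axis,
           `1` = (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) / 2,
           `2` = (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) / 2,
           `3` = (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) / 2)
  }
  w <- c(1, 0.5, 0.25)   # fixed anisotropic direction weighting
  g <- sqrt(w[1] * grad(1L)^2 + w[2] * grad(2L)^2 + w[3] * grad(3L)^2)
  rng <- max(g) - min(g)
  if (rng == 0) array(0, dim = d) else (g - min(g)) / rng
}

#' Generate a dataset of co-registered modality triples
#'
#' Draws `config$n_volumes` independent phantoms; for each, derives the
#' companion "T2w-like" and "FA-like" contrasts at the configured target
#' correlations.  A manifest records every per-volume seed so any volume can
#' be regenerated in isolation.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional directory; when given, all volumes are written as
#'   `.nii.gz` and the manifest as `manifest.yaml` (requires the `yaml`
#'   package).
#' @param overwrite overwrite an existing non-empty `out_dir`?
#' @return A list with `volumes` (a list of `list(AF_like, T2w_like,
#'   FA_like)` triples) and `manifest`.
#' @export
generate_dataset <- function(config, out_dir = NULL, overwrite = FALSE) {
  if (!inherits(config, "voxsr_phantom_config")) {
    stopf("`config` must come from phantom_config()")
  }
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max %/% 2L, 3L * config$n_volumes))
  triples <- vector("list", config$n_volumes)
  manifest <- list(config = unclass(config), volumes = list())
  for (i in seq_len(config$n_volumes)) {
    sd3 <- seeds[(3L * i - 2L):(3L * i)]
    id <- sprintf("phantom%03d", i)
    af <- generate_phantom(config, seed = sd3[1], id = id)
    t2 <- derive_modality(af, "T2w_like", config$target_cross_correlation, sd3[2])
    fa <- derive_modality(af, "FA_like", config$fa_cross_correlation, sd3[3])
    triples[[i]] <- list(AF_like = af, T2w_like = t2, FA_like = fa)
    manifest$volumes[[i]] <- list(id = id, seeds = as.integer(sd3))
  }
  out <- list(volumes = triples, manifest = manifest)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
      stopf("`out_dir` %s exists and is not empty; set overwrite = TRUE", out_dir)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tr in triples) {
      for (m in names(tr)) {
        write_volume(tr[[m]], file.path(out_dir,
                                        paste0(tr[[m]]$id, "_", m, ".nii.gz")))
      }
    }
    if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    } else {
      writeLines(deparse(manifest), file.path(out_dir, "manifest.R"))
    }
  }
  out
}
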