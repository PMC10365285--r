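#' Resampling plan between a training pair of resolutions
#'
#' Records the high-resolution (target) and low-resolution (input) voxel
#' sizes of a super-resolution pair, e.g. 200 -> 100 micrometres; the factor
#' between them must be an exact integer.
#'
#' @param hr_voxel_um high-resolution (training target) voxel size.
#' @param lr_voxel_um low-resolution (network input) voxel size.
#' @return A `voxsr_resample_plan`.
#' @export
resample_plan <- function(hr_voxel_um, lr_voxel_um) {
  if (hr_voxel_um <= 0 || lr_voxel_um <= 0) stopf("voxel sizes must be positive")
  f <- lr_voxel_um / hr_voxel_um
  if (abs(f - round(f)) > 1e-9) {
    stopf("lr/hr voxel ratio %g is not an integer", f)
  }
  structure(list(source_voxel_um = hr_voxel_um, target_voxel_um = lr_voxel_um,
                 factor = as.integer(round(f))),
            class = "voxsr_resample_plan")
}

#' Down-sample a volume by block averaging
#'
#' Simulates acquisition at lower resolution: each output voxel is the
#' arithmetic mean of its `factor`^3 source block (boxcar averaging, no
#' anti-alias filter).  Trailing voxels that do not fill a block are
#' dropped, never padded.
#'
#' @param v a `voxsr_volume`.
#' @param factor positive integer down-sampling factor.
#' @return A `voxsr_volume` with `voxel_size_um` multiplied by `factor`.
#' @export
block_average <- function(v, factor) {
  check_volume(v)
  factor <- as.integer(factor)
  if (factor < 1L) stopf("`factor` must be >= 1")
  if (factor == 1L) return(v)
  d <- dim(v$data)
  if (any(d < factor)) {
    stopf("factor %d exceeds a volume dimension (%s)", factor,
          paste(d, collapse = "x"))
  }
  out <- .block_average3(v$data, d, factor)
  as_volume_like(out, v, voxel_size_um = v$voxel_size_um * factor)
}

# Catmull-Rom (cubic convolution, a = -0.5) interpolation weights for the
# voxel-centre aligned upsampling grid along one axis; returns a dense
# n_out x n_in matrix with mirror boundary handling.
#' @keywords internal
cubic_axis_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  # output voxel centre positions in (0-based) input index coordinates
  xs <- (seq_len(n_out) - 0.5) / factor - 0.5
  base <- floor(xs)
  t <- xs - base
  w <- cbind(((-0.5 * t + 1) * t - 0.5) * t,
             ((1.5 * t - 2.5) * t) * t + 1,
             ((-1.5 * t + 2) * t + 0.5) * t,
             (0.5 * t - 0.5) * t^2)
  M <- matrix(0, n_out, n_in)
  for (j in 1:4) {
    idx <- reflect_index(as.integer(base) + j - 1L, n_in)  # taps base-1 .. base+2, 1-based
    M[cbind(seq_len(n_out), idx)] <- M[cbind(seq_len(n_out), idx)] + w[, j]
  }
  M
}

#' Up-sample a volume by tricubic interpolation
#'
#' Separable Catmull-Rom cubic interpolation on the voxel-centre grid with
#' mirror (reflect) boundary handling; this is the fixed pre-upsampling the
#' SR networks expect before patch extraction.
#'
#' @param v a `voxsr_volume`.
#' @param factor positive integer upsampling factor.
#' @return A `voxsr_volume` with each dimension multiplied by `factor` and
#'   `voxel_size_um` divided by `factor`.
#' @export
cubic_upsample <- function(v, factor) {
  check_volume(v)
  factor <- as.integer(factor)
  if (factor < 1L) stopf("`factor` must be >= 1")
  if (factor == 1L) return(v)
  d <- dim(v$data)
  out <- v$data
  for (ax in 1:3) out <- axis_apply(out, cubic_axis_matrix(d[ax], factor), ax)
  as_volume_like(out, v, voxel_size_um = v$voxel_size_um / factor)
}

#' Build a co-registered low/high-resolution training pair
#'
#' From a native high-resolution volume: the target `hr` is the volume block
#' averaged to the plan's high resolution, and `lr_upsampled` is the volume
#' block averaged further to the plan's low resolution and then cubically
#' up-sampled back onto `hr`'s grid, so that both share one grid.
#'
#' @param v native `voxsr_volume`; its voxel size must divide both plan
#'   resolutions exactly.
#' @param plan a [resample_plan()].
#' @return `list(lr_upsampled, hr)`, two volumes of identical dimensions.
#' @export
make_lr_hr_pair <- function(v, plan) {
  check_volume(v)
  if (!inherits(plan, "voxsr_resample_plan")) {
    stopf("`plan` must come from resample_plan()")
  }
  f_hr <- plan$source_voxel_um / v$voxel_size_um
  if (abs(f_hr - round(f_hr)) > 1e-9 || f_hr < 1 - 1e-9) {
    stopf("volume voxel size %g um does not divide the plan's high resolution %g um",
          v$voxel_size_um, plan$source_voxel_um)
  }
  hr <- block_average(v, as.integer(round(f_hr)))
  lr <- block_average(hr, plan$factor)
  lr_up <- cubic_upsample(lr, plan$factor)
  # block_average floors odd dimensions, so crop hr to the recovered grid
  dlu <- dim(lr_up$data); dhr <- dim(hr$data)
  if (any(dlu != dhr)) {
    hr <- as_volume_like(hr$data[seq_len(dlu[1]), seq_len(dlu[2]),
                                 seq_len(dlu[3]), drop = FALSE], hr)
  }
  list(lr_upsampled = lr_up, hr = hr)
}
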