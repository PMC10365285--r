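#' Construct a 3D volume
#'
#' The universal data container of the pipeline: a 3D scalar intensity grid
#' with an isotropic voxel size in micrometres and a modality tag.
#'
#' @param data 3D numeric array of finite intensities.
#' @param voxel_size_um positive isotropic voxel size in micrometres.
#' @param modality one of `"AF_like"`, `"T2w_like"`, `"FA_like"`, `"other"`.
#' @param id character identifier.
#' @return An object of class `voxsr_volume`.
#' @export
volume <- function(data, voxel_size_um, modality = "other", id = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("`data` must be a 3D array")
  }
  if (!all(is.finite(data))) stopf("volume intensities must all be finite")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0) {
    stopf("`voxel_size_um` must be a single positive number")
  }
  modality <- match.arg(modality, c("AF_like", "T2w_like", "FA_like", "other"))
  structure(
    list(data = data, voxel_size_um = as.numeric(voxel_size_um),
         modality = modality, id = as.character(id)),
    class = "voxsr_volume"
  )
}

#' @export
print.voxsr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxsr_volume> %s  %d x %d x %d voxels @ %g um  [%s]\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              d[1], d[2], d[3], x$voxel_size_um, x$modality))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxsr_volume <- function(x) dim(x$data)

#' @keywords internal
as_volume_like <- function(data, template, voxel_size_um = NULL,
                           modality = NULL, id = NULL) {
  volume(data,
         voxel_size_um %||% template$voxel_size_um,
         modality %||% template$modality,
         id %||% template$id)
}

#' @keywords internal
check_volume <- function(v, arg = "v") {
  if (!inherits(v, "voxsr_volume")) stopf("`%s` must be a voxsr_volume", arg)
  invisible(v)
}

#' Write a volume to a NIfTI file
#'
#' Stores the voxel size (in mm, per NIfTI convention) in the header.
#'
#' @param v a `voxsr_volume`.
#' @param path output path, typically ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  check_volume(v)
  mm <- v$voxel_size_um / 1000
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- c(mm, mm, mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI file
#'
#' @param path NIfTI file path.
#' @param modality modality tag to attach.
#' @param id identifier; defaults to the file name.
#' @return A `voxsr_volume`; voxel size is taken from the header (mm,
#'   converted to micrometres).
#' @export
read_volume <- function(path, modality = "other", id = NULL) {
  img <- RNifti::readNifti(path)
  vox_mm <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  volume(arr, vox_mm * 1000, modality, id %||% basename(path))
}

#' Write a volume as a multi-page TIFF
#'
#' One page per axial (third-axis) slice; intensities must lie in [0, 1].
#' Requires the `tiff` package.
#'
#' @param v a `voxsr_volume` with intensities in [0, 1].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(v, path) {
  check_volume(v)
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stopf("the `tiff` package is required for TIFF export")
  }
  if (min(v$data) < 0 || max(v$data) > 1) {
    stopf("TIFF export requires intensities in [0, 1]")
  }
  pages <- lapply(seq_len(dim(v$data)[3]), function(k) v$data[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
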