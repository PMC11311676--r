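#' MRI volume container
#'
#' A lightweight wrapper around a 3D intensity array with voxel spacing
#' (in mm), a modality tag and a physical origin. All operators in the
#' package consume and return `mri_volume` objects. The axis order is
#' (x, y, z); voxel indices are 0-based in the box conventions used by
#' [bounding_box()] and [make_windows()].
#'
#' @param data A 3D numeric array of intensities (all finite).
#' @param spacing Voxel spacing in mm, a positive triple. Default `c(1, 1, 1)`.
#' @param modality One of `"T2W"`, `"ADC"`, `"DWI"`.
#' @param origin Physical offset of the first voxel, a triple. Default zeros.
#'
#' @return An object of class `mri_volume` with fields `data`, `spacing`,
#'   `modality` and `origin`.
#' @examples
#' vol <- mri_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(0.75, 0.75, 3))
#' dim(vol$data)
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1),
                       modality = c("T2W", "ADC", "DWI"),
                       origin = c(0, 0, 0)) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (!all(is.finite(data))) abort("`data` must contain only finite intensities.")
  assert_triple(spacing, "spacing", positive = TRUE)
  assert_triple(origin, "origin", positive = FALSE)
  structure(
    list(data = data, spacing = as.numeric(spacing),
         modality = modality, origin = as.numeric(origin)),
    class = "mri_volume"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mri_volume %s  %d x %d x %d voxels @ (%g, %g, %g) mm>\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

is_mri_volume <- function(x) inherits(x, "mri_volume")

#' Read and write MRI volumes as NIfTI
#'
#' Thin wrappers around RNifti. Spacing is taken from (written to) the NIfTI
#' `pixdim` header field.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param modality Modality tag to attach on read.
#' @param vol An [mri_volume()].
#' @return `read_mri_volume()` returns an [mri_volume()]; `write_mri_volume()`
#'   returns `path` invisibly.
#' @export
read_mri_volume <- function(path, modality = c("T2W", "ADC", "DWI")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  mri_volume(array(as.numeric(img), dim(img)[1:3]), spacing = spacing,
             modality = modality)
}

#' @rdname read_mri_volume
#' @export
write_mri_volume <- function(vol, path) {
  stopifnot(is_mri_volume(vol))
  img <- RNifti::asNifti(vol$data, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
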