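#' 3D local binary pattern histogram
#'
#' Per-voxel 3D LBP codes over the 6 face-connected neighbours: bit k of the
#' code is 1 when the neighbour's intensity is greater than or equal to the
#' centre voxel (ties encode as 1). Neighbour order is fixed as
#' (+x, -x, +y, -y, +z, -z) with bit weights 1, 2, 4, 8, 16, 32, giving
#' 2^6 = 64 possible codes. Codes are computed on interior voxels (all six
#' neighbours in bounds) and histogrammed into 64 bins, normalised to sum
#' to 1. A constant volume puts all mass in the all-ones code (bin 64).
#'
#' @param vol An [mri_volume()] or plain 3D numeric array, at least 3 voxels
#'   per axis.
#' @return A named numeric vector of 64 bin frequencies (`lbp_b00` ...
#'   `lbp_b63`), summing to 1.
#' @export
lbp_3d <- function(vol) {
  x <- if (is_mri_volume(vol)) vol$data else vol
  d <- dim(x)
  if (any(d < 3)) abort("3D LBP needs at least 3 voxels per axis.")
  xs <- 2:(d[1] - 1); ys <- 2:(d[2] - 1); zs <- 2:(d[3] - 1)
  ctr <- x[xs, ys, zs, drop = FALSE]
  code <- array(0L, dim = dim(ctr))
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    nb <- x[xs + s[1], ys + s[2], zs + s[3], drop = FALSE]
    code <- code + bitwShiftL(1L, k - 1L) * (nb >= ctr)
  }
  h <- tabulate(as.integer(code) + 1L, nbins = 64L)
  h <- h / sum(h)
  names(h) <- sprintf("lbp_b%02d", 0:63)
  h
}
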