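#' Orientation axes for the 3D HOG descriptor
#'
#' 16 unit axes derived from the regular icosahedron: its 12 vertices give 6
#' axes and its 20 face centres give 10 axes after merging antipodal
#' directions (gradients g and -g fall in the same bin). The axes are
#' canonicalised (first nonzero component positive) and ordered
#' lexicographically, so the bin order is deterministic.
#'
#' @return A 16 x 3 matrix of unit vectors.
#' @export
hog_axes_3d <- function() {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1))
  )
  dodec <- rbind(
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    cbind(0, c(1, 1, -1, -1) / phi, c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1) / phi, c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1) / phi)
  )
  canon <- function(m) {
    m <- m / sqrt(rowSums(m^2))
    for (r in seq_len(nrow(m))) {
      nz <- which(abs(m[r, ]) > 1e-9)[1]
      if (m[r, nz] < 0) m[r, ] <- -m[r, ]
    }
    m <- round(m, 9)
    unique(m)
  }
  axes <- rbind(canon(verts), canon(dodec))
  axes[order(axes[, 1], axes[, 2], axes[, 3]), ]
}

# numpy.gradient-style derivative along one axis: central differences in the
# interior, one-sided at the two boundary faces; divided by the spacing.
gradient_axis <- function(x, axis, spacing) {
  d <- dim(x)
  n <- d[axis]
  idx_l <- function(i) {
    ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix[[axis]] <- i
    ix
  }
  sub <- function(i) do.call(`[`, c(list(x), idx_l(i), list(drop = FALSE)))
  g <- array(0, dim = d)
  if (n >= 3) {
    g_int <- (sub(3:n) - sub(1:(n - 2))) / (2 * spacing)
    ix <- idx_l(2:(n - 1))
    g[ix[[1]], ix[[2]], ix[[3]]] <- g_int
  }
  ix <- idx_l(1L)
  g[ix[[1]], ix[[2]], ix[[3]]] <- (sub(2L) - sub(1L)) / spacing
  ix <- idx_l(n)
  g[ix[[1]], ix[[2]], ix[[3]]] <- (sub(n) - sub(n - 1L)) / spacing
  g
}

#' 3D histogram of oriented gradients
#'
#' Spacing-aware gradients (central differences in the interior, one-sided
#' at the boundary) are binned, per spatial cell, into 16 solid-angle
#' orientation bins (see [hog_axes_3d()]) weighted by gradient magnitude;
#' each voxel contributes to the axis maximising `|g . axis|` (ties to the
#' lowest bin index). Each cell histogram is L2-normalised with an epsilon
#' guard, so a constant volume yields an all-zero descriptor. The default
#' 2 x 2 x 1 cell grid respects the thin z axis of the anisotropic volumes;
#' 4 cells x 16 bins = 64 values.
#'
#' @param vol An [mri_volume()] or plain 3D array (>= 2 voxels per axis).
#' @param spacing Voxel spacing; taken from `vol` when it is an
#'   [mri_volume()].
#' @param cells Cell grid, default `c(2, 2, 1)`.
#' @param bins Number of orientation bins (must match `nrow(hog_axes_3d())`).
#' @return A named numeric vector of `prod(cells) * bins` values
#'   (`hog_c<cell>_b<bin>`).
#' @export
hog_3d <- function(vol, spacing = NULL, cells = c(2, 2, 1), bins = 16L) {
  x <- if (is_mri_volume(vol)) vol$data else vol
  if (is.null(spacing)) spacing <- if (is_mri_volume(vol)) vol$spacing else c(1, 1, 1)
  d <- dim(x)
  if (any(d < 2)) abort("3D HOG needs at least 2 voxels per axis.")
  axes <- hog_axes_3d()
  if (bins != nrow(axes)) abort("`bins` must equal the number of orientation axes (16).")
  gx <- gradient_axis(x, 1, spacing[1])
  gy <- gradient_axis(x, 2, spacing[2])
  gz <- gradient_axis(x, 3, spacing[3])
  G <- cbind(as.vector(gx), as.vector(gy), as.vector(gz))
  mag <- sqrt(rowSums(G^2))
  proj <- abs(G %*% t(axes))
  bin <- max.col(proj, ties.method = "first")
  cell_of <- function(i, n, nc) pmin(nc, 1L + ((i - 1L) * nc) %/% n)
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = d[1] * d[2])
  cell <- (cell_of(iz, d[3], cells[3]) - 1L) * cells[1] * cells[2] +
    (cell_of(iy, d[2], cells[2]) - 1L) * cells[1] + cell_of(ix, d[1], cells[1])
  n_cells <- prod(cells)
  idx <- (cell - 1L) * bins + bin
  h <- numeric(n_cells * bins)
  acc <- rowsum(mag, group = idx)
  h[as.integer(rownames(acc))] <- acc[, 1]
  out <- numeric(0)
  for (cc in seq_len(n_cells)) {
    hc <- h[((cc - 1) * bins + 1):(cc * bins)]
    hc <- hc / sqrt(sum(hc^2) + 1e-18)
    out <- c(out, hc)
  }
  names(out) <- sprintf("hog_c%d_b%02d",
                        rep(seq_len(n_cells), each = bins),
                        rep(seq_len(bins), times = n_cells))
  out
}
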