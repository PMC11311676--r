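#' Preprocessing configuration
#'
#' Target geometry and interpolation/normalisation choices applied to every
#' sequence of a study: per-volume z-score normalisation over nonzero voxels,
#' resampling to a fixed voxel spacing (linear for images, nearest-neighbour
#' for masks), and a centred crop/pad to a fixed grid.
#'
#' @param target_spacing_mm Target spacing, default `c(0.75, 0.75, 3)` mm.
#' @param target_shape Target grid, default `c(149, 149, 32)` voxels.
#' @param normalization Currently `"zscore"` or `"none"`.
#' @param image_interpolation `"linear"` (default) or `"nearest"`.
#' @param mask_interpolation `"nearest"` (fixed default).
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(target_spacing_mm = c(0.75, 0.75, 3),
                           target_shape = c(149, 149, 32),
                           normalization = c("zscore", "none"),
                           image_interpolation = c("linear", "nearest"),
                           mask_interpolation = "nearest") {
  assert_triple(target_spacing_mm, "target_spacing_mm")
  assert_triple(target_shape, "target_shape", integer = TRUE)
  structure(
    list(target_spacing_mm = as.numeric(target_spacing_mm),
         target_shape = as.integer(target_shape),
         normalization = match.arg(normalization),
         image_interpolation = match.arg(image_interpolation),
         mask_interpolation = mask_interpolation),
    class = "preproc_config"
  )
}

#' Intensity normalisation
#'
#' Z-score normalisation over the foreground (nonzero) voxels: the foreground
#' is shifted/scaled to mean 0 and SD 1; exact-zero voxels are preserved.
#' Shape and spacing are unchanged. A constant volume has no scale and is
#' mapped to all zeros with a warning. The operation is idempotent up to
#' floating-point tolerance.
#'
#' @param vol An [mri_volume()].
#' @param method `"zscore"` or `"none"`.
#' @return The normalised [mri_volume()].
#' @export
normalize_volume <- function(vol, method = c("zscore", "none")) {
  method <- match.arg(method)
  stopifnot(is_mri_volume(vol))
  if (method == "none") return(vol)
  x <- vol$data
  fg <- x != 0
  v <- x[fg]
  if (length(unique(as.vector(v))) < 2L) {
    warn("Constant volume under z-score normalisation; returning all zeros.")
    x[] <- 0
  } else {
    x[fg] <- (v - mean(v)) / sd(v)
  }
  mri_volume(x, spacing = vol$spacing, modality = vol$modality, origin = vol$origin)
}

# 1D interpolation weight matrix mapping n_in samples at spacing s_in to
# n_out samples at spacing s_out (voxel-centre aligned at the origin).
interp_weights <- function(n_in, s_in, n_out, s_out, mode) {
  pos <- ((seq_len(n_out) - 0.5) * s_out) / s_in - 0.5  # 0-based input coords
  pos <- pmin(pmax(pos, 0), n_in - 1)
  W <- matrix(0, n_out, n_in)
  if (n_in == 1) {
    W[, 1] <- 1
    return(W)
  }
  if (mode == "nearest") {
    i <- pmin(floor(pos + 0.5), n_in - 1)
    W[cbind(seq_len(n_out), i + 1)] <- 1
  } else {
    i0 <- pmin(floor(pos), n_in - 2)
    i0 <- pmax(i0, 0)
    t <- pos - i0
    W[cbind(seq_len(n_out), i0 + 1)] <- W[cbind(seq_len(n_out), i0 + 1)] + (1 - t)
    W[cbind(seq_len(n_out), i0 + 2)] <- W[cbind(seq_len(n_out), i0 + 2)] + t
  }
  W
}

apply_axis_matrix <- function(arr, axis, W) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- W %*% matrix(a, nrow = d[axis])
  out_d <- d[perm]
  out_d[1] <- nrow(W)
  aperm(array(m, out_d), order(perm))
}

# Resample a plain array from `spacing` to `target_spacing`.
resample_array <- function(arr, spacing, target_spacing, mode = "linear") {
  d <- dim(arr)
  for (axis in 1:3) {
    if (isTRUE(all.equal(spacing[axis], target_spacing[axis]))) next
    n_out <- max(1L, as.integer(round(d[axis] * spacing[axis] / target_spacing[axis])))
    W <- interp_weights(dim(arr)[axis], spacing[axis], n_out, target_spacing[axis], mode)
    arr <- apply_axis_matrix(arr, axis, W)
  }
  arr
}

#' Resample a volume to a target voxel spacing
#'
#' The grid size is rescaled by the spacing ratio (rounded). Linear
#' interpolation is the default for images; use `mode = "nearest"` for label
#' maps. A volume already at the target spacing is returned unchanged.
#'
#' @param vol An [mri_volume()].
#' @param target_spacing Positive spacing triple in mm.
#' @param mode `"linear"` or `"nearest"`.
#' @return The resampled [mri_volume()].
#' @export
resample_volume <- function(vol, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is_mri_volume(vol))
  assert_triple(target_spacing, "target_spacing")
  if (isTRUE(all.equal(vol$spacing, as.numeric(target_spacing)))) return(vol)
  out <- resample_array(vol$data, vol$spacing, target_spacing, mode)
  mri_volume(out, spacing = as.numeric(target_spacing), modality = vol$modality,
             origin = vol$origin)
}

# Centred crop/pad of a plain array to `target` (zero fill).
crop_pad_array <- function(arr, target, fill = 0) {
  d <- dim(arr)
  out <- array(fill, dim = target)
  src_lo <- integer(3); src_hi <- integer(3)
  dst_lo <- integer(3); dst_hi <- integer(3)
  for (a in 1:3) {
    if (d[a] >= target[a]) {
      src_lo[a] <- floor((d[a] - target[a]) / 2) + 1L
      src_hi[a] <- src_lo[a] + target[a] - 1L
      dst_lo[a] <- 1L; dst_hi[a] <- target[a]
    } else {
      dst_lo[a] <- floor((target[a] - d[a]) / 2) + 1L
      dst_hi[a] <- dst_lo[a] + d[a] - 1L
      src_lo[a] <- 1L; src_hi[a] <- d[a]
    }
  }
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Crop or pad a volume to a fixed grid
#'
#' Centred crop for oversized axes, symmetric zero-padding for undersized
#' ones; always well defined. Spacing is unchanged.
#'
#' @param vol An [mri_volume()].
#' @param target_shape Positive integer triple, e.g. `c(149, 149, 32)`.
#' @return The cropped/padded [mri_volume()].
#' @export
crop_pad_volume <- function(vol, target_shape) {
  stopifnot(is_mri_volume(vol))
  assert_triple(target_shape, "target_shape", integer = TRUE)
  if (identical(dim(vol$data), as.integer(target_shape))) return(vol)
  out <- crop_pad_array(vol$data, as.integer(target_shape))
  mri_volume(out, spacing = vol$spacing, modality = vol$modality, origin = vol$origin)
}

#' Preprocess a full study case
#'
#' Applies normalisation, resampling and crop/pad to all three sequences, and
#' nearest-neighbour resampling plus the same crop/pad to every mask. Labels
#' are untouched. Re-applying to an already-preprocessed case is a fixed
#' point up to floating-point tolerance.
#'
#' @param case A `study_case` (see [generate_case()]).
#' @param cfg A [preproc_config()].
#' @return The preprocessed `study_case`.
#' @export
preprocess_study <- function(case, cfg = preproc_config()) {
  stopifnot(inherits(case, "study_case"), inherits(cfg, "preproc_config"))
  for (s in c("t2w", "adc", "dwi")) {
    if (is.null(case[[s]])) {
      abort(sprintf("Missing sequence `%s` (%s): all three sequences are required.",
                    s, toupper(s)))
    }
  }
  proc_seq <- function(vol) {
    v <- normalize_volume(vol, cfg$normalization)
    v <- resample_volume(v, cfg$target_spacing_mm, cfg$image_interpolation)
    crop_pad_volume(v, cfg$target_shape)
  }
  proc_mask <- function(mask) {
    if (is.null(mask)) return(NULL)
    m <- resample_array(mask + 0, case$spacing, cfg$target_spacing_mm,
                        cfg$mask_interpolation)
    m <- crop_pad_array(m, cfg$target_shape)
    array(as.integer(m > 0.5), dim = cfg$target_shape)
  }
  out <- case
  for (s in c("t2w", "adc", "dwi")) out[[s]] <- proc_seq(case[[s]])
  out$gland_mask <- proc_mask(case$gland_mask)
  out$pz_mask <- proc_mask(case$pz_mask)
  out$lesions <- lapply(case$lesions, function(l) {
    list(mask = proc_mask(l$mask), label = l$label)
  })
  out$spacing <- cfg$target_spacing_mm
  out
}
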