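#' Axis-aligned bounding box of a mask
#'
#' The tightest box containing all nonzero mask voxels, expanded by a margin
#' and clamped to the grid. Boxes use 0-based voxel indices and half-open
#' intervals `[lo, hi)` on the (x, y, z) axes.
#'
#' @param mask A 3D 0/1 (or logical) array; must be nonempty.
#' @param margin_voxels Expansion per axis; default `c(2, 2, 0)` captures
#'   peritumoral in-plane texture without crossing slices.
#' @param kind Region kind tag.
#' @return A `region_box`: list with integer `lo`, `hi`, and `kind`.
#' @examples
#' m <- array(0L, c(20, 20, 8)); m[11, 5, 3] <- 1L
#' bounding_box(m, margin_voxels = c(0, 0, 0))
#' @export
bounding_box <- function(mask, margin_voxels = c(2, 2, 0), kind = "region") {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("Cannot compute a bounding box of an empty mask.")
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - 1L - margin_voxels, 0)
  hi <- pmin(apply(idx, 2, max) + margin_voxels, d)
  region_box(lo, hi, kind = kind, grid = d)
}

#' @rdname bounding_box
#' @param lo,hi 0-based half-open bounds.
#' @param grid Optional grid shape for bounds checking.
#' @export
region_box <- function(lo, hi, kind = "region", grid = NULL) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo >= hi)) abort("Box must satisfy lo < hi componentwise.")
  if (!is.null(grid) && (any(lo < 0) || any(hi > grid))) {
    abort("Box exceeds grid bounds.")
  }
  structure(list(lo = lo, hi = hi, kind = kind), class = "region_box")
}

# Extract the sub-array covered by a half-open box.
crop_box <- function(arr, box) {
  arr[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
      (box$lo[3] + 1):box$hi[3], drop = FALSE]
}

# Trilinear (or nearest) resize of an array to an exact target shape.
resize_array_to <- function(arr, target_shape, mode = "linear") {
  d <- dim(arr)
  for (axis in 1:3) {
    if (d[axis] == target_shape[axis]) next
    W <- interp_weights(dim(arr)[axis], 1, target_shape[axis],
                        d[axis] / target_shape[axis], mode)
    arr <- apply_axis_matrix(arr, axis, W)
  }
  arr
}

# Fixed per-kind sub-volume shapes so feature support is consistent across
# cases; chosen near the upper-quantile boxes of the default phantom anatomy.
default_region_shape <- function(kind) {
  switch(kind,
         gland = c(64L, 56L, 12L),
         pz = c(56L, 32L, 8L),
         lesion = c(24L, 24L, 6L),
         NULL)
}

#' Build classifier inputs for a regional setting
#'
#' Produces the per-case inputs of the four regional classification
#' settings: `"whole"` (full volumes, all three sequences), `"gland"`
#' (gland bounding box, all three sequences), `"pz"` (peripheral-zone box,
#' ADC only), and `"lesion"` (one entry per lesion, each with that lesion's
#' own label). Mask-derived sub-volumes are resized to a fixed per-kind
#' shape so that downstream feature extraction sees consistent support;
#' pass `region_shape = "native"` to keep the raw boxes.
#'
#' A benign case in lesion mode yields an empty list (a valid outcome, not
#' an error).
#'
#' @param case A `study_case`.
#' @param region One of `"whole"`, `"gland"`, `"pz"`, `"lesion"`.
#' @param region_shape `NULL` for the per-kind default fixed shape, a voxel
#'   triple, or `"native"` for raw boxes.
#' @param margin_voxels Bounding-box margin, default `c(2, 2, 0)`.
#' @param masked Zero out voxels outside the source mask before cropping.
#' @return A list of entries `list(volumes, label, adc_only, box)`, where
#'   `volumes` is a named list of [mri_volume()]s.
#' @export
extract_region_inputs <- function(case, region = c("whole", "gland", "pz", "lesion"),
                                  region_shape = NULL, margin_voxels = c(2, 2, 0),
                                  masked = FALSE) {
  region <- match.arg(region)
  if (region == "whole") {
    return(list(list(volumes = list(t2w = case$t2w, adc = case$adc, dwi = case$dwi),
                     label = case$label, adc_only = FALSE, box = NULL)))
  }
  if (is.null(region_shape)) region_shape <- default_region_shape(region)
  native <- identical(region_shape, "native")

  make_entry <- function(mask, mods, label, kind) {
    box <- bounding_box(mask, margin_voxels, kind = kind)
    vols <- lapply(mods, function(s) {
      vol <- case[[s]]
      x <- vol$data
      if (masked) x <- x * (mask != 0)
      sub <- crop_box(x, box)
      sp <- vol$spacing
      if (!native) {
        sp <- sp * dim(sub) / region_shape
        sub <- resize_array_to(sub, region_shape, "linear")
      }
      mri_volume(sub, spacing = sp, modality = vol$modality)
    })
    names(vols) <- mods
    list(volumes = vols, label = label, adc_only = identical(mods, "adc"), box = box)
  }

  if (region == "gland") {
    if (is.null(case$gland_mask)) abort("Gland mask required for the gland region.")
    return(list(make_entry(case$gland_mask, c("t2w", "adc", "dwi"),
                           case$label, "gland")))
  }
  if (region == "pz") {
    if (is.null(case$pz_mask)) abort("PZ mask required for the pz region.")
    return(list(make_entry(case$pz_mask, "adc", case$label, "pz")))
  }
  # lesion mode: one entry per lesion, labelled per lesion
  lapply(case$lesions, function(l) {
    make_entry(l$mask, c("t2w", "adc", "dwi"), l$label, "lesion")
  })
}

#' Tabulate the region boxes of a case for audit
#'
#' @param case A `study_case`.
#' @param regions Region kinds to include.
#' @return A tibble with `case_id`, `kind`, `lo_x`..`hi_z` (0-based,
#'   half-open) and `label`, one row per box; writable as a BED-like TSV.
#' @export
region_boxes <- function(case, regions = c("gland", "pz", "lesion")) {
  rows <- list()
  for (r in regions) {
    entries <- tryCatch(
      extract_region_inputs(case, r, region_shape = "native"),
      error = function(e) list()
    )
    for (e in entries) {
      b <- e$box
      rows[[length(rows) + 1]] <- tibble::tibble(
        case_id = case$case_id, kind = b$kind,
        lo_x = b$lo[1], lo_y = b$lo[2], lo_z = b$lo[3],
        hi_x = b$hi[1], hi_y = b$hi[2], hi_z = b$hi[3],
        label = e$label
      )
    }
  }
  dplyr::bind_rows(rows)
}
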