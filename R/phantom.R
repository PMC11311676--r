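#' Texture parameter sets for the synthetic phantom
#'
#' Per-sequence, per-class (benign vs malignant) intensity texture parameters:
#' mean, standard deviation, and correlation length (mm) of a Gaussian random
#' field. The malignant class has finer texture (shorter correlation length)
#' and a shifted mean; ADC lesions are hypointense, DWI lesions hyperintense,
#' and T2W intermediate, mimicking multiparametric MRI appearance
#' qualitatively.
#'
#' The `"strong"` preset separates benign and malignant means by at least
#' five noise standard deviations on every sequence, a regime in which the
#' downstream lesion-region classifiers are expected to recover the class
#' signal almost perfectly.
#'
#' @param contrast `"moderate"` (default) or `"strong"`.
#' @return A nested list `params[[sequence]][[class]]` with fields `mean`,
#'   `sd`, `corr_mm`.
#' @export
phantom_texture <- function(contrast = c("moderate", "strong")) {
  contrast <- match.arg(contrast)
  mal_means <- switch(contrast,
    moderate = c(t2w = 80, adc = 105, dwi = 110),
    strong   = c(t2w = 60, adc = 80,  dwi = 140)
  )
  ben <- list(t2w = 100, adc = 140, dwi = 80)
  out <- lapply(c(t2w = "t2w", adc = "adc", dwi = "dwi"), function(s) {
    list(
      benign    = list(mean = ben[[s]], sd = 10, corr_mm = 4.5),
      malignant = list(mean = unname(mal_means[[s]]), sd = 12, corr_mm = 2.2)
    )
  })
  out
}

#' Specification of a synthetic multiparametric MRI phantom
#'
#' Defines the geometry, texture and class composition of generated study
#' cases. The anatomy model is: gland = axis-aligned ellipsoid with semi-axes
#' `gland_radius_mm * c(1, 0.85, 0.7)`; peripheral zone (PZ) = the posterior
#' (+y) part of the outer ellipsoidal shell of thickness
#' `pz_shell_fraction` (as a fraction of the ellipsoidal radius); lesions =
#' spheres rejection-sampled inside the gland, 70% of them targeted at the
#' PZ, matching the clinical prior that about 70% of prostate lesions arise
#' there.
#'
#' @param grid_shape Voxel grid, default `c(149, 149, 32)`.
#' @param spacing_mm Voxel spacing in mm, default `c(0.75, 0.75, 3)`.
#' @param gland_radius_mm Largest gland semi-axis in mm.
#' @param pz_shell_fraction Fraction of the gland radius forming the
#'   posterior shell, in (0, 1).
#' @param lesion_count_range Integer interval for the number of lesions per
#'   case (malignant cases are forced to have at least one).
#' @param lesion_radius_mm_range Lesion radius interval in mm; radii must be
#'   smaller than the smallest gland semi-axis.
#' @param texture_params See [phantom_texture()].
#' @param noise_sd Standard deviation of additive voxel noise.
#' @param class_ratio Benign:malignant case proportion; default `c(718, 448)`,
#'   the composition of the motivating cohort.
#' @param seed Integer seed attached to the spec (used by [generate_cohort()]
#'   when no explicit seed is passed).
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48, 12), gland_radius_mm = 12)
#' case <- generate_case(spec, label = 1, seed = 7)
#' case$label
#' @export
phantom_spec <- function(grid_shape = c(149, 149, 32),
                         spacing_mm = c(0.75, 0.75, 3),
                         gland_radius_mm = 22,
                         pz_shell_fraction = 0.4,
                         lesion_count_range = c(0, 2),
                         lesion_radius_mm_range = c(4, 8),
                         texture_params = phantom_texture(),
                         noise_sd = 5,
                         class_ratio = c(718, 448),
                         seed = 1L) {
  assert_triple(grid_shape, "grid_shape", integer = TRUE)
  assert_triple(spacing_mm, "spacing_mm")
  stopifnot_scalar_number(gland_radius_mm, "gland_radius_mm", positive = TRUE)
  if (pz_shell_fraction <= 0 || pz_shell_fraction >= 1) {
    abort("`pz_shell_fraction` must lie strictly between 0 and 1.")
  }
  if (length(lesion_count_range) != 2L || any(lesion_count_range < 0) ||
      lesion_count_range[1] > lesion_count_range[2]) {
    abort("`lesion_count_range` must be a non-decreasing non-negative pair.")
  }
  if (length(lesion_radius_mm_range) != 2L || any(lesion_radius_mm_range <= 0) ||
      lesion_radius_mm_range[1] > lesion_radius_mm_range[2]) {
    abort("`lesion_radius_mm_range` must be a positive non-decreasing pair.")
  }
  if (length(class_ratio) != 2L || any(class_ratio <= 0)) {
    abort("`class_ratio` components must be positive.")
  }
  semi <- gland_radius_mm * c(1, 0.85, 0.7)
  extent <- grid_shape * spacing_mm
  if (any(2 * semi >= extent)) {
    abort("Gland does not fit inside the grid: reduce `gland_radius_mm`.")
  }
  if (lesion_radius_mm_range[2] >= min(semi)) {
    abort("Lesion radii must be smaller than the smallest gland semi-axis.")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
         gland_radius_mm = gland_radius_mm, gland_semi_mm = semi,
         pz_shell_fraction = pz_shell_fraction,
         lesion_count_range = as.integer(lesion_count_range),
         lesion_radius_mm_range = as.numeric(lesion_radius_mm_range),
         texture_params = texture_params, noise_sd = noise_sd,
         class_ratio = as.numeric(class_ratio), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Squared ellipsoidal radius of every voxel centre w.r.t. centre/semi (mm).
ellipsoid_rho2 <- function(shape, spacing, center, semi) {
  ax <- (((seq_len(shape[1]) - 0.5) * spacing[1] - center[1]) / semi[1])^2
  ay <- (((seq_len(shape[2]) - 0.5) * spacing[2] - center[2]) / semi[2])^2
  az <- (((seq_len(shape[3]) - 0.5) * spacing[3] - center[3]) / semi[3])^2
  array(rep(ax, times = shape[2] * shape[3]) +
          rep(rep(ay, each = shape[1]), times = shape[3]) +
          rep(az, each = shape[1] * shape[2]),
        dim = shape)
}

# One uniform draw from the interior of an ellipsoid (rejection from the cube).
runif_ellipsoid <- function(center, semi) {
  repeat {
    u <- runif(3, -1, 1)
    if (sum(u^2) <= 1) return(center + u * semi)
  }
}

# Draw lesion geometry and labels for one case. Pure function of
# (spec, label, seed); shared by generate_case() and cohort_manifest().
sample_case_layout <- function(spec, label, seed) {
  with_seed(derive_seed(seed, 1L), {
    rng <- spec$lesion_count_range
    n <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    if (label == 1L) n <- max(1L, n)
    lesions <- list()
    if (n > 0) {
      lab <- rep(0L, n)
      if (label == 1L) {
        lab[1] <- 1L
        if (n > 1) lab[-1] <- rbinom(n - 1L, 1L, 0.3)
      }
      center_mm <- spec$grid_shape * spec$spacing_mm / 2
      for (i in seq_len(n)) {
        r <- runif(1, spec$lesion_radius_mm_range[1], spec$lesion_radius_mm_range[2])
        shrunk <- spec$gland_semi_mm - r
        in_pz_target <- runif(1) < 0.7
        ctr <- NULL
        for (try in 1:200) {
          cand <- runif_ellipsoid(center_mm, shrunk)
          rho <- sqrt(sum(((cand - center_mm) / spec$gland_semi_mm)^2))
          pz_ok <- rho >= (1 - spec$pz_shell_fraction) && cand[2] > center_mm[2]
          if (in_pz_target != pz_ok) next
          far <- all(vapply(lesions, function(l) {
            sqrt(sum((cand - l$center_mm)^2)) > (r + l$radius_mm)
          }, logical(1)))
          if (far) { ctr <- cand; break }
        }
        if (is.null(ctr)) ctr <- runif_ellipsoid(center_mm, shrunk)
        lesions[[i]] <- list(center_mm = ctr, radius_mm = r, label = lab[i])
      }
    }
    lesions
  })
}

# Separable Gaussian smoothing of a 3D array, sigma per axis in voxels.
smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 0.3) next
    n <- d[axis]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- K %*% matrix(a, nrow = n)
    arr <- aperm(array(m, dim(arr)[perm]), order(perm))
  }
  arr
}

# Unit-variance, zero-mean Gaussian random field with given correlation
# length (mm, converted to voxels per axis).
grf_field <- function(shape, spacing, corr_mm, seed) {
  with_seed(seed, {
    f <- array(rnorm(prod(shape)), dim = shape)
    f <- smooth_3d(f, corr_mm / spacing)
    (f - mean(f)) / sd(f)
  })
}

#' Generate one synthetic study case
#'
#' Produces three co-registered sequences (T2W, ADC, DWI), nested
#' gland/PZ/lesion masks and a case label. Malignant cases contain at least
#' one lesion whose texture is drawn from the malignant texture parameters;
#' benign lesions share the benign (background) texture statistics and are
#' therefore only weakly conspicuous, like clinically insignificant findings.
#'
#' Identical `(spec, label, seed)` calls return bit-identical cases.
#'
#' @param spec A [phantom_spec()].
#' @param label Case label, 0 (benign / no significant lesion) or 1
#'   (at least one malignant lesion).
#' @param seed Integer seed for this case.
#' @return A `study_case`: fields `case_id`, `t2w`, `adc`, `dwi`
#'   ([mri_volume()]s), `gland_mask`, `pz_mask` (integer 0/1 arrays),
#'   `lesions` (list of `list(mask, label)`), `label`, `spacing`.
#' @export
generate_case <- function(spec, label, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!label %in% c(0L, 1L)) abort("`label` must be 0 or 1.")
  label <- as.integer(label)
  shape <- spec$grid_shape
  spacing <- spec$spacing_mm
  center_mm <- shape * spacing / 2
  semi <- spec$gland_semi_mm

  rho2 <- ellipsoid_rho2(shape, spacing, center_mm, semi)
  gland <- array(as.integer(rho2 <= 1), dim = shape)
  ymm <- (seq_len(shape[2]) - 0.5) * spacing[2]
  posterior <- array(rep(rep(as.integer(ymm > center_mm[2]), each = shape[1]),
                         times = shape[3]), dim = shape)
  pz <- as.integer(gland == 1L & rho2 >= (1 - spec$pz_shell_fraction)^2 &
                     posterior == 1L)
  pz <- array(pz, dim = shape)

  layout <- sample_case_layout(spec, label, seed)
  lesions <- lapply(layout, function(l) {
    m <- ellipsoid_rho2(shape, spacing, l$center_mm, rep(l$radius_mm, 3))
    list(mask = array(as.integer(m <= 1), dim = shape), label = l$label)
  })
  mal_union <- array(0L, dim = shape)
  for (i in seq_along(lesions)) {
    if (lesions[[i]]$label == 1L) mal_union <- mal_union | lesions[[i]]$mask
  }

  seqs <- list()
  mods <- c(t2w = "T2W", adc = "ADC", dwi = "DWI")
  for (k in seq_along(mods)) {
    s <- names(mods)[k]
    tp <- spec$texture_params[[s]]
    f_ben <- grf_field(shape, spacing, tp$benign$corr_mm, derive_seed(seed, 10L + k))
    img <- tp$benign$mean + tp$benign$sd * f_ben
    img[gland == 0L] <- 0.6 * tp$benign$mean + tp$benign$sd * f_ben[gland == 0L]
    if (any(mal_union == 1L)) {
      f_mal <- grf_field(shape, spacing, tp$malignant$corr_mm,
                         derive_seed(seed, 20L + k))
      sel <- mal_union == 1L
      img[sel] <- tp$malignant$mean + tp$malignant$sd * f_mal[sel]
    }
    img <- img + with_seed(derive_seed(seed, 30L + k),
                           array(rnorm(prod(shape), 0, spec$noise_sd), dim = shape))
    seqs[[s]] <- mri_volume(img, spacing = spacing, modality = mods[[k]])
  }

  structure(
    list(case_id = sprintf("case_s%d", as.integer(seed)),
         t2w = seqs$t2w, adc = seqs$adc, dwi = seqs$dwi,
         gland_mask = gland, pz_mask = pz, lesions = lesions,
         label = label, spacing = spacing),
    class = "study_case"
  )
}

#' @export
print.study_case <- function(x, ...) {
  cat(sprintf("<study_case %s  label %d, %d lesion(s), grid %s>\n",
              x$case_id, x$label, length(x$lesions),
              paste(dim(x$t2w$data), collapse = "x")))
  invisible(x)
}

#' Cohort manifest without volume generation
#'
#' Computes, deterministically from the seed, the case identifiers, labels,
#' per-case seeds and lesion counts of a cohort, without materialising any
#' image data. Class counts follow `spec$class_ratio`, rounded. Useful for
#' streaming workflows where cases are generated one at a time.
#'
#' @param spec A [phantom_spec()].
#' @param n_cases Number of cases (at least 2).
#' @param seed Cohort seed; defaults to `spec$seed`.
#' @return A tibble with columns `case_id`, `label`, `n_lesions`, `seed`.
#' @export
cohort_manifest <- function(spec, n_cases, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_cases < 2) abort("`n_cases` must be at least 2 (cannot split one case).")
  p0 <- spec$class_ratio[1] / sum(spec$class_ratio)
  n0 <- round(n_cases * p0)
  labels <- c(rep(0L, n0), rep(1L, n_cases - n0))
  labels <- with_seed(derive_seed(seed, 777L), sample(labels))
  case_seed <- vapply(seq_len(n_cases), function(i) derive_seed(seed, 100L + i),
                      integer(1))
  n_les <- vapply(seq_len(n_cases), function(i) {
    length(sample_case_layout(spec, labels[i], case_seed[i]))
  }, integer(1))
  tibble::tibble(
    case_id = sprintf("case_%04d", seq_len(n_cases)),
    label = labels, n_lesions = n_les, seed = case_seed
  )
}

#' Generate a cohort of synthetic study cases
#'
#' @inheritParams cohort_manifest
#' @return A list with `cases` (list of `study_case`) and `manifest`
#'   (see [cohort_manifest()]); `manifest$case_id` overrides the per-case id.
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 32, 8), gland_radius_mm = 8,
#'                      lesion_radius_mm_range = c(2, 3))
#' cohort <- generate_cohort(spec, n_cases = 2, seed = 5)
#' cohort$manifest
#' @export
generate_cohort <- function(spec, n_cases, seed = spec$seed) {
  manifest <- cohort_manifest(spec, n_cases, seed)
  cases <- purrr::pmap(manifest, function(case_id, label, n_lesions, seed) {
    cs <- generate_case(spec, label, seed)
    cs$case_id <- case_id
    cs
  })
  list(cases = cases, manifest = manifest)
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' Each case is written as `<case_id>_{t2w,adc,dwi}.nii.gz`, mask files
#' `<case_id>_{gland,pz}_mask.nii.gz` and `<case_id>_lesion<k>_mask.nii.gz`,
#' with `manifest.csv` listing case id, label, lesion count and seed.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases) {
    for (s in c("t2w", "adc", "dwi")) {
      write_mri_volume(cs[[s]], file.path(dir, sprintf("%s_%s.nii.gz", cs$case_id, s)))
    }
    write_mask <- function(mask, name) {
      img <- RNifti::asNifti(mask + 0, reference = NULL)
      RNifti::pixdim(img) <- cs$spacing
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_%s.nii.gz", cs$case_id, name)))
    }
    write_mask(cs$gland_mask, "gland_mask")
    write_mask(cs$pz_mask, "pz_mask")
    for (k in seq_along(cs$lesions)) {
      write_mask(cs$lesions[[k]]$mask, sprintf("lesion%d_mask", k))
    }
  }
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
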