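#' Texture feature configuration
#'
#' Fixes the composition of the per-sequence texture descriptor:
#' 13 Haralick statistics for each of the 13 distance-1 co-occurrence
#' offsets (169), a 64-bin 3D LBP histogram, and a 3D HOG descriptor with
#' `prod(hog_cells)` cells of `hog_bins` orientation bins (64 by default),
#' for a total of 297 features per sequence and 891 per three-sequence
#' study. The constructor enforces the 297 contract unless
#' `allow_nonstandard = TRUE`.
#'
#' @param glcm_levels Gray levels for quantisation (default 32).
#' @param glcm_offsets Offset matrix, default [glcm_offsets_3d()].
#' @param lbp_bins LBP histogram bins; the 6-neighbour code has 64.
#' @param hog_cells HOG cell grid, default `c(2, 2, 1)`.
#' @param hog_bins HOG orientation bins, default 16.
#' @param allow_nonstandard Permit configurations whose total differs
#'   from 297.
#' @return A `feature_config` with an `n_features` field.
#' @export
feature_config <- function(glcm_levels = 32L, glcm_offsets = glcm_offsets_3d(),
                           lbp_bins = 64L, hog_cells = c(2, 2, 1),
                           hog_bins = 16L, allow_nonstandard = FALSE) {
  n_har <- 13L * nrow(glcm_offsets)
  n_hog <- as.integer(prod(hog_cells) * hog_bins)
  n <- n_har + as.integer(lbp_bins) + n_hog
  if (!allow_nonstandard && n != 297L) {
    abort(sprintf("Feature configuration yields %d features per sequence, not 297.", n))
  }
  structure(
    list(glcm_levels = as.integer(glcm_levels), glcm_offsets = glcm_offsets,
         lbp_bins = as.integer(lbp_bins), hog_cells = as.integer(hog_cells),
         hog_bins = as.integer(hog_bins), n_features = n),
    class = "feature_config"
  )
}

# Named 297-vector for one volume (internal; used for sequences and windows).
seq_feature_vector <- function(vol, cfg = feature_config(), spacing = NULL) {
  har <- haralick_features(glcm_3d(vol, cfg$glcm_levels, cfg$glcm_offsets))
  lbp <- lbp_3d(vol)
  hog <- hog_3d(vol, spacing = spacing, cells = cfg$hog_cells, bins = cfg$hog_bins)
  c(har, lbp, hog)
}

#' Extract the 297-feature texture descriptor of one sequence
#'
#' Concatenates Haralick (169), LBP (64) and HOG (64) features, with names
#' prefixed by the modality in lower case. Pure: identical inputs give
#' identical outputs.
#'
#' @param vol An [mri_volume()] (or plain 3D array, in which case
#'   `modality` must be given).
#' @param cfg A [feature_config()].
#' @param modality Modality prefix when `vol` is a plain array.
#' @return A one-row tibble with `cfg$n_features` (297) named columns.
#' @export
extract_sequence_features <- function(vol, cfg = feature_config(),
                                      modality = NULL) {
  if (is_mri_volume(vol)) {
    modality <- vol$modality
    spacing <- vol$spacing
  } else {
    if (is.null(modality)) abort("`modality` is required for plain arrays.")
    spacing <- NULL
  }
  v <- seq_feature_vector(vol, cfg, spacing = spacing)
  names(v) <- paste0(tolower(modality), "_", names(v))
  tibble::as_tibble(as.list(v))
}

#' Extract the study-level feature vector
#'
#' Concatenates the per-sequence descriptors in the fixed canonical order
#' T2W, ADC, DWI (891 features), regardless of any other ordering in the
#' case object. In peripheral-zone mode (`adc_only = TRUE`) only the ADC
#' descriptor (297 features) is returned, since PZ lesions are assessed on
#' the ADC sequence.
#'
#' @param case A `study_case`, or a named list with elements `t2w`, `adc`,
#'   `dwi` that are [mri_volume()]s or plain arrays.
#' @param cfg A [feature_config()].
#' @param adc_only Peripheral-zone mode: use the ADC sequence only.
#' @return A one-row tibble with 891 (or 297) named columns.
#' @export
extract_study_features <- function(case, cfg = feature_config(),
                                   adc_only = FALSE) {
  mods <- if (adc_only) "adc" else c("t2w", "adc", "dwi")
  parts <- lapply(mods, function(s) {
    vol <- case[[s]]
    if (is.null(vol)) abort(sprintf("Missing sequence `%s` for feature extraction.", s))
    extract_sequence_features(vol, cfg, modality = toupper(s))
  })
  dplyr::bind_cols(parts)
}

#' Extract features for a whole cohort, streaming case by case
#'
#' Generates (or accepts) cases one at a time, preprocesses them, extracts
#' region inputs of the requested kind and binds the feature rows into a
#' single tibble with `case_id` and `label` columns. Generated volumes are
#' discarded after use, so memory stays flat in the cohort size.
#'
#' @param spec A [phantom_spec()] (cases are generated from `manifest`), or
#'   `NULL` if `cases` is supplied.
#' @param manifest A [cohort_manifest()] tibble (required with `spec`).
#' @param cases Optional pre-built list of `study_case` objects.
#' @param region One of `"whole"`, `"gland"`, `"pz"`, `"lesion"`.
#' @param cfg A [feature_config()].
#' @param preproc A [preproc_config()] applied to each case, or `NULL` to
#'   skip preprocessing.
#' @param region_shape Fixed sub-volume shape for mask-derived regions (see
#'   [extract_region_inputs()]).
#' @return A tibble: `case_id`, `label`, then feature columns. For
#'   `region = "lesion"` there is one row per lesion, labelled per lesion.
#' @export
extract_cohort_features <- function(spec = NULL, manifest = NULL, cases = NULL,
                                    region = "whole", cfg = feature_config(),
                                    preproc = NULL, region_shape = NULL) {
  get_case <- if (!is.null(cases)) {
    n <- length(cases)
    function(i) cases[[i]]
  } else {
    if (is.null(spec) || is.null(manifest)) {
      abort("Supply either `cases` or both `spec` and `manifest`.")
    }
    n <- nrow(manifest)
    function(i) {
      cs <- generate_case(spec, manifest$label[i], manifest$seed[i])
      cs$case_id <- manifest$case_id[i]
      cs
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- get_case(i)
    if (!is.null(preproc)) cs <- preprocess_study(cs, preproc)
    inputs <- extract_region_inputs(cs, region, region_shape = region_shape)
    if (length(inputs) == 0) next
    rows[[i]] <- dplyr::bind_rows(lapply(seq_along(inputs), function(k) {
      inp <- inputs[[k]]
      feats <- extract_study_features(inp$volumes, cfg, adc_only = inp$adc_only)
      dplyr::bind_cols(
        tibble::tibble(case_id = cs$case_id, label = inp$label),
        feats
      )
    }))
  }
  dplyr::bind_rows(rows)
}
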