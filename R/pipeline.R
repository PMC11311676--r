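#' Emulated lesion-segmentation pipeline
#'
#' Stands in for the external UNet-based segmenter the classifiers are meant
#' to filter. It proposes lesion candidates by corrupting the ground truth:
#' each true lesion is dropped with probability `fn_rate`, and spurious
#' candidates (spheres inside the gland) are added with a per-case Poisson
#' rate `fp_rate`. Every emitted candidate counts as a suspicious finding,
#' so the baseline case prediction is 1 iff at least one candidate exists —
#' an over-sensitive, low-specificity regime when `fp_rate` is high, which
#' is exactly the problem setting an upstream filter addresses. With both
#' rates 0 the proposals equal the ground truth.
#'
#' @param fp_rate Expected number of false-positive proposals per case.
#' @param fn_rate Probability of dropping each true lesion.
#' @param fp_radius_mm Radius range of false-positive spheres.
#' @param seed Segmenter seed.
#' @return An `emulated_segmenter`.
#' @export
emulated_segmenter <- function(fp_rate = 0.75, fn_rate = 0, fp_radius_mm = c(3, 6),
                               seed = 1L) {
  if (fp_rate < 0 || fn_rate < 0 || fn_rate > 1) {
    abort("`fp_rate` must be >= 0 and `fn_rate` in [0, 1].")
  }
  structure(list(fp_rate = fp_rate, fn_rate = fn_rate,
                 fp_radius_mm = fp_radius_mm, seed = as.integer(seed)),
            class = "emulated_segmenter")
}

#' Propose lesion candidates for one case
#'
#' @param segmenter An [emulated_segmenter()].
#' @param case A `study_case`.
#' @param case_index Index used to derive the per-case seed.
#' @return A list of proposals `list(mask, truth_label, is_fp)`;
#'   `truth_label` is the true lesion label for retained lesions and 0 for
#'   spurious proposals.
#' @export
propose_lesions <- function(segmenter, case, case_index = 1L) {
  stopifnot(inherits(segmenter, "emulated_segmenter"))
  with_seed(derive_seed(segmenter$seed, case_index), {
    proposals <- list()
    for (l in case$lesions) {
      if (segmenter$fn_rate > 0 && runif(1) < segmenter$fn_rate) next
      proposals[[length(proposals) + 1]] <-
        list(mask = l$mask, truth_label = l$label, is_fp = FALSE)
    }
    n_fp <- if (segmenter$fp_rate > 0) stats::rpois(1, segmenter$fp_rate) else 0L
    if (n_fp > 0) {
      gland_idx <- which(case$gland_mask != 0)
      d <- dim(case$gland_mask)
      for (k in seq_len(n_fp)) {
        ctr_lin <- sample(gland_idx, 1)
        ctr <- arrayInd(ctr_lin, d)
        r <- runif(1, segmenter$fp_radius_mm[1], segmenter$fp_radius_mm[2])
        ctr_mm <- (as.numeric(ctr) - 0.5) * case$spacing
        m <- ellipsoid_rho2(d, case$spacing, ctr_mm, rep(r, 3))
        mask <- array(as.integer(m <= 1 & case$gland_mask != 0), dim = d)
        if (sum(mask) == 0) mask[ctr_lin] <- 1L
        proposals[[length(proposals) + 1]] <-
          list(mask = mask, truth_label = 0L, is_fp = TRUE)
      }
    }
    proposals
  })
}

# Baseline pipeline prediction: malignant iff the segmenter emits any
# candidate.
baseline_prediction <- function(proposals) as.integer(length(proposals) > 0)

resolve_filter <- function(filter, cases) {
  if (is.character(filter) && length(filter) == 1) {
    truth <- vapply(cases, function(cs) cs$label, integer(1))
    return(switch(filter,
                  always_pass = rep(1L, length(cases)),
                  always_block = rep(0L, length(cases)),
                  oracle = truth,
                  abort("Unknown filter preset.")))
  }
  if (is.function(filter)) {
    return(vapply(cases, function(cs) as.integer(filter(cs)), integer(1)))
  }
  as.integer(filter)
}

#' Pipeline evaluation mode 1: upstream case filter
#'
#' A whole-image / gland / PZ classifier is placed upstream of the
#' segmenter: cases it predicts lesion-free receive the final label 0 and
#' skip segmentation entirely (the skip count is reported); the remaining
#' cases receive the emulated segmenter's baseline prediction. Metrics are
#' computed against the case truth with malignant as the positive class.
#'
#' An always-pass filter reproduces the segmenter-only baseline exactly; an
#' always-block filter yields sensitivity 0 and specificity 1; an oracle
#' filter raises specificity over an over-proposing segmenter while
#' leaving sensitivity exactly at baseline.
#'
#' @param cases List of `study_case` objects.
#' @param filter Per-case 0/1 predictions, a `function(case)`, or one of
#'   `"always_pass"`, `"always_block"`, `"oracle"`.
#' @param segmenter An [emulated_segmenter()].
#' @return An `eval_report` (mode `"pipeline_mode1"`) with fields
#'   `n_skipped` and `baseline` (the segmenter-only report).
#' @export
run_mode1 <- function(cases, filter, segmenter) {
  truth <- vapply(cases, function(cs) cs$label, integer(1))
  keep <- resolve_filter(filter, cases)
  base_pred <- vapply(seq_along(cases), function(i) {
    baseline_prediction(propose_lesions(segmenter, cases[[i]], i))
  }, integer(1))
  pred <- ifelse(keep == 0L, 0L, base_pred)
  report_binary <- function(p) {
    ss <- sens_spec(p, truth)
    tibble::tibble(auc_roc = auc_roc(p, truth),
                   sensitivity = ss$sensitivity, specificity = ss$specificity)
  }
  make_eval_report(NULL, report_binary(pred), mode = "pipeline_mode1",
                   extra = list(n_skipped = sum(keep == 0L),
                                baseline = report_binary(base_pred),
                                predictions = tibble::tibble(
                                  case_id = vapply(cases, function(cs) cs$case_id,
                                                   character(1)),
                                  truth = truth, filter = keep,
                                  baseline = base_pred, prediction = pred)))
}

#' Pipeline evaluation mode 2: classify proposed lesions
#'
#' The lesion classifier is placed at the end of the pipeline: every
#' candidate the segmenter proposes is scored, and the case label is 1 iff
#' any candidate is classified malignant. A scorer that labels every
#' proposal malignant reproduces the segmenter-only baseline; with exact
#' proposals and an oracle scorer the case metrics are perfect.
#'
#' @param cases List of `study_case` objects.
#' @param scorer `function(case, mask) -> score in [0, 1]`, or `"oracle"`
#'   (scores each proposal with its truth label), or `"all_malignant"`.
#' @param segmenter An [emulated_segmenter()].
#' @param cutoff Score threshold for calling a proposal malignant
#'   (score >= cutoff), default 0.5.
#' @return An `eval_report` (mode `"pipeline_mode2"`) with a `baseline`
#'   field.
#' @export
run_mode2 <- function(cases, scorer, segmenter, cutoff = 0.5) {
  truth <- vapply(cases, function(cs) cs$label, integer(1))
  score_fun <- if (is.character(scorer) && length(scorer) == 1) {
    switch(scorer,
           oracle = function(case, prop) as.numeric(prop$truth_label),
           all_malignant = function(case, prop) 1,
           abort("Unknown scorer preset."))
  } else {
    function(case, prop) scorer(case, prop$mask)
  }
  pred <- integer(length(cases))
  base_pred <- integer(length(cases))
  max_scores <- numeric(length(cases))
  for (i in seq_along(cases)) {
    props <- propose_lesions(segmenter, cases[[i]], i)
    base_pred[i] <- baseline_prediction(props)
    if (length(props) == 0) { pred[i] <- 0L; max_scores[i] <- 0; next }
    scores <- vapply(props, function(p) score_fun(cases[[i]], p), numeric(1))
    max_scores[i] <- max(scores)
    pred[i] <- as.integer(any(scores >= cutoff))
  }
  report_binary <- function(p, s) {
    ss <- sens_spec(p, truth)
    tibble::tibble(auc_roc = auc_roc(s, truth),
                   sensitivity = ss$sensitivity, specificity = ss$specificity)
  }
  make_eval_report(NULL, report_binary(pred, max_scores), mode = "pipeline_mode2",
                   extra = list(baseline = report_binary(base_pred, base_pred),
                                predictions = tibble::tibble(
                                  case_id = vapply(cases, function(cs) cs$case_id,
                                                   character(1)),
                                  truth = truth, baseline = base_pred,
                                  max_score = max_scores, prediction = pred)))
}

#' Build a proposal scorer from a trained lesion-region classifier
#'
#' Wraps a [train_classifier()] model (plus the selection step it was
#' trained behind, if any) into the `function(case, mask)` interface of
#' [run_mode2()]: the proposal's bounding box is cropped from the case,
#' resized to the lesion-region shape, featurised, and scored.
#'
#' @param model A `trained_classifier` fit on lesion-region features.
#' @param selection Optional fitted `selection_model` applied before
#'   prediction.
#' @param cfg A [feature_config()].
#' @param region_shape Fixed lesion sub-volume shape.
#' @param margin_voxels Bounding-box margin.
#' @return A `function(case, mask)` returning a malignancy score.
#' @export
region_scorer <- function(model, selection = NULL, cfg = feature_config(),
                          region_shape = default_region_shape("lesion"),
                          margin_voxels = c(2, 2, 0)) {
  function(case, mask) {
    box <- bounding_box(mask, margin_voxels, kind = "lesion")
    vols <- lapply(c(t2w = "t2w", adc = "adc", dwi = "dwi"), function(s) {
      vol <- case[[s]]
      sub <- crop_box(vol$data, box)
      sp <- vol$spacing * dim(sub) / region_shape
      mri_volume(resize_array_to(sub, region_shape, "linear"),
                 spacing = sp, modality = vol$modality)
    })
    feats <- extract_study_features(vols, cfg)
    Xn <- as.matrix(feats)
    if (!is.null(selection)) Xn <- select_transform(selection, Xn)
    predict_proba(model, Xn)
  }
}
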