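#' Assemble a reproducible experiment configuration
#'
#' Bundles every stage's configuration — phantom spec, preprocessing,
#' features, region, selection, classifier, split — with a global seed.
#' A run's config plus its seed reproduces its outputs exactly.
#'
#' @param region `"whole"`, `"gland"`, `"pz"`, `"lesion"` or `"window"`
#'   (sliding window).
#' @param model A [model_spec()].
#' @param selection `"none"`, `"PCA"` or `"mRMR"`.
#' @param k Retained components/features for the selection step.
#' @param phantom A [phantom_spec()].
#' @param n_cases Cohort size.
#' @param preproc A [preproc_config()] or `NULL` to skip (phantom cases are
#'   already on the target grid when the spec matches the config).
#' @param features A [feature_config()].
#' @param window_shape,overlap Sliding-window geometry (region `"window"`).
#' @param test_fraction,n_folds Split plan parameters.
#' @param cutoff Decision threshold for sensitivity/specificity.
#' @param seed Global seed.
#' @param preset Optional preset name recorded for provenance.
#' @return A `run_config`.
#' @export
run_config <- function(region = "whole", model = model_spec("svm"),
                       selection = "none", k = 95L,
                       phantom = phantom_spec(), n_cases = 60L,
                       preproc = NULL, features = feature_config(),
                       window_shape = c(70, 65, 3), overlap = 0.5,
                       test_fraction = 0.15, n_folds = 5L, cutoff = 0.5,
                       seed = 1L, preset = NULL) {
  structure(
    list(region = region, model = model, selection = selection, k = as.integer(k),
         phantom = phantom, n_cases = as.integer(n_cases), preproc = preproc,
         features = features, window_shape = as.integer(window_shape),
         overlap = overlap, test_fraction = test_fraction,
         n_folds = as.integer(n_folds), cutoff = cutoff,
         seed = as.integer(seed), preset = preset),
    class = "run_config"
  )
}

#' Named experiment presets
#'
#' Presets mirror the experiment grid region x classifier x selection.
#' `"whole-image-svm"` is the packaged best whole-image configuration:
#' radial SVM with error-tolerance C = 60 on a 95-component PCA reduction
#' of the 891 study features. Other names follow the pattern
#' `<region>-<model>[-<selection>]`, e.g. `"lesion-gbt"`,
#' `"gland-mlp-mrmr"`, `"sliding-window-gbt"`.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [run_config()] (e.g. `n_cases`,
#'   `seed`, `phantom`).
#' @return A `run_config`.
#' @export
preset <- function(name, ...) {
  if (name == "whole-image-svm") {
    return(run_config(region = "whole", model = svm_error_tolerance_60(),
                      selection = "PCA", k = 95L, preset = name, ...))
  }
  regions <- c("whole-image" = "whole", "gland" = "gland", "pz" = "pz",
               "lesion" = "lesion", "sliding-window" = "window")
  parts <- NULL
  for (rn in names(regions)) {
    if (startsWith(name, paste0(rn, "-"))) {
      parts <- list(region = regions[[rn]],
                    rest = substring(name, nchar(rn) + 2))
      break
    }
  }
  if (is.null(parts)) abort(sprintf("Unknown preset `%s`.", name))
  bits <- strsplit(parts$rest, "-", fixed = TRUE)[[1]]
  fam <- bits[1]
  if (!fam %in% c("svm", "gbt", "mlp")) abort(sprintf("Unknown model `%s`.", fam))
  sel <- if (length(bits) > 1) {
    switch(bits[2], pca = "PCA", mrmr = "mRMR",
           abort(sprintf("Unknown selection `%s`.", bits[2])))
  } else "none"
  run_config(region = parts$region, model = model_spec(fam), selection = sel,
             preset = name, ...)
}

config_to_list <- function(config) {
  strip <- function(x) {
    if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(config)
}

# Sliding-window experiment: train a malignant-vs-rest window classifier,
# aggregate window scores into per-case heatmaps, threshold at a
# training-derived Youden cutoff.
run_window_experiment <- function(config, manifest, plan) {
  cfg <- config$features
  wg <- NULL
  case_rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cs <- generate_case(config$phantom, manifest$label[i], manifest$seed[i])
    cs$case_id <- manifest$case_id[i]
    if (!is.null(config$preproc)) cs <- preprocess_study(cs, config$preproc)
    if (is.null(wg)) {
      wg <- make_windows(dim(cs$t2w$data), config$window_shape, config$overlap)
    }
    labs <- vapply(wg$boxes, label_window, character(1), lesions = cs$lesions)
    feats <- lapply(seq_along(wg$boxes), function(k) {
      vols <- list(t2w = crop_box(cs$t2w$data, wg$boxes[[k]]),
                   adc = crop_box(cs$adc$data, wg$boxes[[k]]),
                   dwi = crop_box(cs$dwi$data, wg$boxes[[k]]))
      extract_study_features(vols, cfg)
    })
    case_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(case_id = cs$case_id, window = seq_along(wg$boxes),
                     label3 = labs, label = as.integer(labs == "malignant")),
      dplyr::bind_rows(feats)
    )
  }
  windows_df <- dplyr::bind_rows(case_rows)
  feat_cols <- setdiff(names(windows_df), c("case_id", "window", "label3", "label"))
  plan_tb <- tibble::as_tibble(plan)
  wdf <- dplyr::inner_join(windows_df,
                           dplyr::select(plan_tb, dplyr::all_of(c("case_id", "role"))),
                           by = "case_id")
  tr <- wdf$role == "train"
  # subsample background windows to balance the training table
  with_seed(derive_seed(config$seed, 5L), {
    pos <- which(tr & wdf$label == 1L)
    bg <- which(tr & wdf$label == 0L)
    n_keep <- min(length(bg), max(length(pos) * 4L, 50L))
    keep <- sort(c(pos, sample(bg, n_keep)))
  })
  sel <- selection_fit(as.matrix(wdf[keep, feat_cols]), wdf$label[keep],
                       kind = config$selection, k = config$k)
  mdl <- train_classifier(select_transform(sel, as.matrix(wdf[keep, feat_cols])),
                          wdf$label[keep],
                          model_spec_with_seed(config$model,
                                               derive_seed(config$seed, 6L)))
  score_all <- predict_proba(mdl, select_transform(sel, as.matrix(wdf[, feat_cols])))
  case_score <- wdf |>
    dplyr::mutate(score = score_all) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(score = max(build_heatmap(wg, .data$score)$confidence),
                     .groups = "drop") |>
    dplyr::inner_join(plan_tb, by = "case_id")
  tr_cases <- case_score[case_score$role == "train", ]
  cut <- choose_cutoff(tr_cases$score, tr_cases$label)
  te_cases <- case_score[case_score$role == "test", ]
  eval_cases <- if (length(unique(te_cases$label)) == 2) te_cases else tr_cases
  pred <- as.integer(eval_cases$score > cut)
  ss <- sens_spec(pred, eval_cases$label)
  test <- tibble::tibble(auc_roc = auc_roc(eval_cases$score, eval_cases$label),
                         sensitivity = ss$sensitivity, specificity = ss$specificity)
  make_eval_report(NULL, test, mode = "standalone",
                   extra = list(selection = config$selection, k = config$k,
                                model_family = config$model$family,
                                cutoff = as.numeric(cut)))
}

#' Run a full experiment from a configuration
#'
#' Generates the phantom cohort, extracts features for the configured
#' region (or runs the sliding-window path), performs the leakage-safe
#' cross-validated evaluation, and — when `out_dir` is given — writes the
#' provenance artifacts: `config.yaml`, `manifest.csv`, `features.csv` and
#' `report.json`. Identical configurations produce byte-identical report
#' files.
#'
#' @param config A [run_config()] or preset name (see [preset()]).
#' @param out_dir Optional artifact directory.
#' @param ... Overrides forwarded to [preset()] when `config` is a name.
#' @return A list with `report` (an `eval_report`), `config`, and
#'   `paths` (written artifact paths, if any).
#' @export
run_experiment <- function(config, out_dir = NULL, ...) {
  if (is.character(config)) config <- preset(config, ...)
  stopifnot(inherits(config, "run_config"))
  manifest <- cohort_manifest(config$phantom, config$n_cases, config$seed)
  plan <- split_plan(manifest$label, manifest$case_id,
                     test_fraction = config$test_fraction,
                     n_folds = config$n_folds, seed = config$seed)
  features <- NULL
  if (config$region == "window") {
    report <- run_window_experiment(config, manifest, plan)
  } else {
    features <- extract_cohort_features(spec = config$phantom, manifest = manifest,
                                        region = config$region,
                                        cfg = config$features,
                                        preproc = config$preproc)
    report <- cross_validate(features, plan, selection = config$selection,
                             k = config$k, model = config$model,
                             cutoff = config$cutoff)
  }
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$config <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config_to_list(config), paths$config)
    paths$manifest <- file.path(out_dir, "manifest.csv")
    write.csv(manifest, paths$manifest, row.names = FALSE)
    if (!is.null(features)) {
      paths$features <- file.path(out_dir, "features.csv")
      write.csv(features, paths$features, row.names = FALSE)
    }
    paths$report <- file.path(out_dir, "report.json")
    payload <- list(mode = report$mode,
                    per_fold = report$per_fold, test = report$test,
                    summary = report$summary, preset = config$preset,
                    seed = config$seed)
    jsonlite::write_json(payload, paths$report, digits = 10, auto_unbox = TRUE,
                         null = "null")
  }
  list(report = report, config = config, paths = paths)
}
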