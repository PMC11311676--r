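#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pairwise probability that a random positive
#' outscores a random negative, with ties counting one half (mid-rank
#' formula). The positive class is the malignant class (label 1).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return The AUC in \[0, 1\].
#' @examples
#' auc_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' @export
auc_roc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("AUC requires both classes.")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity
#'
#' Sensitivity = TP / (TP + FN) over the malignant (positive) class;
#' specificity = TN / (TN + FP) over the benign class. When a class is
#' absent the corresponding metric is undefined and reported as `NA`
#' rather than 0.
#'
#' @param pred_labels Predicted binary labels.
#' @param true_labels True binary labels.
#' @return A named list with `sensitivity` and `specificity`.
#' @export
sens_spec <- function(pred_labels, true_labels) {
  p <- as.integer(pred_labels); t <- as.integer(true_labels)
  n_pos <- sum(t == 1); n_neg <- sum(t == 0)
  list(
    sensitivity = if (n_pos == 0) NA_real_ else sum(p == 1 & t == 1) / n_pos,
    specificity = if (n_neg == 0) NA_real_ else sum(p == 0 & t == 0) / n_neg
  )
}

# Stratified fold assignment (1..n_folds), shuffled within class.
# Caller controls the RNG.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Build a stratified train/test split with cross-validation folds
#'
#' Reserves `test_fraction` of the cases as a held-out test set (stratified
#' by label) and partitions the remaining cases into `n_folds` stratified
#' folds. Test cases never appear in any training fold.
#'
#' @param labels Case labels (0/1).
#' @param case_ids Case identifiers; defaults to `case_0001` style ids.
#' @param test_fraction Held-out fraction, default 0.15.
#' @param n_folds Number of folds, default 5.
#' @param seed Seed for the stratified draws.
#' @return A `split_plan`: tibble with `case_id`, `label`, `role`
#'   (`"train"`/`"test"`) and `fold` (`NA` for test cases), carrying the
#'   seed and fold count as attributes.
#' @export
split_plan <- function(labels, case_ids = NULL, test_fraction = 0.15,
                       n_folds = 5L, seed = 1L) {
  y <- as.integer(labels)
  n <- length(y)
  if (is.null(case_ids)) case_ids <- sprintf("case_%04d", seq_len(n))
  role <- rep("train", n)
  with_seed(derive_seed(seed, 1L), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- round(length(idx) * test_fraction)
      if (n_test > 0) role[sample(idx, n_test)] <- "test"
    }
  })
  fold <- rep(NA_integer_, n)
  tr <- which(role == "train")
  fold[tr] <- with_seed(derive_seed(seed, 2L), stratified_folds(y[tr], n_folds))
  plan <- tibble::tibble(case_id = case_ids, label = y, role = role, fold = fold)
  attr(plan, "n_folds") <- as.integer(n_folds)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("split_plan", class(plan))
  plan
}

make_eval_report <- function(per_fold, test, mode, extra = list()) {
  summary <- NULL
  if (!is.null(per_fold) && nrow(per_fold) > 0) {
    summary <- tibble::tibble(
      metric = c("auc_roc", "sensitivity", "specificity"),
      mean = c(mean(per_fold$auc_roc), mean(per_fold$sensitivity),
               mean(per_fold$specificity)),
      sd = c(sd(per_fold$auc_roc), sd(per_fold$sensitivity),
             sd(per_fold$specificity))
    )
  }
  structure(c(list(per_fold = per_fold, test = test, summary = summary,
                   mode = mode), extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report mode=%s>\n", x$mode))
  if (!is.null(x$summary)) {
    cat("Cross-validation (mean +/- sd):\n")
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("  %-12s %.4f +/- %.4f\n", x$summary$metric[i],
                  x$summary$mean[i], x$summary$sd[i]))
    }
  }
  if (!is.null(x$test)) {
    cat(sprintf("Held-out test: AUC %.4f, sens %.4f, spec %.4f\n",
                x$test$auc_roc, x$test$sensitivity, x$test$specificity))
  }
  invisible(x)
}

#' Leakage-safe cross-validated evaluation
#'
#' For each fold, the feature-selection step and the classifier are fitted
#' on that fold's training cases only and evaluated on the fold's
#' validation cases; final test metrics come from a model refit on the full
#' training portion (the standard protocol) and applied once to the
#' held-out test set. Rows of `features` are matched to the plan by
#' `case_id`, so multi-row cases (per-lesion instances) inherit their
#' case's fold and never straddle a split.
#'
#' @param features Tibble with `case_id`, `label` and feature columns (see
#'   [extract_cohort_features()]).
#' @param plan A [split_plan()] built on the case-level labels.
#' @param selection `"none"`, `"PCA"` or `"mRMR"`.
#' @param k Retained components/features for the selection step.
#' @param model A [model_spec()].
#' @param cutoff Decision threshold for sensitivity/specificity.
#' @return An `eval_report` with `per_fold`, `test` and `summary` tables.
#' @export
cross_validate <- function(features, plan, selection = "none", k = 95L,
                           model = model_spec("svm"), cutoff = 0.5) {
  stopifnot(inherits(plan, "split_plan"))
  feat_cols <- setdiff(names(features), c("case_id", "label"))
  df <- dplyr::inner_join(
    features,
    dplyr::select(tibble::as_tibble(plan), dplyr::all_of(c("case_id", "role", "fold"))),
    by = "case_id"
  )
  if (nrow(df) == 0) abort("No overlap between `features` and `plan` case ids.")
  n_folds <- attr(plan, "n_folds")
  X <- as.matrix(df[, feat_cols])
  y <- df$label

  eval_split <- function(tr, te, seed_offset) {
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      abort("Stratification failure: a split contains a single class.")
    }
    sel <- selection_fit(X[tr, , drop = FALSE], y[tr], kind = selection, k = k)
    m <- train_classifier(select_transform(sel, X[tr, , drop = FALSE]), y[tr],
                          model_spec_with_seed(model, seed_offset))
    s <- predict_proba(m, select_transform(sel, X[te, , drop = FALSE]))
    ss <- sens_spec(as.integer(s >= cutoff), y[te])
    tibble::tibble(auc_roc = auc_roc(s, y[te]),
                   sensitivity = ss$sensitivity, specificity = ss$specificity)
  }

  per_fold <- dplyr::bind_rows(lapply(seq_len(n_folds), function(f) {
    tr <- which(df$role == "train" & df$fold != f)
    te <- which(df$role == "train" & df$fold == f)
    dplyr::bind_cols(tibble::tibble(fold = f),
                     eval_split(tr, te, derive_seed(attr(plan, "seed"), 50L + f)))
  }))
  test_idx <- which(df$role == "test")
  test <- NULL
  if (length(test_idx) > 0) {
    test <- eval_split(which(df$role == "train"), test_idx,
                       derive_seed(attr(plan, "seed"), 99L))
  }
  make_eval_report(per_fold, test, mode = "standalone",
                   extra = list(selection = selection, k = k,
                                model_family = model$family, cutoff = cutoff))
}

model_spec_with_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}
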