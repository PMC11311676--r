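#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted selection model
#'
#' For PCA: one row per retained component with its standard deviation and
#' variance share. For mRMR: one row per selected feature in selection
#' order with its criterion value.
#'
#' @param x A `selection_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy selection_model
#' @export
tidy.selection_model <- function(x, ...) {
  check_fitted(x)
  if (x$kind == "PCA") {
    var_share <- x$sdev^2 / sum(x$sdev^2)
    return(tibble::tibble(component = paste0("PC", seq_len(x$k)),
                          sdev = x$sdev[seq_len(x$k)],
                          variance_share = var_share[seq_len(x$k)]))
  }
  if (x$kind == "mRMR") {
    return(tibble::tibble(rank = seq_len(x$k), feature = x$selected_names,
                          index = x$selected, criterion = x$scores))
  }
  tibble::tibble(rank = seq_len(x$k), feature = x$feature_names %||%
                   paste0("f", seq_len(x$k)))
}

#' @rdname tidy.selection_model
#' @method glance selection_model
#' @export
glance.selection_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, k = x$k,
                 n_features_in = length(x$feature_names %||% NA))
}

#' Tidy a trained classifier's hyperparameters
#'
#' @param x A `trained_classifier`.
#' @param ... Unused.
#' @return A tibble with one row per hyperparameter.
#' @method tidy trained_classifier
#' @export
tidy.trained_classifier <- function(x, ...) {
  p <- x$spec$params
  tibble::tibble(hyperparameter = names(p),
                 value = vapply(p, function(v) format(v), character(1)))
}

#' @rdname tidy.trained_classifier
#' @method glance trained_classifier
#' @export
glance.trained_classifier <- function(x, ...) {
  tibble::tibble(family = x$spec$family, n_features = length(x$feature_names),
                 class_weights = x$spec$class_weights, seed = x$spec$seed)
}

#' Tidy an evaluation report
#'
#' One row per fold and metric, plus the held-out test rows; `glance()`
#' returns the one-row summary (fold means, SDs and test metrics).
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$per_fold)) {
    rows$folds <- tidyr::pivot_longer(x$per_fold, -"fold",
                                      names_to = "metric", values_to = "value")
  }
  if (!is.null(x$test)) {
    rows$test <- tidyr::pivot_longer(
      dplyr::mutate(x$test, fold = NA_integer_), -"fold",
      names_to = "metric", values_to = "value"
    )
    rows$test$split <- "test"
  }
  if (!is.null(rows$folds)) rows$folds$split <- "cv"
  dplyr::bind_rows(rows)
}

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  out <- tibble::tibble(mode = x$mode)
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      out[[paste0("cv_", x$summary$metric[i])]] <- x$summary$mean[i]
      out[[paste0("cv_", x$summary$metric[i], "_sd")]] <- x$summary$sd[i]
    }
  }
  if (!is.null(x$test)) {
    out$test_auc_roc <- x$test$auc_roc
    out$test_sensitivity <- x$test$sensitivity
    out$test_specificity <- x$test$specificity
  }
  out
}
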