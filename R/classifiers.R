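#' Specify a classifier
#'
#' Families: `"svm"` (support vector machine; regularisation/error-tolerance
#' `cost`, `kernel`, optional class weighting), `"gbt"` (gradient-boosted
#' decision trees; `eta` learning rate, `max_depth`, `max_leaves`,
#' `nrounds`), `"mlp"` (multilayer perceptron; hidden layer `size`, weight
#' `decay`, `maxit`). All families output malignancy probabilities in
#' \[0, 1\]. Stochastic families are made reproducible by `seed`.
#'
#' @param family `"svm"`, `"gbt"` or `"mlp"`.
#' @param ... Family-specific hyperparameters overriding the defaults.
#' @param class_weights Balance classes by inverse frequency during
#'   training.
#' @param seed Integer seed used at fit time.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("svm", "gbt", "mlp"), ...,
                       class_weights = TRUE, seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm = list(cost = 1, kernel = "radial"),
    gbt = list(eta = 0.3, max_depth = 4L, max_leaves = 16L, nrounds = 60L),
    mlp = list(size = 16L, decay = 1e-3, maxit = 200L)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    abort(sprintf("Unknown hyperparameter(s) for %s: %s", family,
                  paste(bad, collapse = ", ")))
  }
  defaults[names(override)] <- override
  structure(list(family = family, params = defaults,
                 class_weights = isTRUE(class_weights), seed = as.integer(seed)),
            class = "model_spec")
}

#' The packaged best whole-image SVM configuration
#'
#' A named preset: radial-kernel SVM with the error-tolerance
#' (regularisation) parameter C set to 60, intended to be combined with a
#' 95-component PCA reduction of the 891-feature study descriptor.
#'
#' @return A `model_spec`.
#' @export
svm_error_tolerance_60 <- function() model_spec("svm", cost = 60)

#' Train a classifier
#'
#' Deterministic given `(X, y, spec)` including the spec's seed. Class
#' imbalance is handled by inverse-frequency class weights when enabled in
#' the spec. The fitted object records the feature-name contract and
#' refuses prediction inputs that violate it.
#'
#' @param X Feature matrix or data frame (finite values).
#' @param y Binary labels (0/1), both classes present.
#' @param spec A [model_spec()].
#' @return A `trained_classifier`.
#' @export
train_classifier <- function(X, y, spec) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!all(is.finite(X))) abort("`X` must be finite.")
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("`y` must contain both classes.")
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  w0 <- if (spec$class_weights) length(y) / (2 * n0) else 1
  w1 <- if (spec$class_weights) length(y) / (2 * n1) else 1
  p <- spec$params
  fit <- with_seed(spec$seed, switch(spec$family,
    svm = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                     kernel = p$kernel, cost = p$cost,
                     class.weights = c("0" = w0, "1" = w1),
                     scale = FALSE),
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$eta,
                      max_depth = p$max_depth, max_leaves = p$max_leaves,
                      tree_method = "hist",
                      grow_policy = if (p$max_leaves > 0) "lossguide" else "depthwise",
                      scale_pos_weight = if (spec$class_weights) n0 / n1 else 1,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = p$nrounds, verbose = 0)
    },
    mlp = nnet::nnet(x = X, y = y, size = p$size, decay = p$decay,
                     maxit = p$maxit, entropy = TRUE, trace = FALSE,
                     weights = ifelse(y == 1, w1, w0), MaxNWts = 1e5)
  ))
  structure(list(spec = spec, fit = fit, feature_names = colnames(X)),
            class = "trained_classifier")
}

#' Predict malignancy probabilities
#'
#' One score in \[0, 1\] per row. The input's column names and order must
#' match the training feature contract; the first offending feature is
#' named in the error otherwise.
#'
#' @param model A `trained_classifier`.
#' @param X New data with the training feature columns.
#' @return A numeric vector of probabilities.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!identical(colnames(X), model$feature_names)) {
    mism <- which(!(colnames(X) == model$feature_names[seq_len(ncol(X))]))[1]
    off <- if (ncol(X) != length(model$feature_names)) {
      sprintf("expected %d features, got %d", length(model$feature_names), ncol(X))
    } else {
      sprintf("feature %d is `%s`, expected `%s`", mism, colnames(X)[mism],
              model$feature_names[mism])
    }
    abort(paste0("Feature contract violation: ", off, "."))
  }
  scores <- switch(model$spec$family,
    svm = {
      # logistic squash of the (deterministic) decision value; orientation
      # depends on which class e1071 treats as positive
      pr <- predict(model$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      if (colnames(dv)[1] == "0/1") stats::plogis(-dv[, 1]) else stats::plogis(dv[, 1])
    },
    gbt = predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    mlp = as.numeric(predict(model$fit, X))
  )
  pmin(pmax(as.numeric(scores), 0), 1)
}

#' @rdname predict_proba
#' @param cutoff Decision threshold; the predicted label is 1 iff the score
#'   is greater than or equal to `cutoff`.
#' @export
predict_label <- function(model, X, cutoff = 0.5) {
  as.integer(predict_proba(model, X) >= cutoff)
}

#' Seeded random hyperparameter search with inner cross-validation
#'
#' Draws up to `budget` configurations from a discrete search space,
#' evaluates each by mean inner-CV AUC-ROC, and returns the best spec plus
#' the full trial log. This is a deliberately simple, seeded search over
#' the same hyperparameter dimensions a heavier optimiser would tune;
#' exhaustive when the grid is smaller than the budget.
#'
#' @param X,y Training data (binary labels).
#' @param family Classifier family.
#' @param search_space Named list of candidate values per hyperparameter,
#'   e.g. `list(cost = c(0.01, 1, 60))`. Must be non-empty.
#' @param budget Maximum number of configurations to evaluate (>= 1).
#' @param seed Seed for sampling configurations and folds.
#' @param n_folds Inner CV folds (default 3).
#' @return A list with `best_spec` (a [model_spec()]), `best_auc`, and
#'   `trials` (tibble: one row per configuration with its mean AUC).
#' @export
hyperparameter_search <- function(X, y, family, search_space, budget = 10L,
                                  seed = 1L, n_folds = 3L) {
  if (length(search_space) == 0) abort("`search_space` must not be empty.")
  if (budget < 1) abort("`budget` must be at least 1.")
  grid <- expand.grid(search_space, stringsAsFactors = FALSE)
  take <- if (nrow(grid) <= budget) seq_len(nrow(grid)) else {
    with_seed(derive_seed(seed, 1L), sample(nrow(grid), budget))
  }
  folds <- with_seed(derive_seed(seed, 2L), stratified_folds(y, n_folds))
  trials <- vector("list", length(take))
  for (t in seq_along(take)) {
    params <- as.list(grid[take[t], , drop = FALSE])
    names(params) <- names(grid)
    spec <- do.call(model_spec, c(list(family = family), params,
                                  list(seed = derive_seed(seed, 10L + t))))
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      m <- train_classifier(X[tr, , drop = FALSE], y[tr], spec)
      s <- predict_proba(m, X[!tr, , drop = FALSE])
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      auc_roc(s, y[!tr])
    }, numeric(1))
    trials[[t]] <- dplyr::bind_cols(
      tibble::as_tibble(params),
      tibble::tibble(mean_auc = mean(aucs, na.rm = TRUE))
    )
  }
  trials <- dplyr::bind_rows(trials)
  best <- which.max(trials$mean_auc)
  best_params <- as.list(grid[take[best], , drop = FALSE])
  names(best_params) <- names(grid)
  best_spec <- do.call(model_spec, c(list(family = family), best_params,
                                     list(seed = seed)))
  list(best_spec = best_spec, best_auc = trials$mean_auc[best], trials = trials)
}
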