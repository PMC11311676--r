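#' Fit a PCA reduction on a training feature matrix
#'
#' Principal component analysis with training-mean centring (no scaling).
#' The fitted model carries the loadings and centre so that test data are
#' projected with the training parameters only — the API separates fitting
#' from transformation to keep held-out folds untouched.
#'
#' @param X Numeric matrix or data frame of features (rows = samples).
#' @param k Number of retained components; must satisfy
#'   `k <= min(nrow(X) - 1, ncol(X))`.
#' @return A `selection_model` of kind `"PCA"` with fields `rotation`,
#'   `center`, `sdev`, `k`.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1) abort("`k` must be at least 1.")
  if (k > min(nrow(X) - 1L, ncol(X))) {
    abort(sprintf("`k` = %d exceeds min(n_samples - 1, n_features) = %d.",
                  k, min(nrow(X) - 1L, ncol(X))))
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(
    list(kind = "PCA", k = k, rotation = p$rotation[, seq_len(k), drop = FALSE],
         center = p$center, sdev = p$sdev, feature_names = colnames(X),
         fitted = TRUE),
    class = "selection_model"
  )
}

#' Project data onto fitted principal components
#'
#' @param model A fitted `selection_model` of kind `"PCA"`.
#' @param X Data with the same feature columns as at fit time.
#' @return A numeric matrix with `model$k` columns (`PC1` ... `PCk`).
#' @export
pca_transform <- function(model, X) {
  check_fitted(model, "PCA")
  X <- as.matrix(X)
  sweep(X, 2, model$center) %*% model$rotation
}

check_fitted <- function(model, kind = NULL) {
  if (!inherits(model, "selection_model") || !isTRUE(model$fitted)) {
    abort("Selection model must be fitted before transforming data.")
  }
  if (!is.null(kind) && model$kind != kind) {
    abort(sprintf("Expected a %s selection model, got %s.", kind, model$kind))
  }
  invisible(model)
}

# Peng-style 3-level discretisation at mean +/- SD of the training column.
# Features that are already discrete (at most 3 distinct values) are used
# as-is; binning them at mean +/- SD could collapse everything into the
# middle level.
discretize_mrmr <- function(x, m = mean(x), s = sd(x)) {
  u <- unique(x)
  if (length(u) <= 3L) return(match(x, sort(u)))
  if (!is.finite(s) || s == 0) return(rep(2L, length(x)))
  ifelse(x < m - s, 1L, ifelse(x > m + s, 3L, 2L))
}

# Mutual information (nats) of two discrete vectors.
mi_disc <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  sum(ifelse(p > 0, p * log(p / e), 0))
}

#' Greedy mRMR feature selection
#'
#' Maximum-relevance minimum-redundancy selection with the MID (difference)
#' criterion: the first feature maximises the mutual information `I(f; y)`;
#' each subsequent feature maximises
#' `I(f; y) - mean over selected g of I(f; g)`. Continuous features are
#' discretised into three levels at mean +/- SD; mutual information is
#' computed on the discretised values. Ties break to the lowest feature
#' index, so selection is deterministic.
#'
#' @param X Feature matrix or data frame.
#' @param y Binary labels (0/1).
#' @param k Number of features to select (`k <= ncol(X)`).
#' @param criterion `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return A `selection_model` of kind `"mRMR"` with `selected` (indices in
#'   selection order), `selected_names`, and the per-step criterion values.
#' @export
mrmr_select <- function(X, y, k, criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k > ncol(X)) abort("`k` exceeds the number of features.")
  if (length(unique(y)) < 2) abort("`y` must contain both classes.")
  D <- apply(X, 2, discretize_mrmr)
  rel <- apply(D, 2, function(f) mi_disc(f, y))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- rep(0, ncol(X))
  for (step in seq_len(k)) {
    if (step == 1L) {
      crit <- rel
    } else {
      red <- red_sum / length(selected)
      crit <- if (criterion == "MID") rel - red else rel / (red + 1e-12)
    }
    crit[selected] <- -Inf
    s <- unname(which.max(crit))  # first index on ties
    selected <- c(selected, s)
    scores <- c(scores, crit[s])
    if (step < k) {
      red_sum <- red_sum + apply(D, 2, function(f) mi_disc(f, D[, s]))
    }
  }
  structure(
    list(kind = "mRMR", k = k, selected = selected,
         selected_names = colnames(X)[selected], scores = scores,
         criterion = criterion, feature_names = colnames(X), fitted = TRUE),
    class = "selection_model"
  )
}

#' Fit or apply a feature-selection step of any kind
#'
#' Unified front end over [pca_fit()], [mrmr_select()] and the identity
#' (`"none"`), mirroring the fit/transform split.
#'
#' @param X Feature matrix or data frame.
#' @param y Labels (used by mRMR only).
#' @param kind `"PCA"`, `"mRMR"` or `"none"`.
#' @param k Retained components/features (ignored for `"none"`).
#' @return `selection_fit()` returns a `selection_model`;
#'   `select_transform()` the reduced matrix.
#' @export
selection_fit <- function(X, y = NULL, kind = c("PCA", "mRMR", "none"), k = 95L) {
  kind <- match.arg(kind)
  switch(kind,
         PCA = pca_fit(X, k),
         mRMR = mrmr_select(X, y, k),
         none = structure(list(kind = "none", k = ncol(as.matrix(X)),
                               feature_names = colnames(as.matrix(X)),
                               fitted = TRUE),
                          class = "selection_model"))
}

#' @rdname selection_fit
#' @param model A fitted `selection_model`.
#' @export
select_transform <- function(model, X) {
  check_fitted(model)
  X <- as.matrix(X)
  switch(model$kind,
         PCA = pca_transform(model, X),
         mRMR = X[, model$selected, drop = FALSE],
         none = X)
}

#' Serialise / restore a selection model as versioned JSON
#'
#' @param model A fitted `selection_model`.
#' @param path File path.
#' @return `write_selection_model()` returns `path` invisibly;
#'   `read_selection_model()` the restored model.
#' @export
write_selection_model <- function(model, path) {
  check_fitted(model)
  payload <- list(format_version = 1L, kind = model$kind, k = model$k)
  if (model$kind == "PCA") {
    payload$rotation <- unclass(model$rotation)
    payload$center <- model$center
    payload$sdev <- model$sdev
  }
  if (model$kind == "mRMR") {
    payload$selected <- model$selected
    payload$selected_names <- model$selected_names
    payload$criterion <- model$criterion
  }
  payload$feature_names <- model$feature_names
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_selection_model
#' @export
read_selection_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(kind = p$kind, k = as.integer(p$k), fitted = TRUE,
            feature_names = p$feature_names)
  if (p$kind == "PCA") {
    m$rotation <- as.matrix(p$rotation)
    m$center <- p$center
    m$sdev <- p$sdev
  }
  if (p$kind == "mRMR") {
    m$selected <- as.integer(p$selected)
    m$selected_names <- p$selected_names
    m$criterion <- p$criterion
  }
  structure(m, class = "selection_model")
}
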