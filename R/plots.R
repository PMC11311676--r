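#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline geom_errorbar facet_wrap labs scale_fill_viridis_c
#'   theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' Plot transverse slices of a volume or heatmap
#'
#' @param x An [mri_volume()].
#' @param slices z indices to show (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mri_volume
#' @export
autoplot.mri_volume <- function(x, slices = NULL, ...) {
  d <- dim(x$data)
  if (is.null(slices)) slices <- ceiling(d[3] / 2)
  df <- purrr::map_dfr(slices, function(z) {
    tibble::tibble(
      x = rep(seq_len(d[1]), times = d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      z = z, intensity = as.vector(x$data[, , z])
    )
  })
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    geom_raster() +
    facet_wrap(~z, labeller = "label_both") +
    scale_fill_viridis_c(option = "magma") +
    coord_fixed() +
    labs(title = sprintf("%s volume", x$modality), fill = "intensity") +
    theme_minimal()
}

#' @rdname autoplot.mri_volume
#' @method autoplot heatmap
#' @export
autoplot.heatmap <- function(x, slices = NULL, ...) {
  d <- dim(x$confidence)
  if (is.null(slices)) slices <- ceiling(d[3] / 2)
  df <- purrr::map_dfr(slices, function(z) {
    tibble::tibble(
      x = rep(seq_len(d[1]), times = d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      z = z, confidence = as.vector(x$confidence[, , z])
    )
  })
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$confidence)) +
    geom_raster() +
    facet_wrap(~z, labeller = "label_both") +
    scale_fill_viridis_c(limits = c(0, 1)) +
    coord_fixed() +
    labs(title = "Sliding-window confidence heatmap", fill = "confidence") +
    theme_minimal()
}

#' Plot an ROC curve from scores and labels
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return A ggplot object with the empirical ROC curve and its AUC in the
#'   title.
#' @export
plot_roc <- function(scores, labels) {
  y <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- as.integer(scores >= t)
    tibble::tibble(tpr = sum(pred == 1 & y == 1) / sum(y == 1),
                   fpr = sum(pred == 1 & y == 0) / sum(y == 0))
  })
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() + geom_point(size = 0.8) +
    geom_abline(linetype = "dashed", colour = "grey60") +
    coord_fixed() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", auc_roc(scores, y))) +
    theme_minimal()
}

#' Plot the per-fold metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(x, ...) {
  df <- tidy(x)
  ggplot(df, aes(x = .data$metric, y = .data$value, colour = .data$split)) +
    geom_point(position = ggplot2::position_jitter(width = 0.08, height = 0,
                                                   seed = 1)) +
    labs(y = "value", x = NULL, title = sprintf("Evaluation (%s)", x$mode)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
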