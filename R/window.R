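#' Build a sliding-window grid
#'
#' Places windows of `window_shape` (default 70 x 65 x 3 voxels) at regular
#' strides of `floor(dim * (1 - overlap))` per axis (35, 32, 1 for the
#' default geometry at 50% overlap), plus one final clamped window per axis
#' so that every voxel of the grid is covered. Window ordering is
#' deterministic: z-major, then y, then x.
#'
#' @param grid_shape Voxel grid triple.
#' @param window_shape Window size per axis; must not exceed the grid.
#' @param overlap Fractional overlap in \[0, 1), default 0.5.
#' @return A `window_grid`: list with `boxes` (list of `region_box`es,
#'   kind `"window"`), `window_shape`, `overlap`, `grid_shape`.
#' @examples
#' wg <- make_windows(c(10, 4, 3), c(4, 4, 3), overlap = 0.5)
#' vapply(wg$boxes, function(b) b$lo[1], integer(1))  # 0 2 4 6
#' @export
make_windows <- function(grid_shape, window_shape = c(70, 65, 3), overlap = 0.5) {
  assert_triple(grid_shape, "grid_shape", integer = TRUE)
  assert_triple(window_shape, "window_shape", integer = TRUE)
  if (any(window_shape > grid_shape)) {
    abort("Window must not exceed the grid on any axis.")
  }
  if (overlap < 0 || overlap >= 1) abort("`overlap` must lie in [0, 1).")
  origins <- lapply(1:3, function(a) {
    w <- window_shape[a]; g <- grid_shape[a]
    stride <- max(1L, as.integer(floor(w * (1 - overlap))))
    o <- as.integer(seq.int(0L, g - w, by = stride))
    if (o[length(o)] != g - w) o <- c(o, as.integer(g - w))
    o
  })
  boxes <- list()
  for (z in origins[[3]]) for (y in origins[[2]]) for (x in origins[[1]]) {
    lo <- c(x, y, z)
    boxes[[length(boxes) + 1]] <- region_box(lo, lo + window_shape,
                                             kind = "window", grid = grid_shape)
  }
  structure(list(boxes = boxes, window_shape = as.integer(window_shape),
                 overlap = overlap, grid_shape = as.integer(grid_shape),
                 origins = origins),
            class = "window_grid")
}

#' Label a window by its lesion overlap
#'
#' The overlap ratio is lesion-relative: `|window intersect lesion| /
#' |lesion|`, computed per lesion. If any lesion's ratio strictly exceeds
#' `ratio_threshold` the window takes that lesion's label, with malignant
#' winning when several lesions qualify; otherwise the window is background.
#' The lesion-relative denominator keeps small lesions labelable: a
#' window-relative ratio could never exceed 0.5 for any lesion smaller than
#' half the window volume.
#'
#' @param box A `region_box` (window).
#' @param lesions List of `list(mask, label)` on the same grid.
#' @param ratio_threshold Strictly-exceeded threshold, default 0.5.
#' @return `"background"`, `"benign"` or `"malignant"`.
#' @export
label_window <- function(box, lesions, ratio_threshold = 0.5) {
  best <- "background"
  for (l in lesions) {
    vol <- sum(l$mask != 0)
    if (vol == 0) next
    inter <- sum(crop_box(l$mask, box) != 0)
    if (inter / vol > ratio_threshold) {
      lab <- if (l$label == 1L) "malignant" else "benign"
      if (lab == "malignant") return("malignant")
      best <- lab
    }
  }
  best
}

#' Accumulate window confidences into a voxel-wise heatmap
#'
#' Each voxel's confidence is the mean of the scores of all windows covering
#' it (order-independent); the per-voxel coverage count is recorded. With a
#' covering window grid, coverage is at least 1 everywhere.
#'
#' @param grid A [make_windows()] result.
#' @param scores One score in \[0, 1\] per window, in window order.
#' @return A `heatmap`: list with `confidence` and `coverage` arrays.
#' @export
build_heatmap <- function(grid, scores) {
  stopifnot(inherits(grid, "window_grid"))
  if (length(scores) != length(grid$boxes)) {
    abort(sprintf("Need one score per window: %d windows, %d scores.",
                  length(grid$boxes), length(scores)))
  }
  if (any(scores < 0 | scores > 1)) abort("Scores must lie in [0, 1].")
  acc <- array(0, dim = grid$grid_shape)
  cov <- array(0L, dim = grid$grid_shape)
  for (k in seq_along(grid$boxes)) {
    b <- grid$boxes[[k]]
    xs <- (b$lo[1] + 1):b$hi[1]; ys <- (b$lo[2] + 1):b$hi[2]
    zs <- (b$lo[3] + 1):b$hi[3]
    acc[xs, ys, zs] <- acc[xs, ys, zs] + scores[k]
    cov[xs, ys, zs] <- cov[xs, ys, zs] + 1L
  }
  conf <- acc / pmax(cov, 1L)
  structure(list(confidence = conf, coverage = cov), class = "heatmap")
}

#' Choose a heatmap cutoff from a validation ROC curve
#'
#' Maximises Youden's J (sensitivity + specificity - 1) over candidate
#' cutoffs (midpoints between consecutive distinct validation scores plus
#' the two boundary cutoffs), with the decision rule "positive iff score >
#' cutoff". Perfectly separated classes yield the midpoint between them.
#' When no cutoff achieves J > 0 (anti-separated or uninformative scores)
#' the returned cutoff carries `attr(, "degenerate") = TRUE`.
#'
#' @param val_scores Validation scores.
#' @param val_labels Binary validation labels (both classes present).
#' @return The cutoff, with attributes `youden_j` and `degenerate`.
#' @export
choose_cutoff <- function(val_scores, val_labels) {
  y <- as.integer(val_labels)
  if (length(unique(y)) < 2) abort("Validation labels must contain both classes.")
  s <- sort(unique(val_scores))
  cand <- c(s[1] - 1e-9, if (length(s) > 1) (head(s, -1) + s[-1]) / 2, s[length(s)])
  j <- vapply(cand, function(cc) {
    pred <- as.integer(val_scores > cc)
    sens <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)
  out <- cand[best]
  attr(out, "youden_j") <- j[best]
  attr(out, "degenerate") <- j[best] <= 0
  out
}

# Sizes of 6-connected components of a logical 3D array (flood fill).
component_sizes_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(integer(0))
  lab <- integer(prod(d))
  lab[idx] <- -1L  # unvisited foreground
  nxy <- d[1] * d[2]
  sizes <- integer(0)
  comp <- 0L
  for (start in idx) {
    if (lab[start] != -1L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    size <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      z <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      y <- rem %/% d[1]
      x <- rem %% d[1]
      nb <- c(if (x > 0) v - 1L, if (x < d[1] - 1L) v + 1L,
              if (y > 0) v - d[1], if (y < d[2] - 1L) v + d[1],
              if (z > 0) v - nxy, if (z < d[3] - 1L) v + nxy)
      nb <- nb[lab[nb] == -1L]
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Image-level label from a thresholded heatmap
#'
#' Label 1 iff any voxel confidence strictly exceeds the cutoff. An
#' optional minimum connected-component size (6-connectivity) requires a
#' supra-threshold blob of at least `min_area` voxels, and an optional
#' gland mask restricts the decision to the gland — both address the
#' failure mode of lesion-like structures outside the prostate. Raising
#' the cutoff can never flip the label from 0 to 1.
#'
#' @param heatmap A [build_heatmap()] result.
#' @param cutoff Confidence threshold.
#' @param min_area Minimum supra-threshold component size in voxels.
#' @param gland_mask Optional 0/1 array restricting the decision.
#' @return 0 or 1.
#' @export
image_label <- function(heatmap, cutoff, min_area = 1L, gland_mask = NULL) {
  stopifnot(inherits(heatmap, "heatmap"))
  supra <- heatmap$confidence > cutoff
  if (!is.null(gland_mask)) supra <- supra & (gland_mask != 0)
  if (min_area <= 1L) return(as.integer(any(supra)))
  sizes <- component_sizes_3d(supra)
  as.integer(length(sizes) > 0 && max(sizes) >= min_area)
}

#' Tabulate a window grid with labels and scores
#'
#' @param grid A [make_windows()] result.
#' @param lesions Optional lesion list for three-way labelling.
#' @param scores Optional per-window scores.
#' @return A tibble: window index, origin, size, and optional `label3`
#'   (background/benign/malignant), `label` (binary: malignant vs rest)
#'   and `score` columns.
#' @export
window_table <- function(grid, lesions = NULL, scores = NULL) {
  n <- length(grid$boxes)
  tb <- tibble::tibble(
    window = seq_len(n),
    lo_x = vapply(grid$boxes, function(b) b$lo[1], integer(1)),
    lo_y = vapply(grid$boxes, function(b) b$lo[2], integer(1)),
    lo_z = vapply(grid$boxes, function(b) b$lo[3], integer(1))
  )
  if (!is.null(lesions)) {
    tb$label3 <- vapply(grid$boxes, label_window, character(1), lesions = lesions)
    tb$label <- as.integer(tb$label3 == "malignant")
  }
  if (!is.null(scores)) tb$score <- scores
  tb
}
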