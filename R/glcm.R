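#' The 13 unique 3D offsets at Chebyshev distance 1
#'
#' All 26 nearest-neighbour displacement vectors collapse to 13 unique
#' directions once antipodal pairs are merged (the co-occurrence matrix is
#' symmetrised, so an offset and its negation are equivalent). The canonical
#' representative has positive z, or z = 0 and positive y, or z = y = 0 and
#' positive x; ordering is lexicographic in (z, y, x).
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) displacements.
#' @export
glcm_offsets_3d <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  keep <- g$dz > 0 | (g$dz == 0 & g$dy > 0) | (g$dz == 0 & g$dy == 0 & g$dx > 0)
  g <- g[keep, ]
  g <- g[order(g$dz, g$dy, g$dx), ]
  as.matrix(g)
}

#' Quantize a volume to equal-width gray levels
#'
#' Bins intensities into `levels` equal-width bins over the volume's own
#' intensity range. A constant volume maps entirely to level 1.
#'
#' @param x A numeric array.
#' @param levels Number of gray levels.
#' @return An integer array of levels in `1:levels`.
#' @export
quantize_volume <- function(x, levels = 32L) {
  r <- range(x)
  if (r[1] == r[2]) return(array(1L, dim = dim(x)))
  br <- seq(r[1], r[2], length.out = levels + 1)
  q <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  array(as.integer(q), dim = dim(x))
}

#' 3D gray-level co-occurrence matrices
#'
#' Builds one symmetrised, normalised L x L co-occurrence matrix per offset,
#' counting voxel pairs `(v, v + offset)` over the whole volume. Each matrix
#' is symmetric and sums to 1 — the substrate for [haralick_features()].
#'
#' @param vol An [mri_volume()] or a plain 3D numeric array (e.g. a region
#'   sub-volume).
#' @param levels Number of gray levels (default 32).
#' @param offsets Integer matrix of displacement vectors; default
#'   [glcm_offsets_3d()].
#' @return An object of class `glcm3d`: list with `matrices` (list of L x L
#'   matrices, one per offset), `levels`, `offsets`.
#' @export
glcm_3d <- function(vol, levels = 32L, offsets = glcm_offsets_3d()) {
  x <- if (is_mri_volume(vol)) vol$data else vol
  d <- dim(x)
  if (any(d <= apply(abs(offsets), 2, max))) {
    abort("Volume is smaller than the co-occurrence offset reach.")
  }
  q <- quantize_volume(x, levels)
  L <- as.integer(levels)
  mats <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    xs <- seq_len(d[1] - abs(o[1])); ys <- seq_len(d[2] - abs(o[2]))
    zs <- seq_len(d[3] - abs(o[3]))
    a_idx <- list(if (o[1] >= 0) xs else xs + abs(o[1]),
                  if (o[2] >= 0) ys else ys + abs(o[2]),
                  if (o[3] >= 0) zs else zs + abs(o[3]))
    b_idx <- list(a_idx[[1]] + o[1], a_idx[[2]] + o[2], a_idx[[3]] + o[3])
    ia <- q[a_idx[[1]], a_idx[[2]], a_idx[[3]], drop = FALSE]
    ib <- q[b_idx[[1]], b_idx[[2]], b_idx[[3]], drop = FALSE]
    counts <- tabulate((as.integer(ib) - 1L) * L + as.integer(ia), nbins = L * L)
    M <- matrix(counts, L, L)
    M <- M + t(M)
    mats[[k]] <- M / sum(M)
  }
  structure(list(matrices = mats, levels = L, offsets = offsets), class = "glcm3d")
}

# The 13 classic co-occurrence statistics, in fixed order.
haralick_stat_names <- function() {
  c("energy", "contrast", "correlation", "variance", "homogeneity",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2")
}

# log2 with 0 * log(0) := 0
xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

haralick_one <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)                      # == colSums for a symmetric P
  mu <- sum(seq_len(L) * px)
  sdx <- sqrt(sum((seq_len(L) - mu)^2 * px))
  # diagonal-sum / diagonal-difference marginals
  psum <- as.vector(rowsum(as.vector(P), group = as.vector(i + j)))   # k = 2..2L
  ks <- sort(unique(as.vector(i + j)))
  pdiff <- as.vector(rowsum(as.vector(P), group = as.vector(abs(i - j))))
  kd <- sort(unique(as.vector(abs(i - j))))                            # 0..L-1

  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sdx > 0) sum((i - mu) * (j - mu) * P) / sdx^2 else 0
  variance <- sum((i - mu)^2 * P)
  homogeneity <- sum(P / (1 + (i - j)^2))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  diff_average <- sum(kd * pdiff)
  difference_variance <- sum((kd - diff_average)^2 * pdiff)
  difference_entropy <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px))
  hxy1 <- -sum(P * ifelse(outer(px, px) > 0, log2(outer(px, px)), 0))
  hxy2 <- -sum(xlogx(as.vector(outer(px, px))))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * log(2) * (hxy2 - entropy))))
  c(energy, contrast, correlation, variance, homogeneity, sum_average,
    sum_variance, sum_entropy, entropy, difference_variance,
    difference_entropy, imc1, imc2)
}

#' Haralick texture statistics of a 3D co-occurrence object
#'
#' Computes 13 classic statistics (energy, contrast, correlation, variance,
#' homogeneity, sum average, sum variance, sum entropy, entropy, difference
#' variance, difference entropy, and the two information measures of
#' correlation) for each offset's matrix: 13 x 13 = 169 values with stable
#' names. Entropies use log base 2. Sum variance is centred on the sum
#' average. When a marginal SD is zero the correlation is undefined and
#' reported as 0.
#'
#' @param glcm A `glcm3d` from [glcm_3d()].
#' @return A named numeric vector of length `13 * n_offsets` (169 for the
#'   default offsets), ordered statistic-within-offset.
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm3d"))
  stats <- haralick_stat_names()
  out <- numeric(0)
  for (k in seq_along(glcm$matrices)) {
    v <- haralick_one(glcm$matrices[[k]])
    o <- glcm$offsets[k, ]
    names(v) <- sprintf("glcm_%s_o%d%d%d", stats,
                        o[1] + 1, o[2] + 1, o[3] + 1)
    out <- c(out, v)
  }
  out
}
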