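# Small phantom geometry used throughout the tests: full anatomy on a
# 48 x 48 x 12 grid so cases generate in tens of milliseconds.
small_spec <- function(...) {
  args <- list(grid_shape = c(48, 48, 12), spacing_mm = c(0.75, 0.75, 3),
               gland_radius_mm = 12, lesion_radius_mm_range = c(2.5, 4.5),
               lesion_count_range = c(1, 2))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

rand_vol <- function(dim, seed = 1) {
  set.seed(seed)
  array(runif(prod(dim)), dim = dim)
}

# ---- brute-force oracles (independent, loop-based implementations) ----

oracle_quantize <- function(x, levels) {
  r <- range(x)
  if (r[1] == r[2]) return(array(1L, dim(x)))
  q <- 1L + floor((x - r[1]) / (r[2] - r[1]) * levels)
  q[q > levels] <- levels
  array(as.integer(q), dim(x))
}

# Pair enumeration over every voxel and offset, counting both directions.
oracle_glcm <- function(x, levels, offsets) {
  q <- oracle_quantize(x, levels)
  d <- dim(q)
  out <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    M <- matrix(0, levels, levels)
    for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
      ii <- i + o[1]; jj <- j + o[2]; ll <- l + o[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && ll >= 1 && ll <= d[3]) {
        a <- q[i, j, l]; b <- q[ii, jj, ll]
        M[a, b] <- M[a, b] + 1
        M[b, a] <- M[b, a] + 1
      }
    }
    out[[k]] <- M / sum(M)
  }
  out
}

oracle_lbp <- function(x) {
  d <- dim(x)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  h <- numeric(64)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (l in 2:(d[3] - 1)) {
    code <- 0
    for (k in seq_along(shifts)) {
      s <- shifts[[k]]
      if (x[i + s[1], j + s[2], l + s[3]] >= x[i, j, l]) {
        code <- code + 2^(k - 1)
      }
    }
    h[code + 1] <- h[code + 1] + 1
  }
  h / sum(h)
}

# numpy.gradient convention: central differences inside, one-sided at the
# boundary, divided by spacing.
oracle_gradient <- function(x, spacing) {
  d <- dim(x)
  g <- list(array(0, d), array(0, d), array(0, d))
  at <- function(i, j, l) x[i, j, l]
  for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    g[[1]][i, j, l] <- if (i == 1) (at(2, j, l) - at(1, j, l)) / spacing[1]
      else if (i == d[1]) (at(d[1], j, l) - at(d[1] - 1, j, l)) / spacing[1]
      else (at(i + 1, j, l) - at(i - 1, j, l)) / (2 * spacing[1])
    g[[2]][i, j, l] <- if (j == 1) (at(i, 2, l) - at(i, 1, l)) / spacing[2]
      else if (j == d[2]) (at(i, d[2], l) - at(i, d[2] - 1, l)) / spacing[2]
      else (at(i, j + 1, l) - at(i, j - 1, l)) / (2 * spacing[2])
    g[[3]][i, j, l] <- if (l == 1) (at(i, j, 2) - at(i, j, 1)) / spacing[3]
      else if (l == d[3]) (at(i, j, d[3]) - at(i, j, d[3] - 1)) / spacing[3]
      else (at(i, j, l + 1) - at(i, j, l - 1)) / (2 * spacing[3])
  }
  g
}

oracle_hog <- function(x, spacing, cells = c(2, 2, 1), bins = 16) {
  axes <- hog_axes_3d()
  g <- oracle_gradient(x, spacing)
  d <- dim(x)
  n_cells <- prod(cells)
  h <- numeric(n_cells * bins)
  cell_of <- function(i, n, nc) min(nc, 1 + ((i - 1) * nc) %/% n)
  for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    gv <- c(g[[1]][i, j, l], g[[2]][i, j, l], g[[3]][i, j, l])
    mag <- sqrt(sum(gv^2))
    proj <- abs(as.numeric(axes %*% gv))
    b <- which.max(proj)
    cc <- (cell_of(l, d[3], cells[3]) - 1) * cells[1] * cells[2] +
      (cell_of(j, d[2], cells[2]) - 1) * cells[1] + cell_of(i, d[1], cells[1])
    h[(cc - 1) * bins + b] <- h[(cc - 1) * bins + b] + mag
  }
  out <- numeric(0)
  for (cc in seq_len(n_cells)) {
    hc <- h[((cc - 1) * bins + 1):(cc * bins)]
    out <- c(out, hc / sqrt(sum(hc^2) + 1e-18))
  }
  out
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive greedy mRMR with a naive mutual-information routine.
oracle_mi <- function(a, b) {
  lv_a <- sort(unique(a)); lv_b <- sort(unique(b))
  n <- length(a)
  mi <- 0
  for (u in lv_a) for (v in lv_b) {
    pj <- sum(a == u & b == v) / n
    if (pj > 0) mi <- mi + pj * log(pj / ((sum(a == u) / n) * (sum(b == v) / n)))
  }
  mi
}

oracle_mrmr <- function(X, y, k) {
  disc <- function(x) {
    u <- unique(x)
    if (length(u) <= 3) return(match(x, sort(u)))
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(2L, length(x)))
    ifelse(x < m - s, 1L, ifelse(x > m + s, 3L, 2L))
  }
  D <- apply(X, 2, disc)
  sel <- integer(0)
  for (step in 1:k) {
    best <- -Inf; best_i <- NA
    for (i in seq_len(ncol(X))) {
      if (i %in% sel) next
      rel <- oracle_mi(D[, i], y)
      red <- if (length(sel)) mean(sapply(sel, function(s) oracle_mi(D[, i], D[, s]))) else 0
      crit <- rel - red
      if (crit > best + 1e-12) { best <- crit; best_i <- i }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# Stride enumeration for window origins along one axis.
oracle_origins <- function(g, w, overlap) {
  stride <- max(1, floor(w * (1 - overlap)))
  o <- c()
  pos <- 0
  while (pos <= g - w) { o <- c(o, pos); pos <- pos + stride }
  if (o[length(o)] != g - w) o <- c(o, g - w)
  o
}
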