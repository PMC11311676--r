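test_that("there are exactly 13 unique distance-1 offsets", {
  off <- glcm_offsets_3d()
  expect_identical(nrow(off), 13L)
  expect_identical(nrow(unique(rbind(off, -off))), 26L)  # no antipodal dupes
})

test_that("a constant volume yields single-entry co-occurrence matrices", {
  g <- glcm_3d(array(5, c(4, 4, 4)), levels = 8)
  for (M in g$matrices) {
    expect_equal(sum(M), 1)
    expect_equal(M[1, 1], 1)
  }
  h <- haralick_features(g)
  expect_length(h, 169)
  expect_equal(unname(h[grep("energy", names(h))]), rep(1, 13))
  expect_equal(unname(h[grep("^glcm_entropy", names(h))]), rep(0, 13))
  expect_equal(unname(h[grep("contrast", names(h))]), rep(0, 13))
  # degenerate marginals: correlation falls back to 0
  expect_equal(unname(h[grep("correlation", names(h))]), rep(0, 13))
})

test_that("the checkerboard co-occurrence matrix matches hand enumeration", {
  x <- array(c(0, 10, 10, 0, 0, 10, 10, 0), c(2, 2, 2))
  g <- glcm_3d(x, levels = 2, offsets = matrix(c(1, 0, 0), 1))
  # 4 voxel pairs along +x, every pair is (0,10) or (10,0); symmetrised:
  expect_equal(g$matrices[[1]], matrix(c(0, 0.5, 0.5, 0), 2, 2))
  ent <- haralick_features(g)[["glcm_entropy_o211"]]
  p <- as.vector(g$matrices[[1]]); p <- p[p > 0]
  expect_equal(ent, -sum(p * log2(p)))
})

test_that("co-occurrence matrices match brute-force pair enumeration", {
  off <- glcm_offsets_3d()
  for (seed in 1:4) {
    dims <- list(c(5, 4, 3), c(8, 8, 4), c(3, 3, 3), c(6, 2, 2))[[seed]]
    x <- rand_vol(dims, seed = seed)
    g <- glcm_3d(x, levels = 4)
    o <- oracle_glcm(x, 4, off)
    for (k in 1:13) expect_equal(g$matrices[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("co-occurrence matrices are symmetric and normalised", {
  x <- rand_vol(c(7, 6, 5), seed = 9)
  g <- glcm_3d(x, levels = 16)
  for (M in g$matrices) {
    expect_equal(M, t(M))
    expect_equal(sum(M), 1)
    expect_true(all(M >= 0))
  }
  expect_error(glcm_3d(array(1, c(1, 4, 4))), "smaller than")
})

test_that("LBP puts a constant volume entirely in the all-ones code", {
  h <- lbp_3d(array(2, c(5, 5, 5)))
  expect_equal(unname(h[64]), 1)  # code 63: every neighbour >= centre
  expect_equal(sum(h), 1)
})

test_that("LBP histograms match the brute-force neighbourhood oracle", {
  x <- array(0, c(3, 3, 3)); x[2, 2, 2] <- 1  # single bright centre
  expect_equal(unname(lbp_3d(x)), oracle_lbp(x), tolerance = 1e-12)
  for (seed in 5:7) {
    y <- rand_vol(c(6, 5, 4), seed = seed)
    expect_equal(unname(lbp_3d(y)), oracle_lbp(y), tolerance = 1e-12)
    expect_equal(sum(lbp_3d(y)), 1)
  }
  expect_error(lbp_3d(array(1, c(2, 5, 5))), "at least 3")
})

test_that("HOG is zero for constant input and concentrated for a pure ramp", {
  expect_true(all(hog_3d(array(1, c(6, 6, 4))) == 0))
  ramp <- array(rep(1:8, times = 8 * 4), c(8, 8, 4))
  h <- hog_3d(ramp)
  m <- matrix(h, nrow = 16)  # bins x cells
  hits <- apply(m, 2, function(col) which(col > 0))
  expect_true(all(lengths(hits) == 1))       # single active bin per cell
  expect_identical(length(unique(unlist(hits))), 1L)  # same bin in every cell
  expect_equal(unname(m[hits[[1]], 1]), 1)   # L2-normalised single spike
})

test_that("HOG matches the brute-force per-voxel binning oracle", {
  for (seed in 11:13) {
    x <- rand_vol(c(8, 8, 4), seed = seed)
    sp <- c(0.75, 0.75, 3)
    expect_equal(unname(hog_3d(x, spacing = sp)), oracle_hog(x, sp),
                 tolerance = 1e-10)
  }
})

test_that("sequence and study descriptors satisfy the 297/891 contract", {
  cs <- generate_case(small_spec(), 1, seed = 2)
  f1 <- extract_sequence_features(cs$t2w)
  expect_identical(ncol(f1), 297L)
  expect_true(all(startsWith(names(f1), "t2w_")))
  expect_false(anyDuplicated(names(f1)) > 0)

  f3 <- extract_study_features(cs)
  expect_identical(ncol(f3), 891L)
  expect_identical(names(f3),
                   c(names(extract_sequence_features(cs$t2w)),
                     names(extract_sequence_features(cs$adc)),
                     names(extract_sequence_features(cs$dwi))))

  fpz <- extract_study_features(cs, adc_only = TRUE)
  expect_identical(ncol(fpz), 297L)
  expect_true(all(startsWith(names(fpz), "adc_")))

  # purity: identical input, identical output
  expect_identical(extract_study_features(cs), f3)

  cs$dwi <- NULL
  expect_error(extract_study_features(cs), "dwi")
})

test_that("feature configuration enforces the 297 contract", {
  expect_error(feature_config(lbp_bins = 32), "not 297")
  expect_silent(cfg <- feature_config())
  expect_identical(cfg$n_features, 297L)
})

test_that("all features are finite on random inputs", {
  for (seed in 1:25) {
    x <- array(rnorm(6 * 6 * 4, sd = 10^runif(1, -3, 3)), c(6, 6, 4))
    f <- extract_sequence_features(mri_volume(x, spacing = c(0.75, 0.75, 3)))
    expect_true(all(is.finite(as.numeric(f[1, ]))))
  }
})

test_that("GLCM and LBP histograms are nearly invariant to periodic shifts", {
  d <- c(12, 12, 6)
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  x <- array(sin(2 * pi * ix / 4) + cos(2 * pi * iy / 4), d)
  xs <- x[c(2:d[1], 1), , ]  # circular shift by one voxel along x
  g1 <- haralick_features(glcm_3d(x, levels = 8))
  g2 <- haralick_features(glcm_3d(xs, levels = 8))
  expect_lt(max(abs(g1 - g2) / pmax(abs(g1), 1)), 0.1)
  expect_lt(max(abs(lbp_3d(x) - lbp_3d(xs))), 0.05)
})
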