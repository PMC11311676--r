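test_that("window origins follow the stride rule with a final clamped window", {
  wg <- make_windows(c(10, 4, 3), c(4, 4, 3), overlap = 0.5)
  expect_identical(wg$origins[[1]], c(0L, 2L, 4L, 6L))
  expect_identical(wg$origins[[2]], 0L)
  expect_length(wg$boxes, 4)

  single <- make_windows(c(8, 8, 4), c(8, 8, 4))
  expect_length(single$boxes, 1)
  expect_error(make_windows(c(6, 6, 4), c(8, 8, 4)), "exceed")
})

test_that("the default 70x65x3 geometry matches stride enumeration and covers the grid", {
  g <- c(149L, 149L, 32L)
  wg <- make_windows(g, c(70, 65, 3), overlap = 0.5)
  for (a in 1:3) {
    expect_identical(as.integer(wg$origins[[a]]),
                     as.integer(oracle_origins(g[a], c(70, 65, 3)[a], 0.5)))
  }
  n_expected <- prod(vapply(1:3, function(a)
    length(oracle_origins(g[a], c(70, 65, 3)[a], 0.5)), numeric(1)))
  expect_identical(length(wg$boxes), as.integer(n_expected))

  cov <- build_heatmap(wg, rep(0.5, length(wg$boxes)))$coverage
  expect_true(all(cov >= 1L))
})

test_that("window labels follow the lesion-relative overlap rule", {
  d <- c(20, 20, 6)
  lesion <- array(0L, d)
  lesion[5:6, 5:6, 2:3] <- 1L  # 8 voxels
  box_all <- region_box(c(0, 0, 0), c(10, 10, 6))
  expect_identical(label_window(box_all, list(list(mask = lesion, label = 1L))),
                   "malignant")
  expect_identical(label_window(box_all, list(list(mask = lesion, label = 0L))),
                   "benign")
  box_away <- region_box(c(10, 10, 0), c(20, 20, 6))
  expect_identical(label_window(box_away, list(list(mask = lesion, label = 1L))),
                   "background")

  # 5 of 8 voxels inside: ratio 0.625 > 0.5; 4 of 8: ratio 0.5 is NOT exceeded
  box5 <- region_box(c(0, 0, 0), c(20, 20, 3))  # z slices 1..3 -> 5? compute below
  les2 <- array(0L, d)
  les2[5, 5, 1:4] <- 1L; les2[5, 6, 1:4] <- 1L  # 8 voxels over z 1..4
  box_z3 <- region_box(c(0, 0, 0), c(20, 20, 3))  # captures z 1..3: 6/8
  expect_identical(label_window(box_z3, list(list(mask = les2, label = 1L))),
                   "malignant")
  box_z2 <- region_box(c(0, 0, 0), c(20, 20, 2))  # z 1..2: 4/8 = 0.5 exactly
  expect_identical(label_window(box_z2, list(list(mask = les2, label = 1L))),
                   "background")

  # malignant wins over benign when both qualify
  les_b <- array(0L, d); les_b[10, 10, 1] <- 1L
  both <- list(list(mask = les2, label = 0L), list(mask = les_b, label = 1L))
  expect_identical(label_window(box_z3, both), "malignant")
})

test_that("heatmaps average overlapping window scores", {
  wg <- make_windows(c(6, 4, 2), c(4, 4, 2), overlap = 0.5)
  expect_length(wg$boxes, 2)  # origins 0 and 2 along x
  hm <- build_heatmap(wg, c(0.2, 0.8))
  expect_equal(unique(as.vector(hm$confidence[1:2, , ])), 0.2)
  expect_equal(unique(as.vector(hm$confidence[3:4, , ])), 0.5)
  expect_equal(unique(as.vector(hm$confidence[5:6, , ])), 0.8)

  zero <- build_heatmap(wg, c(0, 0))
  expect_true(all(zero$confidence == 0))
  const <- build_heatmap(wg, c(0.7, 0.7))
  expect_true(all(abs(const$confidence - 0.7) < 1e-12))
  expect_error(build_heatmap(wg, 0.5), "one score per window")
})

test_that("heatmap accumulation is order-independent", {
  wg <- make_windows(c(12, 8, 4), c(6, 6, 3), overlap = 0.5)
  set.seed(11)
  s <- runif(length(wg$boxes))
  perm <- sample(length(wg$boxes))
  wg2 <- wg; wg2$boxes <- wg$boxes[perm]
  h1 <- build_heatmap(wg, s)
  h2 <- build_heatmap(wg2, s[perm])
  expect_equal(h1$confidence, h2$confidence, tolerance = 1e-12)
})

test_that("the ROC cutoff maximises Youden's J", {
  cut <- choose_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(cut), 0.5)
  expect_false(attr(cut, "degenerate"))

  anti <- choose_cutoff(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_true(attr(anti, "degenerate"))

  set.seed(12)
  s <- runif(20); y <- rbinom(20, 1, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  cut2 <- choose_cutoff(s, y)
  brute_j <- max(sapply(c(-Inf, sort(s)), function(cc) {
    pred <- as.integer(s > cc)
    sum(pred == 1 & y == 1) / sum(y == 1) + sum(pred == 0 & y == 0) / sum(y == 0) - 1
  }))
  expect_equal(attr(cut2, "youden_j"), brute_j, tolerance = 1e-12)
  expect_error(choose_cutoff(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("image labels follow the any-voxel rule with optional minimum area", {
  wg <- make_windows(c(10, 10, 4), c(10, 10, 4))
  hm <- build_heatmap(wg, 0)
  expect_identical(image_label(hm, 0.5), 0L)
  hm$confidence[3, 3, 2] <- 0.9
  expect_identical(image_label(hm, 0.5), 1L)

  # a 5-voxel blob fails min_area = 10, a 12-voxel blob passes
  hm$confidence[] <- 0
  hm$confidence[2:6, 2, 2] <- 0.9
  expect_identical(image_label(hm, 0.5, min_area = 10), 0L)
  hm$confidence[2:5, 2:4, 2] <- 0.9
  expect_identical(image_label(hm, 0.5, min_area = 10), 1L)

  # gland restriction discards supra-threshold voxels outside the mask
  gm <- array(0L, c(10, 10, 4))
  expect_identical(image_label(hm, 0.5, gland_mask = gm), 0L)
})

test_that("raising the cutoff never flips an image label from 0 to 1", {
  wg <- make_windows(c(8, 8, 4), c(4, 4, 2), overlap = 0.5)
  set.seed(13)
  hm <- build_heatmap(wg, runif(length(wg$boxes)))
  labels <- vapply(seq(0, 1, by = 0.05), function(cc) image_label(hm, cc),
                   integer(1))
  expect_true(all(diff(labels) <= 0))
})

test_that("window tables carry three-way labels", {
  cs <- generate_case(small_spec(), 1, seed = 61)
  wg <- make_windows(dim(cs$t2w$data), c(24, 20, 3), overlap = 0.5)
  tb <- window_table(wg, lesions = cs$lesions)
  expect_true(all(tb$label3 %in% c("background", "benign", "malignant")))
  expect_identical(tb$label, as.integer(tb$label3 == "malignant"))
  expect_true(any(tb$label3 != "background"))
})
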