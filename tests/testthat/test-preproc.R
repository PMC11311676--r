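test_that("z-score normalisation hits mean 0 / SD 1 on the foreground", {
  x <- array(0, c(4, 4, 2))
  x[1:2, , ] <- 10  # half zeros (background), half tens would be constant fg
  x[1, , ] <- 5     # two distinct foreground values
  v <- normalize_volume(mri_volume(x))
  fg <- v$data[x != 0]
  expect_equal(mean(fg), 0, tolerance = 1e-12)
  expect_equal(sd(fg), 1, tolerance = 1e-12)
  expect_true(all(v$data[x == 0] == 0))
})

test_that("constant volumes normalise to zero with a warning", {
  v <- mri_volume(array(7, c(3, 3, 3)))
  expect_warning(out <- normalize_volume(v), "Constant")
  expect_true(all(out$data == 0))
})

test_that("normalisation is idempotent", {
  v <- mri_volume(rand_vol(c(6, 6, 4), seed = 2) + 1)
  once <- normalize_volume(v)
  twice <- normalize_volume(once)
  expect_equal(twice$data, once$data, tolerance = 1e-10)
})

test_that("resampling short-circuits at the target spacing and preserves constants", {
  v <- mri_volume(array(3.5, c(8, 8, 4)), spacing = c(0.75, 0.75, 3))
  expect_identical(resample_volume(v, c(0.75, 0.75, 3)), v)
  w <- mri_volume(array(3.5, c(8, 8, 4)), spacing = c(1, 1, 1))
  out <- resample_volume(w, c(2, 2, 2))
  expect_true(all(abs(out$data - 3.5) < 1e-12))
  expect_error(resample_volume(w, c(-1, 1, 1)), "positive")
})

test_that("2x downsampling of a ramp matches midpoint linear interpolation", {
  n <- 16
  ramp <- array(rep(0:(n - 1), times = 4 * 2), c(n, 4, 2))
  v <- mri_volume(ramp, spacing = c(1, 2, 2))
  out <- resample_volume(v, c(2, 2, 2))
  expect_identical(dim(out$data)[1], 8L)
  # output voxel j (0-based) sits at input coordinate 2j + 0.5: the midpoint
  # average of ramp values 2j and 2j + 1
  expected <- (2 * (0:7)) + 0.5
  expect_equal(out$data[, 1, 1], expected, tolerance = 1e-12)
})

test_that("crop/pad is exact, centred, and conserves padded content", {
  big <- mri_volume(rand_vol(c(200, 200, 40), seed = 3))
  out <- crop_pad_volume(big, c(149, 149, 32))
  expect_identical(dim(out$data), c(149L, 149L, 32L))
  expect_equal(out$data[1, 1, 1], big$data[26, 26, 5])

  same <- mri_volume(rand_vol(c(149, 149, 32), seed = 4))
  expect_identical(crop_pad_volume(same, c(149, 149, 32))$data, same$data)

  sml <- rand_vol(c(100, 100, 20), seed = 5) + 1
  padded <- crop_pad_volume(mri_volume(sml), c(149, 149, 32))
  expect_equal(sum(padded$data != 0), length(sml))
  expect_equal(padded$data[25:124, 25:124, 7:26], sml)
})

test_that("preprocessing delivers the 149x149x32 / 0.75x0.75x3 contract", {
  spec <- small_spec()
  cs <- generate_case(spec, 1, seed = 8)
  cs$spacing <- c(1, 1, 4)
  for (s in c("t2w", "adc", "dwi")) cs[[s]]$spacing <- c(1, 1, 4)
  out <- preprocess_study(cs, preproc_config())
  for (s in c("t2w", "adc", "dwi")) {
    expect_identical(dim(out[[s]]$data), c(149L, 149L, 32L))
    expect_equal(out[[s]]$spacing, c(0.75, 0.75, 3))
  }
  expect_identical(dim(out$gland_mask), c(149L, 149L, 32L))
  expect_identical(out$label, cs$label)

  cs$adc <- NULL
  expect_error(preprocess_study(cs), "adc")
})

test_that("preprocessing is a fixed point on already-processed cases", {
  cs <- generate_case(small_spec(), 1, seed = 13)
  cfg <- preproc_config(target_shape = c(48, 48, 12))
  once <- preprocess_study(cs, cfg)
  twice <- preprocess_study(once, cfg)
  expect_equal(twice$t2w$data, once$t2w$data, tolerance = 1e-10)
  expect_identical(twice$gland_mask, once$gland_mask)
})

test_that("shape contract holds over randomized input geometries", {
  set.seed(42)
  for (i in 1:6) {
    d <- c(sample(40:220, 2), sample(10:48, 1))
    sp <- c(runif(2, 0.4, 1.5), runif(1, 1.5, 5))
    v <- mri_volume(array(rnorm(prod(d)), d), spacing = sp)
    out <- crop_pad_volume(resample_volume(normalize_volume(v),
                                           c(0.75, 0.75, 3)),
                           c(149, 149, 32))
    expect_identical(dim(out$data), c(149L, 149L, 32L))
  }
})

test_that("masks stay binary and nested through the chain", {
  cs <- generate_case(small_spec(), 1, seed = 17)
  cs$spacing <- c(1, 1, 4)
  for (s in c("t2w", "adc", "dwi")) cs[[s]]$spacing <- c(1, 1, 4)
  out <- preprocess_study(cs, preproc_config(target_shape = c(64, 64, 16)))
  expect_true(all(out$gland_mask %in% c(0L, 1L)))
  expect_true(all(out$pz_mask %in% c(0L, 1L)))
  expect_true(all(out$pz_mask <= out$gland_mask))
  for (l in out$lesions) expect_true(all(l$mask <= out$gland_mask))

  # nearest-neighbour resampling conserves mask volume up to the
  # voxel-volume ratio bound
  vol_before <- sum(cs$gland_mask) * prod(c(1, 1, 4))
  vol_after <- sum(out$gland_mask) * prod(c(0.75, 0.75, 3))
  expect_lt(abs(vol_after - vol_before) / vol_before, 0.15)
})
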