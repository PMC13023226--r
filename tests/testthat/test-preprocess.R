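test_that("CLAHE preserves range, fixes constants, and raises low contrast", {
  x <- matrix(0.5, 64, 64)
  expect_identical(clahe(x), x)
  set.seed(61)
  y <- clamp01(matrix(rnorm(64 * 64, 0.5, 0.3), 64, 64))
  out <- clahe(y)
  expect_true(all(out >= 0 & out <= 1))
  # seeded low-contrast image: std strictly increases
  lo <- 0.5 + matrix(rnorm(64 * 64, 0, 0.02), 64, 64)
  expect_gt(sd(clahe(lo)), sd(lo))
  expect_error(clahe(array(0, c(2, 2, 2, 2))), "2D matrix or 3D")
})

test_that("gamma correction is the elementwise power law", {
  x <- matrix(runif(100), 10, 10)
  expect_equal(gamma_correct(x, 1), x)
  expect_equal(gamma_correct(matrix(0.25, 1, 1), 0.5), matrix(0.5, 1, 1))
  # gamma < 1 brightens on (0,1)
  expect_true(all(gamma_correct(x, 0.8) >= x))
  expect_error(gamma_correct(x, 0), "positive")
})

test_that("resize_to_multiple rounds up with the ceil rule and is idempotent", {
  x <- matrix(runif(1024 * 1536), 1024, 1536)
  expect_identical(resize_to_multiple(x, 512), x)
  y <- matrix(runif(1000 * 1300), 1000, 1300)
  z <- resize_to_multiple(y, 512)
  expect_equal(dim(z), c(1024, 1536))
  expect_identical(resize_to_multiple(z, 512), z)
  # nearest-neighbour keeps masks binary
  m <- random_mask(100, 130)
  mz <- resize_to_multiple(m, 64)
  expect_true(all(mz %in% c(0, 1)))
})

test_that("crop_grid tiles exactly and montage is its exact inverse", {
  x <- matrix(runif(1024 * 1536), 1024, 1536)
  cg <- crop_grid(x, 512)
  expect_equal(length(cg$patches), 6)
  expect_equal(c(cg$grid$rows, cg$grid$cols), c(2, 3))
  # pixel-mass conservation across the tiling
  expect_equal(sum(vapply(cg$patches, sum, numeric(1))), sum(x))
  expect_identical(montage(cg$patches, cg$grid), x)
  # single-tile identity
  s <- matrix(runif(512 * 512), 512, 512)
  cg1 <- crop_grid(s, 512)
  expect_identical(cg1$patches[[1]], s)
  expect_identical(montage(cg1$patches, cg1$grid), s)
  expect_error(crop_grid(matrix(0, 100, 100), 64), "resize_to_multiple")
})

test_that("montage reassembles any permutation placed by tile index", {
  set.seed(67)
  x <- matrix(runif(128 * 192), 128, 192)
  cg <- crop_grid(x, 64)
  # feeding tiles through an index map oracle reproduces the image
  perm <- sample(length(cg$patches))
  reordered <- cg$patches[perm]
  restored <- reordered[order(perm)]
  expect_identical(montage(restored, cg$grid), x)
  expect_error(montage(cg$patches[1:2], cg$grid), "patches")
})

test_that("area down-sampling preserves mean intensity", {
  set.seed(71)
  x <- matrix(runif(256 * 384), 256, 384)
  y <- downsample_global(x, 64)
  expect_equal(dim(y), c(64, 64))
  expect_lt(abs(mean(y) - mean(x)) / mean(x), 0.01)
  cst <- matrix(0.42, 128, 128)
  expect_equal(downsample_global(cst, 32), matrix(0.42, 32, 32), tolerance = 1e-12)
  expect_identical(dim(downsample_global(x, 256)), c(256L, 256L))
  expect_warning(downsample_global(matrix(0.1, 64, 64), 128), "up-sampling")
})

test_that("augmentation moves mask geometry with the image and nothing else", {
  set.seed(73)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- random_mask(64, 64, 0.2)
  # no-flip seed with zero jitter is the identity
  noflip <- which(!vapply(1:50, function(s) {
    cmwnet:::with_seed(s, runif(1) < 0.5)
  }, logical(1)))[1]
  out <- augment(img, msk, seed = noflip, brightness = 0, contrast = 0,
                 saturation = 0, hue = 0)
  expect_equal(out$image, img)
  expect_identical(out$mask, msk)
  # a flipping seed applied twice restores the original
  flipseed <- which(vapply(1:50, function(s) {
    cmwnet:::with_seed(s, runif(1) < 0.5)
  }, logical(1)))[1]
  once <- augment(img, msk, seed = flipseed, brightness = 0, contrast = 0,
                  saturation = 0, hue = 0)
  twice <- augment(once$image, once$mask, seed = flipseed, brightness = 0,
                   contrast = 0, saturation = 0, hue = 0)
  expect_equal(twice$image, img)
  expect_identical(twice$mask, msk)
  # mask foreground count invariant over 100 seeded draws
  counts <- vapply(1:100, function(s) sum(augment(img, msk, seed = s)$mask),
                   numeric(1))
  expect_true(all(counts == sum(msk)))
})

test_that("preprocessing never alters mask label values", {
  img <- matrix(runif(200 * 260), 200, 260)
  msk <- random_mask(200, 260, 0.15)
  pp <- preprocess_case(img, msk, base = 128)
  expect_true(all(pp$mask %in% c(0, 1)))
  expect_equal(dim(pp$mask), c(256, 384))
  expect_equal(dim(pp$image), c(256, 384))
})
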