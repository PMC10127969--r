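# Synthetic lesion generator, augmentation and preprocessing.

test_that("generation is deterministic and masks are strictly binary", {
  cfg <- synthConfig(imageSize = 64L, seed = 5L)
  s1 <- generateSample(cfg, 123L)
  s2 <- generateSample(cfg, 123L)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_true(all(s1$mask %in% c(0, 1)))
  expect_equal(dim(s1$image), c(64L, 64L, 3L))
  # a different seed gives a different sample
  expect_false(identical(s1$mask, generateSample(cfg, 124L)$mask))
})

test_that("noiseless samples are piecewise smooth two-level images", {
  cfg <- synthConfig(imageSize = 64L, noiseSigma = 0, seed = 6L)
  s <- generateSample(cfg, 9L)
  inside <- s$image[, , 1][s$mask == 1]
  outside <- s$image[, , 1][s$mask == 0]
  expect_gt(mean(inside), mean(outside))  # lesion brighter than background
  # away from the blurred boundary both regions are constant plateaus, so the
  # median absolute deviation is zero even though the boundary ring is smooth
  expect_equal(unname(mad(outside)), 0)
})

test_that("foreground fraction stays within radius-implied bounds over seeds", {
  cfg <- synthConfig(imageSize = 64L, nBlobs = 1L, radiusRange = c(0.12, 0.3))
  lo <- 0.5 * pi * 0.12^2          # generous roughness allowance
  hi <- min(0.6, pi * (1.6 * 0.3)^2)
  fr <- vapply(1:100, function(s) mean(generateSample(cfg, s)$mask), numeric(1))
  expect_true(all(fr >= lo & fr <= hi))
})

test_that("speckle strictly increases image variance at the same seed", {
  base <- synthConfig(imageSize = 64L, speckle = FALSE)
  spk <- synthConfig(imageSize = 64L, speckle = TRUE)
  for (s in c(3L, 11L, 27L)) {
    expect_gt(var(as.vector(generateSample(spk, s)$image)),
              var(as.vector(generateSample(base, s)$image)))
  }
})

test_that("dataset writing follows the split, refuses overwrites, and is reproducible", {
  dir <- file.path(tempdir(), "synth-ds")
  unlink(dir, recursive = TRUE)
  cfg <- synthConfig(imageSize = 32L, seed = 2L)
  m <- generateDataset(cfg, 10, split = c(train = 0.7, val = 0.1, test = 0.2),
                       dir = dir)
  expect_length(list.files(file.path(dir, "train", "images")), 7L)
  expect_length(list.files(file.path(dir, "val", "images")), 1L)
  expect_length(list.files(file.path(dir, "test", "images")), 2L)
  expect_error(generateDataset(cfg, 10, dir = dir), "overwrite")
  # manifest seeds reproduce every file byte-identically
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  for (i in c(1, 5, 10)) {
    rec <- man$samples[i, ]
    s <- generateSample(cfg, rec$seed)
    f <- tempfile(fileext = ".png")
    png::writePNG(s$image, f)
    orig <- file.path(dir, rec$split, "images", rec$file)
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(orig, "raw", file.size(orig)))
  }
  # empty split allowed
  dir2 <- file.path(tempdir(), "synth-ds2")
  unlink(dir2, recursive = TRUE)
  generateDataset(cfg, 4, split = c(train = 1, val = 0), dir = dir2)
  expect_length(list.files(file.path(dir2, "val", "images")), 0L)
})

test_that("augmentation moves mask pixels with image pixels and is involutive", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mask <- matrix(0, 16, 16)
  mask[4, 11] <- 1
  # deterministic flips: probability 1, no crop
  spec <- augmentSpec(hflipProb = 1, vflipProb = 0, cropFraction = c(1, 1))
  a <- augmentPair(img, mask, spec, seed = 1L)
  expect_equal(which(a$mask == 1, arr.ind = TRUE)[1, ], c(row = 4, col = 6))
  expect_equal(a$image[4, 6, ], img[4, 11, ])  # pixel travels with its mask
  # flipping twice is the identity
  b <- augmentPair(a$image, a$mask, spec, seed = 2L)
  expect_equal(b$image, img)
  expect_equal(b$mask, mask)
  # probability-zero spec is the identity
  id <- augmentSpec(0, 0, c(1, 1))
  c1 <- augmentPair(img, mask, id, seed = 3L)
  expect_identical(c1$image, img)
  # crops keep masks binary and preserve shape
  cr <- augmentSpec(0.5, 0.5, c(0.7, 0.9))
  for (s in 1:5) {
    out <- augmentPair(img, mask, cr, seed = s)
    expect_equal(dim(out$image), dim(img))
    expect_true(all(out$mask %in% c(0, 1)))
    expect_identical(out, augmentPair(img, mask, cr, seed = s))
  }
  expect_error(augmentSpec(cropFraction = c(1, 1.2)), "crop larger")
})

test_that("preprocessing resizes, normalizes and re-binarizes", {
  cfg <- synthConfig(imageSize = 48L, seed = 8L)
  s <- generateSample(cfg, 4L)
  pp <- preprocessPair(s$image, s$mask, size = 32L)
  expect_equal(dim(pp$image), c(3L, 32L, 32L))
  expect_equal(dim(pp$mask), c(32L, 32L))
  expect_true(all(pp$mask %in% c(0, 1)))
  # normalizing with the image's own statistics centers each channel
  mu <- apply(s$image, 3, mean)
  sd_ <- apply(s$image, 3, sd)
  pp2 <- preprocessPair(s$image, s$mask, size = 48L, mean = mu, sd = sd_)
  for (ch in 1:3) {
    expect_lt(abs(mean(pp2$image[ch, , ])), 0.05)
    expect_lt(abs(sd(pp2$image[ch, , ]) - 1), 0.05)
  }
})
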