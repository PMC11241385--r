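test_that("Lab conversion maps the achromatic anchors correctly", {
  black <- rgbToLab(ultrasoundImage(array(0, c(3, 3, 3))))
  expect_equal(unname(labMeans(channelMeans(black))), c(0, 0, 0),
               tolerance = 1e-8)
  white <- rgbToLab(ultrasoundImage(array(255, c(3, 3, 3))))
  m <- labMeans(channelMeans(white))
  expect_equal(unname(m[["L"]]), 100, tolerance = 1e-4)
  expect_lt(abs(m[["a"]]), 1e-6)
  expect_lt(abs(m[["b"]]), 1e-6)
})

test_that("Lab conversion of uniform gray matches the published formulas", {
  img <- rgbToLab(ultrasoundImage(array(128, c(2, 2, 3))))
  ref <- refLab(c(128, 128, 128))
  got <- labMeans(channelMeans(img))
  expect_equal(unname(got[["L"]]), unname(ref[["L"]]), tolerance = 1e-3)
  expect_lt(abs(got[["a"]]), 1e-6)
  expect_lt(abs(got[["b"]]), 1e-6)
})

test_that("grayscale rasters are promoted to three channels before Lab", {
  gray <- ultrasoundImage(matrix(77, 4, 5))
  lab <- rgbToLab(gray)
  expect_equal(dim(lab), c(4L, 5L, 3L))
  expect_identical(colorspace(lab), "Lab")
  rep3 <- rgbToLab(ultrasoundImage(array(77, c(4, 5, 3))))
  expect_equal(pixels(lab), pixels(rep3))
})

test_that("non-8-bit input is rejected", {
  expect_error(ultrasoundImage(matrix(0.5, 2, 2)), "8-bit")
  expect_error(ultrasoundImage(matrix(300, 2, 2)), "\\[0, 255\\]")
  lab <- rgbToLab(ultrasoundImage(matrix(10, 2, 2)))
  expect_error(rgbToLab(lab), "RGB")
})

test_that("cropping copies the exact rectangle", {
  set.seed(41)
  px <- array(sample(0:255, 100 * 100 * 3, replace = TRUE), c(100, 100, 3))
  img <- ultrasoundImage(px)
  full <- cropRegion(img, regionSpec(1, 100, 1, 100))
  expect_identical(pixels(full), px)
  one <- cropRegion(img, regionSpec(1, 1, 1, 1))
  expect_equal(dim(one), c(1L, 1L, 3L))
  expect_equal(as.vector(pixels(one)), px[1, 1, ])
  ## a 10 x 20 interior region against the brute-force loop
  sub <- cropRegion(img, regionSpec(11, 20, 31, 50))
  expect_equal(dim(sub), c(10L, 20L, 3L))
  expect_equal(pixels(sub), naiveCrop(px, 11, 20, 31, 50))
})

test_that("out-of-bounds and malformed regions are rejected", {
  img <- ultrasoundImage(matrix(0, 10, 10))
  expect_error(cropRegion(img, regionSpec(5, 11, 1, 10)), "bounds")
  expect_error(cropRegion(img, regionSpec(1, 10, 8, 12)), "bounds")
  expect_error(regionSpec(5, 4, 1, 10), "non-empty")
  expect_error(regionSpec(0, 4, 1, 10), "1-based")
})

test_that("channel means equal naive accumulation", {
  constant <- new("UltrasoundImage",
                  pixels = array(rep(c(50, 0, 0), each = 12), c(3, 4, 3)),
                  colorspace = "Lab", sourcePath = NA_character_)
  expect_equal(unname(labMeans(channelMeans(constant))), c(50, 0, 0))
  two <- new("UltrasoundImage",
             pixels = array(c(40, 60, 0, 0, 0, 0), c(1, 2, 3)),
             colorspace = "Lab", sourcePath = NA_character_)
  expect_equal(unname(labMeans(channelMeans(two))[["L"]]), 50)
  expect_equal(nPixels(channelMeans(two)), 2L)
  set.seed(7)
  px <- array(rnorm(16 * 16 * 3, 50, 20), c(16, 16, 3))
  lab <- new("UltrasoundImage", pixels = px, colorspace = "Lab",
             sourcePath = NA_character_)
  expect_equal(unname(labMeans(channelMeans(lab))), naiveChannelMeans(px),
               tolerance = 1e-9)
  rgb <- ultrasoundImage(matrix(5, 2, 2))
  expect_error(channelMeans(rgb), "Lab")
})

test_that("Delta E CIE76 equals the three-term Euclidean distance", {
  s <- labSummary(50, 0, 0)
  expect_identical(deltaE(s, s), 0)
  expect_equal(deltaE(labSummary(50, 0, 0), labSummary(53, 4, 0)), 5)
  set.seed(11)
  for (r in 1:50) {
    a <- labSummary(runif(1, 0, 100), runif(1, -60, 60), runif(1, -60, 60))
    b <- labSummary(runif(1, 0, 100), runif(1, -60, 60), runif(1, -60, 60))
    direct <- sqrt((a@LMean - b@LMean)^2 + (a@aMean - b@aMean)^2 +
                   (a@bMean - b@bMean)^2)
    expect_equal(deltaE(a, b), direct, tolerance = 1e-12)
    expect_equal(deltaE(a, b), deltaE(b, a))
  }
})

test_that("Delta E is a metric on Lab triples", {
  set.seed(12)
  for (r in 1:40) {
    t3 <- replicate(3, labSummary(runif(1, 0, 100), runif(1, -60, 60),
                                  runif(1, -60, 60)), simplify = FALSE)
    dab <- deltaE(t3[[1]], t3[[2]])
    dbc <- deltaE(t3[[2]], t3[[3]])
    dac <- deltaE(t3[[1]], t3[[3]])
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-12)
    expect_equal(dab, deltaE(t3[[2]], t3[[1]]))
  }
  expect_identical(deltaE(labSummary(1, 2, 3), labSummary(1, 2, 3)), 0)
})

test_that("grayscale images give Delta E equal to the lightness gap", {
  set.seed(13)
  for (r in 1:10) {
    g1 <- sample(0:255, 1); g2 <- sample(0:255, 1)
    i1 <- rgbToLab(ultrasoundImage(matrix(g1, 6, 6)))
    i2 <- rgbToLab(ultrasoundImage(matrix(g2, 6, 6)))
    s1 <- channelMeans(i1); s2 <- channelMeans(i2)
    expect_lt(abs(s1@aMean), 1e-6)
    expect_lt(abs(s1@bMean), 1e-6)
    expect_equal(deltaE(s1, s2), abs(s1@LMean - s2@LMean), tolerance = 1e-3)
  }
})

test_that("categorization follows the clinical thresholds and partitions", {
  expect_equal(as.character(categorizeDeltaE(5)), "Intensive")
  expect_equal(as.character(categorizeDeltaE(25)), "Moderate")
  expect_equal(as.character(categorizeDeltaE(45)), "Normal")
  ## both boundary points belong to Moderate
  expect_equal(as.character(categorizeDeltaE(c(10, 40))),
               c("Moderate", "Moderate"))
  grid <- c(0, 1e-9, 9.999, 10, 10.001, 39.999, 40, 40.001, 1e6)
  g <- categorizeDeltaE(grid)
  expect_false(anyNA(g))          # exactly one grade for every value
  expect_error(thresholdSet(40, 10), "tIntensive < tNormal")
  expect_error(categorizeDeltaE(-1), "nonnegative")
})

test_that("assessDensity composes the pipeline and is symmetric in dE", {
  set.seed(21)
  img <- ultrasoundImage(
    array(sample(0:255, 40 * 40, replace = TRUE), c(40, 40, 1)))
  roi <- regionSpec(5, 20, 5, 20)
  same <- assessDensity(img, roi, roi)
  expect_equal(deltaE(same), 0)
  expect_equal(as.character(grade(same)), "Intensive")
  roiB <- regionSpec(21, 36, 21, 36)
  ab <- assessDensity(img, roi, roiB)
  ba <- assessDensity(img, roiB, roi)
  expect_equal(deltaE(ab), deltaE(ba))
  expect_identical(as.character(grade(ab)), as.character(grade(ba)))
})

test_that("phantom pairs assessed through the pipeline recover their band", {
  cfg <- phantomConfig(patchHeight = 40, patchWidth = 40, jitterSD = 1e-6)
  pairN <- generatePhantomPair("Normal", cfg, seed = 5)
  img <- concatPatches(pairN$parenchyma, pairN$plexus, axis = "rows")
  a <- assessDensity(img, regionSpec(1, 40, 1, 40), regionSpec(41, 80, 1, 40))
  expect_gt(deltaE(a), 40)
  expect_equal(as.character(grade(a)), "Normal")
  pairM <- generatePhantomPair("Moderate", cfg, seed = 6)
  imgM <- concatPatches(pairM$parenchyma, pairM$plexus, axis = "rows")
  aM <- assessDensity(imgM, regionSpec(1, 40, 1, 40),
                      regionSpec(41, 80, 1, 40))
  expect_equal(as.character(grade(aM)), "Moderate")
})
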