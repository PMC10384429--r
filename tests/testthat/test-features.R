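test_that("pixels classify to the dominant channel with margin", {
  expect_identical(classifyPixelColor(c(200, 40, 30)), "RED")
  expect_identical(classifyPixelColor(c(90, 200, 60)), "GREEN")
  expect_identical(classifyPixelColor(c(30, 40, 220)), "BLUE")
  expect_identical(classifyPixelColor(c(100, 100, 100)), "NONE")
  # margin boundary: dominance by exactly delta counts
  expect_identical(classifyPixelColor(c(110, 100, 100), delta = 10), "RED")
  expect_identical(classifyPixelColor(c(109, 100, 100), delta = 10), "NONE")
})

test_that("a uniform red region yields the full area in the red class", {
  px <- array(0, dim = c(25, 20, 3))
  px[, , 1] <- 220; px[, , 2] <- 30; px[, , 3] <- 30
  mask <- matrix(FALSE, 25, 20)
  mask[1:25, 1:20][seq_len(500)] <- TRUE
  m <- lycosense:::labelMask(mask, 8L)
  f <- extractFeatures(RGBImage(px), m)
  expect_identical(f@areaRed, 500L)
  expect_identical(f@areaGreen, 0L)
  expect_identical(f@areaBlue, 0L)
  expect_identical(f@nFruitPx, 500L)
})

test_that("an empty mask is an explicit error", {
  px <- array(100, dim = c(4, 4, 3))
  m <- lycosense:::labelMask(matrix(FALSE, 4, 4), 8L)
  expect_error(extractFeatures(RGBImage(px), m), "no fruit segmented")
})

test_that("areas equal a brute-force per-pixel classification loop", {
  set.seed(13)
  px <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), dim = c(16, 16, 3))
  mask <- matrix(runif(256) < 0.5, 16, 16)
  m <- lycosense:::labelMask(mask, 8L)
  f <- extractFeatures(RGBImage(px), m)
  counts <- c(RED = 0L, GREEN = 0L, BLUE = 0L)
  for (i in 1:16) for (j in 1:16) {
    if (!mask[i, j]) next
    v <- px[i, j, ]
    cls <- if (v[1] >= v[2] + 10 && v[1] >= v[3] + 10) "RED"
      else if (v[2] >= v[1] + 10 && v[2] >= v[3] + 10) "GREEN"
      else if (v[3] >= v[1] + 10 && v[3] >= v[2] + 10) "BLUE"
      else "NONE"
    if (cls != "NONE") counts[cls] <- counts[cls] + 1L
  }
  expect_identical(c(f@areaRed, f@areaGreen, f@areaBlue), unname(counts))
})

test_that("areas are invariant to pixel permutation within the mask", {
  set.seed(5)
  px <- array(sample(0:255, 10 * 10 * 3, replace = TRUE), dim = c(10, 10, 3))
  full <- matrix(TRUE, 10, 10)
  f1 <- extractFeatures(RGBImage(px), lycosense:::labelMask(full, 8L))
  perm <- sample(100)
  flat <- matrix(px, ncol = 3)[perm, ]
  f2 <- extractFeatures(RGBImage(array(flat, dim = dim(px))),
                        lycosense:::labelMask(full, 8L))
  expect_identical(c(f1@areaRed, f1@areaGreen, f1@areaBlue),
                   c(f2@areaRed, f2@areaGreen, f2@areaBlue))
  expect_equal(c(f1@L, f1@a, f1@b), c(f2@L, f2@a, f2@b))
})

test_that("duplicating the image side-by-side doubles all areas exactly", {
  set.seed(8)
  px <- array(sample(0:255, 12 * 9 * 3, replace = TRUE), dim = c(12, 9, 3))
  mask <- matrix(runif(12 * 9) < 0.6, 12, 9)
  doubledPx <- array(0, dim = c(12, 18, 3))
  doubledPx[, 1:9, ] <- px; doubledPx[, 10:18, ] <- px
  f1 <- extractFeatures(RGBImage(px), lycosense:::labelMask(mask, 8L))
  f2 <- extractFeatures(RGBImage(doubledPx),
                        lycosense:::labelMask(cbind(mask, mask), 8L))
  expect_identical(f2@areaRed, 2L * f1@areaRed)
  expect_identical(f2@areaGreen, 2L * f1@areaGreen)
  expect_identical(f2@areaBlue, 2L * f1@areaBlue)
  expect_identical(f2@nFruitPx, 2L * f1@nFruitPx)
})

test_that("identity scaling reproduces masked Lab means", {
  set.seed(2)
  px <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  mask <- matrix(runif(64) < 0.5, 8, 8)
  f <- extractFeatures(RGBImage(px), lycosense:::labelMask(mask, 8L),
                       scaling = identityScaling())
  lab <- imagePixels(rgbToLab(RGBImage(px)))
  expect_equal(f@L, mean(lab[, , 1][mask]), tolerance = 1e-9)
  expect_equal(f@a, mean(lab[, , 2][mask]), tolerance = 1e-9)
  expect_equal(f@b, mean(lab[, , 3][mask]), tolerance = 1e-9)
  expect_equal(f@ratioAb, f@a / f@b, tolerance = 1e-12)
})

test_that("default scaling lands the features inside the fuzzy domains", {
  set.seed(6)
  for (rep in 1:5) {
    px <- array(sample(0:255, 6 * 6 * 3, replace = TRUE), dim = c(6, 6, 3))
    f <- extractFeatures(RGBImage(px),
                         lycosense:::labelMask(matrix(TRUE, 6, 6), 8L))
    expect_true(f@L >= 0 && f@L <= 2558.3)
    expect_true(f@a >= 0 && f@a <= 1736)
    expect_true(f@b >= -210 && f@b <= 358)
  }
})

test_that("feature tables round-trip through CSV", {
  f <- extractFeatures(uniformHsvImage(0.01, 0.9, 0.8, 5, 5),
                       lycosense:::labelMask(matrix(TRUE, 5, 5), 8L))
  tab <- cbind(data.frame(sample_id = "s1"), as.data.frame(f),
               data.frame(lycopene_ppm = 42))
  p <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, p)
  back <- readFeatureTable(p)
  expect_equal(back$a_feat, tab$a_feat)
  expect_identical(back$area_red, tab$area_red)
  expect_identical(names(back), names(tab))
})
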