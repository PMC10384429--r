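test_that("PNG and JPEG files load as 3-channel 8-bit images", {
  px <- array(runif(24 * 16 * 3), dim = c(24, 16, 3))
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px, p)
  img <- loadImage(p, sourceTag = "no-filter")
  expect_s4_class(img, "RGBImage")
  expect_identical(dim(img), c(24L, 16L, 3L))
  expect_identical(imagePixels(img), array(as.integer(round(px * 255)),
                                           dim = c(24L, 16L, 3L)))
  expect_identical(img@sourceTag, "no-filter")

  j <- withr::local_tempfile(fileext = ".jpg")
  jpeg::writeJPEG(px, j, quality = 1)
  expect_identical(dim(loadImage(j)), c(24L, 16L, 3L))
})

test_that("grayscale input is replicated to three channels", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(seq(0, 1, length.out = 12), 3, 4), p)
  img <- loadImage(p)
  expect_identical(dim(img), c(3L, 4L, 3L))
  expect_identical(imagePixels(img)[, , 1], imagePixels(img)[, , 2])
  expect_identical(imagePixels(img)[, , 1], imagePixels(img)[, , 3])
})

test_that("a 1x1 black PNG decodes to the identity pixel", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(0, dim = c(1, 1, 3)), p)
  img <- loadImage(p)
  expect_identical(imagePixels(img), array(0L, dim = c(1L, 1L, 3L)))
})

test_that("unreadable or truncated files raise an I/O error naming the path", {
  expect_error(loadImage("/nonexistent/file.png"), "does not exist")
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(300), dim = c(10, 10, 3)), p)
  full <- readBin(p, "raw", file.size(p))
  writeBin(full[1:40], p)   # truncate mid-stream
  expect_error(loadImage(p), "cannot decode image.*\\.png")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", bad)
  expect_error(loadImage(bad), "cannot decode")
})

test_that("rgbToHsv reproduces the hexcone reference points", {
  img <- RGBImage(array(rep(c(255, 0, 0), each = 1), dim = c(1, 1, 3)))
  expect_equal(as.vector(imagePixels(rgbToHsv(img))), c(0, 1, 1))
  img <- RGBImage(array(c(0, 255, 0), dim = c(1, 1, 3)))
  expect_equal(as.vector(imagePixels(rgbToHsv(img))), c(1 / 3, 1, 1))
  img <- RGBImage(array(c(128, 128, 128), dim = c(1, 1, 3)))
  hsv <- as.vector(imagePixels(rgbToHsv(img)))
  expect_equal(hsv[2], 0)
  expect_equal(hsv[3], 128 / 255)
})

test_that("HSV conversion inverts to RGB within one intensity unit", {
  set.seed(11)
  px <- array(sample(0:255, 5 * 7 * 3, replace = TRUE), dim = c(5, 7, 3))
  hsv <- imagePixels(rgbToHsv(RGBImage(px)))
  # base-R inverse path: hsv() -> hex -> col2rgb
  back <- grDevices::col2rgb(grDevices::hsv(hsv[, , 1], hsv[, , 2], hsv[, , 3]))
  expect_lte(max(abs(t(back) - matrix(px, ncol = 3))), 1)
})

test_that("rgbToLab matches the scalar textbook sRGB/D65 oracle", {
  white <- rgbToLab(RGBImage(array(255, dim = c(1, 1, 3))))
  expect_equal(imagePixels(white)[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(max(abs(imagePixels(white)[1, 1, 2:3])), 0.5)
  black <- rgbToLab(RGBImage(array(0, dim = c(1, 1, 3))))
  expect_equal(as.vector(imagePixels(black)), c(0, 0, 0), tolerance = 1e-12)

  set.seed(4)
  cases <- rbind(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                 matrix(sample(0:255, 30, replace = TRUE), ncol = 3))
  for (i in seq_len(nrow(cases))) {
    img <- RGBImage(array(cases[i, ], dim = c(1, 1, 3)))
    got <- as.vector(imagePixels(rgbToLab(img)))
    expect_lt(max(abs(got - oracleLab(cases[i, 1], cases[i, 2], cases[i, 3]))),
              0.1)
  }
})

test_that("L* is monotone in uniform gray level", {
  L <- vapply(0:255, function(g)
    imagePixels(rgbToLab(RGBImage(array(g, dim = c(1, 1, 3)))))[1, 1, 1], 0)
  expect_true(all(diff(L) > 0))
})

test_that("conversions are pixel-wise: permutation commutes", {
  set.seed(9)
  px <- array(sample(0:255, 4 * 6 * 3, replace = TRUE), dim = c(4, 6, 3))
  perm <- sample(24)
  permute <- function(a) {
    flat <- matrix(a, ncol = 3)[perm, ]
    array(flat, dim = dim(a))
  }
  pxPerm <- permute(px)
  for (fun in list(rgbToHsv, rgbToLab)) {
    direct <- permute(imagePixels(fun(RGBImage(px))))
    swapped <- imagePixels(fun(RGBImage(pxPerm)))
    expect_equal(direct, swapped)
  }
})

test_that("invalid pixel arrays are rejected", {
  expect_error(RGBImage(array(300, dim = c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(new("HSVImage", pixels = array(2, dim = c(1, 1, 3))), "\\[0, 1\\]")
})
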