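## Image loading and color-space conversions. Conventions: H, S, V are
## unit-scaled to [0, 1] (the segmentation hue thresholds are quoted on that
## scale); Lab uses sRGB primaries with the D65 white point and the 2 degree
## observer, the assumption made throughout for camera output.

#' Construct an RGBImage from an array
#'
#' @param pixels H x W x 3 numeric/integer array of intensities in [0, 255],
#'   or an H x W matrix (grayscale, replicated to 3 channels).
#' @param sourceTag optional free-text acquisition tag (e.g. optical-filter
#'   name).
#' @return an \code{RGBImage}.
#' @export
RGBImage <- function(pixels, sourceTag = NA_character_) {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  storage.mode(pixels) <- "integer"
  new("RGBImage", pixels = pixels, sourceTag = as.character(sourceTag))
}

#' Load a JPEG or PNG image as an RGBImage
#'
#' Grayscale images are replicated to 3 channels; an alpha channel, if
#' present, is dropped. 16-bit PNG content is rescaled to [0, 255] (the
#' decoders return [0, 1] regardless of bit depth).
#'
#' @param path path to a JPEG or PNG file.
#' @param sourceTag optional acquisition tag carried on the result.
#' @return an \code{RGBImage}.
#' @export
loadImage <- function(path, sourceTag = NA_character_) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  magic <- readBin(path, "raw", n = 8L)
  img <- tryCatch({
    if (length(magic) >= 8L &&
        identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
      png::readPNG(path)
    else if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8))))
      jpeg::readJPEG(path)
    else
      stop("not a JPEG or PNG file")
  }, error = function(e)
    stop("cannot decode image ", path, ": ", conditionMessage(e), call. = FALSE))
  if (is.matrix(img))
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  else if (dim(img)[3] == 1L)
    img <- array(rep(img[, , 1], 3L), dim = c(dim(img)[1:2], 3L))
  else if (dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(img) == 0L || any(dim(img)[1:2] < 1L))
    stop("zero-size image: ", path)
  RGBImage(round(img * 255), sourceTag = sourceTag)
}

#' Convert an RGBImage to HSV
#'
#' Standard hexcone conversion with H, S and V each unit-scaled to [0, 1].
#'
#' @param img an \code{RGBImage}.
#' @return an \code{HSVImage} of the same shape.
#' @export
rgbToHsv <- function(img) {
  stopifnot(is(img, "RGBImage"))
  d <- dim(img@pixels)
  flat <- matrix(as.numeric(img@pixels), ncol = 3L)  # N x (R,G,B)
  hsv <- t(grDevices::rgb2hsv(t(flat), maxColorValue = 255))
  new("HSVImage", pixels = array(hsv, dim = d))
}

## sRGB electro-optical transfer function (IEC 61966-2-1), vectorized
srgbToLinear <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

## sRGB (D65) -> XYZ matrix and D65 reference white
.srgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
## reference white = XYZ of sRGB white under the matrix above (D65); taking
## the row sums keeps the conversion self-consistent, so pure white maps to
## exactly L* = 100, a* = b* = 0
.whiteD65 <- rowSums(.srgb2xyz)

#' Convert an RGBImage to CIE-L*a*b*
#'
#' sRGB is linearized, mapped to XYZ under the D65 white point (2 degree
#' observer), then to L*a*b* with the standard cube-root compression.
#'
#' @param img an \code{RGBImage}.
#' @return a \code{LabImage} of the same shape.
#' @export
rgbToLab <- function(img) {
  stopifnot(is(img, "RGBImage"))
  d <- dim(img@pixels)
  lab <- rgbMatrixToLab(matrix(as.numeric(img@pixels), ncol = 3L))
  new("LabImage", pixels = array(lab, dim = d))
}

## N x 3 matrix of 0-255 RGB -> N x 3 matrix of L*, a*, b*
rgbMatrixToLab <- function(rgb255) {
  lin <- srgbToLinear(rgb255 / 255)
  xyz <- lin %*% t(.srgb2xyz)
  t3 <- sweep(xyz, 2, .whiteD65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t3 > eps, t3^(1 / 3), t3 / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' @describeIn RGBImage-class compact display
#' @param object an \code{RGBImage}.
#' @export
setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage: %d x %d px, 3 channels (8-bit)\n", d[1], d[2]))
  if (!is.na(object@sourceTag))
    cat("  sourceTag:", object@sourceTag, "\n")
})

setMethod("show", "HSVImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("HSVImage: %d x %d px, H/S/V in [0,1]\n", d[1], d[2]))
})

setMethod("show", "LabImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LabImage: %d x %d px, CIE-L*a*b* (D65)\n", d[1], d[2]))
})

#' Image dimensions
#' @param x an \code{RGBImage}.
#' @return integer(3): height, width, channels.
#' @export
setMethod("dim", "RGBImage", function(x) dim(x@pixels))

#' Raw pixel array of an image object
#' @param x an \code{RGBImage}, \code{HSVImage} or \code{LabImage}.
#' @return the underlying H x W x 3 array.
#' @export
imagePixels <- function(x) {
  stopifnot(is(x, "RGBImage") || is(x, "HSVImage") || is(x, "LabImage"))
  x@pixels
}
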