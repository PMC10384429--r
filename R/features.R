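## Color features of a segmented fruit: red/green/blue pixel areas by
## dominant channel, masked-pixel mean L*a*b* mapped into the fuzzy input
## domains, and the a/b chromaticity ratio.

#' Construct a FeatureScaling
#'
#' @param gain,offset numeric(3) named (L, a, b); feature = gain * value +
#'   offset. Defaults map L* in [0, 100] onto (0, 2558.3], a* in [-128, 127]
#'   onto (0, 1736] and b* in [-128, 127] onto (-210, 358], the input domains
#'   of the fuzzy membership functions.
#' @return a \code{FeatureScaling}.
#' @export
FeatureScaling <- function(gain = NULL, offset = NULL) {
  obj <- new("FeatureScaling")
  if (!is.null(gain)) obj@gain <- gain
  if (!is.null(offset)) obj@offset <- offset
  validObject(obj)
  obj
}

#' Identity feature scaling (gain 1, offset 0)
#'
#' With identity scaling the L/a/b features equal the masked-pixel Lab means.
#' @return a \code{FeatureScaling}.
#' @export
identityScaling <- function() {
  FeatureScaling(gain = c(L = 1, a = 1, b = 1), offset = c(L = 0, a = 0, b = 0))
}

#' Classify pixels by dominant color channel
#'
#' A pixel is RED/GREEN/BLUE when that channel exceeds \emph{both} others by
#' at least \code{delta} intensity units, NONE otherwise (achromatic or
#' ambiguous pixels).
#'
#' @param rgb numeric vector of length 3, or an N x 3 matrix of intensities
#'   in [0, 255].
#' @param delta dominance margin in intensity units (default 10).
#' @return character vector of "RED", "GREEN", "BLUE" or "NONE".
#' @export
classifyPixelColor <- function(rgb, delta = 10) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3L)
  stopifnot(ncol(rgb) == 3L, min(rgb) >= 0, max(rgb) <= 255)
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  out <- rep("NONE", nrow(rgb))
  out[r >= g + delta & r >= b + delta] <- "RED"
  out[g >= r + delta & g >= b + delta] <- "GREEN"
  out[b >= r + delta & b >= g + delta] <- "BLUE"
  out
}

#' Extract the color-feature vector of a segmented fruit
#'
#' Counts masked pixels per dominant-channel class, averages L*, a*, b* over
#' the mask, and maps the averages into the fuzzy input domains via
#' \code{scaling}.
#'
#' @param img the source \code{RGBImage}.
#' @param m the \code{FruitMask} (after area filtering).
#' @param scaling a \code{FeatureScaling} (default: the documented map onto
#'   the fuzzy domains; use \code{identityScaling()} for raw Lab means).
#' @param delta dominance margin for \code{\link{classifyPixelColor}}.
#' @return a \code{ColorFeatures} object. Areas are raw pixel counts; see
#'   \code{\link{normalizedAreas}} for fruit-size-normalized fractions.
#' @export
extractFeatures <- function(img, m, scaling = FeatureScaling(), delta = 10) {
  stopifnot(is(img, "RGBImage"), is(m, "FruitMask"),
            is(scaling, "FeatureScaling"))
  if (!identical(dim(img@pixels)[1:2], dim(m@mask)))
    stop("image and mask shapes differ")
  sel <- as.vector(m@mask)
  if (!any(sel)) stop("no fruit segmented: the mask is empty")
  flat <- matrix(as.numeric(img@pixels), ncol = 3L)[sel, , drop = FALSE]
  cls <- classifyPixelColor(flat, delta = delta)
  lab <- rgbMatrixToLab(flat)
  mu <- colMeans(lab)
  feat <- scaling@gain * mu + scaling@offset
  if (feat[3] == 0)
    stop("b feature is zero: a/b chromaticity ratio undefined")
  new("ColorFeatures",
      areaRed = sum(cls == "RED"), areaGreen = sum(cls == "GREEN"),
      areaBlue = sum(cls == "BLUE"),
      L = unname(feat[1]), a = unname(feat[2]), b = unname(feat[3]),
      ratioAb = unname(feat[2] / feat[3]), nFruitPx = sum(sel))
}

setMethod("show", "ColorFeatures", function(object) {
  cat("ColorFeatures:\n")
  cat(sprintf("  areas (px): red %d, green %d, blue %d of %d fruit px\n",
              object@areaRed, object@areaGreen, object@areaBlue,
              object@nFruitPx))
  cat(sprintf("  L %.2f, a %.2f, b %.2f, a/b %.4f (fuzzy-domain units)\n",
              object@L, object@a, object@b, object@ratioAb))
})

#' Flatten ColorFeatures to a one-row data.frame
#'
#' Column dialect shared by the feature-table CSV and the synthetic dataset:
#' area_red, area_green, area_blue, L_feat, a_feat, b_feat, ratio_ab,
#' n_fruit_px.
#'
#' @param x a \code{ColorFeatures}.
#' @param row.names,optional,... ignored (base-generic signature).
#' @return a one-row data.frame.
#' @export
as.data.frame.ColorFeatures <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(area_red = x@areaRed, area_green = x@areaGreen,
             area_blue = x@areaBlue, L_feat = x@L, a_feat = x@a,
             b_feat = x@b, ratio_ab = x@ratioAb, n_fruit_px = x@nFruitPx)
}

#' Red/green/blue areas as fractions of the fruit pixel count
#'
#' @param x a \code{ColorFeatures}.
#' @return named numeric(3) summing to at most 1.
#' @export
normalizedAreas <- function(x) {
  stopifnot(is(x, "ColorFeatures"))
  c(red = x@areaRed, green = x@areaGreen, blue = x@areaBlue) / x@nFruitPx
}

#' Write a feature table to CSV
#'
#' One row per image: sample_id, the \code{ColorFeatures} columns, and an
#' optional lycopene_ppm label column.
#'
#' @param tab a data.frame in the feature-table dialect.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV path written by \code{\link{writeFeatureTable}}.
#' @return a data.frame.
#' @export
readFeatureTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
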