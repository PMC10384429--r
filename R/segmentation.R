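## Fruit/background separation. The backdrop is removed by its hue: pixels
## whose hue falls inside the cyan-to-magenta band [0.466, 0.842] are
## background, everything else (red through green, i.e. every tomato hue) is
## foreground. Small stray components are then discarded by area.

#' Construct segmentation parameters
#'
#' @param hBackgroundLow,hBackgroundHigh hue band treated as background
#'   (defaults 0.466 and 0.842 on the unit hue scale).
#' @param sRange,vRange inclusive saturation / value windows for foreground
#'   (defaults [0, 1], i.e. no-ops; narrow \code{vRange} to drop shadows).
#' @param minArea smallest connected component kept, in pixels (default 400:
#'   components \emph{smaller} than this are discarded).
#' @param connectivity 4 or 8 (default 8) for component labeling.
#' @return a \code{SegmentationParams} object.
#' @export
SegmentationParams <- function(hBackgroundLow = 0.466, hBackgroundHigh = 0.842,
                               sRange = c(0, 1), vRange = c(0, 1),
                               minArea = 400L, connectivity = 8L) {
  new("SegmentationParams", hBackgroundLow = hBackgroundLow,
      hBackgroundHigh = hBackgroundHigh, sRange = as.numeric(sRange),
      vRange = as.numeric(vRange), minArea = as.integer(minArea),
      connectivity = as.integer(connectivity))
}

## logical matrix -> FruitMask with labeled components
labelMask <- function(mask, connectivity = 8L) {
  labels <- .ccLabel(mask, as.integer(connectivity))
  areas <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer(0)
  new("FruitMask", mask = mask, labels = labels, areas = as.integer(areas),
      connectivity = as.integer(connectivity))
}

#' Segment the fruit from the background in HSV space
#'
#' A pixel is foreground iff its hue lies \emph{outside}
#' [\code{hBackgroundLow}, \code{hBackgroundHigh}] and its saturation and
#' value lie inside \code{sRange} / \code{vRange}. The foreground is then
#' labeled into connected components. An all-background image yields an
#' empty mask, not an error.
#'
#' @param img an \code{HSVImage}.
#' @param params a \code{SegmentationParams} object.
#' @return a \code{FruitMask} (not yet area-filtered; see
#'   \code{\link{filterSmallRegions}}).
#' @export
segmentFruit <- function(img, params = SegmentationParams()) {
  stopifnot(is(img, "HSVImage"), is(params, "SegmentationParams"))
  h <- img@pixels[, , 1]
  s <- img@pixels[, , 2]
  v <- img@pixels[, , 3]
  fg <- !(h >= params@hBackgroundLow & h <= params@hBackgroundHigh) &
    s >= params@sRange[1] & s <= params@sRange[2] &
    v >= params@vRange[1] & v <= params@vRange[2]
  labelMask(fg, params@connectivity)
}

#' Remove connected components smaller than a pixel-area threshold
#'
#' Components with area < \code{minArea} are deleted; components with area
#' >= \code{minArea} are kept unchanged. Idempotent and anti-extensive.
#'
#' @param m a \code{FruitMask}.
#' @param minArea area cutoff in pixels (default 400).
#' @return a \code{FruitMask} with surviving components relabeled 1..k.
#' @export
filterSmallRegions <- function(m, minArea = 400L) {
  stopifnot(is(m, "FruitMask"))
  if (!length(m@areas) || minArea <= 1L) return(m)
  keep <- which(m@areas >= minArea)
  mask <- matrix(m@labels %in% keep, nrow = nrow(m@mask))
  labelMask(mask, m@connectivity)
}

#' @describeIn nComponents component count of a labeled mask
#' @export
setMethod("nComponents", "FruitMask", function(x) length(x@areas))

#' @describeIn componentAreas areas of a labeled mask's components
#' @export
setMethod("componentAreas", "FruitMask", function(x) x@areas)

#' Logical foreground matrix of a mask
#' @param x a \code{FruitMask}.
#' @return logical matrix.
#' @export
maskMatrix <- function(x) {
  stopifnot(is(x, "FruitMask"))
  x@mask
}

setMethod("show", "FruitMask", function(object) {
  cat(sprintf("FruitMask: %d x %d px, %d component(s), %d foreground px\n",
              nrow(object@mask), ncol(object@mask), length(object@areas),
              sum(object@mask)))
})

#' Jaccard similarity of two masks
#'
#' @param a,b \code{FruitMask} objects or logical matrices of equal shape.
#' @return |a & b| / |a | b|; 1 when both masks are empty.
#' @export
maskJaccard <- function(a, b) {
  ma <- if (is(a, "FruitMask")) a@mask else a
  mb <- if (is(b, "FruitMask")) b@mask else b
  stopifnot(identical(dim(ma), dim(mb)))
  u <- sum(ma | mb)
  if (u == 0L) return(1)
  sum(ma & mb) / u
}

#' Per-component summary table
#'
#' Debug output: one row per connected component with its id, pixel area and
#' centroid (row, col).
#'
#' @param m a \code{FruitMask}.
#' @param path optional CSV path; when given the table is also written there.
#' @return a data.frame with columns component, area, centroid_row,
#'   centroid_col.
#' @export
componentTable <- function(m, path = NULL) {
  stopifnot(is(m, "FruitMask"))
  if (!length(m@areas)) {
    tab <- data.frame(component = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
    return(tab)
  }
  idx <- which(m@labels > 0L, arr.ind = TRUE)
  lab <- m@labels[m@labels > 0L]
  tab <- data.frame(
    component = seq_along(m@areas),
    area = m@areas,
    centroid_row = as.numeric(tapply(idx[, 1], lab, mean)),
    centroid_col = as.numeric(tapply(idx[, 2], lab, mean)))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Write a binary mask as a PNG file
#'
#' @param m a \code{FruitMask}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskPNG <- function(m, path) {
  stopifnot(is(m, "FruitMask"))
  png::writePNG(m@mask * 1, path)
  invisible(path)
}
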