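#' @import methods
#' @importFrom stats rnorm runif sd cor lm.fit predict
#' @importFrom grDevices rgb2hsv
#' @useDynLib lycosense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Image containers
## ---------------------------------------------------------------------------

#' RGBImage: an 8-bit RGB image of a single fruit
#'
#' Wraps an H x W x 3 array of integer intensities in [0, 255]. The optional
#' \code{sourceTag} records free text about acquisition, e.g. the name of the
#' optical bandpass filter the image was taken through.
#'
#' @slot pixels integer array, H x W x 3, values in [0, 255].
#' @slot sourceTag character(1), free-text acquisition tag (may be \code{NA}).
#' @exportClass RGBImage
setClass("RGBImage",
  representation(pixels = "array", sourceTag = "character"),
  prototype(sourceTag = NA_character_))

setValidity("RGBImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must have height >= 1 and width >= 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("channel values must lie in [0, 255]")
  TRUE
})

#' HSVImage: unit-scaled hue/saturation/value image
#'
#' H, S and V are each scaled to [0, 1]; hue 0 is red, 1/3 green, 2/3 blue.
#'
#' @slot pixels numeric array, H x W x 3, all components in [0, 1].
#' @exportClass HSVImage
setClass("HSVImage", representation(pixels = "array"))

setValidity("HSVImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("H, S, V must all lie in [0, 1]")
  TRUE
})

#' LabImage: CIE-L*a*b* image under D65 / 2 degree observer
#'
#' @slot pixels numeric array, H x W x 3 holding L*, a*, b*; L* in [0, 100],
#'   a* and b* unbounded (typically within [-128, 127]).
#' @exportClass LabImage
setClass("LabImage", representation(pixels = "array"))

setValidity("LabImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (anyNA(p) || any(!is.finite(p)))
    return("all L*a*b* values must be finite")
  L <- p[, , 1]
  if (min(L) < -1e-6 || max(L) > 100 + 1e-6)
    return("L* must lie in [0, 100]")
  TRUE
})

## ---------------------------------------------------------------------------
## Segmentation
## ---------------------------------------------------------------------------

#' FruitMask: labeled foreground mask of a segmented fruit
#'
#' @slot mask logical matrix, TRUE on foreground pixels.
#' @slot labels integer matrix of the same shape; 0 on background, component
#'   id (1..n) on foreground.
#' @slot areas integer vector of component pixel counts, indexed by label.
#' @slot connectivity integer(1), 4 or 8.
#' @exportClass FruitMask
setClass("FruitMask",
  representation(mask = "matrix", labels = "matrix", areas = "integer",
                 connectivity = "integer"))

setValidity("FruitMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!identical(dim(object@mask), dim(object@labels)))
    return("mask and labels must have identical shape")
  if (length(object@areas) && any(object@areas < 1L))
    return("every component area must be >= 1")
  if (length(object@areas) != max(0L, object@labels))
    return("number of areas must equal the number of labeled components")
  if (sum(object@mask) != sum(object@areas))
    return("component areas must sum to the foreground pixel count")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' SegmentationParams: hue band and area filter configuration
#'
#' Pixels whose hue falls inside [hBackgroundLow, hBackgroundHigh] are treated
#' as background (the cyan-to-magenta band); everything else whose saturation
#' and value fall inside \code{sRange} / \code{vRange} is foreground.
#' Components smaller than \code{minArea} pixels are then discarded.
#'
#' @slot hBackgroundLow numeric(1), lower hue bound of the background band.
#' @slot hBackgroundHigh numeric(1), upper hue bound.
#' @slot sRange,vRange numeric(2), inclusive saturation / value windows.
#' @slot minArea integer(1), minimum component area kept, in pixels.
#' @slot connectivity integer(1), 4 or 8.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(hBackgroundLow = "numeric", hBackgroundHigh = "numeric",
                 sRange = "numeric", vRange = "numeric",
                 minArea = "integer", connectivity = "integer"),
  prototype(hBackgroundLow = 0.466, hBackgroundHigh = 0.842,
            sRange = c(0, 1), vRange = c(0, 1),
            minArea = 400L, connectivity = 8L))

setValidity("SegmentationParams", function(object) {
  if (!(object@hBackgroundLow >= 0 && object@hBackgroundLow < object@hBackgroundHigh &&
        object@hBackgroundHigh <= 1))
    return("need 0 <= hBackgroundLow < hBackgroundHigh <= 1")
  if (object@minArea < 0L) return("minArea must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  if (length(object@sRange) != 2L || length(object@vRange) != 2L)
    return("sRange and vRange must have length 2")
  TRUE
})

## ---------------------------------------------------------------------------
## Features
## ---------------------------------------------------------------------------

#' FeatureScaling: affine map from L*a*b* statistics to fuzzy input units
#'
#' The fuzzy membership functions are defined on non-standard input domains
#' (L in (0, 2558.3], a in (0, 1736], b in (-210, 358]). This class holds the
#' per-input gain and offset mapping masked-pixel mean L*, a*, b* into those
#' domains: feature = gain * value + offset. The default maps
#' L* in [0, 100] onto [0, 2558.3], a* in [-128, 127] onto [0, 1736] and
#' b* in [-128, 127] onto [-210, 358]. \code{identityScaling()} gives
#' gain 1 / offset 0 on every channel.
#'
#' @slot gain,offset numeric(3), named L, a, b.
#' @exportClass FeatureScaling
setClass("FeatureScaling",
  representation(gain = "numeric", offset = "numeric"),
  prototype(
    gain   = c(L = 2558.3 / 100, a = 1736 / 255, b = (358 + 210) / 255),
    offset = c(L = 0, a = 1736 * 128 / 255, b = -210 + 128 * (358 + 210) / 255)))

setValidity("FeatureScaling", function(object) {
  if (length(object@gain) != 3L || length(object@offset) != 3L)
    return("gain and offset must each have length 3 (L, a, b)")
  if (any(!is.finite(c(object@gain, object@offset))))
    return("gain and offset must be finite")
  TRUE
})

#' ColorFeatures: the per-image color feature vector the models consume
#'
#' @slot areaRed,areaGreen,areaBlue integer(1), counts of masked pixels whose
#'   dominant channel is red / green / blue.
#' @slot L,a,b numeric(1), masked-pixel mean L*, a*, b* mapped into the fuzzy
#'   input domains by a \code{FeatureScaling}.
#' @slot ratioAb numeric(1), a / b in feature units.
#' @slot nFruitPx integer(1), number of masked (fruit) pixels.
#' @exportClass ColorFeatures
setClass("ColorFeatures",
  representation(areaRed = "integer", areaGreen = "integer",
                 areaBlue = "integer", L = "numeric", a = "numeric",
                 b = "numeric", ratioAb = "numeric", nFruitPx = "integer"))

setValidity("ColorFeatures", function(object) {
  if (object@areaRed < 0L || object@areaGreen < 0L || object@areaBlue < 0L)
    return("areas must be >= 0")
  if (object@areaRed + object@areaGreen + object@areaBlue > object@nFruitPx)
    return("class areas cannot exceed the fruit pixel count")
  TRUE
})

## ---------------------------------------------------------------------------
## Fuzzy system
## ---------------------------------------------------------------------------

#' TriangularMF: a clipped piecewise-linear (triangular) membership function
#'
#' Degrees rise linearly from \code{left} to 1 at \code{peak} and fall back to
#' 0 at \code{right}; \code{left == peak} makes a left shoulder (degree 1 for
#' all x <= peak) and \code{peak == right} a right shoulder. All degrees are
#' clipped to [0, 1] and are 0 outside the variable domain (lo, hi].
#'
#' @slot name character(1), e.g. "Low_a".
#' @slot left,peak,right numeric(1) breakpoints, left <= peak <= right.
#' @slot domain numeric(2), the half-open variable domain (lo, hi].
#' @exportClass TriangularMF
setClass("TriangularMF",
  representation(name = "character", left = "numeric", peak = "numeric",
                 right = "numeric", domain = "numeric"))

setValidity("TriangularMF", function(object) {
  if (!(object@left <= object@peak && object@peak <= object@right))
    return("breakpoints must satisfy left <= peak <= right")
  if (length(object@domain) != 2L || object@domain[1] >= object@domain[2])
    return("domain must be an increasing pair")
  TRUE
})

#' FuzzyVariable: an ordered family of membership functions on one input
#'
#' @slot name character(1), e.g. "L".
#' @slot mfs list of \code{TriangularMF}.
#' @slot domain numeric(2), the half-open input domain (lo, hi].
#' @exportClass FuzzyVariable
setClass("FuzzyVariable",
  representation(name = "character", mfs = "list", domain = "numeric"))

setValidity("FuzzyVariable", function(object) {
  if (!length(object@mfs)) return("a variable needs at least one MF")
  if (!all(vapply(object@mfs, is, TRUE, "TriangularMF")))
    return("mfs must all be TriangularMF")
  TRUE
})

#' TakagiSugenoModel: fuzzy rule base with linear (Sugeno) consequents
#'
#' Rules are rows of \code{antecedents}: one MF index per input variable. For
#' a first-order model, row i of \code{coefficients} holds the consequent
#' (p_i1, ..., p_ip, r_i) so that the rule output level is
#' Z_i(x) = p_i . x + r_i; a zero-order model keeps the intercept only.
#' Prediction is the firing-strength-weighted average sum(w_i Z_i) / sum(w_i).
#'
#' @slot variables list of \code{FuzzyVariable}.
#' @slot antecedents integer matrix, nRules x nVariables.
#' @slot coefficients numeric matrix, nRules x (nVariables + 1) for a
#'   first-order model, nRules x 1 for zero-order.
#' @slot tnorm character(1), "product" or "min".
#' @slot order character(1), "one" or "zero".
#' @slot inputNames character, the feature-table columns the model reads.
#' @slot fitInfo list, training diagnostics from \code{fitConsequents}.
#' @exportClass TakagiSugenoModel
setClass("TakagiSugenoModel",
  representation(variables = "list", antecedents = "matrix",
                 coefficients = "matrix", tnorm = "character",
                 order = "character", inputNames = "character",
                 fitInfo = "list"),
  prototype(tnorm = "product", order = "one", fitInfo = list()))

setValidity("TakagiSugenoModel", function(object) {
  nv <- length(object@variables)
  if (!nv) return("model needs at least one variable")
  if (ncol(object@antecedents) != nv)
    return("antecedents must have one column per variable")
  nm <- vapply(object@variables, function(v) length(v@mfs), 1L)
  for (j in seq_len(nv))
    if (any(object@antecedents[, j] < 1L | object@antecedents[, j] > nm[j]))
      return("antecedent MF index out of range for a variable")
  expCols <- if (identical(object@order, "one")) nv + 1L else 1L
  if (!identical(dim(object@coefficients),
                 c(nrow(object@antecedents), as.integer(expCols))))
    return("coefficient matrix shape inconsistent with order and rule count")
  if (!object@tnorm %in% c("product", "min")) return("tnorm must be product or min")
  if (!object@order %in% c("zero", "one")) return("order must be zero or one")
  TRUE
})

## ---------------------------------------------------------------------------
## Baseline regressors
## ---------------------------------------------------------------------------

#' LinearABModel: least-squares line from a*/b* chromaticity to lycopene
#'
#' @slot slope numeric(1), ppm per unit ratio.
#' @slot intercept numeric(1), ppm.
#' @slot inputNames character(1), feature column consumed (default ratio_ab).
#' @exportClass LinearABModel
setClass("LinearABModel",
  representation(slope = "numeric", intercept = "numeric",
                 inputNames = "character"),
  prototype(inputNames = "ratio_ab"))

setValidity("LinearABModel", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("coefficients must be finite")
  TRUE
})

#' MLPModel: small feed-forward network (sigmoid hidden layer, linear output)
#'
#' Inputs are z-scored with the stored \code{center} / \code{scale} before the
#' forward pass. Trained by damped Gauss-Newton (Levenberg-Marquardt) on the
#' residual Jacobian; \code{lossTrace} holds the mean squared error after each
#' accepted step (element 1 is the MSE at initialization).
#'
#' @slot W1 numeric matrix, hiddenUnits x nInputs.
#' @slot b1 numeric, hidden biases.
#' @slot W2 numeric matrix, 1 x hiddenUnits.
#' @slot b2 numeric(1), output bias.
#' @slot center,scale numeric, per-input standardization parameters.
#' @slot lossTrace numeric, accepted-step MSE sequence.
#' @slot inputNames character, feature columns consumed.
#' @slot seed integer(1), RNG seed used at initialization.
#' @exportClass MLPModel
setClass("MLPModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 center = "numeric", scale = "numeric", lossTrace = "numeric",
                 inputNames = "character", seed = "integer"))

setValidity("MLPModel", function(object) {
  h <- nrow(object@W1)
  if (length(object@b1) != h || ncol(object@W2) != h || nrow(object@W2) != 1L)
    return("weight shapes inconsistent with layer sizes")
  if (length(object@b2) != 1L) return("b2 must be scalar")
  if (length(object@center) != ncol(object@W1) ||
      length(object@scale) != ncol(object@W1))
    return("standardization parameters must match the input count")
  TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data generator
## ---------------------------------------------------------------------------

#' GeneratorConfig: study conditions for the synthetic tomato generator
#'
#' Defaults mirror the sensor study design: 18 single-fruit images across five
#' maturity classes (5 green, 3 turned, 3 pink, 2 light red, 5 red) at
#' 768 x 1366 px on a blue backdrop, with a lycopene law anchored to the HPLC
#' scale (approximately 0-90 ppm): ppm = lambdaMax * r^gamma + N(0, noiseSd),
#' where r is the red fraction area_red / (area_red + area_green).
#'
#' @slot classCounts named integer, samples per maturity class (G, T, P, LR, R).
#' @slot imageShape integer(2), (height, width) in pixels.
#' @slot backgroundHue numeric(1), backdrop hue in [0, 1].
#' @slot palettes named list; per class a list with \code{red} and
#'   \code{green} anchor RGB triples in [0, 255] and \code{redFraction}, the
#'   probability a fruit pixel takes the red anchor (ripening mottle model).
#' @slot jitterSd numeric(1), per-pixel Gaussian RGB jitter sd.
#' @slot speckleCount integer(1), small (< 400 px) non-fruit specks injected.
#' @slot lambdaMax numeric(1), ppm at full redness.
#' @slot gamma numeric(1), redness exponent.
#' @slot noiseSd numeric(1), label noise sd in ppm.
#' @slot seed integer(1).
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(classCounts = "integer", imageShape = "integer",
                 backgroundHue = "numeric", palettes = "list",
                 jitterSd = "numeric", speckleCount = "integer",
                 lambdaMax = "numeric", gamma = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  prototype(
    classCounts = c(G = 5L, T = 3L, P = 3L, LR = 2L, R = 5L),
    imageShape = c(768L, 1366L),
    backgroundHue = 0.65,
    palettes = list(
      G  = list(red = c(200, 35, 30), green = c(70, 150, 55), redFraction = 0.02),
      T  = list(red = c(190, 70, 45), green = c(80, 150, 55), redFraction = 0.30),
      P  = list(red = c(215, 110, 100), green = c(90, 150, 60), redFraction = 0.55),
      LR = list(red = c(225, 85, 60), green = c(95, 145, 60), redFraction = 0.78),
      R  = list(red = c(200, 35, 30), green = c(100, 140, 60), redFraction = 0.97)),
    jitterSd = 8,
    speckleCount = 3L,
    lambdaMax = 90, gamma = 1.5, noiseSd = 2,
    seed = 1L))

setValidity("GeneratorConfig", function(object) {
  if (any(object@classCounts < 0L)) return("class counts must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@lambdaMax <= 0) return("lambdaMax must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    return("imageShape must be (height, width), each >= 8")
  if (object@backgroundHue < 0 || object@backgroundHue > 1)
    return("backgroundHue must lie in [0, 1]")
  if (!all(names(object@classCounts) %in% names(object@palettes)))
    return("every class needs a palette entry")
  TRUE
})
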