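## Seeded synthetic tomato images, feature tables and ground-truth lycopene
## labels. The generator emulates the study conditions: 18 single-fruit
## images (5 G / 3 T / 3 P / 2 LR / 5 R maturity classes) at 768 x 1366 px on
## a blue backdrop, each fruit an ellipse of red/green anchor-color mottle
## (the class sets the red fraction) with per-pixel Gaussian jitter, plus a
## few sub-400-px stray specks. The
## lycopene label follows ppm = lambdaMax * r^gamma + N(0, noiseSd) with
## r = area_red / (area_red + area_green), anchored to the ~0-90 ppm HPLC
## scale.

#' Construct a generator configuration
#'
#' See \code{\linkS4class{GeneratorConfig}} for the slots; any argument left
#' NULL keeps the default study conditions.
#'
#' @param classCounts named integer vector over G, T, P, LR, R.
#' @param imageShape integer(2): height, width.
#' @param backgroundHue backdrop hue in [0, 1].
#' @param palettes named list of mean RGB triples.
#' @param jitterSd per-pixel RGB jitter sd.
#' @param speckleCount number of injected sub-400-px specks.
#' @param lambdaMax,gamma,noiseSd lycopene law parameters.
#' @param seed integer seed.
#' @return a \code{GeneratorConfig}.
#' @export
GeneratorConfig <- function(classCounts = NULL, imageShape = NULL,
                            backgroundHue = NULL, palettes = NULL,
                            jitterSd = NULL, speckleCount = NULL,
                            lambdaMax = NULL, gamma = NULL, noiseSd = NULL,
                            seed = NULL) {
  obj <- new("GeneratorConfig")
  if (!is.null(classCounts)) obj@classCounts <- as.integer(classCounts) |>
      stats::setNames(names(classCounts))
  if (!is.null(imageShape)) obj@imageShape <- as.integer(imageShape)
  if (!is.null(backgroundHue)) obj@backgroundHue <- backgroundHue
  if (!is.null(palettes)) obj@palettes <- palettes
  if (!is.null(jitterSd)) obj@jitterSd <- jitterSd
  if (!is.null(speckleCount)) obj@speckleCount <- as.integer(speckleCount)
  if (!is.null(lambdaMax)) obj@lambdaMax <- lambdaMax
  if (!is.null(gamma)) obj@gamma <- gamma
  if (!is.null(noiseSd)) obj@noiseSd <- noiseSd
  if (!is.null(seed)) obj@seed <- as.integer(seed)
  validObject(obj)
  obj
}

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:\n")
  cat("  classes:", paste(sprintf("%s=%d", names(object@classCounts),
                                  object@classCounts), collapse = " "), "\n")
  cat(sprintf("  image %d x %d px, background hue %.3f, %d speckle(s)\n",
              object@imageShape[1], object@imageShape[2],
              object@backgroundHue, object@speckleCount))
  cat(sprintf("  lycopene law: %.4g * r^%.4g + N(0, %.4g), seed %d\n",
              object@lambdaMax, object@gamma, object@noiseSd, object@seed))
})

## hue/sat/val triple -> RGB triple in 0..255
.hsv255 <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h, s, v)))
}

#' Generate one synthetic tomato image
#'
#' An ellipse (the fruit) whose pixels take the class's red anchor color
#' with probability \code{redFraction} and the green anchor otherwise (a
#' ripening-mottle model), plus Gaussian jitter, centered on a uniform
#' backdrop of \code{backgroundHue}, with \code{speckleCount} small
#' (< 400 px) fruit-colored specks placed away from the fruit.
#' Bit-identical for a fixed (class, config, seed).
#'
#' @param class maturity class label: "G", "T", "P", "LR" or "R".
#' @param cfg a \code{GeneratorConfig}.
#' @param seed integer seed (default: the config seed).
#' @return list with elements \code{image} (\code{RGBImage}) and
#'   \code{trueMask} (\code{FruitMask} of the fruit ellipse only).
#' @export
generateTomatoImage <- function(class, cfg = GeneratorConfig(),
                                seed = cfg@seed) {
  stopifnot(class %in% names(cfg@palettes))
  set.seed(seed)
  H <- cfg@imageShape[1]; W <- cfg@imageShape[2]

  bgRGB <- .hsv255(cfg@backgroundHue, 0.55, 0.75)
  px <- array(0, dim = c(H, W, 3L))
  for (k in 1:3) px[, , k] <- bgRGB[k]

  # fruit ellipse: centered, semi-axes ~1/3 of each dimension
  ry <- floor(H * 0.34); rx <- floor(W * 0.22)
  cy <- H / 2 + 0.5; cx <- W / 2 + 0.5
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
  nIn <- sum(inside)

  # ripening mottle: each fruit pixel takes the red or green anchor color
  pal <- cfg@palettes[[class]]
  isRed <- runif(nIn) < pal$redFraction
  for (k in 1:3) {
    ch <- px[, , k]
    base <- ifelse(isRed, pal$red[k], pal$green[k])
    ch[inside] <- pmin(255, pmax(0, round(base + rnorm(nIn, 0, cfg@jitterSd))))
    px[, , k] <- ch
  }

  # stray specks: small reddish discs outside the fruit (area < 400 px each)
  if (cfg@speckleCount > 0L) {
    placed <- 0L
    while (placed < cfg@speckleCount) {
      r <- sample(3:8, 1L)
      si <- sample(seq_len(H), 1L); sj <- sample(seq_len(W), 1L)
      # keep clear of the fruit so specks stay separate components
      if (((si - cy) / (ry + r + 4))^2 + ((sj - cx) / (rx + r + 4))^2 <= 1)
        next
      disc <- (row - si)^2 + (col - sj)^2 <= r^2
      spk <- c(200, 60, 40) + round(rnorm(3, 0, 10))
      for (k in 1:3) {
        ch <- px[, , k]
        ch[disc] <- pmin(255, pmax(0, spk[k]))
        px[, , k] <- ch
      }
      placed <- placed + 1L
    }
  }

  list(image = RGBImage(px, sourceTag = paste0("synthetic_", class)),
       trueMask = labelMask(inside, 8L))
}

#' Generate the full synthetic study dataset from images
#'
#' For each sample an image is generated, segmented with the default
#' parameters, area-filtered, and reduced to color features; the label is
#' lambdaMax * r^gamma + N(0, noiseSd) truncated at 0, with
#' r = area_red / (area_red + area_green) measured on the generated image.
#'
#' @param cfg a \code{GeneratorConfig}.
#' @param params segmentation parameters (defaults).
#' @param scaling feature scaling (defaults).
#' @param keepImages if TRUE, attach the per-sample images and masks as
#'   \code{attr(, "samples")} (list of \code{image}, \code{trueMask},
#'   \code{recoveredMask}).
#' @param dir optional directory: when given, images are written as PNG, the
#'   table as \code{features.csv}, and the config and seed as a
#'   \code{config.yaml} sidecar.
#' @return a data.frame: sample_id, maturity_class, the feature-table
#'   columns, redness and lycopene_ppm.
#' @export
generateDataset <- function(cfg = GeneratorConfig(),
                            params = SegmentationParams(),
                            scaling = FeatureScaling(),
                            keepImages = FALSE, dir = NULL) {
  classes <- rep(names(cfg@classCounts), cfg@classCounts)
  samples <- list()
  rows <- vector("list", length(classes))
  set.seed(cfg@seed)
  noise <- rnorm(length(classes), 0, cfg@noiseSd)
  for (i in seq_along(classes)) {
    gen <- generateTomatoImage(classes[i], cfg, seed = cfg@seed + i)
    m <- filterSmallRegions(segmentFruit(rgbToHsv(gen$image), params),
                            params@minArea)
    f <- extractFeatures(gen$image, m, scaling = scaling)
    denom <- f@areaRed + f@areaGreen
    r <- if (denom > 0L) f@areaRed / denom else 0
    ppm <- max(0, cfg@lambdaMax * r^cfg@gamma + noise[i])
    rows[[i]] <- cbind(
      data.frame(sample_id = sprintf("%s_%02d", classes[i], i),
                 maturity_class = classes[i]),
      as.data.frame(f),
      data.frame(redness = r, lycopene_ppm = ppm))
    if (keepImages || !is.null(dir))
      samples[[i]] <- list(image = gen$image, trueMask = gen$trueMask,
                           recoveredMask = m)
  }
  ds <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(samples))
      png::writePNG(imagePixels(samples[[i]]$image) / 255,
                    file.path(dir, paste0(ds$sample_id[i], ".png")))
    writeFeatureTable(ds, file.path(dir, "features.csv"))
    yaml::write_yaml(generatorConfigAsList(cfg), file.path(dir, "config.yaml"))
  }
  if (keepImages) attr(ds, "samples") <- samples
  ds
}

## plain-list view of a GeneratorConfig (YAML sidecar)
generatorConfigAsList <- function(cfg) {
  list(classCounts = as.list(cfg@classCounts),
       imageShape = cfg@imageShape, backgroundHue = cfg@backgroundHue,
       palettes = cfg@palettes, jitterSd = cfg@jitterSd,
       speckleCount = cfg@speckleCount, lambdaMax = cfg@lambdaMax,
       gamma = cfg@gamma, noiseSd = cfg@noiseSd, seed = cfg@seed)
}

#' Generate a feature table directly in fuzzy-domain units
#'
#' Bypasses imaging: (L, a, b) are sampled uniformly from the fuzzy input
#' domains ((0, 2558.3], (0, 1736], (-210, 358]). Labels come either from a
#' planted \code{TakagiSugenoModel} (noiseless unless \code{noiseSd} > 0) or
#' from the default smooth law
#' ppm = lambdaMax * (0.5 * a/1736 + 0.5 * (358 - b)/568)^gamma + noise,
#' which increases with a (greener to redder) and decreases with b.
#'
#' @param n number of samples.
#' @param cfg a \code{GeneratorConfig} (lycopene law and seed defaults).
#' @param seed integer seed (default: the config seed).
#' @param model optional planted \code{TakagiSugenoModel} used as the true
#'   surface.
#' @param noiseSd label noise sd (default: the config value; use 0 for
#'   noiseless parameter-recovery tests).
#' @return a data.frame: sample_id, L_feat, a_feat, b_feat, ratio_ab,
#'   lycopene_ppm.
#' @export
generateFeatureTable <- function(n, cfg = GeneratorConfig(), seed = cfg@seed,
                                 model = NULL, noiseSd = cfg@noiseSd) {
  stopifnot(n >= 1L)
  set.seed(seed)
  L <- runif(n, 1e-6, 2558.3)
  a <- runif(n, 1e-6, 1736)
  b <- runif(n, -210 + 1e-6, 358)
  X <- cbind(L, a, b)
  if (is.null(model)) {
    s <- 0.5 * a / 1736 + 0.5 * (358 - b) / 568
    ppm <- pmax(0, cfg@lambdaMax * s^cfg@gamma + rnorm(n, 0, noiseSd))
  } else {
    # planted-model surface: kept untruncated so the table stays an exact
    # realization of the model (parameter-recovery use)
    ppm <- predict(model, X) + rnorm(n, 0, noiseSd)
  }
  data.frame(sample_id = sprintf("f_%04d", seq_len(n)),
             L_feat = L, a_feat = a, b_feat = b, ratio_ab = a / b,
             lycopene_ppm = ppm)
}
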