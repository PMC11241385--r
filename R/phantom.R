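## Speckle phantom generator. The only image property the grading method
## consumes is the region-mean Lab difference, so phantoms are calibrated
## purely to the Delta E bands of the three grades: a bright plexus-like
## reference patch and a parenchyma patch offset in mean lightness, both
## textured with multiplicative gamma speckle and lightly blurred.

## invert L* -> linear luminance -> sRGB-companded gray level (continuous,
## 0..255); the forward map is applied per-pixel by rgbToLab()
.grayForL <- function(L) {
  kappa <- 24389 / 27
  Y <- ifelse(L > 8, ((L + 16) / 116)^3, L / kappa)
  g <- ifelse(Y > 0.0031308, 1.055 * Y^(1 / 2.4) - 0.055, 12.92 * Y)
  pmin(pmax(g, 0), 1) * 255
}

.specklePatch <- function(gray0, h, w, shape, blurSigma) {
  field <- gray0 * stats::rgamma(h * w, shape = shape, rate = shape)
  m <- matrix(field, h, w)
  if (blurSigma > 0)
    m <- EBImage::imageData(EBImage::gblur(m, sigma = blurSigma))
  ultrasoundImage(round(pmin(pmax(m, 0), 255)))
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Generate one phantom ROI pair for a given grade
#'
#' Draws a plexus reference patch at the configured mean lightness and a
#' parenchyma patch whose mean lightness is offset by the grade's Delta E
#' target (plus jitter), then applies multiplicative gamma speckle and
#' Gaussian blur. The realized Delta E is measured on the finished patches
#' with the stage-one pipeline ([rgbToLab()], [channelMeans()],
#' [deltaE()]), so it reflects quantization, speckle and blur.
#'
#' @param cls one of [gradeLevels()].
#' @param cfg a [PhantomConfig-class].
#' @param seed optional integer; when given, generation is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A list with `parenchyma` and `plexus`
#'   ([UltrasoundImage-class] grayscale patches), `trueDeltaE` (the
#'   realized score) and `label` (factor).
#' @export
#' @examples
#' p <- generatePhantomPair("Normal", phantomConfig(), seed = 1)
#' p$trueDeltaE > 40
generatePhantomPair <- function(cls, cfg = phantomConfig(), seed = NULL) {
  stopifnot(cls %in% gradeLevels(), is(cfg, "PhantomConfig"))
  validObject(cfg)
  .withSeed(seed, {
    target <- stats::rnorm(1L, cfg@deltaETargets[[cls]], cfg@jitterSD)
    target <- max(target, 0.25)
    LPar <- max(cfg@plexusL - target, 0.5)
    h <- cfg@patchHeight; w <- cfg@patchWidth
    par <- .specklePatch(.grayForL(LPar), h, w, cfg@speckleShape,
                         cfg@blurSigma)
    plex <- .specklePatch(.grayForL(cfg@plexusL), h, w, cfg@speckleShape,
                          cfg@blurSigma)
    dE <- deltaE(channelMeans(rgbToLab(par)), channelMeans(rgbToLab(plex)))
    list(parenchyma = par, plexus = plex, trueDeltaE = dE,
         label = .gradeFactor(cls))
  })
}

#' Generate a balanced labeled phantom dataset of composites
#'
#' Draws `nPerClass` phantom pairs per grade, builds the two-region
#' composite of each pair with [compositeFromPatches()], and returns the
#' stack as a [CompositeDataset-class]. The manifest records, per sample,
#' the generating label, the realized Delta E and the grade the clinical
#' thresholds assign to that Delta E. Fully reproducible from
#' `(cfg, seed)`.
#'
#' @param nPerClass samples per grade, >= 1.
#' @param cfg a [PhantomConfig-class].
#' @param seed integer seed.
#' @param inputHeight,inputWidth composite (network input) size,
#'   default 100 x 100.
#' @return A [CompositeDataset-class] with `3 * nPerClass` samples.
#' @export
#' @examples
#' ds <- generatePhantomDataset(3, phantomConfig(patchHeight = 24,
#'                                               patchWidth = 24), seed = 1)
#' table(labels(ds))
generatePhantomDataset <- function(nPerClass, cfg = phantomConfig(),
                                   seed = 1, inputHeight = 100,
                                   inputWidth = 100) {
  stopifnot(nPerClass >= 1L, is(cfg, "PhantomConfig"))
  n <- 3L * as.integer(nPerClass)
  px <- array(0, c(inputHeight, inputWidth, 3L, n))
  lab <- character(n)
  dE <- numeric(n)
  .withSeed(seed, {
    i <- 0L
    for (cls in gradeLevels()) {
      for (s in seq_len(nPerClass)) {
        i <- i + 1L
        pair <- generatePhantomPair(cls, cfg)
        comp <- compositeFromPatches(pair$parenchyma, pair$plexus,
                                     inputHeight, inputWidth)
        px[, , , i] <- comp@pixels
        lab[i] <- cls
        dE[i] <- pair$trueDeltaE
      }
    }
  })
  man <- data.frame(
    id = sprintf("phantom_%03d", seq_len(n)),
    label = lab,
    deltaE = dE,
    thresholdGrade = as.character(categorizeDeltaE(dE)),
    seed = as.integer(seed),
    stringsAsFactors = FALSE)
  new("CompositeDataset", pixels = px, labels = .gradeFactor(lab),
      manifest = man)
}

#' Fraction of phantoms whose thresholded Delta E recovers the label
#'
#' Compares the grade assigned by the clinical thresholds to each
#' sample's realized Delta E against the label the generator used. At the
#' default band separation this agreement is expected to exceed 0.95.
#'
#' @param dataset a [CompositeDataset-class] produced by
#'   [generatePhantomDataset()].
#' @return Proportion in \[0, 1\].
#' @export
labelRecovery <- function(dataset) {
  stopifnot(is(dataset, "CompositeDataset"))
  man <- dataset@manifest
  if (is.null(man$thresholdGrade))
    stop("dataset manifest lacks a thresholdGrade column")
  mean(man$thresholdGrade == as.character(dataset@labels))
}
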