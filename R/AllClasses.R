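#' @import methods
NULL

#' Injury grade levels
#'
#' The three echogenicity grades used throughout the package, in fixed
#' order: `"Normal"`, `"Moderate"`, `"Intensive"`. Normal means the
#' parenchyma is much darker than the choroid-plexus reference (large
#' Delta E); Intensive means the parenchyma is about as echogenic as the
#' plexus (near-zero Delta E), the hallmark of severe hypoxic-ischemic
#' white-matter injury.
#'
#' @return Character vector of length 3.
#' @export
#' @examples
#' gradeLevels()
gradeLevels <- function() c("Normal", "Moderate", "Intensive")

.gradeFactor <- function(x) factor(x, levels = gradeLevels())

## ---------------------------------------------------------------------------
## UltrasoundImage
## ---------------------------------------------------------------------------

#' UltrasoundImage: a 2-D raster with colorspace metadata
#'
#' Container for a cranial-ultrasound raster. RGB images hold 8-bit
#' integer-valued samples in \[0, 255\] (grayscale rasters carry a single
#' channel and are replicated to three channels before Lab conversion);
#' Lab images hold real-valued CIE L*a*b* coordinates with L in \[0, 100\].
#'
#' @slot pixels numeric array `height x width x channels`.
#' @slot colorspace `"RGB"` or `"Lab"`.
#' @slot sourcePath optional path the raster was read from.
#'
#' @aliases UltrasoundImage
#' @exportClass UltrasoundImage
setClass("UltrasoundImage",
  representation(pixels = "array", colorspace = "character",
                 sourcePath = "character"),
  prototype(pixels = array(0, c(1L, 1L, 1L)), colorspace = "RGB",
            sourcePath = NA_character_))

setValidity("UltrasoundImage", function(object) {
  d <- dim(object@pixels)
  msg <- NULL
  if (length(d) != 3L)
    msg <- c(msg, "pixels must be a height x width x channels array")
  else {
    if (d[1L] < 1L || d[2L] < 1L)
      msg <- c(msg, "image must have height >= 1 and width >= 1")
    if (!d[3L] %in% c(1L, 3L))
      msg <- c(msg, "channels must be 1 or 3")
  }
  if (length(object@colorspace) != 1L ||
      !object@colorspace %in% c("RGB", "Lab"))
    msg <- c(msg, "colorspace must be \"RGB\" or \"Lab\"")
  if (anyNA(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "pixel values must be finite")
  else if (identical(object@colorspace, "RGB")) {
    p <- object@pixels
    if (min(p) < 0 || max(p) > 255)
      msg <- c(msg, "RGB samples must lie in [0, 255]")
    if (max(abs(p - round(p))) > 1e-8)
      msg <- c(msg, "RGB samples must be 8-bit integer values")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an UltrasoundImage
#'
#' @param pixels numeric array `height x width x channels` (a plain matrix is
#'   treated as a single-channel raster). RGB rasters must hold 8-bit
#'   integer values in \[0, 255\].
#' @param colorspace `"RGB"` (default) or `"Lab"`.
#' @param sourcePath optional file path recorded as provenance.
#' @return An [UltrasoundImage-class] object.
#' @export
#' @examples
#' img <- ultrasoundImage(matrix(128, 10, 10))
#' dim(img)
ultrasoundImage <- function(pixels, colorspace = c("RGB", "Lab"),
                            sourcePath = NA_character_) {
  colorspace <- match.arg(colorspace)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  new("UltrasoundImage", pixels = pixels, colorspace = colorspace,
      sourcePath = as.character(sourcePath))
}

#' @describeIn ultrasoundImage dimensions `c(height, width, channels)`.
#' @param x an `UltrasoundImage`.
#' @export
setMethod("dim", "UltrasoundImage", function(x) dim(x@pixels))

setMethod("show", "UltrasoundImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("UltrasoundImage: %d x %d, %d channel(s), %s\n",
              d[1L], d[2L], d[3L], object@colorspace))
  if (!is.na(object@sourcePath))
    cat("  source:", object@sourcePath, "\n")
})

## ---------------------------------------------------------------------------
## RegionSpec
## ---------------------------------------------------------------------------

#' RegionSpec: a rectangular region of interest
#'
#' Pixel bounds of a manually chosen region of interest, as 1-based closed
#' intervals (`rowStart:rowEnd` by `colStart:colEnd`), the native R
#' convention.
#'
#' @slot rowStart,rowEnd,colStart,colEnd integer bounds,
#'   `1 <= rowStart <= rowEnd` and `1 <= colStart <= colEnd`.
#' @aliases RegionSpec
#' @exportClass RegionSpec
setClass("RegionSpec",
  representation(rowStart = "integer", rowEnd = "integer",
                 colStart = "integer", colEnd = "integer"))

setValidity("RegionSpec", function(object) {
  b <- c(object@rowStart, object@rowEnd, object@colStart, object@colEnd)
  if (length(b) != 4L || anyNA(b))
    return("all four bounds must be single non-missing integers")
  if (object@rowStart < 1L || object@colStart < 1L)
    return("region bounds are 1-based: starts must be >= 1")
  if (object@rowEnd < object@rowStart || object@colEnd < object@colStart)
    return("region must be non-empty: end bounds must be >= start bounds")
  TRUE
})

#' Construct a RegionSpec
#'
#' @param rowStart,rowEnd,colStart,colEnd 1-based inclusive pixel bounds.
#' @return A [RegionSpec-class] object.
#' @export
#' @examples
#' regionSpec(11, 20, 31, 50)  # a 10 x 20 region
regionSpec <- function(rowStart, rowEnd, colStart, colEnd) {
  new("RegionSpec", rowStart = as.integer(rowStart),
      rowEnd = as.integer(rowEnd), colStart = as.integer(colStart),
      colEnd = as.integer(colEnd))
}

setMethod("show", "RegionSpec", function(object) {
  cat(sprintf("RegionSpec: rows %d..%d, cols %d..%d (%d x %d)\n",
              object@rowStart, object@rowEnd, object@colStart, object@colEnd,
              object@rowEnd - object@rowStart + 1L,
              object@colEnd - object@colStart + 1L))
})

## ---------------------------------------------------------------------------
## ThresholdSet
## ---------------------------------------------------------------------------

#' ThresholdSet: clinical Delta E category bounds
#'
#' The two Delta E bounds separating the grades: values below `tIntensive`
#' are Intensive, values above `tNormal` are Normal, everything in between
#' (both boundaries included) is Moderate. Defaults 10 and 40 are the
#' clinically established bounds.
#'
#' @slot tIntensive upper Delta E bound of the Intensive grade (default 10).
#' @slot tNormal lower Delta E bound of the Normal grade (default 40).
#' @aliases ThresholdSet
#' @exportClass ThresholdSet
setClass("ThresholdSet",
  representation(tIntensive = "numeric", tNormal = "numeric"),
  prototype(tIntensive = 10, tNormal = 40))

setValidity("ThresholdSet", function(object) {
  if (length(object@tIntensive) != 1L || length(object@tNormal) != 1L ||
      !is.finite(object@tIntensive) || !is.finite(object@tNormal))
    return("thresholds must be single finite numbers")
  if (!(0 < object@tIntensive && object@tIntensive < object@tNormal))
    return("thresholds must satisfy 0 < tIntensive < tNormal")
  TRUE
})

#' Construct a ThresholdSet
#'
#' @param tIntensive,tNormal Delta E bounds, `0 < tIntensive < tNormal`.
#' @return A [ThresholdSet-class] object.
#' @export
#' @examples
#' thresholdSet()          # clinical defaults 10 / 40
thresholdSet <- function(tIntensive = 10, tNormal = 40) {
  new("ThresholdSet", tIntensive = as.numeric(tIntensive),
      tNormal = as.numeric(tNormal))
}

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf(
    "ThresholdSet: Intensive < %g <= Moderate <= %g < Normal\n",
    object@tIntensive, object@tNormal))
})

## ---------------------------------------------------------------------------
## LabSummary
## ---------------------------------------------------------------------------

#' LabSummary: region-mean CIE Lab coordinates
#'
#' The triple of channel means over a region of interest, plus the pixel
#' count. For achromatic (gray) ultrasound content the a* and b* means are
#' numerically zero.
#'
#' @slot LMean mean lightness L* (0-100).
#' @slot aMean mean red-green opponent a*.
#' @slot bMean mean blue-yellow opponent b*.
#' @slot nPixels number of pixels averaged, >= 1.
#' @aliases LabSummary
#' @exportClass LabSummary
setClass("LabSummary",
  representation(LMean = "numeric", aMean = "numeric", bMean = "numeric",
                 nPixels = "integer"))

setValidity("LabSummary", function(object) {
  v <- c(object@LMean, object@aMean, object@bMean)
  if (length(v) != 3L || any(!is.finite(v)))
    return("channel means must be single finite numbers")
  if (length(object@nPixels) != 1L || is.na(object@nPixels) ||
      object@nPixels < 1L)
    return("nPixels must be >= 1")
  TRUE
})

#' Construct a LabSummary
#'
#' @param LMean,aMean,bMean channel means.
#' @param nPixels pixel count the means were taken over.
#' @return A [LabSummary-class] object.
#' @export
#' @examples
#' labSummary(50, 0, 0, 100)
labSummary <- function(LMean, aMean, bMean, nPixels = 1L) {
  new("LabSummary", LMean = as.numeric(LMean), aMean = as.numeric(aMean),
      bMean = as.numeric(bMean), nPixels = as.integer(nPixels))
}

setMethod("show", "LabSummary", function(object) {
  cat(sprintf("LabSummary: L*=%.3f a*=%.3f b*=%.3f (n=%d pixels)\n",
              object@LMean, object@aMean, object@bMean, object@nPixels))
})

## ---------------------------------------------------------------------------
## DensityAssessment
## ---------------------------------------------------------------------------

#' DensityAssessment: Delta E score and assigned grade for one image
#'
#' Result of comparing the parenchyma and plexus regions of one image:
#' the CIE76 Delta E between the two region-mean Lab summaries, the grade
#' it maps to under the thresholds, and all intermediates.
#'
#' @slot deltaE nonnegative Delta E (CIE76) between the two region summaries.
#' @slot grade factor with levels [gradeLevels()].
#' @slot parenchyma,plexus the two [LabSummary-class] objects.
#' @slot thresholds the [ThresholdSet-class] used.
#' @aliases DensityAssessment
#' @exportClass DensityAssessment
setClass("DensityAssessment",
  representation(deltaE = "numeric", grade = "factor",
                 parenchyma = "LabSummary", plexus = "LabSummary",
                 thresholds = "ThresholdSet"))

setValidity("DensityAssessment", function(object) {
  if (length(object@deltaE) != 1L || !is.finite(object@deltaE) ||
      object@deltaE < 0)
    return("deltaE must be a single nonnegative finite number")
  if (!identical(levels(object@grade), gradeLevels()))
    return("grade must be a factor with levels Normal/Moderate/Intensive")
  want <- categorizeDeltaE(object@deltaE, object@thresholds)
  if (!identical(as.character(want), as.character(object@grade)))
    return("grade is inconsistent with deltaE under the thresholds")
  TRUE
})

setMethod("show", "DensityAssessment", function(object) {
  cat(sprintf("DensityAssessment: deltaE = %.3f -> %s\n",
              object@deltaE, as.character(object@grade)))
  cat(sprintf("  parenchyma: L*=%.2f a*=%.2f b*=%.2f (n=%d)\n",
              object@parenchyma@LMean, object@parenchyma@aMean,
              object@parenchyma@bMean, object@parenchyma@nPixels))
  cat(sprintf("  plexus:     L*=%.2f a*=%.2f b*=%.2f (n=%d)\n",
              object@plexus@LMean, object@plexus@aMean,
              object@plexus@bMean, object@plexus@nPixels))
  cat(sprintf("  thresholds: %g / %g\n", object@thresholds@tIntensive,
              object@thresholds@tNormal))
})

## ---------------------------------------------------------------------------
## CompositeDataset
## ---------------------------------------------------------------------------

#' CompositeDataset: labeled composite images for the classifier
#'
#' A stack of two-region composite images with class labels and a
#' per-sample manifest (provenance, realized Delta E for phantoms, split
#' assignments and the like).
#'
#' @slot pixels numeric array `height x width x channels x n`, 8-bit values.
#' @slot labels factor of length `n` with levels [gradeLevels()].
#' @slot manifest data.frame with one row per sample.
#' @aliases CompositeDataset
#' @exportClass CompositeDataset
setClass("CompositeDataset",
  representation(pixels = "array", labels = "factor",
                 manifest = "data.frame"))

setValidity("CompositeDataset", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 4L)
    return("pixels must be a height x width x channels x n array")
  if (length(object@labels) != d[4L])
    return("labels length must equal the number of samples")
  if (!identical(levels(object@labels), gradeLevels()))
    return("labels must use levels Normal/Moderate/Intensive")
  if (nrow(object@manifest) != d[4L])
    return("manifest must have one row per sample")
  TRUE
})

#' Number of samples in a CompositeDataset
#' @param x a [CompositeDataset-class].
#' @return Integer sample count.
#' @export
setMethod("length", "CompositeDataset", function(x) dim(x@pixels)[4L])

#' Subset a CompositeDataset by sample index
#' @param x a [CompositeDataset-class].
#' @param i integer or logical sample index.
#' @param j,...,drop ignored.
#' @return The subsetted [CompositeDataset-class].
#' @export
setMethod("[", "CompositeDataset", function(x, i, j, ..., drop = FALSE) {
  new("CompositeDataset",
      pixels = x@pixels[, , , i, drop = FALSE],
      labels = x@labels[i],
      manifest = x@manifest[i, , drop = FALSE])
})

setMethod("show", "CompositeDataset", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CompositeDataset: %d samples of %d x %d x %d\n",
              d[4L], d[1L], d[2L], d[3L]))
  print(table(object@labels))
})

## ---------------------------------------------------------------------------
## Network configuration and model
## ---------------------------------------------------------------------------

#' NetworkConfig: architecture of the composite-image classifier
#'
#' Describes the compact CNN: repeated blocks of same-padded 3x3
#' convolution, batch normalization and ReLU, with 2x2 stride-2 max
#' pooling after every block except the last, followed by a fully
#' connected softmax classifier. With the default four blocks of
#' 16/32/64/128 channels on 100x100x3 input, the spatial sides after the
#' successive pools are 50, 25 and 12 (floor division).
#'
#' @slot inputHeight,inputWidth,inputChannels input dimensions
#'   (default 100, 100, 3).
#' @slot blockChannels integer vector of per-block output channels
#'   (default 16, 32, 64, 128).
#' @slot kernelSize odd convolution kernel side (default 3).
#' @slot nClasses number of output classes (default 3).
#' @aliases NetworkConfig
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(inputHeight = "integer", inputWidth = "integer",
                 inputChannels = "integer", blockChannels = "integer",
                 kernelSize = "integer", nClasses = "integer"),
  prototype(inputHeight = 100L, inputWidth = 100L, inputChannels = 3L,
            blockChannels = c(16L, 32L, 64L, 128L), kernelSize = 3L,
            nClasses = 3L))

setValidity("NetworkConfig", function(object) {
  if (object@inputHeight < 4L || object@inputWidth < 4L)
    return("input must be at least 4 x 4")
  if (!object@inputChannels %in% c(1L, 3L))
    return("inputChannels must be 1 or 3")
  if (length(object@blockChannels) < 1L || any(object@blockChannels < 1L))
    return("blockChannels must be a nonempty positive integer vector")
  if (object@kernelSize < 1L || object@kernelSize %% 2L == 0L)
    return("kernelSize must be odd (same padding)")
  if (object@nClasses < 2L)
    return("nClasses must be >= 2")
  np <- length(object@blockChannels) - 1L
  if (min(object@inputHeight, object@inputWidth) %/% 2L^np < 1L)
    return("too many pooling stages for the input size")
  TRUE
})

#' Construct a NetworkConfig
#'
#' @param inputHeight,inputWidth,inputChannels input raster dimensions.
#' @param blockChannels per-block channel counts; one conv/batch-norm/ReLU
#'   block per entry, max-pooled after every block but the last.
#' @param kernelSize odd convolution kernel side.
#' @param nClasses number of classes.
#' @return A [NetworkConfig-class] object.
#' @export
#' @examples
#' networkConfig()
networkConfig <- function(inputHeight = 100, inputWidth = 100,
                          inputChannels = 3,
                          blockChannels = c(16, 32, 64, 128),
                          kernelSize = 3, nClasses = 3) {
  new("NetworkConfig", inputHeight = as.integer(inputHeight),
      inputWidth = as.integer(inputWidth),
      inputChannels = as.integer(inputChannels),
      blockChannels = as.integer(blockChannels),
      kernelSize = as.integer(kernelSize), nClasses = as.integer(nClasses))
}

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:\n")
  print(layerShapes(object), row.names = FALSE)
})

#' TrainingConfig: optimizer and protocol settings
#'
#' RMSProp settings, stopping epoch, batch size and the
#' train/validation/test split fractions. The 0.70/0.15/0.15 split and the
#' 200-epoch cap follow the method's evaluation protocol; learning rate,
#' decay, epsilon and batch size are conventional defaults and
#' configurable.
#'
#' @slot learningRate RMSProp step size (default 1e-3).
#' @slot decay squared-gradient smoothing factor (default 0.9).
#' @slot epsilon numerical stabilizer (default 1e-8).
#' @slot maxEpochs stopping epoch (default 200).
#' @slot batchSize minibatch size (default 16).
#' @slot splitFractions train/validation/test fractions summing to 1
#'   (default 0.70, 0.15, 0.15).
#' @slot seed integer seed driving shuffling and weight initialization.
#' @aliases TrainingConfig
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(learningRate = "numeric", decay = "numeric",
                 epsilon = "numeric", maxEpochs = "integer",
                 batchSize = "integer", splitFractions = "numeric",
                 seed = "integer"),
  prototype(learningRate = 1e-3, decay = 0.9, epsilon = 1e-8,
            maxEpochs = 200L, batchSize = 16L,
            splitFractions = c(0.70, 0.15, 0.15), seed = 1L))

setValidity("TrainingConfig", function(object) {
  if (object@learningRate < 0)
    return("learningRate must be >= 0")
  if (object@decay < 0 || object@decay >= 1)
    return("decay must lie in [0, 1)")
  if (object@epsilon <= 0)
    return("epsilon must be > 0")
  if (object@maxEpochs < 1L)
    return("maxEpochs must be >= 1")
  if (object@batchSize < 1L)
    return("batchSize must be >= 1")
  f <- object@splitFractions
  if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    return("splitFractions must be three nonnegative numbers summing to 1")
  TRUE
})

#' Construct a TrainingConfig
#'
#' @param learningRate,decay,epsilon RMSProp hyperparameters.
#' @param maxEpochs stopping epoch.
#' @param batchSize minibatch size.
#' @param splitFractions train/validation/test fractions (sum to 1).
#' @param seed integer seed for shuffling and initialization.
#' @return A [TrainingConfig-class] object.
#' @export
#' @examples
#' trainingConfig(maxEpochs = 10, seed = 7)
trainingConfig <- function(learningRate = 1e-3, decay = 0.9, epsilon = 1e-8,
                           maxEpochs = 200, batchSize = 16,
                           splitFractions = c(0.70, 0.15, 0.15), seed = 1) {
  new("TrainingConfig", learningRate = as.numeric(learningRate),
      decay = as.numeric(decay), epsilon = as.numeric(epsilon),
      maxEpochs = as.integer(maxEpochs), batchSize = as.integer(batchSize),
      splitFractions = as.numeric(splitFractions), seed = as.integer(seed))
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf(paste0(
    "TrainingConfig: RMSProp(lr=%g, decay=%g, eps=%g), ",
    "<=%d epochs, batch %d, split %.2f/%.2f/%.2f, seed %d\n"),
    object@learningRate, object@decay, object@epsilon, object@maxEpochs,
    object@batchSize, object@splitFractions[1L], object@splitFractions[2L],
    object@splitFractions[3L], object@seed))
})

#' TrainedModel: parameters, state and history of a fitted classifier
#'
#' @slot params named list of weight arrays (convolution kernels, biases,
#'   batch-norm scales/offsets, fully connected weights).
#' @slot state named list of batch-norm running means/variances used at
#'   inference time.
#' @slot config the [NetworkConfig-class].
#' @slot history data.frame of per-epoch training/validation loss and
#'   accuracy.
#' @slot trained logical; `FALSE` for a freshly initialized network.
#' @aliases TrainedModel
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(params = "list", state = "list", config = "NetworkConfig",
                 history = "data.frame", trained = "logical"),
  prototype(trained = FALSE))

setMethod("show", "TrainedModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1L)))
  cat(sprintf("TrainedModel: %s, %d parameters, %s\n",
              paste(object@config@blockChannels, collapse = "/"),
              np,
              if (object@trained)
                sprintf("trained %d epochs", nrow(object@history))
              else "untrained"))
})

## ---------------------------------------------------------------------------
## PhantomConfig
## ---------------------------------------------------------------------------

#' PhantomConfig: speckle phantom generator settings
#'
#' Controls the synthetic neurosonogram ROI pairs: one bright
#' choroid-plexus-like patch at fixed mean lightness, and a parenchyma
#' patch whose mean lightness is offset so the realized Delta E falls in
#' the grade's target band (Normal 50, Moderate 25, Intensive 5, each
#' jittered). Texture is multiplicative gamma speckle (mean 1) followed by
#' Gaussian blur; patches are achromatic so Delta E is carried by the L*
#' channel alone.
#'
#' @slot patchHeight,patchWidth patch size in pixels (default 100 x 100).
#' @slot deltaETargets named numeric, target mean Delta E per grade
#'   (default Normal 50, Moderate 25, Intensive 5).
#' @slot jitterSD sd of the per-sample jitter on the Delta E target
#'   (default 2).
#' @slot plexusL mean lightness of the plexus reference patch (default 75).
#' @slot speckleShape gamma shape of the multiplicative speckle; larger is
#'   smoother (default 60, relative sd about 0.13).
#' @slot blurSigma Gaussian blur sd in pixels (default 1).
#' @aliases PhantomConfig
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(patchHeight = "integer", patchWidth = "integer",
                 deltaETargets = "numeric", jitterSD = "numeric",
                 plexusL = "numeric", speckleShape = "numeric",
                 blurSigma = "numeric"),
  prototype(patchHeight = 100L, patchWidth = 100L,
            deltaETargets = c(Normal = 50, Moderate = 25, Intensive = 5),
            jitterSD = 2, plexusL = 75, speckleShape = 60, blurSigma = 1))

setValidity("PhantomConfig", function(object) {
  if (object@patchHeight < 2L || object@patchWidth < 2L)
    return("patches must be at least 2 x 2")
  t <- object@deltaETargets
  if (!identical(sort(names(t)), sort(gradeLevels())))
    return("deltaETargets must be named Normal/Moderate/Intensive")
  if (!(t[["Intensive"]] < t[["Moderate"]] && t[["Moderate"]] < t[["Normal"]]))
    return("targets must be ordered Intensive < Moderate < Normal")
  if (object@jitterSD < 0)
    return("jitterSD must be >= 0")
  j <- 2 * object@jitterSD
  if (t[["Intensive"]] + j >= t[["Moderate"]] - j ||
      t[["Moderate"]] + j >= t[["Normal"]] - j)
    return("grade bands overlap: targets must be separated by > 4 * jitterSD")
  if (object@plexusL <= max(t) || object@plexusL > 95)
    return("plexusL must exceed the largest Delta E target and be <= 95")
  if (object@speckleShape <= 0)
    return("speckleShape must be > 0")
  if (object@blurSigma < 0)
    return("blurSigma must be >= 0")
  TRUE
})

#' Construct a PhantomConfig
#'
#' @param patchHeight,patchWidth patch size in pixels.
#' @param deltaETargets named per-grade target mean Delta E.
#' @param jitterSD per-sample jitter sd on the target.
#' @param plexusL mean lightness of the plexus reference patch.
#' @param speckleShape gamma shape of the multiplicative speckle.
#' @param blurSigma Gaussian blur sd in pixels.
#' @return A [PhantomConfig-class] object.
#' @export
#' @examples
#' phantomConfig()
phantomConfig <- function(patchHeight = 100, patchWidth = 100,
                          deltaETargets = c(Normal = 50, Moderate = 25,
                                            Intensive = 5),
                          jitterSD = 2, plexusL = 75, speckleShape = 60,
                          blurSigma = 1) {
  new("PhantomConfig", patchHeight = as.integer(patchHeight),
      patchWidth = as.integer(patchWidth),
      deltaETargets = deltaETargets[gradeLevels()],
      jitterSD = as.numeric(jitterSD), plexusL = as.numeric(plexusL),
      speckleShape = as.numeric(speckleShape),
      blurSigma = as.numeric(blurSigma))
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(paste0(
    "PhantomConfig: %d x %d patches, targets N=%g/M=%g/I=%g (jitter sd %g),\n",
    "  plexus L*=%g, speckle shape %g, blur sigma %g\n"),
    object@patchHeight, object@patchWidth,
    object@deltaETargets[["Normal"]], object@deltaETargets[["Moderate"]],
    object@deltaETargets[["Intensive"]], object@jitterSD, object@plexusL,
    object@speckleShape, object@blurSigma))
})

## ---------------------------------------------------------------------------
## EvaluationReport
## ---------------------------------------------------------------------------

#' EvaluationReport: confusion matrix and one-vs-rest metric suite
#'
#' @slot confusion K x K integer matrix, rows = true class, columns =
#'   predicted class.
#' @slot perClass data.frame of per-class sensitivity, specificity,
#'   precision, accuracy, F-measure (and AUC when probabilities were
#'   supplied), as proportions in \[0, 1\].
#' @slot overall named numeric of unweighted macro means of the per-class
#'   metrics.
#' @aliases EvaluationReport
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 overall = "numeric"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n\nConfusion matrix (rows = truth):\n")
  print(object@confusion)
  cat("\nPer-class metrics (%):\n")
  print(round(object@perClass * 100, 2))
  cat("\nOverall (macro, %):\n")
  print(round(object@overall * 100, 2))
})
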