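## Stage one of the grading pipeline: CIE Lab conversion, ROI cropping,
## channel means, Delta E CIE76 and threshold categorization.

#' Convert an RGB ultrasound image to CIE Lab
#'
#' Converts an 8-bit RGB (or grayscale, replicated to three channels)
#' raster to CIE 1976 L*a*b* assuming sRGB primaries and the D65 reference
#' white. Lab separates lightness from the chromatic axes, so echogenicity
#' comparisons are carried by L* and are insensitive to chromatic overlays.
#'
#' @param img an [UltrasoundImage-class] with `colorspace == "RGB"`.
#' @return An [UltrasoundImage-class] with `colorspace == "Lab"`; the L*
#'   channel lies in \[0, 100\], and achromatic input maps to a* = b* = 0.
#' @export
#' @examples
#' img <- ultrasoundImage(array(255, c(2, 2, 3)))
#' labMeans(channelMeans(rgbToLab(img)))  # sRGB white -> L* = 100
rgbToLab <- function(img) {
  stopifnot(is(img, "UltrasoundImage"))
  if (!identical(img@colorspace, "RGB"))
    stop("rgbToLab() expects an RGB image")
  p <- img@pixels
  if (max(abs(p - round(p))) > 1e-8 || max(p) > 255 || min(p) < 0)
    stop("input depth error: pixel samples must be 8-bit integers in [0, 255]")
  d <- dim(p)
  if (d[3L] == 1L) {
    p <- array(p, c(d[1L], d[2L], 3L))  # replicate gray to three channels
    d <- dim(p)
  }
  m <- matrix(p, ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  new("UltrasoundImage", pixels = array(lab, d), colorspace = "Lab",
      sourcePath = img@sourcePath)
}

#' Crop a region of interest out of an image
#'
#' Extracts the rectangular sub-raster given by a [RegionSpec-class]
#' (1-based inclusive bounds). Pixel values are copied unchanged.
#'
#' @param img an [UltrasoundImage-class] (any colorspace).
#' @param region a [RegionSpec-class] lying within the image bounds.
#' @return The cropped [UltrasoundImage-class].
#' @export
#' @examples
#' img <- ultrasoundImage(matrix(0:99, 10, 10))
#' dim(cropRegion(img, regionSpec(2, 4, 1, 10)))  # 3 x 10 x 1
cropRegion <- function(img, region) {
  stopifnot(is(img, "UltrasoundImage"), is(region, "RegionSpec"))
  d <- dim(img@pixels)
  if (region@rowEnd > d[1L] || region@colEnd > d[2L])
    stop(sprintf("region bounds error: rows %d..%d, cols %d..%d exceed %d x %d",
                 region@rowStart, region@rowEnd, region@colStart,
                 region@colEnd, d[1L], d[2L]))
  new("UltrasoundImage",
      pixels = img@pixels[region@rowStart:region@rowEnd,
                          region@colStart:region@colEnd, , drop = FALSE],
      colorspace = img@colorspace, sourcePath = img@sourcePath)
}

#' Region-mean Lab channels
#'
#' Averages each Lab channel over all pixels of a (typically cropped)
#' Lab image: the sum of the channel over the region divided by the pixel
#' count.
#'
#' @param labImg an [UltrasoundImage-class] with `colorspace == "Lab"`.
#' @return A [LabSummary-class] holding the three channel means and the
#'   pixel count.
#' @export
#' @examples
#' lab <- rgbToLab(ultrasoundImage(matrix(128, 4, 4)))
#' channelMeans(lab)
channelMeans <- function(labImg) {
  stopifnot(is(labImg, "UltrasoundImage"))
  if (!identical(labImg@colorspace, "Lab"))
    stop("channelMeans() expects a Lab image; call rgbToLab() first")
  d <- dim(labImg@pixels)
  if (d[3L] != 3L)
    stop("Lab image must have three channels")
  m <- colMeans(matrix(labImg@pixels, ncol = 3L))
  labSummary(m[1L], m[2L], m[3L], d[1L] * d[2L])
}

#' Delta E (CIE76) between two region summaries
#'
#' The Euclidean distance between two points in CIE Lab space,
#' `sqrt(dL^2 + da^2 + db^2)`, computed between the region-mean triples
#' (means first, then distance). This is the echogenicity-difference
#' score: large when the parenchyma is much darker than the plexus
#' reference, near zero when the two regions are equally echogenic.
#'
#' @param object,other two [LabSummary-class] objects.
#' @param ... unused.
#' @return Single nonnegative number; symmetric in its arguments.
#' @export
#' @examples
#' deltaE(labSummary(50, 0, 0), labSummary(53, 4, 0))  # 3-4-5 triangle -> 5
setMethod("deltaE", "LabSummary", function(object, other, ...) {
  stopifnot(is(other, "LabSummary"))
  sqrt((object@LMean - other@LMean)^2 +
       (object@aMean - other@aMean)^2 +
       (object@bMean - other@bMean)^2)
})

#' Categorize a Delta E score into an injury grade
#'
#' Applies the clinical thresholds: `Intensive` if `deltaE < tIntensive`,
#' `Normal` if `deltaE > tNormal`, otherwise `Moderate`. Both boundary
#' values map to Moderate, so the three grades partition `[0, Inf)`.
#'
#' @param deltaE numeric vector of nonnegative Delta E scores.
#' @param thresholds a [ThresholdSet-class] (defaults 10 / 40).
#' @return Factor with levels [gradeLevels()], same length as `deltaE`.
#' @export
#' @examples
#' categorizeDeltaE(c(5, 25, 45))  # Intensive, Moderate, Normal
categorizeDeltaE <- function(deltaE, thresholds = thresholdSet()) {
  stopifnot(is(thresholds, "ThresholdSet"))
  validObject(thresholds)
  if (any(!is.finite(deltaE)) || any(deltaE < 0))
    stop("deltaE must be finite and nonnegative")
  out <- ifelse(deltaE < thresholds@tIntensive, "Intensive",
         ifelse(deltaE > thresholds@tNormal, "Normal", "Moderate"))
  .gradeFactor(out)
}

#' Score one image: Delta E between parenchyma and plexus ROIs
#'
#' The full stage-one pipeline for one image: convert to Lab, crop the
#' parenchyma and plexus regions, average the channels of each, take the
#' CIE76 distance between the two mean triples, and assign the grade.
#' All intermediates are recorded in the returned assessment.
#'
#' @param img an RGB [UltrasoundImage-class] (a Lab image is accepted
#'   as-is).
#' @param roiParenchyma,roiPlexus [RegionSpec-class] objects for the
#'   brain-parenchyma and choroid-plexus regions.
#' @param thresholds a [ThresholdSet-class] (defaults 10 / 40).
#' @return A [DensityAssessment-class].
#' @export
#' @examples
#' img <- ultrasoundImage(matrix(120, 20, 20))
#' a <- assessDensity(img, regionSpec(1, 10, 1, 20), regionSpec(11, 20, 1, 20))
#' deltaE(a); grade(a)  # identical regions -> 0, Intensive
assessDensity <- function(img, roiParenchyma, roiPlexus,
                          thresholds = thresholdSet()) {
  stopifnot(is(img, "UltrasoundImage"))
  lab <- if (identical(img@colorspace, "Lab")) img else rgbToLab(img)
  sPar <- channelMeans(cropRegion(lab, roiParenchyma))
  sPlex <- channelMeans(cropRegion(lab, roiPlexus))
  dE <- deltaE(sPar, sPlex)
  new("DensityAssessment", deltaE = dE,
      grade = categorizeDeltaE(dE, thresholds),
      parenchyma = sPar, plexus = sPlex, thresholds = thresholds)
}
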