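## Composite construction: the two ROIs are standardized to a common patch
## size, stacked parenchyma-over-plexus into a 200 x 100 raw composite, and
## resized to the network input size.

#' Bilinear image resize
#'
#' Resamples a raster to `P x Q` pixels by bilinear interpolation on a
#' half-pixel-center grid (output pixel centers are placed uniformly inside
#' the input extent), without anti-aliasing, so results are bit-stable and
#' resizing an image to its own size is the identity. 8-bit inputs give
#' 8-bit outputs (rounded); Lab inputs stay real-valued.
#'
#' @param img an [UltrasoundImage-class].
#' @param P,Q target height and width, both >= 1.
#' @return The resized [UltrasoundImage-class].
#' @export
#' @examples
#' img <- ultrasoundImage(matrix(rep(7, 16), 4, 4))
#' pixels(resizeImage(img, 2, 2))[, , 1]  # constants stay constant
resizeImage <- function(img, P, Q) {
  stopifnot(is(img, "UltrasoundImage"))
  P <- as.integer(P); Q <- as.integer(Q)
  if (is.na(P) || is.na(Q) || P < 1L || Q < 1L)
    stop("target dimensions must be positive")
  d <- dim(img@pixels)
  out <- array(0, c(P, Q, d[3L]))
  ## sample coordinates of output pixel centers in input pixel units
  sr <- (seq_len(P) - 0.5) * d[1L] / P + 0.5
  sc <- (seq_len(Q) - 0.5) * d[2L] / Q + 0.5
  r0 <- pmin(pmax(floor(sr), 1L), d[1L]); r1 <- pmin(r0 + 1L, d[1L])
  c0 <- pmin(pmax(floor(sc), 1L), d[2L]); c1 <- pmin(c0 + 1L, d[2L])
  wr <- pmin(pmax(sr - r0, 0), 1); wc <- pmin(pmax(sc - c0, 0), 1)
  WR <- matrix(wr, P, Q); WC <- matrix(wc, P, Q, byrow = TRUE)
  for (ch in seq_len(d[3L])) {
    x <- img@pixels[, , ch]
    out[, , ch] <-
      (1 - WR) * (1 - WC) * x[r0, c0, drop = FALSE] +
      WR * (1 - WC) * x[r1, c0, drop = FALSE] +
      (1 - WR) * WC * x[r0, c1, drop = FALSE] +
      WR * WC * x[r1, c1, drop = FALSE]
  }
  if (identical(img@colorspace, "RGB"))
    out <- round(pmin(pmax(out, 0), 255))
  new("UltrasoundImage", pixels = out, colorspace = img@colorspace,
      sourcePath = img@sourcePath)
}

#' Concatenate two patches into one composite raster
#'
#' Joins two patches along the row axis (one above the other) or the
#' column axis (side by side). No resampling happens at this step: each
#' half of the output is a verbatim copy of its source patch, so the
#' total intensity of the composite is the sum of the patch intensities.
#'
#' @param patchA,patchB [UltrasoundImage-class] objects sharing the
#'   non-concatenated dimension, channel count and colorspace. `patchA`
#'   comes first (top, or left).
#' @param axis `"rows"` (default, stacked vertically) or `"cols"`.
#' @return The concatenated [UltrasoundImage-class].
#' @export
#' @examples
#' a <- ultrasoundImage(matrix(0, 100, 100))
#' b <- ultrasoundImage(matrix(255, 100, 100))
#' dim(concatPatches(a, b))  # 200 x 100 x 1
concatPatches <- function(patchA, patchB, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  stopifnot(is(patchA, "UltrasoundImage"), is(patchB, "UltrasoundImage"))
  if (!identical(patchA@colorspace, patchB@colorspace))
    stop("patches must share a colorspace")
  da <- dim(patchA@pixels); db <- dim(patchB@pixels)
  if (da[3L] != db[3L])
    stop("shape error: patches must share the channel count")
  shared <- if (axis == "rows") 2L else 1L
  if (da[shared] != db[shared])
    stop(sprintf("shape error: patches differ along the %s axis (%d vs %d)",
                 if (axis == "rows") "column" else "row",
                 da[shared], db[shared]))
  px <- if (axis == "rows") {
    out <- array(0, c(da[1L] + db[1L], da[2L], da[3L]))
    out[seq_len(da[1L]), , ] <- patchA@pixels
    out[da[1L] + seq_len(db[1L]), , ] <- patchB@pixels
    out
  } else {
    out <- array(0, c(da[1L], da[2L] + db[2L], da[3L]))
    out[, seq_len(da[2L]), ] <- patchA@pixels
    out[, da[2L] + seq_len(db[2L]), ] <- patchB@pixels
    out
  }
  new("UltrasoundImage", pixels = px, colorspace = patchA@colorspace,
      sourcePath = NA_character_)
}

.ensureThreeChannels <- function(img) {
  d <- dim(img@pixels)
  if (d[3L] == 3L) return(img)
  new("UltrasoundImage", pixels = array(img@pixels, c(d[1L], d[2L], 3L)),
      colorspace = img@colorspace, sourcePath = img@sourcePath)
}

#' Build a classifier-ready composite from two patches
#'
#' Standardizes the parenchyma and plexus patches to `patchSize`, stacks
#' them parenchyma-on-top along the row axis (giving a raw composite twice
#' as tall as wide, 200 x 100 by default), then resizes the composite to
#' the network input size. Grayscale patches are replicated to three
#' channels. The whole construction is deterministic: identical inputs
#' give bit-identical composites.
#'
#' @param parenchyma,plexus [UltrasoundImage-class] RGB patches.
#' @param outHeight,outWidth network input size (default 100 x 100).
#' @param patchSize side to which each patch is standardized before
#'   stacking (default 100).
#' @return An [UltrasoundImage-class] of `outHeight x outWidth x 3`.
#' @export
#' @examples
#' a <- ultrasoundImage(matrix(40, 60, 80))
#' b <- ultrasoundImage(matrix(200, 50, 50))
#' dim(compositeFromPatches(a, b))  # 100 x 100 x 3
compositeFromPatches <- function(parenchyma, plexus, outHeight = 100,
                                 outWidth = 100, patchSize = 100) {
  a <- resizeImage(.ensureThreeChannels(parenchyma), patchSize, patchSize)
  b <- resizeImage(.ensureThreeChannels(plexus), patchSize, patchSize)
  raw <- concatPatches(a, b, axis = "rows")
  resizeImage(raw, outHeight, outWidth)
}

#' Build a labeled composite sample from one image and two ROIs
#'
#' Crops both regions out of the source image and hands them to
#' [compositeFromPatches()]: each ROI is standardized to `patchSize`,
#' stacked parenchyma first, and the stack is resized to the network
#' input.
#'
#' @param img an RGB [UltrasoundImage-class].
#' @param roiParenchyma,roiPlexus [RegionSpec-class] objects.
#' @param label optional grade label (one of [gradeLevels()]).
#' @param outHeight,outWidth,patchSize as in [compositeFromPatches()].
#' @return A list with elements `composite` (the
#'   [UltrasoundImage-class]), `label` (factor or `NA`) and `provenance`
#'   (source path plus ROI bounds).
#' @export
makeCompositeSample <- function(img, roiParenchyma, roiPlexus, label = NA,
                                outHeight = 100, outWidth = 100,
                                patchSize = 100) {
  comp <- compositeFromPatches(cropRegion(img, roiParenchyma),
                               cropRegion(img, roiPlexus),
                               outHeight, outWidth, patchSize)
  if (!is.na(label) && !label %in% gradeLevels())
    stop("label must be one of ", paste(gradeLevels(), collapse = "/"))
  list(composite = comp,
       label = .gradeFactor(if (is.na(label)) NA else label),
       provenance = list(source = img@sourcePath,
                         roiParenchyma = roiParenchyma,
                         roiPlexus = roiPlexus))
}
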