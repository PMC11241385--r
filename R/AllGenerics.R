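#' Accessors for neosono classes
#'
#' Small accessor generics so that slot layout stays an implementation
#' detail: `pixels()` returns the raster array, `colorspace()` the color
#' space tag, `deltaE()` the echogenicity-difference score, `grade()` the
#' assigned category, `labMeans()` the named (L, a, b) mean triple,
#' `nPixels()` the pixel count behind a summary, `thresholds()` the
#' threshold set, `manifest()` the per-sample metadata of a dataset, and
#' `trainHistory()` the per-epoch training record of a model.
#'
#' @param object an object of the documented class.
#' @return The slot value described above.
#' @name accessors
#' @examples
#' deltaE(labSummary(50, 0, 0), labSummary(53, 4, 0))
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "UltrasoundImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "CompositeDataset", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("colorspace", function(object) standardGeneric("colorspace"))
#' @rdname accessors
#' @export
setMethod("colorspace", "UltrasoundImage", function(object) object@colorspace)

#' @rdname accessors
#' @export
setGeneric("deltaE", function(object, ...) standardGeneric("deltaE"))
#' @rdname accessors
#' @export
setMethod("deltaE", "DensityAssessment", function(object, ...) object@deltaE)

#' @rdname accessors
#' @export
setGeneric("grade", function(object) standardGeneric("grade"))
#' @rdname accessors
#' @export
setMethod("grade", "DensityAssessment", function(object) object@grade)

#' @rdname accessors
#' @export
setGeneric("labMeans", function(object) standardGeneric("labMeans"))
#' @rdname accessors
#' @export
setMethod("labMeans", "LabSummary", function(object)
  c(L = object@LMean, a = object@aMean, b = object@bMean))

#' @rdname accessors
#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))
#' @rdname accessors
#' @export
setMethod("nPixels", "LabSummary", function(object) object@nPixels)

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setMethod("thresholds", "DensityAssessment",
          function(object) object@thresholds)

#' @rdname accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setMethod("manifest", "CompositeDataset", function(object) object@manifest)

#' @rdname accessors
#' @param x a `CompositeDataset` (for `labels`).
#' @param ... unused.
#' @export
setMethod("labels", "CompositeDataset", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))
#' @rdname accessors
#' @export
setMethod("trainHistory", "TrainedModel", function(object) object@history)

#' @rdname accessors
#' @export
setGeneric("networkConfigOf",
           function(object) standardGeneric("networkConfigOf"))
#' @rdname accessors
#' @export
setMethod("networkConfigOf", "TrainedModel", function(object) object@config)
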