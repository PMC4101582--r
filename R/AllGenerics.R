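#' Accessor generics
#'
#' Standard accessors for the package's data containers.
#'
#' @param x an object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("spectraLabels", function(x) standardGeneric("spectraLabels"))

#' @rdname accessors
#' @export
setGeneric("spectraLabels<-",
           function(x, value) standardGeneric("spectraLabels<-"))

#' @rdname accessors
#' @export
setGeneric("detailMatrices", function(x) standardGeneric("detailMatrices"))

#' @rdname accessors
#' @export
setGeneric("approxMatrix", function(x) standardGeneric("approxMatrix"))

#' @rdname accessors
#' @export
setGeneric("metaData", function(x) standardGeneric("metaData"))

#' @rdname accessors
#' @export
setGeneric("explainedRatios", function(x) standardGeneric("explainedRatios"))

#' @name accessors
#' @aliases intensities,SpectraMatrix-method
#' @export
setMethod("intensities", "SpectraMatrix", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("mzValues", "SpectraMatrix", function(x) x@mz)

#' @rdname accessors
#' @export
setMethod("sampleIds", "SpectraMatrix", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("spectraLabels", "SpectraMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setReplaceMethod("spectraLabels", "SpectraMatrix", function(x, value) {
  x@labels <- as.character(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("detailMatrices", "WaveletDecomposition", function(x) x@details)

#' @rdname accessors
#' @export
setMethod("approxMatrix", "WaveletDecomposition", function(x) x@approx)

#' @rdname accessors
#' @export
setMethod("metaData", "DCAModel", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("explainedRatios", "DCAModel", function(x) x@rhoM)
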