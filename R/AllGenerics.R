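# Accessor generics for the result and phantom containers. Slots are never
# accessed with @ outside the package.

#' @rdname SegmentationResult-class
#' @param object,x An object.
#' @export
setGeneric("segMask", function(x) standardGeneric("segMask"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("levelSet", function(x) standardGeneric("levelSet"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("iterationCount", function(x) standardGeneric("iterationCount"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("iterationHistory", function(x) standardGeneric("iterationHistory"))

#' @rdname FourPhaseResult-class
#' @param x An object.
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname FourPhaseResult-class
#' @export
setGeneric("phaseMeans", function(x) standardGeneric("phaseMeans"))

#' @rdname FourPhaseResult-class
#' @export
setGeneric("phaseLegend", function(x) standardGeneric("phaseLegend"))

#' @rdname Phantom-class
#' @param x An object.
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname Phantom-class
#' @export
setGeneric("phantomTruth", function(x) standardGeneric("phantomTruth"))

#' @rdname Phantom-class
#' @export
setGeneric("phantomParams", function(x) standardGeneric("phantomParams"))

#' @rdname SegmentationResult-class
#' @export
setMethod("segMask", "SegmentationResult", function(x) x@mask)

#' @rdname SegmentationResult-class
#' @export
setMethod("levelSet", "SegmentationResult", function(x) x@phi)

#' @rdname SegmentationResult-class
#' @export
setMethod("iterationCount", "SegmentationResult", function(x) x@iterations)

#' @rdname SegmentationResult-class
#' @export
setMethod("isConverged", "SegmentationResult", function(x) x@converged)

#' @rdname SegmentationResult-class
#' @export
setMethod("iterationHistory", "SegmentationResult", function(x) x@history)

#' @rdname FourPhaseResult-class
#' @export
setMethod("labelMap", "FourPhaseResult", function(x) x@labels)

#' @rdname FourPhaseResult-class
#' @export
setMethod("levelSet", "FourPhaseResult", function(x) list(phi1 = x@phi1,
                                                          phi2 = x@phi2))

#' @rdname FourPhaseResult-class
#' @export
setMethod("iterationCount", "FourPhaseResult", function(x) x@iterations)

#' @rdname FourPhaseResult-class
#' @export
setMethod("isConverged", "FourPhaseResult", function(x) x@converged)

#' @rdname FourPhaseResult-class
#' @export
setMethod("iterationHistory", "FourPhaseResult", function(x) x@history)

#' @rdname FourPhaseResult-class
#' @export
setMethod("phaseMeans", "FourPhaseResult", function(x) x@means)

#' @rdname FourPhaseResult-class
#' @export
setMethod("phaseLegend", "FourPhaseResult", function(x) x@legend)

#' @rdname Phantom-class
#' @export
setMethod("phantomImage", "Phantom", function(x) x@image)

#' @rdname Phantom-class
#' @export
setMethod("phantomTruth", "Phantom", function(x) x@truth)

#' @rdname Phantom-class
#' @export
setMethod("phantomParams", "Phantom", function(x) x@spec)
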