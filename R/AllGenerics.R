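# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @name accessors
#' @title Accessors for hertzmap classes
#' @description Small accessor generics for the package's S4 containers.
#' @param object a hertzmap S4 object.
#' @return The requested component, in interface units (um, nm, nN, Pa).
NULL

#' @rdname accessors
#' @export
setGeneric("zPosition", function(object) standardGeneric("zPosition"))
#' @rdname accessors
#' @export
setGeneric("deflection", function(object) standardGeneric("deflection"))
#' @rdname accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
#' @rdname accessors
#' @export
setGeneric("probeRadius", function(object) standardGeneric("probeRadius"))
#' @rdname accessors
#' @export
setGeneric("springConstant", function(object) standardGeneric("springConstant"))
#' @rdname accessors
#' @export
setGeneric("curvePosition", function(object) standardGeneric("curvePosition"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("indentation", function(object) standardGeneric("indentation"))
#' @rdname accessors
#' @export
setGeneric("force", function(object) standardGeneric("force"))
#' @rdname accessors
#' @export
setGeneric("contactPoint", function(object) standardGeneric("contactPoint"))
#' @rdname accessors
#' @export
setGeneric("modulus", function(object) standardGeneric("modulus"))
#' @rdname accessors
#' @export
setGeneric("qcStatus", function(object) standardGeneric("qcStatus"))
#' @rdname accessors
#' @export
setGeneric("qcReason", function(object) standardGeneric("qcReason"))
#' @rdname accessors
#' @export
setGeneric("linearity", function(object) standardGeneric("linearity"))
#' @rdname accessors
#' @export
setGeneric("validityReport", function(object) standardGeneric("validityReport"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(object) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname accessors
#' @export
setMethod("zPosition", "ForceCurve", function(object) object@z)
#' @rdname accessors
#' @export
setMethod("deflection", "ForceCurve", function(object) object@d)
#' @rdname accessors
#' @export
setMethod("segmentLabels", "ForceCurve", function(object) object@segment)
#' @rdname accessors
#' @export
setMethod("probeRadius", "ForceCurve", function(object) object@probeRadius)
#' @rdname accessors
#' @export
setMethod("springConstant", "ForceCurve", function(object) object@springConstant)
#' @rdname accessors
#' @export
setMethod("curvePosition", "ForceCurve", function(object) object@position)
#' @rdname accessors
#' @export
setMethod("groundTruth", "ForceCurve", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setMethod("indentation", "IndentationCurve", function(object) object@delta)
#' @rdname accessors
#' @export
setMethod("force", "IndentationCurve", function(object) object@force)
#' @rdname accessors
#' @export
setMethod("contactPoint", "IndentationCurve", function(object) object@z0)
#' @rdname accessors
#' @export
setMethod("probeRadius", "IndentationCurve", function(object) object@probeRadius)
#' @rdname accessors
#' @export
setMethod("springConstant", "IndentationCurve",
          function(object) object@springConstant)
#' @rdname accessors
#' @export
setMethod("curvePosition", "IndentationCurve", function(object) object@position)
#' @rdname accessors
#' @export
setMethod("groundTruth", "IndentationCurve", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setMethod("springConstant", "CantileverCalibration", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("modulus", "HertzFit", function(object) object@Ea)
#' @rdname accessors
#' @export
setMethod("qcStatus", "HertzFit", function(object) object@qc)
#' @rdname accessors
#' @export
setMethod("qcReason", "HertzFit", function(object) object@qcReason)
#' @rdname accessors
#' @export
setMethod("linearity", "HertzFit", function(object) object@linearityR2)
#' @rdname accessors
#' @export
setMethod("validityReport", "HertzFit", function(object) object@validity)
#' @rdname accessors
#' @export
setMethod("curvePosition", "HertzFit", function(object) object@position)

#' @rdname accessors
#' @export
setMethod("mapValues", "StiffnessMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("cellSize", "StiffnessMap", function(object) object@cellSize)
#' @rdname accessors
#' @export
setMethod("qcReason", "StiffnessMap", function(object) object@qcReasons)

#' @rdname accessors
#' @export
setMethod("modulus", "SampleSummary", function(object) object@median)
#' @rdname accessors
#' @export
setMethod("modulus", "TissueSummary", function(object) object@meanOfMedians)

#' @rdname accessors
#' @export
setMethod("pValue", "GroupComparison", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("isSignificant", "GroupComparison", function(object) object@significant)
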