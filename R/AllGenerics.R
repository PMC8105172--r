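#' @rdname ReferenceSet-class
#' @param object,x a package object.
#' @export
setGeneric("referenceMode", function(object) standardGeneric("referenceMode"))

#' @rdname ReferenceSet-class
#' @export
setMethod("referenceMode", "ReferenceSet", function(object) object@mode)

#' @rdname ReferenceSet-class
#' @export
setGeneric("referenceLabels", function(object)
  standardGeneric("referenceLabels"))

#' @rdname ReferenceSet-class
#' @export
setMethod("referenceLabels", "ReferenceSet", function(object) object@labels)

#' @rdname PredictionSet-class
#' @export
setGeneric("methodName", function(object) standardGeneric("methodName"))

#' @rdname PredictionSet-class
#' @export
setMethod("methodName", "PredictionSet", function(object) object@methodName)

#' @rdname PredictionSet-class
#' @export
setGeneric("predictionScores", function(object)
  standardGeneric("predictionScores"))

#' @rdname PredictionSet-class
#' @export
setMethod("predictionScores", "PredictionSet", function(object) object@scores)

#' @rdname PredictionSet-class
#' @export
setGeneric("predictionStates", function(object)
  standardGeneric("predictionStates"))

#' @rdname PredictionSet-class
#' @export
setMethod("predictionStates", "PredictionSet", function(object) object@states)

#' @rdname PredictionSet-class
#' @export
setGeneric("effectiveThreshold", function(object)
  standardGeneric("effectiveThreshold"))

#' @rdname PredictionSet-class
#' @export
setMethod("effectiveThreshold", "PredictionSet",
          function(object) object@effectiveThreshold)

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("confusionCounts", function(object)
  standardGeneric("confusionCounts"))

#' @rdname ConfusionMatrix-class
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(object)
  c(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn,
    masked = object@masked))

#' @rdname CurveSet-class
#' @export
setGeneric("fMax", function(object) standardGeneric("fMax"))

#' @rdname CurveSet-class
#' @export
setMethod("fMax", "CurveSet", function(object) object@fMax)

#' @rdname CurveSet-class
#' @export
setGeneric("fMaxThreshold", function(object) standardGeneric("fMaxThreshold"))

#' @rdname CurveSet-class
#' @export
setMethod("fMaxThreshold", "CurveSet", function(object) object@fMaxThreshold)

#' @rdname CurveSet-class
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))

#' @rdname CurveSet-class
#' @export
setMethod("aucValue", "CurveSet", function(object) object@auc)

#' @rdname CurveSet-class
#' @export
setGeneric("curveTable", function(object) standardGeneric("curveTable"))

#' @rdname CurveSet-class
#' @export
setMethod("curveTable", "CurveSet", function(object) object@curve)

#' @rdname BootstrapResult-class
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))

#' @rdname BootstrapResult-class
#' @export
setMethod("confInt", "BootstrapResult", function(object)
  c(low = object@ciLow, high = object@ciHigh))

#' @rdname BootstrapResult-class
#' @export
setGeneric("replicateValues", function(object)
  standardGeneric("replicateValues"))

#' @rdname BootstrapResult-class
#' @export
setMethod("replicateValues", "BootstrapResult",
          function(object) object@replicates)

#' Number of targets in a set
#' @rdname ReferenceSet-class
#' @export
setMethod("length", "ReferenceSet", function(x) length(x@labels))

#' @rdname PredictionSet-class
#' @export
setMethod("length", "PredictionSet", function(x) length(x@scores))

#' @rdname ReferenceSet-class
#' @export
setMethod("names", "ReferenceSet", function(x) names(x@labels))

#' @rdname PredictionSet-class
#' @export
setMethod("names", "PredictionSet", function(x) names(x@scores))
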