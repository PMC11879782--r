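# Accessor generics and show methods for the core classes.

#' @rdname EEGRecording-class
#' @param object,x an object of the documented class
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EEGRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname EEGRecording-class
#' @export
setGeneric("isAverageReferenced", function(x) standardGeneric("isAverageReferenced"))

#' @rdname TemplateSet-class
#' @param x a \code{TemplateSet}
#' @export
setGeneric("templateMaps", function(x) standardGeneric("templateMaps"))
#' @rdname TemplateSet-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname TemplateSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname TemplateSet-class
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))
#' @rdname TemplateSet-class
#' @export
setGeneric("templateGEV", function(x) standardGeneric("templateGEV"))

#' @rdname LabelSequence-class
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname MicrostateFeatures-class
#' @param x a \code{MicrostateFeatures}
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname MicrostateFeatures-class
#' @export
setGeneric("overallDuration", function(x) standardGeneric("overallDuration"))

#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
#' @rdname EEGRecording-class
#' @export
setMethod("isAverageReferenced", "EEGRecording", function(x) x@averageReferenced)

#' @rdname LabelSequence-class
#' @param x a \code{LabelSequence}
#' @export
setMethod("samplingRate", "LabelSequence", function(x) x@samplingRate)
#' @rdname LabelSequence-class
#' @export
setMethod("nSamples", "LabelSequence", function(x) length(x@labels))
#' @rdname LabelSequence-class
#' @export
setMethod("nClasses", "LabelSequence", function(x) x@nClasses)
#' @rdname LabelSequence-class
#' @export
setMethod("stateLabels", "LabelSequence", function(x) x@labels)

#' @rdname TemplateSet-class
#' @export
setMethod("templateMaps", "TemplateSet", function(x) x@maps)
#' @rdname TemplateSet-class
#' @export
setMethod("classNames", "TemplateSet", function(x) x@classNames)
#' @rdname TemplateSet-class
#' @export
setMethod("provenance", "TemplateSet", function(x) x@provenance)
#' @rdname TemplateSet-class
#' @export
setMethod("nClasses", "TemplateSet", function(x) nrow(x@maps))
#' @rdname TemplateSet-class
#' @export
setMethod("nChannels", "TemplateSet", function(x) ncol(x@maps))
#' @rdname TemplateSet-class
#' @export
setMethod("templateGEV", "TemplateSet", function(x) x@gev)
#' @rdname TemplateSet-class
#' @export
setMethod("channelNames", "TemplateSet", function(x) colnames(x@maps))

#' @rdname Montage-class
#' @param x a \code{Montage}
#' @export
setMethod("channelNames", "Montage", function(x) x@channelNames)
#' @rdname Montage-class
#' @export
setMethod("nChannels", "Montage", function(x) nrow(x@positions))
#' @rdname Montage-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname Montage-class
#' @export
setMethod("positions", "Montage", function(x) x@positions)

#' @rdname MicrostateFeatures-class
#' @export
setMethod("featureTable", "MicrostateFeatures", function(x) x@table)
#' @rdname MicrostateFeatures-class
#' @export
setMethod("overallDuration", "MicrostateFeatures", function(x) x@overallDurationMs)
#' @rdname MicrostateFeatures-class
#' @export
setMethod("samplingRate", "MicrostateFeatures", function(x) x@samplingRate)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate,
              if (object@averageReferenced) ", average-referenced" else ""))
})

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d channels on the unit head sphere\n",
              nrow(object@positions)))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet (%s): %d maps x %d channels [%s]%s\n",
              object@provenance, nrow(object@maps), ncol(object@maps),
              paste(object@classNames, collapse = ", "),
              if (is.na(object@gev)) "" else sprintf(", GEV = %.4f", object@gev)))
})

setMethod("show", "LabelSequence", function(object) {
  cat(sprintf("LabelSequence: %d samples @ %g Hz, K = %d\n",
              length(object@labels), object@samplingRate, object@nClasses))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: K = %d, GEV = %.4f (restart %d, %d iterations)\n",
              nrow(object@templates@maps), object@gev, object@restartIndex,
              object@nIterations))
})

setMethod("show", "MicrostateFeatures", function(object) {
  cat(sprintf("MicrostateFeatures (fs = %g Hz):\n", object@samplingRate))
  print(object@table, row.names = FALSE)
  cat(sprintf("overall mean duration: %.2f ms (unweighted), %.2f ms (segment-weighted)\n",
              object@overallDurationMs[["unweighted"]],
              object@overallDurationMs[["segment_weighted"]]))
})
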