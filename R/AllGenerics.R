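#' @rdname Recording-class
#' @param object,x a [Recording-class]
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname Recording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname Recording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname Recording-class
#' @export
setGeneric("recordingLabel", function(x) standardGeneric("recordingLabel"))

#' @rdname Recording-class
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("spectrumPower", function(x) standardGeneric("spectrumPower"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("spectrumPhase", function(x) standardGeneric("spectrumPhase"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureSet-class
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname FeatureSet-class
#' @export
setGeneric("kindTag", function(x) standardGeneric("kindTag"))
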