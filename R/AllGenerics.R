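#' @rdname AudioRecording
#' @param x an object with samples.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname AudioRecording
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname AudioRecording
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname AudioRecording
#' @export
setGeneric("subsetLabel", function(x) standardGeneric("subsetLabel"))

#' @rdname AudioRecording
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname SegmentSet-accessors
#' @param x a \linkS4class{SegmentSet} or \linkS4class{MelFeatureSet}.
#' @export
setGeneric("segmentInfo", function(x) standardGeneric("segmentInfo"))

#' @rdname SegmentSet-accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname SegmentSet-accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname SegmentSet-accessors
#' @export
setGeneric("positiveFraction", function(x) standardGeneric("positiveFraction"))

#' @rdname SegmentSet-accessors
#' @param i segment index.
#' @export
setGeneric("segmentSamples", function(x, i) standardGeneric("segmentSamples"))

#' @rdname MelFeatureSet-accessors
#' @param x a \linkS4class{MelFeatureSet}.
#' @export
setGeneric("melValues", function(x) standardGeneric("melValues"))

#' @rdname MetricsReport-accessors
#' @param x a \linkS4class{MetricsReport}.
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname MetricsReport-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname MetricsReport-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname MetricsReport-accessors
#' @export
setGeneric("mixedScore", function(x) standardGeneric("mixedScore"))

#' @rdname MetricsReport-accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname MetricsReport-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
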