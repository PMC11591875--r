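# Accessors and show methods for the S4 containers.

#' @rdname AudioRecording
#' @export
setMethod("samples", "AudioRecording", function(x) x@samples)

#' @rdname AudioRecording
#' @export
setMethod("sampleRate", "AudioRecording", function(x) x@sampleRate)

#' @rdname AudioRecording
#' @export
setMethod("sourceId", "AudioRecording", function(x) x@sourceId)

#' @rdname AudioRecording
#' @export
setMethod("subsetLabel", "AudioRecording", function(x) x@subset)

#' @rdname AudioRecording
#' @export
setMethod("duration", "AudioRecording",
          function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AudioRecording", function(object) {
    cat(sprintf("AudioRecording '%s': %.2f s at %g Hz%s\n",
                object@sourceId, duration(object), object@sampleRate,
                if (is.na(object@subset)) ""
                else sprintf(" [subset %s]", object@subset)))
})

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf(paste0(
        "ScenarioConfig: %.0f s at %g Hz, %.2g bouts/min (%d-%d coughs,",
        " decay %.2f),\n  coughs %.2f-%.2f s, %.2g distractors/min,",
        " noise floor %g dB, seed %d\n"),
        object@duration, object@sampleRate, object@boutRate,
        object@coughsPerBout[1], object@coughsPerBout[2], object@boutDecay,
        object@coughDuration[1], object@coughDuration[2],
        object@distractorRate, object@noiseFloorDb, object@seed))
})

#' @rdname SegmentSet-accessors
#' @export
setMethod("segmentInfo", "SegmentSet", function(x) x@info)

#' @rdname SegmentSet-accessors
#' @export
setMethod("nSegments", "SegmentSet", function(x) nrow(x@info))

#' @rdname SegmentSet-accessors
#' @export
setMethod("segmentLabels", "SegmentSet", function(x) x@info$label)

#' @rdname SegmentSet-accessors
#' @export
setMethod("sampleRate", "SegmentSet", function(x) x@sampleRate)

#' @rdname SegmentSet-accessors
#' @export
setMethod("subsetLabel", "SegmentSet", function(x) x@subset)

#' @rdname SegmentSet-accessors
#' @export
setMethod("sourceId", "SegmentSet", function(x) x@sourceId)

#' @rdname SegmentSet-accessors
#' @export
setMethod("positiveFraction", "SegmentSet", function(x) {
    n <- nrow(x@info)
    if (n == 0L) return(NA_real_)
    mean(x@info$label)
})

#' @rdname SegmentSet-accessors
#' @export
setMethod("segmentSamples", "SegmentSet", function(x, i) {
    stopifnot(length(i) == 1L, i >= 1L, i <= nrow(x@info))
    nwin <- round(x@window * x@sampleRate)
    from <- round(x@info$start_s[i] * x@sampleRate) + 1L
    to <- min(from + nwin - 1L, length(x@waveform))
    out <- numeric(nwin)
    if (to >= from) out[seq_len(to - from + 1L)] <- x@waveform[from:to]
    out
})

setMethod("show", "SegmentSet", function(object) {
    pf <- positiveFraction(object)
    cat(sprintf(
        "SegmentSet '%s': %d segments of %.2g s (stride %.2g s), %s positive\n",
        object@sourceId, nrow(object@info), object@window, object@stride,
        if (is.na(pf)) "NA" else sprintf("%.1f%%", 100 * pf)))
})

#' @rdname MelFeatureSet-accessors
#' @export
setMethod("melValues", "MelFeatureSet", function(x) x@values)

#' @rdname MelFeatureSet-accessors
#' @export
setMethod("segmentInfo", "MelFeatureSet", function(x) x@info)

#' @rdname MelFeatureSet-accessors
#' @export
setMethod("nSegments", "MelFeatureSet", function(x) dim(x@values)[3])

#' @rdname MelFeatureSet-accessors
#' @export
setMethod("segmentLabels", "MelFeatureSet", function(x) x@info$label)

#' @rdname MelFeatureSet-accessors
#' @export
setMethod("sampleRate", "MelFeatureSet", function(x) x@sampleRate)

setMethod("show", "MelFeatureSet", function(object) {
    cat(sprintf("MelFeatureSet: %d segments of %d x %d (dB-scaled)\n",
                dim(object@values)[3], object@nMels, object@nFrames))
})

#' @rdname MetricsReport-accessors
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)

#' @rdname MetricsReport-accessors
#' @export
setMethod("sensitivity", "MetricsReport", function(x) x@sensitivity)

#' @rdname MetricsReport-accessors
#' @export
setMethod("specificity", "MetricsReport", function(x) x@specificity)

#' @rdname MetricsReport-accessors
#' @export
setMethod("mixedScore", "MetricsReport", function(x) x@mixed)

#' @rdname MetricsReport-accessors
#' @export
setMethod("aucValue", "MetricsReport", function(x) x@auc)

#' @rdname MetricsReport-accessors
#' @export
setMethod("confusionCounts", "MetricsReport", function(x)
    c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

setMethod("show", "MetricsReport", function(object) {
    fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
    cat(sprintf(
        "MetricsReport: acc %s, sens %s, spec %s (tp %d, tn %d, fp %d, fn %d)%s\n",
        fmt(object@accuracy), fmt(object@sensitivity), fmt(object@specificity),
        object@tp, object@tn, object@fp, object@fn,
        if (is.na(object@auc)) "" else sprintf(", AUC %.4f", object@auc)))
})
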