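#' @import methods
NULL

#' Single-channel audio recording
#'
#' Container for a sampled waveform together with its sampling rate and
#' provenance. Every stage of the pipeline consumes this class: the synthetic
#' generator emits it, \code{\link{readWav}} constructs it from disk, and
#' \code{\link{windowRecording}} cuts it into segments.
#'
#' Samples are stored as doubles in \eqn{[-1, 1]} (full-scale PCM). A
#' zero-length waveform is permitted only as the degenerate result of
#' \code{\link{trimSilence}} on an all-silent input; file readers reject
#' empty data.
#'
#' @slot samples numeric waveform, amplitudes in \eqn{[-1, 1]}.
#' @slot sampleRate sampling rate in Hz (reference rate 22050).
#' @slot sourceId free-text identifier of the recording.
#' @slot subset optional environment/subset tag (\code{NA} if untagged).
#'
#' @aliases AudioRecording-class
#' @exportClass AudioRecording
setClass("AudioRecording",
    slots = c(
        samples    = "numeric",
        sampleRate = "numeric",
        sourceId   = "character",
        subset     = "character"
    ),
    prototype = prototype(sourceId = "recording", subset = NA_character_)
)

setValidity("AudioRecording", function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
        msg <- c(msg, "sampleRate must be a single positive number")
    if (anyNA(object@samples))
        msg <- c(msg, "samples must not contain NA")
    else if (length(object@samples) &&
             max(abs(object@samples)) > 1 + 1e-9)
        msg <- c(msg, "samples must lie in [-1, 1]")
    if (length(object@sourceId) != 1L)
        msg <- c(msg, "sourceId must be a single string")
    if (length(msg)) msg else TRUE
})

#' Construct an AudioRecording
#'
#' @param samples numeric waveform in \eqn{[-1, 1]}.
#' @param sampleRate sampling rate in Hz.
#' @param sourceId identifier string.
#' @param subset optional subset/environment tag.
#' @return An \linkS4class{AudioRecording}.
#' @examples
#' rec <- AudioRecording(sin(2 * pi * 440 * seq(0, 1, by = 1/8000)), 8000)
#' duration(rec)
#' @export
AudioRecording <- function(samples, sampleRate, sourceId = "recording",
                           subset = NA_character_) {
    new("AudioRecording", samples = as.numeric(samples),
        sampleRate = as.numeric(sampleRate),
        sourceId = as.character(sourceId), subset = as.character(subset))
}

#' Scenario configuration for the synthetic cough-audio generator
#'
#' Describes one simulated recording session: how long, how densely coughs
#' and distractor events occur, and how loud the background is. See
#' \code{\link{scenarioConfig}} for defaults and units.
#'
#' @slot duration recording length in seconds.
#' @slot sampleRate sampling rate in Hz.
#' @slot boutRate cough bouts per minute.
#' @slot coughsPerBout integer pair, inclusive range of coughs per bout.
#' @slot boutDecay per-cough amplitude multiplier within a bout, in (0, 1].
#' @slot coughDuration numeric pair, single-cough duration range in seconds
#'   (each cough is shorter than one second).
#' @slot distractorRate non-cough events (speech, throat clear) per minute.
#' @slot noiseFloorDb background noise RMS in dB relative to the nominal
#'   cough peak (negative; -40 is a quiet room).
#' @slot seed integer seed driving all randomness for this recording.
#'
#' @aliases ScenarioConfig-class
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
    slots = c(
        duration       = "numeric",
        sampleRate     = "numeric",
        boutRate       = "numeric",
        coughsPerBout  = "integer",
        boutDecay      = "numeric",
        coughDuration  = "numeric",
        distractorRate = "numeric",
        noiseFloorDb   = "numeric",
        seed           = "integer"
    )
)

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
    if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
    if (object@boutRate < 0) msg <- c(msg, "boutRate must be >= 0")
    if (length(object@coughsPerBout) != 2L ||
        any(object@coughsPerBout < 1L) ||
        object@coughsPerBout[1] > object@coughsPerBout[2])
        msg <- c(msg, "coughsPerBout must be an increasing integer pair >= 1")
    if (object@boutDecay <= 0 || object@boutDecay > 1)
        msg <- c(msg, "boutDecay must lie in (0, 1]")
    if (length(object@coughDuration) != 2L ||
        any(object@coughDuration <= 0) || any(object@coughDuration >= 1) ||
        object@coughDuration[1] > object@coughDuration[2])
        msg <- c(msg, "coughDuration must be an increasing pair within (0, 1)")
    if (object@distractorRate < 0) msg <- c(msg, "distractorRate must be >= 0")
    if (object@noiseFloorDb >= 0) msg <- c(msg, "noiseFloorDb must be negative")
    if (length(msg)) msg else TRUE
})

#' Set of labeled fixed-length segments from one recording
#'
#' Produced by \code{\link{windowRecording}}. The waveform is stored once;
#' individual windows are materialized on demand by
#' \code{\link{segmentSamples}} (a trailing partial window is zero-padded),
#' so a segment set costs little more memory than its source recording.
#'
#' @slot info data.frame with one row per segment: \code{source_id},
#'   \code{start_s}, \code{end_s}, \code{label} (logical, contains cough),
#'   \code{mean_abs_amplitude} (mean of |samples| before padding).
#' @slot waveform the source recording's samples.
#' @slot sampleRate Hz.
#' @slot window window length in seconds.
#' @slot stride hop between window starts in seconds.
#' @slot sourceId source recording identifier.
#' @slot subset subset/environment tag inherited from the recording.
#'
#' @aliases SegmentSet-class
#' @exportClass SegmentSet
setClass("SegmentSet",
    slots = c(
        info       = "data.frame",
        waveform   = "numeric",
        sampleRate = "numeric",
        window     = "numeric",
        stride     = "numeric",
        sourceId   = "character",
        subset     = "character"
    )
)

setValidity("SegmentSet", function(object) {
    need <- c("source_id", "start_s", "end_s", "label", "mean_abs_amplitude")
    msg <- character()
    if (!all(need %in% names(object@info)))
        msg <- c(msg, paste("info must have columns:",
                            paste(need, collapse = ", ")))
    if (object@window <= 0 || object@stride <= 0)
        msg <- c(msg, "window and stride must be > 0")
    if (nrow(object@info) &&
        any(abs((object@info$end_s - object@info$start_s) -
                object@window) > 1e-9))
        msg <- c(msg, "every segment must span exactly one window length")
    if (nrow(object@info) && any(object@info$mean_abs_amplitude < 0))
        msg <- c(msg, "mean_abs_amplitude must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Mel-spectrogram features for a batch of segments
#'
#' The model-facing representation: one dB-scaled Mel spectrogram per
#' segment, all sharing a single (nMels x nFrames) shape — the shape
#' contract the CRNN relies on.
#'
#' @slot values numeric array of dim (nMels, nFrames, nSegments), dB-scaled
#'   Mel energies; per-segment dynamic range is clipped to 80 dB.
#' @slot info per-segment metadata carried over from the segment sets.
#' @slot nMels number of Mel bands.
#' @slot nFrames number of STFT frames per segment.
#' @slot sampleRate Hz of the audio the features were computed from.
#' @slot params list of STFT parameters (n_fft, hop, top_db).
#'
#' @aliases MelFeatureSet-class
#' @exportClass MelFeatureSet
setClass("MelFeatureSet",
    slots = c(
        values     = "array",
        info       = "data.frame",
        nMels      = "integer",
        nFrames    = "integer",
        sampleRate = "numeric",
        params     = "list"
    )
)

setValidity("MelFeatureSet", function(object) {
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3L)
        msg <- c(msg, "values must be a 3-d array (mels, frames, segments)")
    else {
        if (d[1] != object@nMels || d[2] != object@nFrames)
            msg <- c(msg, "values dim must match (nMels, nFrames)")
        if (d[3] != nrow(object@info))
            msg <- c(msg, "one info row per segment required")
        if (length(object@values) && !all(is.finite(object@values)))
            msg <- c(msg, "values must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Classification metrics with confusion counts
#'
#' Accuracy, sensitivity (recall) and specificity computed from a binary
#' confusion matrix, plus the mixed score (accuracy + sensitivity) used for
#' checkpoint selection, and optionally an AUC. Ratios with a zero
#' denominator are reported as \code{NA}, never coerced to 0 or 1.
#'
#' @slot tp,tn,fp,fn confusion counts.
#' @slot accuracy (tp + tn) / total.
#' @slot sensitivity tp / (tp + fn).
#' @slot specificity tn / (tn + fp).
#' @slot mixed accuracy + sensitivity.
#' @slot auc area under the ROC curve (\code{NA} when not computed).
#'
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
    slots = c(
        tp = "integer", tn = "integer", fp = "integer", fn = "integer",
        accuracy = "numeric", sensitivity = "numeric",
        specificity = "numeric", mixed = "numeric", auc = "numeric"
    ),
    prototype = prototype(auc = NA_real_)
)

setValidity("MetricsReport", function(object) {
    msg <- character()
    if (any(c(object@tp, object@tn, object@fp, object@fn) < 0L))
        msg <- c(msg, "confusion counts must be non-negative")
    ok <- function(x) is.na(x) || (x >= 0 && x <= 1)
    if (!ok(object@accuracy) || !ok(object@sensitivity) ||
        !ok(object@specificity))
        msg <- c(msg, "metrics must lie in [0, 1] or be NA")
    if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
        msg <- c(msg, "auc must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
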