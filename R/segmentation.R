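# Sliding-window segmentation, the amplitude-based imbalance filter, and the
# silence-trimming utility.
#
# Training uses un-trimmed audio: silence trimming exists to shorten
# recordings for manual review, not as a preprocessing step of the learning
# pipeline. The amplitude filter, by contrast, is part of the classical-ML
# track only; the CRNN consumes unfiltered segments.

#' Label sliding windows from an annotation table
#'
#' A window is positive when its overlap with some cough annotation is at
#' least \code{min(minOverlap, half that annotation's duration)} -- the
#' second term keeps very short coughs from slipping between windows.
#' Only the annotation table is needed, so positive-window density can be
#' computed without synthesizing or loading audio.
#'
#' @param ann annotation data.frame (\code{start_s}, \code{end_s},
#'   \code{label}); only rows labeled \code{"cough"} make windows positive.
#' @param durationS recording duration in seconds.
#' @param window,stride window length and hop in seconds.
#' @param minOverlap overlap (s) required to call a window positive.
#' @return logical vector, one flag per window tiling \code{[0, durationS)}.
#' @export
windowLabelFlags <- function(ann, durationS, window = 0.5, stride = 0.5,
                             minOverlap = 0.1) {
    stopifnot(window > 0, stride > 0, durationS >= 0)
    nWin <- ceiling(durationS / stride)
    if (nWin == 0L) return(logical())
    starts <- (seq_len(nWin) - 1L) * stride
    flags <- logical(nWin)
    coughs <- ann[ann$label == "cough", , drop = FALSE]
    for (j in seq_len(nrow(coughs))) {
        need <- min(minOverlap, (coughs$end_s[j] - coughs$start_s[j]) / 2)
        ov <- pmin(starts + window, coughs$end_s[j]) -
            pmax(starts, coughs$start_s[j])
        flags <- flags | (ov >= need - 1e-12)
    }
    flags
}

#' Cut a recording into labeled fixed-length segments
#'
#' Tiles \code{[0, duration)} with windows of \code{window} seconds every
#' \code{stride} seconds (defaults give the non-overlapping 0.5-s tiling).
#' A trailing partial window is zero-padded to full length when its samples
#' are materialized; its \code{mean_abs_amplitude} is computed on the
#' unpadded samples.
#'
#' @param rec an \linkS4class{AudioRecording}.
#' @param ann optional annotation data.frame; windows overlapping a cough
#'   annotation by at least \code{min(minOverlap, half the cough)} get
#'   \code{label = TRUE}.
#' @param window,stride seconds; both must be positive.
#' @param minOverlap seconds of cough overlap required for a positive label.
#' @return A \linkS4class{SegmentSet}.
#' @examples
#' rec <- AudioRecording(numeric(22050 * 2), 22050, "silence")
#' windowRecording(rec)
#' @export
windowRecording <- function(rec, ann = NULL, window = 0.5, stride = 0.5,
                            minOverlap = 0.1) {
    stopifnot(is(rec, "AudioRecording"), window > 0, stride > 0)
    durS <- duration(rec)
    nWin <- ceiling(durS / stride)
    starts <- (seq_len(nWin) - 1L) * stride
    sr <- rec@sampleRate
    nSamp <- length(rec@samples)
    winN <- round(window * sr)
    meanAbs <- numeric(nWin)
    absx <- abs(rec@samples)
    cum <- c(0, cumsum(absx))
    for (i in seq_len(nWin)) {
        from <- round(starts[i] * sr) + 1L
        to <- min(from + winN - 1L, nSamp)
        meanAbs[i] <- if (to >= from) (cum[to + 1L] - cum[from]) /
            (to - from + 1L) else 0
    }
    flags <- if (is.null(ann) || nrow(ann) == 0L) logical(nWin)
             else windowLabelFlags(ann, durS, window, stride, minOverlap)
    info <- data.frame(
        source_id = rep(rec@sourceId, nWin),
        start_s = starts, end_s = starts + window,
        label = flags, mean_abs_amplitude = meanAbs)
    new("SegmentSet", info = info, waveform = rec@samples, sampleRate = sr,
        window = window, stride = stride, sourceId = rec@sourceId,
        subset = rec@subset)
}

#' Global mean absolute amplitude of a recording
#'
#' The reference value of the imbalance filter: the average amplitude of the
#' entire raw audio, computed per recording.
#'
#' @param x an \linkS4class{AudioRecording} or \linkS4class{SegmentSet}.
#' @return scalar mean of |samples|.
#' @export
globalMeanAbs <- function(x) {
    w <- if (is(x, "AudioRecording")) x@samples
         else if (is(x, "SegmentSet")) x@waveform
         else stop("need an AudioRecording or SegmentSet")
    mean(abs(w))
}

#' Amplitude-based class-imbalance filter
#'
#' Removes segments whose mean absolute amplitude falls below the global
#' average of the raw audio -- unless they contain a cough, in which case
#' they are always retained. Consequently the positive fraction of the
#' output is never lower than that of the input, and no positive segment is
#' ever dropped. Used on the classical-ML track only.
#'
#' @param set a \linkS4class{SegmentSet}.
#' @param globalMean reference amplitude; defaults to the mean |sample| of
#'   the set's own recording.
#' @return A filtered \linkS4class{SegmentSet}.
#' @export
amplitudeFilter <- function(set, globalMean = NULL) {
    stopifnot(is(set, "SegmentSet"))
    if (is.null(globalMean)) globalMean <- globalMeanAbs(set)
    stopifnot(globalMean >= 0)
    keep <- set@info$mean_abs_amplitude >= globalMean | set@info$label
    out <- set
    out@info <- set@info[keep, , drop = FALSE]
    rownames(out@info) <- NULL
    out
}

#' Remove long silent stretches from a recording
#'
#' Frames the recording into \code{frame}-second blocks, flags frames whose
#' RMS falls below \code{relThreshold} times the recording's global RMS, and
#' removes contiguous silent runs longer than \code{minGap} seconds. Returns
#' the shortened recording and a monotone time map from trimmed time back to
#' original time. This utility shortens recordings for manual annotation; the
#' training path consumes the original, un-trimmed audio.
#'
#' @param rec an \linkS4class{AudioRecording}.
#' @param frame frame length in seconds.
#' @param relThreshold silence threshold relative to global RMS.
#' @param minGap minimum silent-run length (s) eligible for removal.
#' @return list with \code{recording} (trimmed \linkS4class{AudioRecording};
#'   zero samples if everything was silent) and \code{map}: a data.frame of
#'   kept spans with columns \code{orig_start_s}, \code{orig_end_s},
#'   \code{new_start_s}.
#' @export
trimSilence <- function(rec, frame = 0.05, relThreshold = 0.1,
                        minGap = 1.0) {
    stopifnot(is(rec, "AudioRecording"), frame > 0, relThreshold > 0,
              minGap > 0)
    sr <- rec@sampleRate
    x <- rec@samples
    fn <- max(1L, round(frame * sr))
    nF <- ceiling(length(x) / fn)
    pad <- numeric(nF * fn)
    pad[seq_along(x)] <- x
    fr <- matrix(pad, nrow = fn)
    rms <- sqrt(colMeans(fr^2))
    gRms <- sqrt(mean(x^2))
    # <= so an all-silent recording (global RMS 0) is removed entirely
    silent <- rms <= relThreshold * gRms
    # runs of silent frames exceeding minGap are dropped
    r <- rle(silent)
    drop <- r$values & (r$lengths * frame > minGap)
    keepFrame <- rep(!drop, r$lengths)
    emptyMap <- data.frame(orig_start_s = numeric(), orig_end_s = numeric(),
                           new_start_s = numeric())
    if (!any(keepFrame)) {
        return(list(recording = new("AudioRecording", samples = numeric(),
                                    sampleRate = sr, sourceId = rec@sourceId,
                                    subset = rec@subset),
                    map = emptyMap))
    }
    kr <- rle(keepFrame)
    ends <- cumsum(kr$lengths)
    startsF <- c(1L, head(ends, -1L) + 1L)
    spans <- data.frame(fromF = startsF[kr$values], toF = ends[kr$values])
    from <- (spans$fromF - 1L) * fn + 1L
    to <- pmin(spans$toF * fn, length(x))
    lenS <- (to - from + 1L) / sr
    map <- data.frame(
        orig_start_s = (from - 1L) / sr,
        orig_end_s = to / sr,
        new_start_s = cumsum(c(0, lenS))[seq_len(nrow(spans))])
    pieces <- lapply(seq_len(nrow(spans)), function(i) x[from[i]:to[i]])
    trimmed <- AudioRecording(unlist(pieces), sr, rec@sourceId, rec@subset)
    list(recording = trimmed, map = map)
}

#' Map annotations through a silence-trimming time map
#'
#' Projects original-time annotations onto the trimmed timeline: each
#' interval is intersected with the kept spans and shifted; parts falling in
#' removed silence are clipped, and annotations entirely inside removed
#' silence are dropped.
#'
#' @param map time map returned by \code{\link{trimSilence}}.
#' @param ann annotation data.frame in original time.
#' @return annotation data.frame in trimmed time.
#' @export
applyTimeMap <- function(map, ann) {
    out <- list()
    for (i in seq_len(nrow(ann))) {
        for (j in seq_len(nrow(map))) {
            lo <- max(ann$start_s[i], map$orig_start_s[j])
            hi <- min(ann$end_s[i], map$orig_end_s[j])
            if (hi > lo + 1e-9) {
                off <- map$new_start_s[j] - map$orig_start_s[j]
                row <- ann[i, , drop = FALSE]
                row$start_s <- lo + off
                row$end_s <- hi + off
                out[[length(out) + 1L]] <- row
            }
        }
    }
    if (!length(out))
        return(ann[0, , drop = FALSE])
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Export a segment table
#'
#' Serializes segment metadata (not audio) as CSV: samples persist via the
#' source WAV plus offsets rather than duplicated waveforms.
#'
#' @param set a \linkS4class{SegmentSet}.
#' @param path destination CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentTable <- function(set, path) {
    stopifnot(is(set, "SegmentSet"))
    utils::write.csv(set@info, path, row.names = FALSE)
    invisible(path)
}
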