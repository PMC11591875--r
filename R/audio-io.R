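# WAV and Audacity label-track IO.
#
# The pipeline's on-disk formats are deliberately minimal: PCM WAV for audio
# and the tab-separated label-track dialect (start<TAB>end<TAB>label, seconds
# as decimals) that Audacity exports, since clinical annotation was done in
# Audacity.

.KNOWN_LABELS <- c("cough", "speech", "laugh", "throat_clear", "other")

# Synonym table applied case-insensitively when parsing label files; manual
# tags vary ("clear throat", "coughing", ...).
.LABEL_SYNONYMS <- c(
    "cough" = "cough", "coughing" = "cough", "coughs" = "cough",
    "speech" = "speech", "talk" = "speech", "talking" = "speech",
    "speaking" = "speech", "voice" = "speech",
    "laugh" = "laugh", "laughing" = "laugh", "laughter" = "laugh",
    "throat_clear" = "throat_clear", "throat clear" = "throat_clear",
    "clear throat" = "throat_clear", "throat-clear" = "throat_clear",
    "throatclear" = "throat_clear", "clearing throat" = "throat_clear",
    "other" = "other"
)

.canonicalLabel <- function(label) {
    key <- tolower(trimws(label))
    out <- unname(.LABEL_SYNONYMS[key])
    unknown <- is.na(out)
    if (any(unknown)) {
        warning("unknown label(s) mapped to 'other': ",
                paste(unique(label[unknown]), collapse = ", "),
                call. = FALSE)
        out[unknown] <- "other"
    }
    out
}

#' Construct an annotation table
#'
#' Annotations are plain data.frames with columns \code{start_s},
#' \code{end_s} and \code{label}; this helper validates them. Intervals are
#' not required to be sorted or disjoint (human tags may overlap); the
#' windowing stage resolves overlap when assigning segment labels.
#'
#' @param start_s,end_s event boundaries in seconds, \code{0 <= start < end}.
#' @param label one of cough, speech, laugh, throat_clear, other (synonyms
#'   are canonicalized; unknown strings become "other" with a warning).
#' @return data.frame with one row per event.
#' @export
annotations <- function(start_s = numeric(), end_s = numeric(),
                        label = character()) {
    stopifnot(length(start_s) == length(end_s),
              length(start_s) == length(label))
    if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
        stop("annotation times must be finite numbers")
    if (any(start_s < 0)) stop("annotation start times must be >= 0")
    if (any(end_s <= start_s)) stop("annotation intervals need end_s > start_s")
    data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
               label = .canonicalLabel(as.character(label)))
}

.readChunkHeader <- function(con) {
    id <- rawToChar(readBin(con, "raw", 4L))
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    list(id = id, size = size)
}

#' Read a PCM WAV file
#'
#' Supports uncompressed PCM (8/16/24/32-bit integer) and 32-bit IEEE float
#' WAV. Multi-channel audio is averaged to mono; samples are scaled to
#' \eqn{[-1, 1]}; the file's sampling rate is preserved (resampling, when
#' needed, is a separate explicit step).
#'
#' @param path path to a .wav file.
#' @param sourceId identifier for the returned recording (defaults to the
#'   file name without extension).
#' @param subset optional subset tag.
#' @return An \linkS4class{AudioRecording}.
#' @export
readWav <- function(path, sourceId = NULL, subset = NA_character_) {
    if (!file.exists(path)) stop("WAV file not found: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    riff <- .readChunkHeader(con)
    wave <- rawToChar(readBin(con, "raw", 4L))
    if (!identical(riff$id, "RIFF") || !identical(wave, "WAVE"))
        stop("not a RIFF/WAVE file: ", path)
    fmt <- NULL
    dat <- NULL
    repeat {
        hdr <- tryCatch(.readChunkHeader(con), error = function(e) NULL)
        if (is.null(hdr) || length(hdr$id) == 0L || nchar(hdr$id) < 4L) break
        if (identical(hdr$id, "fmt ")) {
            raw <- readBin(con, "raw", hdr$size)
            fmt <- list(
                audioFormat = readBin(raw[1:2], "integer", 1L, 2L,
                                      signed = FALSE, endian = "little"),
                channels = readBin(raw[3:4], "integer", 1L, 2L,
                                   signed = FALSE, endian = "little"),
                sampleRate = readBin(raw[5:8], "integer", 1L, 4L,
                                     endian = "little"),
                bits = readBin(raw[15:16], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"))
        } else if (identical(hdr$id, "data")) {
            dat <- readBin(con, "raw", hdr$size)
        } else {
            # skip unknown chunk (word-aligned)
            seek(con, hdr$size + hdr$size %% 2L, origin = "current")
        }
        if (!is.null(fmt) && !is.null(dat)) break
    }
    if (is.null(fmt)) stop("corrupt WAV (no fmt chunk): ", path)
    if (is.null(dat) || length(dat) == 0L)
        stop("corrupt WAV (no data chunk): ", path)
    if (!fmt$audioFormat %in% c(1L, 3L))
        stop("unsupported WAV encoding (", fmt$audioFormat,
             "), only PCM/float supported: ", path)
    x <- if (fmt$audioFormat == 3L) {
        if (fmt$bits != 32L) stop("float WAV must be 32-bit: ", path)
        readBin(dat, "numeric", length(dat) %/% 4L, size = 4L,
                endian = "little")
    } else if (fmt$bits == 16L) {
        readBin(dat, "integer", length(dat) %/% 2L, size = 2L,
                signed = TRUE, endian = "little") / 32767
    } else if (fmt$bits == 8L) {
        (readBin(dat, "integer", length(dat), size = 1L, signed = FALSE,
                 endian = "little") - 128) / 127
    } else if (fmt$bits == 32L) {
        readBin(dat, "integer", length(dat) %/% 4L, size = 4L,
                endian = "little") / 2147483647
    } else if (fmt$bits == 24L) {
        n <- length(dat) %/% 3L
        b <- matrix(as.integer(dat[seq_len(3L * n)]), nrow = 3L)
        v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388607
    } else stop("unsupported PCM bit depth (", fmt$bits, "): ", path)
    if (fmt$channels > 1L) {
        n <- length(x) %/% fmt$channels
        x <- colMeans(matrix(x[seq_len(n * fmt$channels)],
                             nrow = fmt$channels))
    }
    x <- pmin(1, pmax(-1, x))
    if (is.null(sourceId)) sourceId <- sub("\\.wav$", "", basename(path),
                                           ignore.case = TRUE)
    AudioRecording(x, fmt$sampleRate, sourceId, subset)
}

#' Write a recording as 16-bit PCM WAV
#'
#' @param rec an \linkS4class{AudioRecording}, or a numeric matrix
#'   (samples x channels) for multi-channel output.
#' @param path destination path.
#' @param sampleRate required when \code{rec} is a bare matrix/vector.
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(rec, path, sampleRate = NULL) {
    if (is(rec, "AudioRecording")) {
        x <- matrix(rec@samples, ncol = 1L)
        sampleRate <- rec@sampleRate
    } else {
        if (is.null(sampleRate)) stop("sampleRate required for raw samples")
        x <- if (is.matrix(rec)) rec else matrix(rec, ncol = 1L)
    }
    nch <- ncol(x)
    pcm <- as.integer(round(pmin(1, pmax(-1, t(x))) * 32767))
    dataSize <- length(pcm) * 2L
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot write WAV at: ", path))
    on.exit(close(con))
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(16L, con, size = 4L, endian = "little")
    writeBin(c(1L, nch), con, size = 2L, endian = "little")
    writeBin(as.integer(sampleRate), con, size = 4L, endian = "little")
    writeBin(as.integer(sampleRate * nch * 2L), con, size = 4L,
             endian = "little")
    writeBin(c(nch * 2L, 16L), con, size = 2L, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(dataSize, con, size = 4L, endian = "little")
    writeBin(pcm, con, size = 2L, endian = "little")
    invisible(path)
}

#' Read an Audacity-style label track
#'
#' One event per line, \code{start<TAB>end<TAB>label}. Label strings are
#' matched case-insensitively against a small synonym table; unrecognized
#' labels map to \code{"other"} with a warning. Lines are returned in file
#' order; no sorting or overlap resolution is applied.
#'
#' @param path path to the label file.
#' @return data.frame with columns \code{start_s}, \code{end_s},
#'   \code{label} (empty for an empty file).
#' @export
readLabels <- function(path) {
    if (!file.exists(path)) stop("label file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    empty <- annotations()
    if (!any(keep)) return(empty)
    lineNo <- which(keep)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    out <- vector("list", length(parts))
    for (i in seq_along(parts)) {
        p <- parts[[i]]
        if (length(p) < 3L)
            stop("label parse error at line ", lineNo[i],
                 ": expected start<TAB>end<TAB>label")
        st <- suppressWarnings(as.numeric(p[1]))
        en <- suppressWarnings(as.numeric(p[2]))
        if (is.na(st) || is.na(en))
            stop("label parse error at line ", lineNo[i],
                 ": non-numeric time")
        if (en <= st || st < 0)
            stop("label parse error at line ", lineNo[i],
                 ": need 0 <= start < end")
        out[[i]] <- data.frame(start_s = st, end_s = en,
                               label = paste(p[-(1:2)], collapse = " "))
    }
    res <- do.call(rbind, out)
    res$label <- .canonicalLabel(res$label)
    rownames(res) <- NULL
    res
}

#' Write annotations as an Audacity-style label track
#'
#' Inverse of \code{\link{readLabels}} up to 6-decimal float formatting.
#'
#' @param ann annotation data.frame (see \code{\link{annotations}}).
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(ann, path) {
    stopifnot(is.data.frame(ann),
              all(c("start_s", "end_s", "label") %in% names(ann)))
    lines <- if (nrow(ann)) sprintf("%.6f\t%.6f\t%s", ann$start_s,
                                    ann$end_s, ann$label) else character()
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write label file at: ", path)
    invisible(path)
}
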