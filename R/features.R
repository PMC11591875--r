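# Feature extraction: Mel spectrograms (the model input), MFCC, zero-crossing
# rate, spectral roll-off, and the flatten -> PCA -> standardize track used by
# the classical baselines.
#
# STFT parameters default to n_fft = 2048, hop = 512 with centered frames and
# a periodic Hann window: the common configuration that yields exactly 22
# frames from a 0.5-s window at 22,050 Hz, giving the 128 x 22 segment shape
# the classifier expects.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Power spectrogram with centered (zero-padded) frames.
# Returns (nFft/2 + 1) x nFrames, nFrames = 1 + floor(length(x) / hop).
.stftPower <- function(x, nFft = 2048L, hop = 512L) {
    n <- length(x)
    half <- nFft %/% 2L
    padded <- c(numeric(half), x, numeric(nFft))
    nFrames <- 1L + n %/% hop
    idx <- outer(seq_len(nFft), (seq_len(nFrames) - 1L) * hop, `+`)
    frames <- matrix(padded[idx], nrow = nFft) * .hann(nFft)
    spec <- stats::mvfft(frames)[seq_len(half + 1L), , drop = FALSE]
    Mod(spec)^2
}

.hzToMel <- function(f) 2595 * log10(1 + f / 700)
.melToHz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filter bank
#'
#' Triangular filters (unit peak) spaced evenly on the HTK Mel scale from
#' \code{fmin} to \code{fmax}, evaluated at the STFT bin frequencies.
#'
#' @param sampleRate Hz.
#' @param nFft FFT size.
#' @param nMels number of bands.
#' @param fmin,fmax band-edge frequencies in Hz (defaults 0 to Nyquist).
#' @return matrix (nMels x nFft/2 + 1) of filter weights; row attribute
#'   \code{"centers"} gives each band's center frequency in Hz.
#' @export
melFilterbank <- function(sampleRate, nFft = 2048L, nMels = 128L,
                          fmin = 0, fmax = sampleRate / 2) {
    pts <- .melToHz(seq(.hzToMel(fmin), .hzToMel(fmax),
                        length.out = nMels + 2L))
    binHz <- (seq_len(nFft %/% 2L + 1L) - 1L) * sampleRate / nFft
    fb <- matrix(0, nMels, length(binHz))
    for (m in seq_len(nMels)) {
        lo <- pts[m]; ctr <- pts[m + 1L]; hi <- pts[m + 2L]
        up <- (binHz - lo) / max(ctr - lo, 1e-12)
        down <- (hi - binHz) / max(hi - ctr, 1e-12)
        fb[m, ] <- pmax(0, pmin(up, down))
    }
    attr(fb, "centers") <- pts[2:(nMels + 1L)]
    fb
}

#' Mel spectrogram of one fixed-length segment
#'
#' STFT power -> Mel filter bank (0 to Nyquist) -> dB scale clipped to the
#' top \code{topDb} decibels of the segment. An all-zero segment yields a
#' uniform grid at the dB floor (power is floored at 1e-10 before the log).
#' For the reference configuration (0.5 s at 22,050 Hz, 128 bands) the
#' output is 128 x 22.
#'
#' @param x numeric samples of one segment.
#' @param sampleRate Hz.
#' @param nMels number of Mel bands.
#' @param nFft,hop STFT size and hop in samples.
#' @param topDb dynamic range kept below the segment maximum.
#' @param db if \code{FALSE}, return linear Mel power instead of dB.
#' @return matrix (nMels x nFrames).
#' @export
melSpectrogram <- function(x, sampleRate = 22050, nMels = 128L,
                           nFft = 2048L, hop = 512L, topDb = 80, db = TRUE) {
    P <- .stftPower(x, nFft, hop)
    M <- melFilterbank(sampleRate, nFft, nMels) %*% P
    if (!db) return(M)
    S <- 10 * log10(pmax(M, 1e-10))
    pmax(S, max(S) - topDb)
}

#' Mel features for every segment of one or more segment sets
#'
#' Applies \code{\link{melSpectrogram}} to each window of the given
#' \linkS4class{SegmentSet} (or list of sets), stacking the results into the
#' (nMels x nFrames x nSegments) array the CRNN consumes. The sets'
#' sampling rate must equal \code{sampleRate}; resampling is an explicit
#' upstream step, never silent.
#'
#' @param sets a \linkS4class{SegmentSet} or list of them.
#' @param sampleRate expected sampling rate in Hz.
#' @param nMels,nFft,hop,topDb see \code{\link{melSpectrogram}}.
#' @return A \linkS4class{MelFeatureSet}; its \code{info} gains a
#'   \code{subset} column from each set's subset tag.
#' @export
melFeatures <- function(sets, sampleRate = 22050, nMels = 128L,
                        nFft = 2048L, hop = 512L, topDb = 80) {
    if (is(sets, "SegmentSet")) sets <- list(sets)
    stopifnot(length(sets) > 0L, all(vapply(sets, is, logical(1),
                                            "SegmentSet")))
    for (s in sets)
        if (abs(s@sampleRate - sampleRate) > 1e-9)
            stop("segment set '", s@sourceId, "' is sampled at ",
                 s@sampleRate, " Hz, expected ", sampleRate,
                 " Hz; resample explicitly upstream")
    total <- sum(vapply(sets, nSegments, integer(1)))
    winN <- round(sets[[1]]@window * sampleRate)
    nFrames <- 1L + winN %/% hop
    vals <- array(0, dim = c(nMels, nFrames, total))
    infos <- vector("list", length(sets))
    k <- 0L
    for (si in seq_along(sets)) {
        set <- sets[[si]]
        inf <- set@info
        inf$subset <- set@subset
        infos[[si]] <- inf
        for (i in seq_len(nSegments(set))) {
            k <- k + 1L
            vals[, , k] <- melSpectrogram(segmentSamples(set, i), sampleRate,
                                          nMels, nFft, hop, topDb)
        }
    }
    info <- do.call(rbind, infos)
    rownames(info) <- NULL
    new("MelFeatureSet", values = vals, info = info, nMels = as.integer(nMels),
        nFrames = as.integer(nFrames), sampleRate = sampleRate,
        params = list(n_fft = nFft, hop = hop, top_db = topDb))
}

#' Mel-frequency cepstral coefficients of a segment
#'
#' Orthonormal DCT-II of the per-frame dB Mel energies (no dynamic-range
#' clipping), keeping the first \code{nCoef} coefficients. A silent segment
#' gives a constant log spectrum, hence all coefficients beyond the first
#' are zero.
#'
#' @param x numeric samples of one segment.
#' @param sampleRate Hz.
#' @param nCoef number of coefficients.
#' @param nMels,nFft,hop Mel/STFT parameters.
#' @return matrix (nCoef x nFrames).
#' @export
mfcc <- function(x, sampleRate = 22050, nCoef = 13L, nMels = 128L,
                 nFft = 2048L, hop = 512L) {
    P <- .stftPower(x, nFft, hop)
    M <- melFilterbank(sampleRate, nFft, nMels) %*% P
    S <- 10 * log10(pmax(M, 1e-10))
    k <- seq_len(nCoef) - 1L
    n <- seq_len(nMels) - 1L
    D <- sqrt(2 / nMels) * cos(pi * outer(k, n + 0.5) / nMels)
    D[1, ] <- D[1, ] / sqrt(2)
    D %*% S
}

#' Per-frame zero-crossing rate
#'
#' Fraction of adjacent sample pairs whose sign differs, per frame, in
#' \eqn{[0, 1]}. Frames are taken without padding; a segment shorter than
#' one frame yields a single frame covering the whole segment.
#'
#' @param x numeric samples.
#' @param frame,hop frame length and hop in samples.
#' @return numeric vector of per-frame rates.
#' @export
zeroCrossingRate <- function(x, frame = 2048L, hop = 512L) {
    n <- length(x)
    if (n < 2L) return(0)
    if (n < frame) return(mean((x[-n] >= 0) != (x[-1] >= 0)))
    nFrames <- 1L + (n - frame) %/% hop
    s <- x >= 0
    vapply(seq_len(nFrames), function(t) {
        i <- (t - 1L) * hop + seq_len(frame)
        mean(s[i[-frame]] != s[i[-1]])
    }, numeric(1))
}

#' Per-frame spectral roll-off frequency
#'
#' For each STFT frame, the smallest bin frequency below which at least
#' \code{pct} of the frame's total spectral energy is contained. A frame
#' with zero energy reports bin 0 (0 Hz) by convention.
#'
#' @param x numeric samples.
#' @param sampleRate Hz.
#' @param pct energy fraction in (0, 1].
#' @param nFft,hop STFT parameters (centered frames, as the Mel track).
#' @return numeric vector of per-frame roll-off frequencies in Hz.
#' @export
spectralRolloff <- function(x, sampleRate = 22050, pct = 0.85,
                            nFft = 2048L, hop = 512L) {
    stopifnot(pct > 0, pct <= 1)
    P <- .stftPower(x, nFft, hop)
    binHz <- (seq_len(nrow(P)) - 1L) * sampleRate / nFft
    apply(P, 2L, function(col) {
        tot <- sum(col)
        if (tot <= 0) return(0)
        binHz[which(cumsum(col) >= pct * tot - 1e-15)[1]]
    })
}

#' Flatten Mel segments to row vectors
#'
#' Each (nMels x nFrames) grid becomes one row of length nMels * nFrames
#' (2816 for the reference 128 x 22 shape), column-major.
#'
#' @param mels a \linkS4class{MelFeatureSet}.
#' @return matrix (nSegments x nMels*nFrames).
#' @export
flattenMels <- function(mels) {
    stopifnot(is(mels, "MelFeatureSet"))
    d <- dim(mels@values)
    t(matrix(mels@values, nrow = d[1] * d[2], ncol = d[3]))
}

#' Fit the flatten -> PCA -> standardize transform
#'
#' Fits, on a training split only, the baseline feature track: flatten each
#' Mel segment, project onto the smallest number of principal components
#' reaching at least \code{varianceKept} explained variance, then scale each
#' retained component to zero mean and unit variance (standardization after
#' PCA, in that order). The returned object is a plain parameter list and is
#' serializable with \code{saveRDS}.
#'
#' @param x a \linkS4class{MelFeatureSet} or a numeric matrix with one
#'   segment per row; at least two segments are required.
#' @param varianceKept fraction of variance to retain, in (0, 1].
#' @return object of class \code{FeatureTransform}: list with \code{center},
#'   \code{rotation}, \code{postMean}, \code{postSd}, \code{k} (components
#'   kept), \code{explained} (cumulative variance fractions) and
#'   \code{inputDim}.
#' @export
fitFeatureTransform <- function(x, varianceKept = 0.95) {
    stopifnot(varianceKept > 0, varianceKept <= 1)
    X <- if (is(x, "MelFeatureSet")) flattenMels(x) else as.matrix(x)
    if (nrow(X) < 2L)
        stop("need at least 2 segments to fit the feature transform")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    expl <- cumsum(v) / sum(v)
    k <- which(expl >= varianceKept - 1e-12)[1]
    scores <- pc$x[, seq_len(k), drop = FALSE]
    postMean <- colMeans(scores)
    postSd <- apply(scores, 2L, stats::sd)
    postSd[postSd < 1e-12] <- 1
    structure(list(center = pc$center,
                   rotation = pc$rotation[, seq_len(k), drop = FALSE],
                   postMean = postMean, postSd = postSd, k = k,
                   explained = expl, varianceKept = varianceKept,
                   inputDim = ncol(X)),
              class = "FeatureTransform")
}

#' Apply a fitted feature transform
#'
#' Projects new segments with the training split's PCA rotation and
#' standardization parameters -- the fitted transform is reused as-is, so no
#' test-split information leaks into it.
#'
#' @param ft a \code{FeatureTransform} from \code{\link{fitFeatureTransform}}.
#' @param x a \linkS4class{MelFeatureSet} or matrix of flattened segments.
#' @return matrix (nSegments x k) of standardized component scores.
#' @export
applyFeatureTransform <- function(ft, x) {
    stopifnot(inherits(ft, "FeatureTransform"))
    X <- if (is(x, "MelFeatureSet")) flattenMels(x) else as.matrix(x)
    if (ncol(X) != ft$inputDim)
        stop("feature dimension mismatch: got ", ncol(X), ", transform was ",
             "fitted on ", ft$inputDim)
    S <- sweep(X, 2L, ft$center) %*% ft$rotation
    sweep(sweep(S, 2L, ft$postMean), 2L, ft$postSd, "/")
}

#' @export
print.FeatureTransform <- function(x, ...) {
    cat(sprintf(
        "FeatureTransform: %d -> %d components (%.1f%% variance kept)\n",
        x$inputDim, x$k, 100 * x$explained[x$k]))
    invisible(x)
}
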