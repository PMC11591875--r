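# Synthetic cough-audio generator.
#
# Clinical cough-challenge recordings are private, so the pipeline is
# developed and tested against synthetic recordings that reproduce the
# statistical structure that matters downstream: sparse bouts of 1-6
# consecutive cough bursts whose peak amplitude declines across the bout,
# speech-like and throat-clear distractor events, long stretches of
# near-silence, and a positive-window fraction below 5% before filtering.
# Coughs are modeled as band-emphasized noise (~300-4000 Hz) under a
# fast-attack (~10 ms) exponential-decay envelope -- the "sudden, short
# amplitude spike" signature -- not as physiologically accurate acoustics.

# Nominal peak amplitude of the first cough in a bout; the noise floor is
# expressed in dB relative to this.
.REF_COUGH_PEAK <- 0.6

#' Scenario configuration for synthetic recordings
#'
#' @param duration recording length in seconds.
#' @param sampleRate sampling rate in Hz.
#' @param boutRate cough bouts per minute; the generator honors the rate
#'   exactly (\code{round(boutRate * duration / 60)} bouts), so configured
#'   event density is reproducible rather than Poisson-dispersed.
#' @param coughsPerBout inclusive integer range of coughs per bout.
#' @param boutDecay per-cough peak multiplier within a bout, in (0, 1]:
#'   cough \eqn{k} of a bout peaks at \code{boutDecay^(k-1)} times the first.
#' @param coughDuration range of single-cough durations in seconds; coughs
#'   are shorter than one second.
#' @param distractorRate non-cough events (speech-like, throat clears) per
#'   minute, also honored exactly.
#' @param noiseFloorDb background-noise RMS in dB relative to the nominal
#'   first-cough peak (negative; -40 dB is a quiet clinical room).
#' @param seed integer seed; identical configs generate bit-identical audio.
#' @return A \linkS4class{ScenarioConfig}.
#' @examples
#' cfg <- scenarioConfig(duration = 30, boutRate = 2, seed = 7)
#' rec <- generateRecording(cfg)
#' rec$recording
#' head(rec$annotations)
#' @export
scenarioConfig <- function(duration = 600, sampleRate = 22050,
                           boutRate = 2, coughsPerBout = c(1L, 4L),
                           boutDecay = 0.75,
                           coughDuration = c(0.15, 0.35),
                           distractorRate = 2, noiseFloorDb = -40,
                           seed = 1L) {
    new("ScenarioConfig", duration = as.numeric(duration),
        sampleRate = as.numeric(sampleRate), boutRate = as.numeric(boutRate),
        coughsPerBout = as.integer(coughsPerBout),
        boutDecay = as.numeric(boutDecay),
        coughDuration = as.numeric(coughDuration),
        distractorRate = as.numeric(distractorRate),
        noiseFloorDb = as.numeric(noiseFloorDb), seed = as.integer(seed))
}

# Band-passed white noise under a fast-attack / exponential-decay envelope.
.burst <- function(n, sr, lo, hi, attack = 0.01, tau) {
    x <- stats::rnorm(n)
    ny <- sr / 2
    bf <- signal::butter(1, c(max(lo, 1) / ny, min(hi, ny * 0.99) / ny),
                         type = "pass")
    x <- as.numeric(signal::filter(bf, x))
    t <- (seq_len(n) - 1) / sr
    env <- pmin(t / attack, 1) * exp(-pmax(t - attack, 0) / tau)
    x * env
}

# One cough: main burst plus, for longer coughs, a weaker second expulsion
# ~80 ms after onset. Scaled so max |amplitude| equals `peak` exactly.
.coughWave <- function(d, sr, peak) {
    n <- max(8L, round(d * sr))
    sig <- .burst(n, sr, 300, 4000, attack = 0.01, tau = d / 5)
    if (d >= 0.2) {
        off <- round(0.08 * sr)
        d2 <- min(0.1, d - 0.08 - 0.02)
        n2 <- round(d2 * sr)
        if (n2 > 8L && off + n2 <= n) {
            sig2 <- .burst(n2, sr, 300, 4000, attack = 0.008, tau = d2 / 4)
            idx <- off + seq_len(n2)
            sig[idx] <- sig[idx] + 0.4 * sig2 * max(abs(sig)) /
                max(abs(sig2), .Machine$double.eps)
        }
    }
    sig * (peak / max(abs(sig), .Machine$double.eps))
}

# Speech-like distractor: harmonic stack with slow amplitude modulation.
.speechWave <- function(d, sr, peak) {
    n <- max(8L, round(d * sr))
    t <- (seq_len(n) - 1) / sr
    f0 <- stats::runif(1, 100, 250)
    sig <- numeric(n)
    for (h in 1:5)
        sig <- sig + sin(2 * pi * f0 * h * t + stats::runif(1, 0, 2 * pi)) / h
    am <- 1 + 0.4 * sin(2 * pi * 3 * t + stats::runif(1, 0, 2 * pi))
    ramp <- pmin(1, t / 0.05, (d - t) / 0.05)
    sig <- sig * am * pmax(ramp, 0)
    sig * (peak / max(abs(sig), .Machine$double.eps))
}

# Throat clear: two weak low-frequency bursts in quick succession.
.throatClearWave <- function(sr, peak) {
    d1 <- 0.09; gap <- 0.12; d2 <- 0.09
    n <- round((d1 + gap + d2) * sr)
    sig <- numeric(n)
    b1 <- .burst(round(d1 * sr), sr, 150, 1200, attack = 0.012, tau = d1 / 3)
    b2 <- .burst(round(d2 * sr), sr, 150, 1200, attack = 0.012, tau = d2 / 3)
    sig[seq_along(b1)] <- b1 / max(abs(b1), .Machine$double.eps)
    j <- round((d1 + gap) * sr) + seq_along(b2)
    sig[j] <- sig[j] + 0.8 * b2 / max(abs(b2), .Machine$double.eps)
    sig * (peak / max(abs(sig), .Machine$double.eps))
}

# Reserve a start time for a block of `span` seconds, keeping `margin`
# seconds clear of every previously placed block. Rejection sampling with an
# explicit failure: configured rates that cannot fit the duration raise an
# error instead of silently dropping events.
.placeBlock <- function(span, durationS, placed, margin = 0.25,
                        tries = 400L) {
    lo <- 0.2
    hi <- durationS - span - 0.2
    if (hi <= lo) return(NA_real_)
    for (i in seq_len(tries)) {
        st <- stats::runif(1, lo, hi)
        en <- st + span
        if (!nrow(placed) ||
            all(st >= placed$end + margin | en <= placed$start - margin))
            return(st)
    }
    NA_real_
}

#' Generate one synthetic labeled recording
#'
#' Draws the event schedule and waveform for a \linkS4class{ScenarioConfig}:
#' Gaussian noise at the configured floor, cough bouts whose per-cough peaks
#' follow \code{boutDecay^(k-1)} exactly, and distractor events. All
#' randomness flows from the config's seed (the caller's RNG state is left
#' untouched), so identical configs give bit-identical output.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @return list with \code{recording} (\linkS4class{AudioRecording}) and
#'   \code{annotations}: a data.frame with \code{start_s}, \code{end_s},
#'   \code{label}, plus bookkeeping columns \code{bout} (bout index, NA for
#'   distractors) and \code{peak} (synthesized peak amplitude). Events never
#'   overlap and always lie within \code{[0, duration]}.
#' @export
generateRecording <- function(config) {
    stopifnot(is(config, "ScenarioConfig"))
    validObject(config)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(config@seed)

    sr <- config@sampleRate
    durS <- config@duration
    n <- round(durS * sr)
    noiseSd <- .REF_COUGH_PEAK * 10^(config@noiseFloorDb / 20)
    wave <- stats::rnorm(n, sd = noiseSd)

    nBouts <- round(config@boutRate * durS / 60)
    nDistr <- round(config@distractorRate * durS / 60)

    # Draw bout structure first so the schedule is a pure function of seed.
    bouts <- vector("list", nBouts)
    for (b in seq_len(nBouts)) {
        k <- sample(config@coughsPerBout[1]:config@coughsPerBout[2], 1L)
        d <- stats::runif(k, config@coughDuration[1], config@coughDuration[2])
        gap <- if (k > 1L) stats::runif(k - 1L, 0.2, 0.5) else numeric()
        bouts[[b]] <- list(d = d, gap = gap, span = sum(d) + sum(gap),
                           firstPeak = stats::runif(1, 0.45, 0.7))
    }
    dTypes <- if (nDistr) sample(c("speech", "throat_clear"), nDistr,
                                 replace = TRUE, prob = c(0.7, 0.3))
              else character()
    dSpan <- vapply(dTypes, function(ty)
        if (ty == "speech") stats::runif(1, 0.5, 2) else 0.3, numeric(1))
    dPeak <- vapply(dTypes, function(ty)
        if (ty == "speech") stats::runif(1, 0.07, 0.15)
        else stats::runif(1, 0.1, 0.2), numeric(1))

    placed <- data.frame(start = numeric(), end = numeric())
    ann <- list()

    addEvent <- function(st, sig, label, bout, peak) {
        i0 <- round(st * sr)
        idx <- i0 + seq_along(sig)
        wave[idx] <<- wave[idx] + sig
        ann[[length(ann) + 1L]] <<- data.frame(
            start_s = st, end_s = st + length(sig) / sr, label = label,
            bout = bout, peak = peak)
    }

    for (b in seq_len(nBouts)) {
        bt <- bouts[[b]]
        st <- .placeBlock(bt$span, durS, placed)
        if (is.na(st))
            stop("event placement impossible: bout/distractor rates too ",
                 "high for a ", durS, " s recording")
        placed <- rbind(placed, data.frame(start = st, end = st + bt$span))
        t0 <- st
        for (k in seq_along(bt$d)) {
            peak <- bt$firstPeak * config@boutDecay^(k - 1)
            addEvent(t0, .coughWave(bt$d[k], sr, peak), "cough", b, peak)
            t0 <- t0 + bt$d[k] + if (k < length(bt$d)) bt$gap[k] else 0
        }
    }
    for (j in seq_len(nDistr)) {
        st <- .placeBlock(dSpan[j], durS, placed)
        if (is.na(st))
            stop("event placement impossible: bout/distractor rates too ",
                 "high for a ", durS, " s recording")
        placed <- rbind(placed, data.frame(start = st, end = st + dSpan[j]))
        sig <- if (dTypes[j] == "speech") .speechWave(dSpan[j], sr, dPeak[j])
               else .throatClearWave(sr, dPeak[j])
        addEvent(st, sig, dTypes[j], NA_integer_, dPeak[j])
    }

    anno <- if (length(ann)) {
        out <- do.call(rbind, ann)
        out <- out[order(out$start_s), , drop = FALSE]
        rownames(out) <- NULL
        out
    } else data.frame(start_s = numeric(), end_s = numeric(),
                      label = character(), bout = integer(),
                      peak = numeric())

    rec <- AudioRecording(pmin(1, pmax(-1, wave)), sr,
                          sourceId = sprintf("synthetic_seed%d", config@seed))
    list(recording = rec, annotations = anno)
}

#' Generate a multi-subset corpus on disk
#'
#' Writes one 16-bit PCM WAV and one Audacity-style label file per config,
#' plus a tab-separated \code{manifest.tsv} recording subset membership.
#' Subsets typically differ in noise floor and distractor rate to emulate
#' distinct recording environments.
#'
#' @param configs list of \linkS4class{ScenarioConfig}.
#' @param subsetLabels character vector, one subset tag per config.
#' @param dir destination directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
generateCorpus <- function(configs, subsetLabels, dir) {
    stopifnot(length(configs) == length(subsetLabels))
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create corpus directory: ", dir)
    rows <- vector("list", length(configs))
    counter <- integer()
    for (i in seq_along(configs)) {
        sub <- subsetLabels[i]
        key <- paste0("s_", if (is.na(sub)) "NA" else sub)
        counter[key] <- if (is.na(counter[key])) 1L else counter[key] + 1L
        id <- sprintf("rec_%s_%02d", if (is.na(sub)) "NA" else sub,
                      counter[[key]])
        gen <- generateRecording(configs[[i]])
        wavPath <- file.path(dir, paste0(id, ".wav"))
        labPath <- file.path(dir, paste0(id, ".txt"))
        writeWav(gen$recording, wavPath)
        writeLabels(gen$annotations[, c("start_s", "end_s", "label")],
                    labPath)
        rows[[i]] <- data.frame(
            recording = basename(wavPath), labels = basename(labPath),
            subset = sub, duration_s = duration(gen$recording),
            sample_rate = configs[[i]]@sampleRate,
            n_events = nrow(gen$annotations),
            n_coughs = sum(gen$annotations$label == "cough"))
    }
    manifest <- if (length(rows)) do.call(rbind, rows) else
        data.frame(recording = character(), labels = character(),
                   subset = character(), duration_s = numeric(),
                   sample_rate = numeric(), n_events = integer(),
                   n_coughs = integer())
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(manifest)
}

#' Read a corpus manifest written by \code{generateCorpus}
#'
#' @param dir corpus directory containing \code{manifest.tsv}.
#' @return The manifest data.frame.
#' @export
readCorpusManifest <- function(dir) {
    path <- file.path(dir, "manifest.tsv")
    if (!file.exists(path)) stop("no manifest.tsv in: ", dir)
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(subset = "character"))
}

#' Standard three-environment corpus scenarios
#'
#' Builds the scenario configs for the two study designs the package's
#' experiments use: \code{"train"} -- three moderately different environments
#' (A quietest, C somewhat noisier) suited to end-to-end model training; and
#' \code{"crossval"} -- two clean environments plus a deliberately degraded
#' subset C (loud noise floor, frequent distractors) for probing
#' cross-environment generalization.
#'
#' @param kind \code{"train"} or \code{"crossval"}.
#' @param seed integer; per-recording seeds are derived from it.
#' @param duration per-recording length in seconds.
#' @param recordingsPerSubset recordings per environment.
#' @param boutRate cough bouts per minute.
#' @param sampleRate Hz.
#' @return list with \code{configs} (list of \linkS4class{ScenarioConfig})
#'   and \code{subsets} (character vector of subset tags).
#' @export
corpusScenarios <- function(kind = c("train", "crossval"), seed = 1L,
                            duration = 160, recordingsPerSubset = 1L,
                            boutRate = 3, sampleRate = 22050) {
    kind <- match.arg(kind)
    env <- if (kind == "train")
        data.frame(subset = c("A", "B", "C"),
                   noise = c(-40, -34, -28), distractors = c(1, 1.5, 2))
    else
        data.frame(subset = c("A", "B", "C"),
                   noise = c(-40, -32, -14), distractors = c(1, 2, 5))
    configs <- list()
    subsets <- character()
    k <- 0L
    for (e in seq_len(nrow(env))) {
        for (r in seq_len(recordingsPerSubset)) {
            k <- k + 1L
            configs[[k]] <- scenarioConfig(
                duration = duration, sampleRate = sampleRate,
                boutRate = boutRate, distractorRate = env$distractors[e],
                noiseFloorDb = env$noise[e],
                seed = (as.integer(seed) * 131L + k * 17L) %% 2147483629L)
            subsets[k] <- env$subset[e]
        }
    }
    list(configs = configs, subsets = subsets)
}
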