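# Shared fixtures, generated in code at test time.

# A short scenario with dense events, cheap to synthesize.
quickScenario <- function(duration = 20, boutRate = 6, distractorRate = 3,
                          noiseFloorDb = -40, seed = 1L, ...) {
    scenarioConfig(duration = duration, boutRate = boutRate,
                   distractorRate = distractorRate,
                   noiseFloorDb = noiseFloorDb, seed = seed, ...)
}

sineWave <- function(freq, durS = 0.5, sr = 22050, amp = 0.8)
    amp * sin(2 * pi * freq * (seq_len(round(durS * sr)) - 1) / sr)

# Random Mel-like arrays with a class-dependent mean shift, for exercising
# the CRNN machinery without audio.
fakeMelData <- function(n, nMels = 16L, nFrames = 22L, shift = 6,
                        posFrac = 0.3, seed = 99L) {
    set.seed(seed)
    y <- seq_len(n) %in% sample(n, max(1L, round(posFrac * n)))
    X <- array(rnorm(nMels * nFrames * n, mean = -60, sd = 4),
               c(nMels, nFrames, n))
    for (i in which(y))
        X[, 8:14, i] <- X[, 8:14, i] + shift
    list(X = X, y = y)
}

tinyCrnnConfig <- function(..., nMels = 16L, baseFilters = 2L,
                           lstmLayers = 2L, lstmHidden = 4L, epochs = 2L,
                           batchSize = 16L, seed = 1L)
    crnnConfig(nMels = nMels, baseFilters = baseFilters,
               lstmLayers = lstmLayers, lstmHidden = lstmHidden,
               epochs = epochs, batchSize = batchSize, seed = seed, ...)

# A tiny on-disk corpus: 3 subsets x 1 short recording.
makeTinyCorpus <- function(dir, duration = 20, seed = 5L) {
    sc <- corpusScenarios("train", seed = seed, duration = duration,
                          boutRate = 6)
    generateCorpus(sc$configs, sc$subsets, dir)
}
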