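test_that("Mel spectrograms have the contracted shape and dynamic range", {
    seg <- sineWave(440, 0.5)
    m <- melSpectrogram(seg)
    expect_equal(dim(m), c(128L, 22L))
    expect_true(all(is.finite(m)))
    expect_lte(diff(range(m)), 80)

    # all-zero segment: uniform grid at the dB floor
    m0 <- melSpectrogram(numeric(11025))
    expect_equal(dim(m0), c(128L, 22L))
    expect_equal(max(m0) - min(m0), 0)
    expect_equal(unique(as.vector(m0)), -100)
})

test_that("a 1 kHz sine lights up the Mel band containing 1 kHz in every frame", {
    m <- melSpectrogram(sineWave(1000, 0.5))
    centers <- attr(melFilterbank(22050), "centers")
    hit <- centers[apply(m, 2L, which.max)]
    # band spacing near 1 kHz is ~45 Hz; every frame must peak in the band
    # whose center is within one band of 1 kHz
    expect_true(all(abs(hit - 1000) < 100))
})

test_that("melFeatures stacks segment sets and enforces the sampling rate", {
    gen <- generateRecording(quickScenario(duration = 4, seed = 6))
    set <- windowRecording(gen$recording, gen$annotations)
    mels <- melFeatures(set, nMels = 32)
    expect_equal(dim(melValues(mels)), c(32L, 22L, nSegments(set)))
    expect_equal(segmentLabels(mels), segmentLabels(set))
    expect_error(melFeatures(set, sampleRate = 16000), "resample")

    # deterministic featurization
    expect_identical(melValues(melFeatures(set, nMels = 32)),
                     melValues(mels))
})

test_that("MFCCs are the DCT of the log-Mel energies", {
    cc <- mfcc(sineWave(440, 0.5))
    expect_equal(dim(cc), c(13L, 22L))

    # silence: constant -100 dB log spectrum -> only coefficient 0 non-zero
    cc0 <- mfcc(numeric(11025))
    expect_equal(cc0[1, ], rep(-100 * sqrt(128), 22), tolerance = 1e-9)
    expect_true(all(abs(cc0[-1, ]) < 1e-9))

    # spectral envelope differs between noise and a pure tone
    set.seed(8)
    ccNoise <- mfcc(rnorm(11025) * 0.3)
    ccSine <- mfcc(sineWave(1000, 0.5))
    expect_gt(abs(mean(ccSine[2, ]) - mean(ccNoise[2, ])), 1)
})

test_that("zero-crossing rate matches a brute-force sign-change count", {
    expect_true(all(zeroCrossingRate(rep(0.5, 11025)) == 0))
    alt <- rep(c(1, -1), length.out = 11025)
    expect_true(all(zeroCrossingRate(alt) > 0.999))

    x <- sineWave(100, 0.5)
    zcr <- zeroCrossingRate(x, frame = 2048, hop = 512)
    # oracle: direct count over the same frames
    s <- x >= 0
    oracle <- vapply(seq_along(zcr), function(t) {
        i <- (t - 1) * 512 + seq_len(2048)
        sum(s[i[-2048]] != s[i[-1]]) / 2047
    }, numeric(1))
    expect_equal(zcr, oracle, tolerance = 1e-12)
    # a 100 Hz sine crosses zero ~200 times per second
    expect_equal(mean(zcr) * 22050, 200, tolerance = 0.05)
})

test_that("spectral roll-off matches a cumulative-energy oracle and handles boundaries", {
    x <- sineWave(1000, 0.5)
    ro <- spectralRolloff(x, pct = 0.85)

    # independent oracle: plain FFT frames + cumulative sum
    half <- 1024
    padded <- c(numeric(half), x, numeric(2048))
    w <- 0.5 - 0.5 * cos(2 * pi * (0:2047) / 2048)
    oracle <- vapply(seq_along(ro), function(t) {
        fr <- padded[(t - 1) * 512 + 1:2048] * w
        p <- Mod(fft(fr)[1:1025])^2
        if (sum(p) <= 0) return(0)
        (which(cumsum(p) >= 0.85 * sum(p))[1] - 1) * 22050 / 2048
    }, numeric(1))
    expect_equal(ro, oracle, tolerance = 1e-9)

    # interior frames roll off within ~2 bins of the tone
    expect_true(all(abs(ro[3:20] - 1000) <= 2 * 22050 / 2048))

    # pct = 1 reaches the highest occupied bin; silence reports 0 Hz
    roAll <- spectralRolloff(x, pct = 1)
    expect_true(all(roAll >= ro))
    expect_true(all(spectralRolloff(numeric(11025)) == 0))
})

test_that("flattening yields 2816-dim vectors for the reference shape", {
    gen <- generateRecording(quickScenario(duration = 2, seed = 12))
    set <- windowRecording(gen$recording, gen$annotations)
    mels <- melFeatures(set)  # full 128 x 22
    X <- flattenMels(mels)
    expect_equal(ncol(X), 2816L)
    expect_equal(nrow(X), nSegments(set))
    expect_equal(X[2, ], as.vector(melValues(mels)[, , 2]))
})

test_that("PCA retains exactly the structural rank of noiseless low-rank data", {
    set.seed(31)
    scores <- matrix(rnorm(40 * 3), 40, 3) %*% diag(c(1, 0.8, 0.6))
    load <- qr.Q(qr(matrix(rnorm(2816 * 3), 2816, 3)))
    X <- scores %*% t(load)
    ft <- fitFeatureTransform(X, varianceKept = 0.95)
    expect_equal(ft$k, 3L)
    expect_gte(ft$explained[3], 1 - 1e-9)
})

test_that("retained components are standardized on the fitted split only", {
    set.seed(32)
    X <- matrix(rnorm(60 * 50, sd = rep(c(4, 1), each = 25)), 60, 50,
                byrow = TRUE)
    tr <- 1:40; te <- 41:60
    ft <- fitFeatureTransform(X[tr, ], varianceKept = 0.9)
    Ztr <- applyFeatureTransform(ft, X[tr, ])
    expect_true(all(abs(colMeans(Ztr)) < 1e-6))
    expect_true(all(abs(apply(Ztr, 2, var) - 1) < 1e-6))
    # test split uses the training parameters, so it is NOT re-centered
    Zte <- applyFeatureTransform(ft, X[te, ])
    expect_false(all(abs(colMeans(Zte)) < 1e-6))
    expect_error(applyFeatureTransform(ft, X[, 1:10]), "dimension mismatch")
    expect_error(fitFeatureTransform(X[1, , drop = FALSE]), "at least 2")
})

test_that("PCA reconstruction error is non-increasing in the variance kept", {
    set.seed(33)
    X <- matrix(rnorm(50 * 30), 50, 30) %*% matrix(rnorm(30 * 100), 30, 100)
    err <- vapply(c(0.5, 0.8, 0.99), function(v) {
        ft <- fitFeatureTransform(X, v)
        S <- sweep(X, 2, ft$center) %*% ft$rotation
        sum((sweep(X, 2, ft$center) - S %*% t(ft$rotation))^2)
    }, numeric(1))
    expect_true(all(diff(err) <= 1e-6))
})
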