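test_that("a silent recording windows into all-negative segments", {
    rec <- AudioRecording(numeric(22050 * 2), 22050, "silence")
    set <- windowRecording(rec)
    expect_equal(nSegments(set), 4L)
    expect_false(any(segmentLabels(set)))
    expect_equal(positiveFraction(set), 0)
    expect_true(all(segmentInfo(set)$mean_abs_amplitude == 0))
})

test_that("window labels follow the overlap rule on a 1217.0-1217.3-style event", {
    # same geometry as the reference example, shifted near the origin:
    # a 0.3-s cough starting exactly on a window boundary
    rec <- AudioRecording(numeric(22050 * 2), 22050)
    ann <- annotations(1.0, 1.3, "cough")
    set <- windowRecording(rec, ann)
    info <- segmentInfo(set)
    expect_false(info$label[info$start_s == 0.5])   # no overlap
    expect_true(info$label[info$start_s == 1.0])    # 0.3 s >= 0.1 s
    expect_false(info$label[info$start_s == 1.5])

    # 0.1 s of overlap is exactly enough
    set2 <- windowRecording(rec, annotations(0.4, 0.8, "cough"))
    expect_true(all(segmentInfo(set2)$label[1:2]))
    # a very short cough is caught by the half-duration rule
    set3 <- windowRecording(rec, annotations(0.47, 0.55, "cough"))
    expect_true(sum(segmentLabels(set3)) >= 1L)
    # non-cough events never make a window positive
    set4 <- windowRecording(rec, annotations(1.0, 1.4, "speech"))
    expect_false(any(segmentLabels(set4)))
})

test_that("window count is ceil(duration/stride) and trailing windows are zero-padded", {
    rec <- AudioRecording(rep(0.5, round(22050 * 2.3)), 22050)
    set <- windowRecording(rec)
    expect_equal(nSegments(set), ceiling(2.3 / 0.5))
    info <- segmentInfo(set)
    expect_equal(info$end_s[5], 2.5)
    # padded tail: samples come back full-length with zeros past the end
    tail5 <- segmentSamples(set, 5)
    expect_length(tail5, 11025L)
    expect_true(all(tail5[(round(0.3 * 22050) + 1):11025] == 0))
    # mean_abs is computed on the unpadded samples
    expect_equal(info$mean_abs_amplitude[5], 0.5, tolerance = 1e-9)

    # overlapping stride also tiles [0, duration)
    set2 <- windowRecording(rec, stride = 0.25)
    expect_equal(nSegments(set2), ceiling(2.3 / 0.25))
})

test_that("amplitude filter keeps every positive and never lowers the positive fraction", {
    # hand-built toy: 10 quiet negatives + 1 quiet positive, global mean 0.2
    rec <- AudioRecording(numeric(22050 * 5 + 11025), 22050)
    set <- windowRecording(rec)
    set@info$mean_abs_amplitude <- c(rep(0.1, 10), 0.05)
    set@info$label <- c(rep(FALSE, 10), TRUE)
    out <- amplitudeFilter(set, globalMean = 0.2)
    expect_equal(nSegments(out), 1L)
    expect_true(all(segmentLabels(out)))
    expect_equal(positiveFraction(out), 1.0)

    # all segments above the global mean: filter is the identity
    set@info$mean_abs_amplitude <- rep(0.5, 11)
    expect_equal(segmentInfo(amplitudeFilter(set, 0.2)),
                 segmentInfo(set))

    # property over random segment sets
    set.seed(4)
    for (i in 1:25) {
        set@info$mean_abs_amplitude <- runif(11, 0, 0.4)
        set@info$label <- runif(11) < 0.3
        g <- runif(1, 0, 0.4)
        out <- amplitudeFilter(set, g)
        expect_equal(sum(segmentLabels(out)), sum(segmentLabels(set)))
        if (nSegments(out) > 0 && any(segmentLabels(set)))
            expect_gte(positiveFraction(out), positiveFraction(set))
    }
})

test_that("amplitude filtering a synthetic recording raises the positive fraction", {
    gen <- generateRecording(quickScenario(duration = 30, seed = 9))
    set <- windowRecording(gen$recording, gen$annotations)
    out <- amplitudeFilter(set)
    expect_gt(positiveFraction(out), positiveFraction(set))
    expect_equal(sum(segmentLabels(out)), sum(segmentLabels(set)))
})

test_that("trimSilence removes long quiet runs and its time map preserves annotations", {
    # all-silent input disappears entirely
    silent <- AudioRecording(numeric(22050 * 3), 22050)
    ts <- trimSilence(silent)
    expect_equal(length(samples(ts$recording)), 0L)
    expect_equal(nrow(ts$map), 0L)

    # no sub-threshold run longer than minGap: recording unchanged
    busy <- AudioRecording(sineWave(500, 3, amp = 0.5), 22050)
    ts2 <- trimSilence(busy)
    expect_equal(samples(ts2$recording), samples(busy))

    # mostly-silent synthetic recording shrinks; events survive the map
    gen <- generateRecording(scenarioConfig(duration = 60, boutRate = 3,
                                            distractorRate = 1,
                                            noiseFloorDb = -60, seed = 13))
    ts3 <- trimSilence(gen$recording, relThreshold = 0.5)
    expect_lt(duration(ts3$recording), 60)
    expect_true(all(diff(ts3$map$new_start_s) > 0))
    expect_true(all(ts3$map$orig_end_s <= 60 + 1e-9))
    mapped <- applyTimeMap(ts3$map, gen$annotations)
    expect_equal(nrow(mapped), nrow(gen$annotations))
    expect_true(all(mapped$end_s > mapped$start_s))
    expect_true(all(mapped$end_s <= duration(ts3$recording) + 1e-6))
})

test_that("segment tables export as CSV", {
    gen <- generateRecording(quickScenario(duration = 5, seed = 2))
    set <- windowRecording(gen$recording, gen$annotations)
    path <- withr::local_tempfile(fileext = ".csv")
    writeSegmentTable(set, path)
    back <- read.csv(path)
    expect_equal(nrow(back), nSegments(set))
    expect_equal(back$label, segmentLabels(set))
})
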