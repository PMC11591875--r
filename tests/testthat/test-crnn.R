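test_that("the positive-class weight is n_false/n_true and up-weights the minority", {
    expect_equal(classWeight(100, 100)$wTrue, 1)
    expect_equal(classWeight(74, 926)$wTrue, 926 / 74, tolerance = 1e-12)
    expect_gt(classWeight(74, 926)$wTrue, 1)
    # strictly decreasing in nTrue at fixed nFalse
    w <- vapply(c(10, 50, 200, 900), function(nt) classWeight(nt, 900)$wTrue,
                numeric(1))
    expect_true(all(diff(w) < 0))
    expect_error(classWeight(0, 10), "no positive")
    expect_error(classWeight(10, 0), "no negative")
})

test_that("the weighted loss reduces to BCE at weight 1 and scales only the positive term", {
    expect_equal(weightedLoss(1, 0.5, 1), log(2), tolerance = 1e-12)
    expect_equal(weightedLoss(0, 0.5, 12.5), log(2), tolerance = 1e-12)
    expect_equal(weightedLoss(1, 0.5, 926 / 74), (926 / 74) * log(2),
                 tolerance = 1e-12)
    expect_equal(weightedLoss(1, 0.5, 12.514), 8.674, tolerance = 1e-3)

    set.seed(41)
    y <- runif(200) < 0.5
    p <- runif(200, 0.01, 0.99)
    bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    expect_equal(weightedLoss(y, p, 1), bce, tolerance = 1e-12)
    expect_equal(weightedLoss(y, p, classWeight(5, 5)), bce,
                 tolerance = 1e-12)

    # loss is minimized at p = y for either class, any weight
    grid <- seq(0.01, 0.99, by = 0.01)
    for (w in c(1, 3, 12.5)) {
        l1 <- vapply(grid, function(p) weightedLoss(1, p, w), numeric(1))
        expect_equal(grid[which.min(l1)], 0.99)
        l0 <- vapply(grid, function(p) weightedLoss(0, p, w), numeric(1))
        expect_equal(grid[which.min(l0)], 0.01)
    }
    # clamping keeps the loss finite at the boundaries
    expect_true(is.finite(weightedLoss(1, 0, 5)))
    expect_true(is.finite(weightedLoss(0, 1, 5)))
})

test_that("config invariants are enforced at construction", {
    cfg <- crnnConfig()
    expect_equal(cfg$lstmInput, 1024L)
    expect_equal(cfg$channels, c(128L, 256L, 512L, 1024L))
    expect_error(crnnConfig(lstmInput = 512), "lstmInput must equal")
    expect_error(crnnConfig(nMels = 100), "divisible")
    expect_silent(crnnConfig(nMels = 16, baseFilters = 2, lstmInput = 16))
})

test_that("forward pass is well-posed and shape-consistent on a tiny model", {
    cfg <- tinyCrnnConfig()
    mdl <- buildCrnn(cfg)
    X <- array(0, c(16, 22, 3))
    p <- predictCrnn(mdl, X, details = TRUE)
    expect_length(p, 3L)
    expect_true(all(p > 0 & p < 1))
    tr <- attr(p, "trace")
    expect_equal(tr$convChannels, c(2L, 4L, 8L, 16L))
    expect_equal(tr$seqLen, 22L)
    expect_equal(tr$lstmInput, cfg$lstmInput)
    expect_error(predictCrnn(mdl, array(0, c(8, 22, 3))), "shape")
})

test_that("training records history, maintains the checkpoint triple, and is deterministic", {
    dat <- fakeMelData(60, seed = 101)
    sp <- trainTestSplit(dat$y, 0.2, seed = 1)
    run <- function(seed = 3, epochs = 3) {
        cfg <- tinyCrnnConfig(epochs = epochs, seed = seed)
        trainCrnn(buildCrnn(cfg),
                  dat$X[, , sp$train], dat$y[sp$train],
                  dat$X[, , sp$test], dat$y[sp$test])
    }
    fit <- run()
    expect_equal(nrow(fit$history), 3L)
    expect_equal(fit$history$epoch, 1:3)
    long <- historyLong(fit$history)
    expect_equal(nrow(long), 6L)
    expect_setequal(unique(long$split), c("train", "test"))

    # best-mixed checkpoint dominates every recorded epoch
    mixed <- fit$history$test_accuracy + fit$history$test_sensitivity
    expect_gte(fit$checkpoints$bestMixed$score, max(mixed, na.rm = TRUE))
    expect_gte(fit$checkpoints$bestAccuracy$score,
               max(fit$history$test_accuracy, na.rm = TRUE))
    expect_true(fit$checkpoints$bestMixed$model$trained)

    # full determinism given (seed, data, config)
    fit2 <- run()
    expect_identical(fit$model$params, fit2$model$params)
    expect_identical(fit$history, fit2$history)

    # single-class training split is rejected
    expect_error(trainCrnn(buildCrnn(tinyCrnnConfig()),
                           dat$X[, , which(!dat$y)[1:10]],
                           rep(FALSE, 10),
                           dat$X[, , sp$test], dat$y[sp$test]),
                 "both classes")
})

test_that("predictions are deterministic, bounded, and separate the synthetic classes", {
    dat <- fakeMelData(80, shift = 10, seed = 103)
    sp <- trainTestSplit(dat$y, 0.25, seed = 2)
    cfg <- tinyCrnnConfig(epochs = 6, seed = 5)
    fit <- trainCrnn(buildCrnn(cfg),
                     dat$X[, , sp$train], dat$y[sp$train],
                     dat$X[, , sp$test], dat$y[sp$test])
    p1 <- predictCrnn(fit$model, dat$X[, , sp$test])
    p2 <- predictCrnn(fit$model, dat$X[, , sp$test])
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    yte <- dat$y[sp$test]
    expect_gt(mean(p1[yte]), mean(p1[!yte]))
})

test_that("checkpoints survive a save/load round trip", {
    dat <- fakeMelData(40, seed = 104)
    cfg <- tinyCrnnConfig(epochs = 2, seed = 7)
    fit <- trainCrnn(buildCrnn(cfg), dat$X[, , 1:30], dat$y[1:30],
                     dat$X[, , 31:40], dat$y[31:40])
    path <- withr::local_tempfile(fileext = ".rds")
    saveCrnn(fit$checkpoints$bestMixed, path)
    back <- loadCrnn(path)
    expect_identical(back$model$params, fit$checkpoints$bestMixed$model$params)
    expect_identical(predictCrnn(back$model, dat$X[, , 31:40]),
                     predictCrnn(fit$checkpoints$bestMixed$model,
                                 dat$X[, , 31:40]))
})
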