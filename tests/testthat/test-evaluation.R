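test_that("metrics match hand-computed confusion ratios", {
    y <- c(rep(TRUE, 8), rep(FALSE, 92))
    p <- c(rep(TRUE, 3), rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 90))
    rep <- computeMetrics(y, p)
    expect_equal(confusionCounts(rep),
                 c(tp = 3L, tn = 90L, fp = 2L, fn = 5L))
    expect_equal(accuracy(rep), 0.93)
    expect_equal(sensitivity(rep), 0.375)
    expect_equal(specificity(rep), 90 / 92)
    expect_equal(mixedScore(rep), 0.93 + 0.375)

    perfect <- computeMetrics(y, y)
    expect_equal(accuracy(perfect), 1)
    expect_equal(sensitivity(perfect), 1)
    expect_equal(specificity(perfect), 1)

    expect_error(computeMetrics(y, p[-1]), "length")
})

test_that("the all-negative predictor on a 7.4%-positive set scores 92.6%", {
    n <- 1000L
    y <- seq_len(n) <= 74L
    rep <- computeMetrics(y, rep(FALSE, n))
    expect_equal(accuracy(rep), 0.926)
    expect_equal(sensitivity(rep), 0)
    expect_equal(baselineAccuracy(0.074), 0.926)
    expect_equal(baselineAccuracy(0), 1)
    expect_equal(baselineAccuracy(0.5), 0.5)
})

test_that("zero-denominator ratios are NA with a warning, never 0 or 1", {
    expect_warning(rep <- computeMetrics(c(FALSE, FALSE), c(FALSE, TRUE)),
                   "sensitivity undefined")
    expect_true(is.na(sensitivity(rep)))
    expect_true(is.na(mixedScore(rep)))
    expect_false(is.na(specificity(rep)))
})

test_that("metric formulas agree with a brute-force oracle on random pairs", {
    set.seed(71)
    for (rep_i in 1:20) {
        n <- 50
        y <- runif(n) < runif(1, 0.1, 0.9)
        p <- runif(n) < runif(1, 0.1, 0.9)
        if (!any(y) || all(y)) next
        r <- computeMetrics(y, p, warn = FALSE)
        # oracle: literal per-case counting
        tp <- 0; tn <- 0; fp <- 0; fn <- 0
        for (i in seq_len(n)) {
            if (y[i] && p[i]) tp <- tp + 1
            else if (!y[i] && !p[i]) tn <- tn + 1
            else if (!y[i] && p[i]) fp <- fp + 1
            else fn <- fn + 1
        }
        expect_equal(accuracy(r), (tp + tn) / n)
        if (tp + fn > 0) expect_equal(sensitivity(r), tp / (tp + fn))
        if (tn + fp > 0) expect_equal(specificity(r), tn / (tn + fp))
        # algebraic identity: acc = sens*pi + spec*(1-pi)
        if (!is.na(sensitivity(r)) && !is.na(specificity(r)))
            expect_equal(accuracy(r),
                         sensitivity(r) * mean(y) +
                             specificity(r) * (1 - mean(y)))
    }
})

test_that("ROC endpoints, AUC oracle and monotone-transform invariance hold", {
    y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
    roc <- rocCurve(y, as.numeric(y))
    expect_equal(roc$auc, 1)
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(roc$points$tpr[1], 0)
    expect_equal(tail(roc$points$fpr, 1), 1)
    expect_equal(tail(roc$points$tpr, 1), 1)

    expect_error(rocCurve(rep(TRUE, 5), rnorm(5)), "both classes")

    # AUC equals the pairwise Mann-Whitney probability to 1e-9
    set.seed(72)
    for (i in 1:10) {
        y <- runif(40) < 0.4
        if (!any(y) || all(y)) next
        s <- round(rnorm(40, mean = y), 1)  # rounding forces ties
        auc <- rocCurve(y, s)$auc
        pos <- s[y]; neg <- s[!y]
        mw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
        expect_equal(auc, mw, tolerance = 1e-9)
        # invariance under strictly monotone transforms
        expect_equal(rocCurve(y, exp(2 * s))$auc, auc, tolerance = 1e-12)
    }

    # independent labels: AUC near 1/2 at n = 2000
    set.seed(73)
    y <- runif(2000) < 0.5
    s <- rnorm(2000)
    expect_lt(abs(rocCurve(y, s)$auc - 0.5), 0.05)
})

test_that("AUC agrees with the pROC reference implementation", {
    set.seed(74)
    y <- runif(300) < 0.3
    s <- rnorm(300, mean = y)
    ours <- rocCurve(y, s)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("stratified splits keep both classes and the requested fraction", {
    y <- c(rep(TRUE, 20), rep(FALSE, 180))
    sp <- trainTestSplit(y, 0.1, seed = 5)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_along(y))
    expect_equal(sum(y[sp$test]), 2L)
    expect_equal(length(sp$test), 20L)
    expect_identical(trainTestSplit(y, 0.1, seed = 5), sp)
})

test_that("crossValidate fills the (subsets+1) x subsets grid and flags degenerate subsets", {
    set.seed(75)
    n <- 240
    subsets <- rep(c("A", "B", "C"), each = n / 3)
    y <- runif(n) < 0.3
    X <- matrix(rnorm(n * 6), n, 6) + 2 * y
    factory <- function(x, yy, seed) {
        fit <- fitBaseline("logistic_regression", x, yy, seed)
        list(score = function(nx) scoreBaseline(fit, nx), threshold = 0.5)
    }
    mat <- crossValidate(X, y, subsets, factory, seed = 2,
                         testFraction = 0.2)
    expect_equal(nrow(mat), 12L)
    expect_setequal(unique(mat$train), c("A", "B", "C", "full"))
    expect_setequal(unique(mat$test), c("A", "B", "C"))
    expect_true(all(!is.na(mat$accuracy)))
    # statistically identical subsets: diagonal metrics are comparable
    diagAcc <- mat$accuracy[mat$train == mat$test]
    expect_lt(max(diagAcc) - min(diagAcc), 0.35)

    # a single-class subset is skipped with a warning and NA rows
    y2 <- y
    y2[subsets == "B"] <- FALSE
    expect_warning(mat2 <- crossValidate(X, y2, subsets, factory, seed = 2,
                                         testFraction = 0.2),
                   "skipped")
    expect_equal(nrow(mat2), 12L)
    expect_true(all(is.na(mat2$accuracy[mat2$test == "B"])))

    expect_error(crossValidate(X, y, rep("A", n), factory), "at least 2")
})

test_that("metricsTable lines up one row per model", {
    r <- computeMetrics(c(TRUE, FALSE), c(TRUE, FALSE))
    tab <- metricsTable(list(a = r, b = r))
    expect_equal(tab$model, c("a", "b"))
    expect_equal(tab$accuracy, c(1, 1))
})
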