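# Evaluation: confusion-matrix metrics, ROC/AUC, the all-negative baseline
# accuracy, stratified splitting, and the cross-environment generalization
# matrix.

#' Accuracy, sensitivity and specificity from binary predictions
#'
#' Computes the confusion counts and
#' \deqn{accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{specificity = TN/(TN+FP)}
#' \deqn{sensitivity = TP/(TP+FN)}
#' Ratios with a zero denominator are reported as \code{NA} (with a warning),
#' never silently coerced to 0 or 1 -- coercion corrupts averages across
#' cross-validation cells.
#'
#' @param labels true binary labels (logical or 0/1).
#' @param predictions predicted binary labels, same length.
#' @param auc optional AUC to embed in the report.
#' @param warn warn on undefined ratios.
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' computeMetrics(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
#' @export
computeMetrics <- function(labels, predictions, auc = NA_real_, warn = TRUE) {
    if (length(labels) != length(predictions))
        stop("labels and predictions differ in length")
    y <- as.logical(labels)
    p <- as.logical(predictions)
    tp <- sum(y & p); tn <- sum(!y & !p)
    fp <- sum(!y & p); fn <- sum(y & !p)
    total <- tp + tn + fp + fn
    ratio <- function(num, den, what) {
        if (den == 0) {
            if (warn) warning(what, " undefined (zero denominator), ",
                              "reported as NA", call. = FALSE)
            return(NA_real_)
        }
        num / den
    }
    acc <- ratio(tp + tn, total, "accuracy")
    sens <- ratio(tp, tp + fn, "sensitivity")
    spec <- ratio(tn, tn + fp, "specificity")
    new("MetricsReport", tp = as.integer(tp), tn = as.integer(tn),
        fp = as.integer(fp), fn = as.integer(fn), accuracy = acc,
        sensitivity = sens, specificity = spec, mixed = acc + sens,
        auc = as.numeric(auc))
}

#' ROC curve and AUC
#'
#' Thresholds are taken at every distinct score value (plus the trivial
#' all-negative endpoint), giving the exact small-sample curve from (0,0) to
#' (1,1); the AUC is the trapezoidal area, which for this construction
#' equals the probability that a random positive outscores a random negative
#' (ties counted half).
#'
#' @param labels binary labels; both classes must be present.
#' @param scores continuous scores, higher = more cough-like.
#' @return list with \code{points} (data.frame \code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{auc}.
#' @export
rocCurve <- function(labels, scores) {
    y <- as.logical(labels)
    stopifnot(length(y) == length(scores))
    if (!any(y) || all(y))
        stop("ROC requires both classes in `labels`")
    ord <- order(scores, decreasing = TRUE)
    y <- y[ord]
    s <- scores[ord]
    P <- sum(y)
    N <- length(y) - P
    last <- cumsum(rle(s)$lengths)  # last index of each distinct score
    tpr <- c(0, cumsum(y)[last] / P)
    fpr <- c(0, cumsum(!y)[last] / N)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(points = data.frame(threshold = c(Inf, s[last]),
                             fpr = fpr, tpr = tpr),
         auc = auc)
}

#' Accuracy of the constant all-negative predictor
#'
#' On a set with positive fraction \eqn{\pi} the majority-class predictor
#' scores \eqn{1 - \pi}; every useful model must beat this reference.
#'
#' @param positiveFraction fraction of positive segments, in [0, 1].
#' @return \code{1 - positiveFraction}.
#' @examples
#' baselineAccuracy(0.074)  # 0.926
#' @export
baselineAccuracy <- function(positiveFraction) {
    stopifnot(positiveFraction >= 0, positiveFraction <= 1)
    1 - positiveFraction
}

#' Stratified train/test split
#'
#' Holds out \code{testFraction} of each class (at least one element per
#' class present), seeded for reproducibility.
#'
#' @param labels logical labels.
#' @param testFraction held-out fraction (default the 10\% protocol).
#' @param seed integer seed.
#' @return list of integer index vectors \code{train}, \code{test}.
#' @export
trainTestSplit <- function(labels, testFraction = 0.1, seed = 1L) {
    stopifnot(testFraction > 0, testFraction < 1)
    y <- as.logical(labels)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    test <- integer()
    for (cls in unique(y)) {
        idx <- which(y == cls)
        nTest <- max(1L, round(length(idx) * testFraction))
        test <- c(test, sample(idx, min(nTest, length(idx) - 1L)))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(y), test), test = test)
}

# Row/segment slicing that works for both feature matrices and Mel arrays.
.sliceX <- function(x, idx) {
    if (is(x, "MelFeatureSet")) x <- melValues(x)
    if (is.matrix(x)) x[idx, , drop = FALSE]
    else if (length(dim(x)) == 3L) x[, , idx, drop = FALSE]
    else stop("x must be a matrix, 3-d array, or MelFeatureSet")
}

.nObs <- function(x) {
    if (is(x, "MelFeatureSet")) return(nSegments(x))
    if (is.matrix(x)) nrow(x) else dim(x)[3]
}

#' Cross-environment generalization matrix
#'
#' Fits one model per training source -- each subset plus the pooled
#' \code{"full"} corpus -- and evaluates every fit on the held-out portion of
#' every subset: a (nSubsets + 1) x nSubsets grid of metrics. Within each
#' subset a stratified \code{testFraction} split is drawn once with the
#' shared seed; training always uses train portions only, and every cell is
#' evaluated on held-out segments, so the diagonal is not resubstitution.
#'
#' @param x features: matrix (segments x dims), 3-d Mel array, or
#'   \linkS4class{MelFeatureSet}.
#' @param labels logical segment labels.
#' @param subsets character subset tag per segment.
#' @param factory \code{function(x, y, seed)} returning a fitted predictor:
#'   a list with \code{score(x)} (continuous, higher = cough) and
#'   \code{threshold}. See \code{\link{baselineFactory}}.
#' @param seed shared seed for splitting and fitting.
#' @param testFraction held-out fraction per subset.
#' @return data.frame with one row per (train source, test subset):
#'   accuracy, sensitivity, specificity, auc and confusion counts. Subsets
#'   whose training portion has a single class are skipped with a warning
#'   (their rows carry NA metrics).
#' @export
crossValidate <- function(x, labels, subsets, factory, seed = 1L,
                          testFraction = 0.1) {
    y <- as.logical(labels)
    subsets <- as.character(subsets)
    stopifnot(.nObs(x) == length(y), length(y) == length(subsets))
    subs <- unique(subsets)
    if (length(subs) < 2L)
        stop("cross-validation needs at least 2 subsets")
    trainIdx <- list()
    testIdx <- list()
    for (s in subs) {
        idx <- which(subsets == s)
        if (length(unique(y[idx])) < 2L) {
            trainIdx[[s]] <- integer()
            testIdx[[s]] <- integer()
            next
        }
        sp <- trainTestSplit(y[idx], testFraction, seed)
        trainIdx[[s]] <- idx[sp$train]
        testIdx[[s]] <- idx[sp$test]
    }
    sources <- c(subs, "full")
    rows <- list()
    for (src in sources) {
        tr <- if (src == "full") sort(unlist(trainIdx))
              else trainIdx[[src]]
        fitted <- NULL
        if (length(tr) && length(unique(y[tr])) == 2L) {
            fitted <- factory(.sliceX(x, tr), y[tr], seed)
        } else {
            warning("training source '", src, "' skipped: single-class or ",
                    "empty training data", call. = FALSE)
        }
        for (s in subs) {
            te <- testIdx[[s]]
            if (is.null(fitted) || !length(te) ||
                length(unique(y[te])) < 2L) {
                rows[[length(rows) + 1L]] <- data.frame(
                    train = src, test = s, n = length(te),
                    accuracy = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_, auc = NA_real_,
                    tp = NA_integer_, tn = NA_integer_,
                    fp = NA_integer_, fn = NA_integer_)
                next
            }
            sc <- fitted$score(.sliceX(x, te))
            roc <- rocCurve(y[te], sc)
            rep <- computeMetrics(y[te], sc >= fitted$threshold,
                                  auc = roc$auc, warn = FALSE)
            cc <- confusionCounts(rep)
            rows[[length(rows) + 1L]] <- data.frame(
                train = src, test = s, n = length(te),
                accuracy = accuracy(rep), sensitivity = sensitivity(rep),
                specificity = specificity(rep), auc = aucValue(rep),
                tp = cc["tp"], tn = cc["tn"], fp = cc["fp"], fn = cc["fn"])
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Render metrics reports as a model-comparison table
#'
#' @param reports named list of \linkS4class{MetricsReport}.
#' @return data.frame with one row per model (accuracy, sensitivity,
#'   specificity, auc).
#' @export
metricsTable <- function(reports) {
    stopifnot(length(reports) > 0L, !is.null(names(reports)))
    do.call(rbind, lapply(names(reports), function(nm) {
        r <- reports[[nm]]
        data.frame(model = nm, accuracy = accuracy(r),
                   sensitivity = sensitivity(r),
                   specificity = specificity(r), auc = aucValue(r))
    }))
}
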