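# The cough classifier: a residual convolutional encoder feeding a
# multi-layer LSTM and a fully connected head, trained with class-imbalance
# weighted binary cross-entropy.
#
# Architecture, per convolution block k (reference configuration):
#   main path:  3x3 conv -> (+ residual) -> batch norm -> ReLU ->
#               3x3 conv -> batch norm -> ReLU -> 2x max pool (frequency)
#   residual:   width-1 (pointwise) projection of the block input to the
#               block's channel count, added to the first convolution's
#               output.
# Channels go 1 -> 128 -> 256 -> 512 -> 1024 across four blocks while the
# frequency axis shrinks 128 -> 8; the remaining 8 frequency rows are
# mean-pooled, yielding a 22-step sequence of 1024-dim features for a
# 4-layer LSTM (hidden 512) whose final hidden state drives a sigmoid unit.

#' CRNN configuration
#'
#' Reference values give the full-size model (128 base filters, LSTM input
#' 1024 / hidden 512). The LSTM input size is structural:
#' \code{baseFilters * 2^(nConvBlocks - 1)}; passing an inconsistent
#' \code{lstmInput} is a construction error. Reduced configurations (fewer
#' Mel bands, fewer filters) keep the same architecture at desk scale.
#'
#' @param nMels,nFrames input grid shape; \code{nMels} must be divisible by
#'   \code{2^nConvBlocks}.
#' @param baseFilters channels of the first block; doubled per block.
#' @param nConvBlocks number of residual convolution blocks.
#' @param lstmLayers,lstmHidden recurrent depth and hidden size.
#' @param lstmInput optional; must equal
#'   \code{baseFilters * 2^(nConvBlocks-1)} when given.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param weighted use the class-weighted loss (weight
#'   \code{nFalse / nTrue} from the training split) instead of plain BCE.
#' @param headMode read the LSTM's final time step (\code{"last"}) or the
#'   mean over steps (\code{"mean"}).
#' @param seed integer seed covering initialization and batch shuffling.
#' @return list of class \code{CRNNConfig}.
#' @export
crnnConfig <- function(nMels = 128L, nFrames = 22L, baseFilters = 128L,
                       nConvBlocks = 4L, lstmLayers = 4L, lstmHidden = 512L,
                       lstmInput = NULL, epochs = 50L, batchSize = 64L,
                       learningRate = 1e-3, weighted = TRUE,
                       headMode = c("last", "mean"), seed = 1L) {
    headMode <- match.arg(headMode)
    nMels <- as.integer(nMels)
    nConvBlocks <- as.integer(nConvBlocks)
    baseFilters <- as.integer(baseFilters)
    expected <- baseFilters * 2L^(nConvBlocks - 1L)
    if (!is.null(lstmInput) && as.integer(lstmInput) != expected)
        stop("invalid CRNN configuration: lstmInput must equal ",
             "baseFilters * 2^(nConvBlocks-1) = ", expected)
    if (nMels %% 2L^nConvBlocks != 0L)
        stop("nMels must be divisible by 2^nConvBlocks = ", 2L^nConvBlocks)
    structure(list(
        nMels = nMels, nFrames = as.integer(nFrames),
        baseFilters = baseFilters, nConvBlocks = nConvBlocks,
        lstmLayers = as.integer(lstmLayers),
        lstmHidden = as.integer(lstmHidden), lstmInput = expected,
        epochs = as.integer(epochs), batchSize = as.integer(batchSize),
        learningRate = learningRate, weighted = isTRUE(weighted),
        headMode = headMode, seed = as.integer(seed),
        channels = baseFilters * 2L^(seq_len(nConvBlocks) - 1L)),
        class = "CRNNConfig")
}

#' @export
print.CRNNConfig <- function(x, ...) {
    cat(sprintf(paste0(
        "CRNNConfig: input %d x %d, conv channels %s, LSTM %d x %d",
        " (input %d), %s loss, %d epochs\n"),
        x$nMels, x$nFrames, paste(x$channels, collapse = "->"),
        x$lstmLayers, x$lstmHidden, x$lstmInput,
        if (x$weighted) "weighted" else "unweighted", x$epochs))
    invisible(x)
}

#' Positive-class weight for imbalanced training
#'
#' The weight applied to the positive (cough) term of the loss:
#' \code{wTrue = nFalse / nTrue}, so minority positives are up-weighted
#' whenever negatives dominate (\code{wTrue > 1} iff \code{nFalse > nTrue}).
#'
#' @param nTrue,nFalse counts of positive and negative training segments;
#'   both must be positive (the weight is undefined without positives).
#' @return list of class \code{ClassWeight} with \code{nTrue}, \code{nFalse},
#'   \code{wTrue}.
#' @examples
#' classWeight(74, 926)$wTrue  # ~12.51 at a 7.4% positive rate
#' @export
classWeight <- function(nTrue, nFalse) {
    if (nTrue <= 0) stop("class weighting undefined: no positive segments")
    if (nFalse <= 0) stop("class weighting undefined: no negative segments")
    structure(list(nTrue = nTrue, nFalse = nFalse, wTrue = nFalse / nTrue),
              class = "ClassWeight")
}

#' Class-weighted binary cross-entropy
#'
#' \deqn{L = -[w_{true} \, y \log p + (1-y) \log(1-p)]}{
#'   L = -(wTrue * y * log(p) + (1-y) * log(1-p))}
#' averaged over the batch, with probabilities clamped 1e-7 away from 0 and
#' 1. With \code{wTrue = 1} this is ordinary binary cross-entropy; the
#' weight touches only the positive term.
#'
#' @param y binary labels (0/1 or logical).
#' @param p predicted probabilities.
#' @param wTrue positive-class weight (a number or a \code{ClassWeight}).
#' @return mean loss, a non-negative scalar.
#' @export
weightedLoss <- function(y, p, wTrue = 1) {
    if (inherits(wTrue, "ClassWeight")) wTrue <- wTrue$wTrue
    stopifnot(length(y) == length(p))
    y <- as.numeric(y)
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    mean(-(wTrue * y * log(p) + (1 - y) * log(1 - p)))
}

#' Build an untrained CRNN
#'
#' Allocates and seeds all parameters: He-scaled 3x3 convolutions and
#' pointwise residual projections, unit/zero batch-norm affines,
#' uniform \eqn{\pm 1/\sqrt{hidden}} LSTM weights with forget-gate bias 1,
#' and a zero-initialized head.
#'
#' @param config a \code{\link{crnnConfig}}.
#' @return list of class \code{CRNNModel} with \code{config}, \code{params},
#'   \code{running} (batch-norm statistics) and \code{trained} flag.
#' @export
buildCrnn <- function(config) {
    stopifnot(inherits(config, "CRNNConfig"))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    nb <- config$nConvBlocks
    cin <- c(1L, config$channels[-nb])
    cout <- config$channels
    params <- list()
    running <- list()
    for (k in seq_len(nb)) {
        p <- sprintf("b%d_", k)
        params[[paste0(p, "conv1W")]] <- matrix(
            stats::rnorm(cout[k] * cin[k] * 9L, sd = sqrt(2 / (cin[k] * 9))),
            cout[k], cin[k] * 9L)
        params[[paste0(p, "conv1b")]] <- numeric(cout[k])
        params[[paste0(p, "projW")]] <- matrix(
            stats::rnorm(cout[k] * cin[k], sd = sqrt(2 / cin[k])),
            cout[k], cin[k])
        params[[paste0(p, "conv2W")]] <- matrix(
            stats::rnorm(cout[k] * cout[k] * 9L, sd = sqrt(2 / (cout[k] * 9))),
            cout[k], cout[k] * 9L)
        params[[paste0(p, "conv2b")]] <- numeric(cout[k])
        for (bn in c("bn1", "bn2")) {
            params[[paste0(p, bn, "g")]] <- rep(1, cout[k])
            params[[paste0(p, bn, "b")]] <- numeric(cout[k])
            running[[paste0(p, bn, "m")]] <- numeric(cout[k])
            running[[paste0(p, bn, "v")]] <- rep(1, cout[k])
        }
    }
    hid <- config$lstmHidden
    for (l in seq_len(config$lstmLayers)) {
        inDim <- if (l == 1L) config$lstmInput else hid
        r <- 1 / sqrt(hid)
        params[[sprintf("lstm_Wx%d", l)]] <- matrix(
            stats::runif(4L * hid * inDim, -r, r), 4L * hid, inDim)
        params[[sprintf("lstm_Wh%d", l)]] <- matrix(
            stats::runif(4L * hid * hid, -r, r), 4L * hid, hid)
        b <- numeric(4L * hid)
        b[hid + seq_len(hid)] <- 1  # forget-gate bias
        params[[sprintf("lstm_b%d", l)]] <- b
    }
    params$head_W <- matrix(0, 1L, hid)
    params$head_b <- 0
    structure(list(config = config, params = params, running = running,
                   trained = FALSE),
              class = "CRNNModel")
}

#' @export
print.CRNNModel <- function(x, ...) {
    np <- sum(vapply(x$params, length, numeric(1)))
    cat(sprintf("CRNNModel (%s): %s parameters\n",
                if (x$trained) "trained" else "untrained",
                format(np, big.mark = ",")))
    print(x$config)
    invisible(x)
}

# Fixed affine input scaling: dB values (~[-100, 0]) are mapped to a range
# the first convolution sees as roughly unit-scale.
.scaleInput <- function(X) (as.numeric(X) + 40) / 20

# Full forward pass. X: (nMels, nFrames, B) array. Returns probabilities,
# updated running stats, and (optionally) every intermediate needed for the
# backward pass plus the traced shapes.
.crnnForward <- function(params, running, cfg, X, plans, train = FALSE,
                         keep = FALSE) {
    d <- dim(X)
    B <- d[3]
    H <- d[1]
    W <- d[2]
    A <- matrix(.scaleInput(X), nrow = 1L)
    nb <- cfg$nConvBlocks
    cin <- c(1L, cfg$channels[-nb])
    blocks <- if (keep) vector("list", nb)
    trace <- list(convChannels = integer(nb))
    for (k in seq_len(nb)) {
        p <- sprintf("b%d_", k)
        plan <- .getPlan(plans, H, W, B)
        c1 <- .convF(A, params[[paste0(p, "conv1W")]],
                     params[[paste0(p, "conv1b")]], plan)
        s <- c1$Y + params[[paste0(p, "projW")]] %*% A
        bn1 <- .bnF(s, params[[paste0(p, "bn1g")]],
                    params[[paste0(p, "bn1b")]],
                    running[[paste0(p, "bn1m")]],
                    running[[paste0(p, "bn1v")]], train)
        if (train) {
            running[[paste0(p, "bn1m")]] <- bn1$rmean
            running[[paste0(p, "bn1v")]] <- bn1$rvar
        }
        m1 <- bn1$Y > 0
        a1 <- bn1$Y * m1
        c2 <- .convF(a1, params[[paste0(p, "conv2W")]],
                     params[[paste0(p, "conv2b")]], plan)
        bn2 <- .bnF(c2$Y, params[[paste0(p, "bn2g")]],
                    params[[paste0(p, "bn2b")]],
                    running[[paste0(p, "bn2m")]],
                    running[[paste0(p, "bn2v")]], train)
        if (train) {
            running[[paste0(p, "bn2m")]] <- bn2$rmean
            running[[paste0(p, "bn2v")]] <- bn2$rvar
        }
        m2 <- bn2$Y > 0
        a2 <- bn2$Y * m2
        pool <- .poolF(a2)
        if (keep)
            blocks[[k]] <- list(A = A, Ap1 = c1$Ap, xhat1 = bn1$xhat,
                                inv1 = bn1$inv, m1 = m1, Ap2 = c2$Ap,
                                xhat2 = bn2$xhat, inv2 = bn2$inv, m2 = m2,
                                poolM = pool$m, poolN = pool$n,
                                plan = plan, cin = cin[k])
        A <- pool$Y
        H <- H %/% 2L
        trace$convChannels[k] <- nrow(A)
    }
    Hr <- H
    S <- .freqMeanF(A, Hr)
    trace$seqLen <- ncol(S) %/% B
    trace$lstmInput <- nrow(S)
    lst <- .lstmF(S, W, B, list(
        Wx = lapply(seq_len(cfg$lstmLayers),
                    function(l) params[[sprintf("lstm_Wx%d", l)]]),
        Wh = lapply(seq_len(cfg$lstmLayers),
                    function(l) params[[sprintf("lstm_Wh%d", l)]]),
        b = lapply(seq_len(cfg$lstmLayers),
                   function(l) params[[sprintf("lstm_b%d", l)]])),
        cfg$lstmLayers, cfg$lstmHidden, keep = keep)
    hOut <- if (cfg$headMode == "last") lst$hLast else lst$hMean
    logits <- as.numeric(params$head_W %*% hOut + params$head_b)
    list(p = .sigm(logits), logits = logits, running = running,
         cache = if (keep) list(blocks = blocks, lstm = lst$caches,
                                hOut = hOut, Hr = Hr, W = W, B = B,
                                preMean = A) else NULL,
         trace = trace)
}

# Backward pass from d(loss)/d(logit). Mirrors .crnnForward exactly.
.crnnBackward <- function(params, cfg, cache, dlogit) {
    B <- cache$B
    W <- cache$W
    hid <- cfg$lstmHidden
    L <- cfg$lstmLayers
    dlogit <- matrix(dlogit, 1L, B)
    grads <- list(head_W = tcrossprod(dlogit, cache$hOut),
                  head_b = sum(dlogit))
    dhOut <- crossprod(params$head_W, dlogit)
    dhTop <- vector("list", W)
    if (cfg$headMode == "last") {
        for (t in seq_len(W)) dhTop[[t]] <- matrix(0, hid, B)
        dhTop[[W]] <- dhOut
    } else {
        for (t in seq_len(W)) dhTop[[t]] <- dhOut / W
    }
    prm <- list(
        Wx = lapply(seq_len(L), function(l) params[[sprintf("lstm_Wx%d", l)]]),
        Wh = lapply(seq_len(L), function(l) params[[sprintf("lstm_Wh%d", l)]]),
        b = lapply(seq_len(L), function(l) params[[sprintf("lstm_b%d", l)]]))
    lb <- .lstmB(dhTop, prm, cache$lstm, L, hid, W, B)
    for (l in seq_len(L)) {
        grads[[sprintf("lstm_Wx%d", l)]] <- lb$dWx[[l]]
        grads[[sprintf("lstm_Wh%d", l)]] <- lb$dWh[[l]]
        grads[[sprintf("lstm_b%d", l)]] <- lb$db[[l]]
    }
    dS <- matrix(0, cfg$lstmInput, W * B)
    for (t in seq_len(W))
        dS[, t + W * (seq_len(B) - 1L)] <- lb$dX[[t]]
    dA <- .freqMeanB(dS, cache$Hr)
    for (k in seq(cfg$nConvBlocks, 1L)) {
        p <- sprintf("b%d_", k)
        blk <- cache$blocks[[k]]
        da2 <- .poolB(dA, blk$poolM, blk$poolN)
        dsb2 <- da2 * blk$m2
        bb2 <- .bnB(dsb2, params[[paste0(p, "bn2g")]], blk$xhat2, blk$inv2)
        grads[[paste0(p, "bn2g")]] <- bb2$dgamma
        grads[[paste0(p, "bn2b")]] <- bb2$dbeta
        cb2 <- .convB(bb2$dA, params[[paste0(p, "conv2W")]], blk$Ap2,
                      blk$plan, nrow(blk$xhat2))
        grads[[paste0(p, "conv2W")]] <- cb2$dW
        grads[[paste0(p, "conv2b")]] <- cb2$db
        dsb1 <- cb2$dA * blk$m1
        bb1 <- .bnB(dsb1, params[[paste0(p, "bn1g")]], blk$xhat1, blk$inv1)
        grads[[paste0(p, "bn1g")]] <- bb1$dgamma
        grads[[paste0(p, "bn1b")]] <- bb1$dbeta
        cb1 <- .convB(bb1$dA, params[[paste0(p, "conv1W")]], blk$Ap1,
                      blk$plan, blk$cin)
        grads[[paste0(p, "conv1W")]] <- cb1$dW
        grads[[paste0(p, "conv1b")]] <- cb1$db
        grads[[paste0(p, "projW")]] <- tcrossprod(bb1$dA, blk$A)
        dA <- cb1$dA + crossprod(params[[paste0(p, "projW")]], bb1$dA)
    }
    grads
}

.asMelArray <- function(x, cfg) {
    X <- if (is(x, "MelFeatureSet")) melValues(x) else x
    d <- dim(X)
    if (length(d) != 3L)
        stop("expected a MelFeatureSet or (nMels, nFrames, n) array")
    if (d[1] != cfg$nMels || d[2] != cfg$nFrames)
        stop("input shape (", d[1], ", ", d[2], ") does not match the ",
             "model's (", cfg$nMels, ", ", cfg$nFrames, ")")
    X
}

#' Predict cough probabilities for Mel segments
#'
#' @param model a \code{CRNNModel}.
#' @param x a \linkS4class{MelFeatureSet} or (nMels, nFrames, n) array
#'   matching the model's input shape.
#' @param batchSize forward-pass chunk size.
#' @param details if \code{TRUE}, attach the traced architecture shapes
#'   (per-block output channels, LSTM sequence length and input size) as
#'   attribute \code{"trace"}.
#' @return numeric vector of probabilities in [0, 1], one per segment.
#' @export
predictCrnn <- function(model, x, batchSize = 256L, details = FALSE) {
    stopifnot(inherits(model, "CRNNModel"))
    X <- .asMelArray(x, model$config)
    n <- dim(X)[3]
    plans <- new.env(parent = emptyenv())
    p <- numeric(n)
    trace <- NULL
    i <- 1L
    while (i <= n) {
        j <- min(i + batchSize - 1L, n)
        fw <- .crnnForward(model$params, model$running, model$config,
                           X[, , i:j, drop = FALSE], plans, train = FALSE)
        p[i:j] <- fw$p
        if (is.null(trace)) trace <- fw$trace
        i <- j + 1L
    }
    if (details) attr(p, "trace") <- trace
    p
}

.evalSplit <- function(params, running, cfg, X, y, wTrue, plans) {
    n <- dim(X)[3]
    p <- numeric(n)
    i <- 1L
    while (i <= n) {
        j <- min(i + 255L, n)
        p[i:j] <- .crnnForward(params, running, cfg,
                               X[, , i:j, drop = FALSE], plans,
                               train = FALSE)$p
        i <- j + 1L
    }
    rep <- computeMetrics(y, p >= 0.5, warn = FALSE)
    list(loss = weightedLoss(y, p, wTrue), metrics = rep, p = p)
}

#' Train the CRNN with checkpoint selection
#'
#' Minibatch Adam on the (optionally class-weighted) binary cross-entropy.
#' After every epoch both splits are evaluated and three checkpoints are
#' maintained online from the test-split metrics: best accuracy, best
#' sensitivity, and best mixed performance (accuracy + sensitivity). All
#' randomness (shuffling) flows from the config seed, so training is fully
#' deterministic given (data, config).
#'
#' The CRNN consumes unfiltered segments: do not amplitude-filter its
#' training data (the filter belongs to the classical-ML track).
#'
#' @param model an untrained (or warm) \code{CRNNModel}.
#' @param trainX,trainY training Mel segments
#'   (\linkS4class{MelFeatureSet} or array) and logical labels; both classes
#'   must be present.
#' @param testX,testY held-out split evaluated each epoch.
#' @param epochs optional override of the config's epoch count.
#' @param verbose print one line per epoch.
#' @return list with \code{model} (final state), \code{history} (one row per
#'   epoch: losses and metrics for both splits) and \code{checkpoints}
#'   (\code{bestAccuracy}, \code{bestSensitivity}, \code{bestMixed}; each
#'   holds a model snapshot, its epoch, and its test metrics).
#' @export
trainCrnn <- function(model, trainX, trainY, testX, testY, epochs = NULL,
                      verbose = FALSE) {
    stopifnot(inherits(model, "CRNNModel"))
    cfg <- model$config
    if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
    Xtr <- .asMelArray(trainX, cfg)
    Xte <- .asMelArray(testX, cfg)
    ytr <- as.logical(trainY)
    yte <- as.logical(testY)
    stopifnot(length(ytr) == dim(Xtr)[3], length(yte) == dim(Xte)[3])
    if (!any(ytr) || all(ytr))
        stop("training split must contain both classes")
    w <- if (cfg$weighted) classWeight(sum(ytr), sum(!ytr))$wTrue else 1
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed((cfg$seed %% 2147483600L) + 1L)

    params <- model$params
    running <- model$running
    adam <- .adamInit(params)
    plans <- new.env(parent = emptyenv())
    nTr <- length(ytr)
    hist <- vector("list", cfg$epochs)
    best <- list(bestAccuracy = list(score = -Inf),
                 bestSensitivity = list(score = -Inf),
                 bestMixed = list(score = -Inf))

    for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(nTr)
        pEpoch <- numeric(nTr)
        i <- 1L
        while (i <= nTr) {
            j <- min(i + cfg$batchSize - 1L, nTr)
            sel <- ord[i:j]
            fw <- .crnnForward(params, running, cfg,
                               Xtr[, , sel, drop = FALSE], plans,
                               train = TRUE, keep = TRUE)
            running <- fw$running
            pEpoch[sel] <- fw$p
            y <- as.numeric(ytr[sel])
            dlogit <- (w * y * (fw$p - 1) + (1 - y) * fw$p) / length(sel)
            grads <- .crnnBackward(params, cfg, fw$cache, dlogit)
            upd <- .adamStep(params, grads, adam, cfg$learningRate)
            params <- upd$params
            adam <- upd$st
            i <- j + 1L
        }
        # train metrics accumulate over the epoch's own minibatch outputs
        # (the usual running-metrics convention; no second full pass)
        mTr <- computeMetrics(ytr, pEpoch >= 0.5, warn = FALSE)
        trLoss <- weightedLoss(ytr, pEpoch, w)
        evTe <- .evalSplit(params, running, cfg, Xte, yte, w, plans)
        mTe <- evTe$metrics
        hist[[ep]] <- data.frame(
            epoch = ep,
            train_loss = trLoss, test_loss = evTe$loss,
            train_accuracy = accuracy(mTr), test_accuracy = accuracy(mTe),
            train_sensitivity = sensitivity(mTr),
            test_sensitivity = sensitivity(mTe),
            train_specificity = specificity(mTr),
            test_specificity = specificity(mTe))
        snap <- function() structure(list(config = cfg, params = params,
                                          running = running, trained = TRUE),
                                     class = "CRNNModel")
        scores <- c(bestAccuracy = accuracy(mTe),
                    bestSensitivity = sensitivity(mTe),
                    bestMixed = mixedScore(mTe))
        for (nm in names(scores)) {
            s <- scores[[nm]]
            if (!is.na(s) && s > best[[nm]]$score)
                best[[nm]] <- list(score = s, epoch = ep, metrics = mTe,
                                   model = snap())
        }
        if (verbose)
            message(sprintf(
                "epoch %2d  loss %.4f/%.4f  acc %.3f  sens %s  spec %.3f",
                ep, evTr$loss, evTe$loss, accuracy(mTe),
                ifelse(is.na(sensitivity(mTe)), "NA",
                       sprintf("%.3f", sensitivity(mTe))),
                specificity(mTe)))
    }
    final <- structure(list(config = cfg, params = params, running = running,
                            trained = TRUE), class = "CRNNModel")
    list(model = final, history = do.call(rbind, hist), checkpoints = best)
}

#' Convert a training history to long format
#'
#' One row per (epoch, split) with loss, accuracy, sensitivity and
#' specificity -- the layout used for CSV export and plotting learning
#' curves.
#'
#' @param history the wide history from \code{\link{trainCrnn}}.
#' @return long-format data.frame.
#' @export
historyLong <- function(history) {
    long <- function(split) data.frame(
        epoch = history$epoch, split = split,
        loss = history[[paste0(split, "_loss")]],
        accuracy = history[[paste0(split, "_accuracy")]],
        sensitivity = history[[paste0(split, "_sensitivity")]],
        specificity = history[[paste0(split, "_specificity")]])
    rbind(long("train"), long("test"))
}

#' Save / load a CRNN checkpoint
#'
#' The checkpoint is a single file embedding the model parameters, running
#' statistics, config, and (when present) the epoch and test metrics it was
#' selected at.
#'
#' @param checkpoint a \code{CRNNModel} or a checkpoint entry from
#'   \code{trainCrnn}'s \code{checkpoints} list.
#' @param path file path.
#' @return \code{path} invisibly (\code{saveCrnn}); the restored object
#'   (\code{loadCrnn}).
#' @export
saveCrnn <- function(checkpoint, path) {
    saveRDS(checkpoint, path)
    invisible(path)
}

#' @rdname saveCrnn
#' @export
loadCrnn <- function(path) readRDS(path)
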