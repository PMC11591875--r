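# Classical baselines on the flatten -> PCA -> standardize feature track.
#
# Hyperparameters follow the study protocol: ridge-penalized logistic
# regression (inverse regularization C = 1.0, iteration cap 1000), a
# decision tree split on information gain with unlimited depth and minimum
# split 2, a 100-tree random forest seeded at 42, and an RBF support vector
# machine with C = 1.0 and scale-derived kernel width
# gamma = 1 / (d * var(x)).

.BASELINE_NAMES <- c("logistic_regression", "decision_tree",
                     "random_forest", "svm_rbf")

#' Fit one classical baseline classifier
#'
#' @param name one of \code{"logistic_regression"}, \code{"decision_tree"},
#'   \code{"random_forest"}, \code{"svm_rbf"}.
#' @param x numeric feature matrix (segments x dims), normally the output of
#'   \code{\link{applyFeatureTransform}} fitted on the training split.
#' @param y logical labels; both classes must be present.
#' @param seed seed for the stochastic learners (the forest always uses its
#'   protocol seed 42; others fall back to this pipeline seed).
#' @return list of class \code{BaselineModel} with the fitted object, a
#'   \code{score} semantics tag and the decision \code{threshold} (0.5 for
#'   probability scores, 0 for the SVM margin).
#' @export
fitBaseline <- function(name, x, y, seed = 1L) {
    name <- match.arg(name, .BASELINE_NAMES)
    x <- as.matrix(x)
    y <- as.logical(y)
    stopifnot(nrow(x) == length(y))
    if (length(unique(y)) < 2L)
        stop("cannot fit '", name, "': training labels contain one class")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    fit <- switch(name,
        logistic_regression = {
            set.seed(seed)
            # ridge logistic: penalty lambda = 1/(n*C) matches an
            # average-loss objective with inverse regularization C = 1
            glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                           lambda = 1 / nrow(x), standardize = FALSE,
                           maxit = 1000L)
        },
        decision_tree = {
            set.seed(seed)
            df <- data.frame(x)
            df$.y <- factor(y)
            rpart::rpart(.y ~ ., data = df, method = "class",
                         parms = list(split = "information"),
                         control = rpart::rpart.control(
                             minsplit = 2L, cp = 0, xval = 0L,
                             maxdepth = 30L))
        },
        random_forest = {
            set.seed(42L)
            randomForest::randomForest(x, factor(y), ntree = 100L)
        },
        svm_rbf = {
            set.seed(seed)
            v <- stats::var(as.vector(x))
            gam <- if (v > 1e-12) 1 / (ncol(x) * v) else 1 / ncol(x)
            e1071::svm(x, factor(y), kernel = "radial", cost = 1,
                       gamma = gam, scale = FALSE)
        })
    mdl <- structure(list(name = name, fit = fit, dim = ncol(x),
                          threshold = if (name == "svm_rbf") 0 else 0.5),
                     class = "BaselineModel")
    if (name == "svm_rbf") {
        # orient the margin so higher = more cough-like
        dv <- .svmDecision(mdl, x)
        mdl$flip <- mean(dv[y]) < mean(dv[!y])
    }
    mdl
}

.svmDecision <- function(model, x) {
    pr <- stats::predict(model$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    if (isTRUE(model$flip)) -dv else dv
}

#' Continuous decision scores from a fitted baseline
#'
#' Probability of the positive class where the learner provides one
#' (logistic regression, tree, forest); the signed margin for the SVM,
#' oriented so higher always means more cough-like. These scores drive the
#' ROC analysis.
#'
#' @param model a \code{BaselineModel}.
#' @param x feature matrix with the same dimensionality the model was
#'   fitted on.
#' @return numeric score per segment.
#' @export
scoreBaseline <- function(model, x) {
    stopifnot(inherits(model, "BaselineModel"))
    x <- as.matrix(x)
    if (ncol(x) != model$dim)
        stop("feature dimension mismatch: got ", ncol(x), ", model was ",
             "fitted on ", model$dim)
    unname(switch(model$name,
        logistic_regression =
            as.numeric(stats::predict(model$fit, x, type = "response")),
        decision_tree =
            stats::predict(model$fit, data.frame(x), type = "prob")[, "TRUE"],
        random_forest =
            stats::predict(model$fit, x, type = "prob")[, "TRUE"],
        svm_rbf = .svmDecision(model, x)))
}

#' Binary predictions from a fitted baseline
#'
#' @param model a \code{BaselineModel}.
#' @param x feature matrix.
#' @return logical vector (score at or above the model's threshold).
#' @export
predictBaseline <- function(model, x)
    scoreBaseline(model, x) >= model$threshold

#' @export
print.BaselineModel <- function(x, ...) {
    cat(sprintf("BaselineModel '%s' on %d features\n", x$name, x$dim))
    invisible(x)
}

#' Model factory for the cross-validation harness
#'
#' Wraps a baseline (plus its own flatten/PCA/standardize transform, fitted
#' on the training data it receives, so no leakage across cells) into the
#' \code{factory} interface of \code{\link{crossValidate}}.
#'
#' @param name baseline name, see \code{\link{fitBaseline}}.
#' @param varianceKept PCA variance retention for the internal transform.
#' @return \code{function(x, y, seed)} returning \code{list(score, threshold)}.
#' @export
baselineFactory <- function(name = "logistic_regression",
                            varianceKept = 0.95) {
    name <- match.arg(name, .BASELINE_NAMES)
    function(x, y, seed = 1L) {
        X <- if (is.matrix(x)) x else t(matrix(x, prod(dim(x)[1:2]),
                                               dim(x)[3]))
        ft <- fitFeatureTransform(X, varianceKept)
        mdl <- fitBaseline(name, applyFeatureTransform(ft, X), y, seed)
        list(score = function(newx) {
                 Xn <- if (is.matrix(newx)) newx
                       else t(matrix(newx, prod(dim(newx)[1:2]),
                                     dim(newx)[3]))
                 scoreBaseline(mdl, applyFeatureTransform(ft, Xn))
             },
             threshold = mdl$threshold)
    }
}
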