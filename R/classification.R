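#' Remove near-zero-variance PAS features
#'
#' Drops features (pathways) whose value distribution is almost constant:
#' the ratio of the most common to the second most common value exceeds
#' \code{freqRatioCut} while the fraction of distinct values is below
#' \code{uniqueFracCut}. Strictly constant features are always removed.
#' The defaults (19, i.e. 95/5, and 10\%) are the conventional ones for
#' this filter.
#'
#' @param x features x samples matrix or \linkS4class{PASMatrix}.
#' @param freqRatioCut frequency-ratio cutoff, default 19.
#' @param uniqueFracCut unique-value fraction cutoff, default 0.10.
#' @return a \code{FeatureFilterReport}: list with
#'   \code{removedNearZeroVariance}, \code{removedCollinear} (empty here)
#'   and \code{retained} feature names.
#' @export
nearZeroVarFilter <- function(x, freqRatioCut = 19, uniqueFracCut = 0.10) {
    m <- if (is(x, "PASMatrix")) pasScores(x) else x
    stopifnot(is.matrix(m), nrow(m) >= 1L)
    idx <- caret::nearZeroVar(t(m), freqCut = freqRatioCut,
                              uniqueCut = uniqueFracCut * 100)
    removed <- rownames(m)[idx]
    structure(list(removedNearZeroVariance = removed,
                   removedCollinear = character(0),
                   retained = setdiff(rownames(m), removed)),
              class = "FeatureFilterReport")
}

#' Remove collinear PAS features
#'
#' Greedy removal of highly correlated predictors: while any pair of
#' features has absolute Pearson correlation above \code{cutoff}, the
#' member of the worst pair with the larger mean absolute correlation to
#' all other features is dropped. Deterministic given the input order. The
#' output never contains a pair with \eqn{|r| >} cutoff.
#'
#' @param x features x samples matrix or \linkS4class{PASMatrix}.
#' @param cutoff absolute correlation cutoff, default 0.85.
#' @return a \code{FeatureFilterReport} (see [nearZeroVarFilter()]).
#' @export
collinearityFilter <- function(x, cutoff = 0.85) {
    m <- if (is(x, "PASMatrix")) pasScores(x) else x
    stopifnot(is.matrix(m), nrow(m) >= 2L)
    cm <- suppressWarnings(cor(t(m)))
    cm[!is.finite(cm)] <- 0
    drop <- caret::findCorrelation(cm, cutoff = cutoff, exact = TRUE,
                                   names = TRUE)
    ## safety sweep: guarantee the post-condition whatever the library did
    keep <- setdiff(rownames(m), drop)
    repeat {
        sub <- abs(cm[keep, keep, drop = FALSE]); diag(sub) <- 0
        if (all(sub <= cutoff)) break
        worst <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
        pair <- keep[worst]
        meanAbs <- rowMeans(abs(cm[pair, keep, drop = FALSE]))
        victim <- if (diff(meanAbs) == 0) sort(pair)[2L]
                  else pair[which.max(meanAbs)]
        drop <- c(drop, victim); keep <- setdiff(keep, victim)
    }
    structure(list(removedNearZeroVariance = character(0),
                   removedCollinear = drop,
                   retained = keep),
              class = "FeatureFilterReport")
}

#' @export
print.FeatureFilterReport <- function(x, ...) {
    cat(sprintf("FeatureFilterReport: %d retained, %d near-zero-variance, %d collinear removed\n",
                length(x$retained), length(x$removedNearZeroVariance),
                length(x$removedCollinear)))
    invisible(x)
}

SUPPORTED_MODELS <- c("svm_linear", "svm_radial", "random_forest",
                      "regularized_logistic", "naive_bayes", "pls")

fitModel <- function(model, x, y, seed = 1L) {
    model <- match.arg(model, SUPPORTED_MODELS)
    y <- droplevels(factor(y))
    switch(model,
        ## PAS features share one natural unit, so the kernels operate on
        ## raw values; per-feature standardization would inflate noise
        ## pathways relative to weakly displaced classes
        svm_linear = e1071::svm(x, y, kernel = "linear", cost = 1,
                                scale = FALSE),
        svm_radial = e1071::svm(x, y, kernel = "radial", scale = FALSE),
        random_forest = withr::with_seed(seed,
            randomForest::randomForest(x, y, ntree = 300, importance = TRUE)),
        regularized_logistic = withr::with_seed(seed,
            glmnet::cv.glmnet(x, y, family = "multinomial", nfolds = 3,
                              type.measure = "class")),
        naive_bayes = e1071::naiveBayes(x, y),
        pls = {
            if (!requireNamespace("mixOmics", quietly = TRUE))
                stop("the 'pls' model needs the mixOmics package")
            ncomp <- min(10L, ncol(x) - 1L, nrow(x) - 1L)
            fit <- mixOmics::plsda(x, y, ncomp = ncomp)
            fit$pasflowNcomp <- ncomp
            fit
        })
}

predictModel <- function(fit, model, newx, levels) {
    p <- switch(model,
        svm_linear = ,
        svm_radial = predict(fit, newx),
        random_forest = predict(fit, newx),
        regularized_logistic = {
            pr <- predict(fit, newx, s = "lambda.min", type = "class")
            factor(as.vector(pr), levels = levels)
        },
        naive_bayes = predict(fit, newx),
        pls = {
            pr <- predict(fit, newx, dist = "max.dist")
            factor(pr$class$max.dist[, fit$pasflowNcomp], levels = levels)
        })
    factor(as.character(p), levels = levels)
}

#' One-vs-rest metrics from a multiclass confusion matrix
#'
#' Rows are true classes, columns predictions. For each class:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
#' their mean. An empty class (row sum 0) yields \code{NA} sensitivity with
#' a warning, never a silent 0.
#'
#' @param confusion square non-negative matrix (counts; fractional counts
#'   from repeat-averaged cross-validation are accepted).
#' @param classIndex optional single class (index or name); default all.
#' @return data.frame with columns \code{class}, \code{sensitivity},
#'   \code{specificity}, \code{balancedAccuracy} (one row per class), or a
#'   single-row data.frame when \code{classIndex} is given.
#' @export
classMetrics <- function(confusion, classIndex = NULL) {
    stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
              all(confusion >= 0))
    classes <- rownames(confusion)
    if (is.null(classes)) classes <- as.character(seq_len(nrow(confusion)))
    one <- function(i) {
        tp <- confusion[i, i]
        fn <- sum(confusion[i, ]) - tp
        fp <- sum(confusion[, i]) - tp
        tn <- sum(confusion) - tp - fn - fp
        sens <- if (tp + fn == 0) {
            warning("class '", classes[i],
                    "' has no samples; sensitivity undefined")
            NA_real_
        } else tp / (tp + fn)
        spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
        data.frame(class = classes[i], sensitivity = sens, specificity = spec,
                   balancedAccuracy = mean(c(sens, spec)),
                   stringsAsFactors = FALSE)
    }
    if (!is.null(classIndex)) {
        i <- if (is.character(classIndex)) match(classIndex, classes)
             else classIndex
        return(one(i))
    }
    do.call(rbind, lapply(seq_along(classes), one))
}

#' Train and evaluate one classifier under repeated stratified k-fold CV
#'
#' Out-of-fold predictions are pooled into a confusion matrix; per-class
#' sensitivity, specificity and balanced accuracy are one-vs-rest. Folds
#' are stratified by class; if the smallest class has fewer members than
#' \code{folds}, the fold count is reduced with a warning. Margin-based
#' models handle the 4-class problem one-vs-one with voting (their native
#' multiclass scheme).
#'
#' @param x samples x features matrix, or a \linkS4class{PASMatrix}
#'   (transposed internally).
#' @param labels class labels, one per sample.
#' @param model one of \code{"svm_linear"}, \code{"svm_radial"},
#'   \code{"random_forest"}, \code{"regularized_logistic"},
#'   \code{"naive_bayes"}, \code{"pls"} (the last needs mixOmics).
#' @param folds number of CV folds, default 10.
#' @param repeats number of CV repeats, default 3.
#' @param seed RNG seed governing fold assignment and stochastic fits.
#' @param keepFit keep a final fit on all data (needed for
#'   [variableImportance()]).
#' @return a \code{ClassifierReport}: list with the (repeat-averaged)
#'   \code{confusion} matrix, the pooled integer \code{confusionPooled},
#'   per-class \code{metrics}, \code{averageBalancedAccuracy}, the
#'   \code{cv} scheme, and (optionally) the final \code{fit} with its
#'   training data.
#' @export
trainEval <- function(x, labels, model = "svm_linear", folds = 10L,
                      repeats = 3L, seed = 1L, keepFit = TRUE) {
    if (is(x, "PASMatrix")) x <- t(pasScores(x))
    stopifnot(is.matrix(x), nrow(x) == length(labels))
    y <- droplevels(factor(labels))
    if (nlevels(y) < 2L) stop("need at least 2 classes to classify")
    minClass <- min(table(y))
    if (minClass < folds) {
        warning("smallest class has ", minClass, " samples; reducing folds from ",
                folds, " to ", minClass)
        folds <- minClass
    }
    foldSets <- withr::with_seed(seed,
        caret::createMultiFolds(y, k = folds, times = repeats))
    lv <- levels(y)
    pooled <- matrix(0L, nlevels(y), nlevels(y), dimnames = list(lv, lv))
    for (fi in seq_along(foldSets)) {
        tr <- foldSets[[fi]]
        te <- setdiff(seq_len(nrow(x)), tr)
        fit <- fitModel(model, x[tr, , drop = FALSE], y[tr],
                        seed = seed + fi)
        pred <- predictModel(fit, model, x[te, , drop = FALSE], lv)
        pooled <- pooled + unclass(table(truth = y[te], pred = pred))
    }
    metrics <- classMetrics(pooled)
    rep <- list(model = model,
                confusion = pooled / repeats,
                confusionPooled = pooled,
                metrics = metrics,
                averageBalancedAccuracy = mean(metrics$balancedAccuracy),
                cv = list(folds = folds, repeats = repeats, seed = seed),
                levels = lv)
    if (keepFit) {
        rep$fit <- fitModel(model, x, y, seed = seed)
        rep$trainX <- x
        rep$trainY <- y
    }
    structure(rep, class = "ClassifierReport")
}

#' @export
print.ClassifierReport <- function(x, ...) {
    cat(sprintf("ClassifierReport: %s (%d-fold CV x %d repeats)\n", x$model,
                x$cv$folds, x$cv$repeats))
    print(x$metrics, row.names = FALSE)
    cat(sprintf("average balanced accuracy: %.3f\n",
                x$averageBalancedAccuracy))
    invisible(x)
}
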