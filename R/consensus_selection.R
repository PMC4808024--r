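#' Model-appropriate variable importance, scaled to [0, 100]
#'
#' Ranks the features a fitted classifier relied on. The score depends on
#' the model family: absolute coefficient magnitudes summed over classes
#' for linear models (linear SVM one-vs-one weight vectors, regularized
#' logistic coefficients), the model's permutation importance for random
#' forests, loading-based VIP for PLS, training-set permutation importance
#' (mean accuracy drop over \code{nPerm} shuffles) for radial SVM, and the
#' model-free one-vs-rest ROC-AUC filter score for naive Bayes (the usual
#' convention for probabilistic models without native coefficients).
#' Scores are rescaled to \eqn{[0, 100]}.
#'
#' @param report a \code{ClassifierReport} from [trainEval()] with
#'   \code{keepFit = TRUE} (or a list with \code{fit}, \code{model},
#'   \code{trainX}, \code{trainY}).
#' @param nPerm permutations per feature for permutation importance.
#' @param seed RNG seed for the permutations.
#' @return an \code{ImportanceRanking}: data.frame with columns
#'   \code{feature} and \code{importance}, sorted non-increasing, with the
#'   model name in attribute \code{"model"}.
#' @export
variableImportance <- function(report, nPerm = 3L, seed = 1L) {
    if (is.null(report$fit))
        stop("report carries no fitted model; rerun trainEval(keepFit = TRUE)")
    fit <- report$fit
    model <- report$model
    x <- report$trainX
    feats <- colnames(x)
    imp <- switch(model,
        svm_linear = {
            w <- crossprod(fit$coefs, fit$SV)   # one-vs-one weight rows
            setNames(colSums(abs(w)), colnames(w))[feats]
        },
        regularized_logistic = {
            cf <- coef(fit, s = "lambda.min")
            tot <- Reduce(`+`, lapply(cf, function(m) abs(as.matrix(m)[-1L, 1L])))
            setNames(as.vector(tot), rownames(cf[[1L]])[-1L])[feats]
        },
        random_forest = {
            im <- randomForest::importance(fit, type = 1)
            setNames(pmax(im[, 1L], 0), rownames(im))[feats]
        },
        pls = {
            vip <- mixOmics::vip(fit)
            setNames(rowMeans(vip), rownames(vip))[feats]
        },
        naive_bayes = {
            auc <- caret::filterVarImp(as.data.frame(x), report$trainY)
            setNames(apply(as.matrix(auc), 1L, max), rownames(auc))[feats]
        },
        ## permutation importance on the training data
        {
            y <- report$trainY
            base <- mean(predictModel(fit, model, x, levels(y)) == y)
            drops <- withr::with_seed(seed, vapply(seq_along(feats), function(j) {
                mean(vapply(seq_len(nPerm), function(k) {
                    xp <- x
                    xp[, j] <- sample(xp[, j])
                    base - mean(predictModel(fit, model, xp, levels(y)) == y)
                }, numeric(1)))
            }, numeric(1)))
            setNames(pmax(drops, 0), feats)
        })
    rng <- range(imp)
    scaled <- if (diff(rng) == 0) rep(0, length(imp))
              else 100 * (imp - rng[1L]) / diff(rng)
    out <- data.frame(feature = feats, importance = unname(scaled),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$importance, out$feature), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("ImportanceRanking", "data.frame"),
              model = model)
}

#' Intersect the top-k features of several importance rankings
#'
#' The consensus step: each model contributes its \code{k} most important
#' features and the strict intersection across models (default) is taken.
#' Because a strict intersection can be empty on noisy data, a relaxation is
#' available: keep features appearing in at least \code{minModels} of the
#' rankings. Rankings shorter than \code{k} contribute all their features.
#'
#' @param rankings list of \code{ImportanceRanking} objects (or data.frames
#'   with a \code{feature} column ordered by importance).
#' @param k top-list depth, default 30.
#' @param minModels minimum number of rankings a feature must appear in;
#'   default \code{length(rankings)} (strict intersection).
#' @return sorted character vector of consensus features.
#' @export
topKIntersection <- function(rankings, k = 30L, minModels = NULL) {
    if (length(rankings) == 0L) stop("no rankings supplied")
    if (is.null(minModels)) minModels <- length(rankings)
    stopifnot(minModels >= 1L, minModels <= length(rankings))
    tops <- lapply(rankings, function(r) unique(head(r$feature, k)))
    counts <- table(unlist(tops))
    sort(names(counts)[counts >= minModels])
}

#' Default progression ladders of the melanoma study
#'
#' Two ordered class triples: the nevus-mediated route Skin - Nevus -
#' Primary Melanoma and the direct route Skin - Primary Melanoma -
#' Metastatic Melanoma.
#'
#' @return named list of character vectors of class labels.
#' @export
defaultProgressions <- function() {
    list(SkinNevusPrimary = c("Skin", "Nevus", "PrimaryMelanoma"),
         SkinPrimaryMetastatic = c("Skin", "PrimaryMelanoma",
                                   "MetastaticMelanoma"))
}

#' Kruskal-Wallis filter of candidate pathways
#'
#' Retains a candidate feature iff, in at least one progression ladder, its
#' PAS values differ across that ladder's classes at level \code{alpha}.
#' The omnibus reading (one Kruskal-Wallis test per ladder) is the default;
#' \code{mode = "pairwise"} instead requires at least one significant
#' two-class comparison within a ladder.
#'
#' @param pas features x samples matrix or \linkS4class{PASMatrix}.
#' @param labels per-sample class labels.
#' @param candidates feature names to filter.
#' @param progressions list of ordered class vectors, default
#'   [defaultProgressions()].
#' @param alpha significance level, default 0.05.
#' @param mode \code{"omnibus"} (default) or \code{"pairwise"}.
#' @return character vector of retained features.
#' @export
kruskalFilter <- function(pas, labels, candidates,
                          progressions = defaultProgressions(),
                          alpha = 0.05, mode = c("omnibus", "pairwise")) {
    mode <- match.arg(mode)
    m <- if (is(pas, "PASMatrix")) pasScores(pas) else pas
    labels <- as.character(labels)
    stopifnot(ncol(m) == length(labels))
    candidates <- intersect(candidates, rownames(m))
    for (pr in progressions) {
        n <- table(factor(labels, levels = pr))
        if (any(n < 3L))
            stop("progression class '", names(n)[n < 3L][1L],
                 "' has fewer than 3 samples")
    }
    keep <- vapply(candidates, function(f) {
        v <- m[f, ]
        any(vapply(progressions, function(pr) {
            idx <- labels %in% pr
            g <- factor(labels[idx], levels = pr)
            if (mode == "omnibus") {
                kruskal.test(v[idx], g)$p.value <= alpha
            } else {
                pairs <- utils::combn(pr, 2L, simplify = FALSE)
                any(vapply(pairs, function(pp) {
                    ii <- labels %in% pp
                    kruskal.test(v[ii], factor(labels[ii]))$p.value <= alpha
                }, logical(1)))
            }
        }, logical(1)))
    }, logical(1))
    candidates[keep]
}

#' The five progression contrasts (case vs control)
#'
#' @return named list; each element is \code{c(case, control)} and the
#'   direction of a contrast is the sign of case minus control.
#' @export
progressionContrasts <- function() {
    list(NevusVsSkin = c("Nevus", "Skin"),
         PrimaryVsSkin = c("PrimaryMelanoma", "Skin"),
         MetastaticVsSkin = c("MetastaticMelanoma", "Skin"),
         MetastaticVsPrimary = c("MetastaticMelanoma", "PrimaryMelanoma"),
         PrimaryVsNevus = c("PrimaryMelanoma", "Nevus"))
}

#' UP/DOWN direction table across progression contrasts
#'
#' For each feature and contrast, the direction is the sign of the
#' difference of group medians (case minus control): UP if positive, DOWN
#' if negative, and flagged \code{NA} (never silently assigned) if exactly
#' zero. Significance is a Welch t-test with Benjamini-Hochberg adjustment
#' across all cells of the table.
#'
#' @param pas features x samples matrix or \linkS4class{PASMatrix}.
#' @param labels per-sample class labels.
#' @param features feature names to tabulate; default all rows.
#' @param contrasts named list of \code{c(case, control)} pairs, default
#'   [progressionContrasts()].
#' @param adjust multiple-testing correction method, default \code{"BH"}.
#' @param category optional named vector mapping features to pathway
#'   categories (taken from a \code{PASMatrix} automatically).
#' @return a \code{ConsensusTable}: list with \code{direction} (wide
#'   data.frame, one column per contrast), \code{stats} (long data.frame
#'   with median change, p and adjusted p per cell) and \code{contrasts}.
#' @export
directionTable <- function(pas, labels, features = NULL,
                           contrasts = progressionContrasts(),
                           adjust = "BH", category = NULL) {
    m <- if (is(pas, "PASMatrix")) pasScores(pas) else pas
    if (is(pas, "PASMatrix") && is.null(category))
        category <- setNames(SummarizedExperiment::rowData(pas)$category,
                             rownames(pas))
    labels <- as.character(labels)
    stopifnot(ncol(m) == length(labels))
    if (is.null(features)) features <- rownames(m)
    stopifnot(all(features %in% rownames(m)))
    for (nm in names(contrasts)) {
        for (gg in contrasts[[nm]])
            if (!any(labels == gg))
                stop("contrast '", nm, "': no samples in group '", gg, "'")
    }
    cells <- expand.grid(feature = features, contrast = names(contrasts),
                         stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(cells)), function(i) {
        f <- cells$feature[i]
        cc <- contrasts[[cells$contrast[i]]]
        a <- m[f, labels == cc[1L]]
        b <- m[f, labels == cc[2L]]
        md <- median(a) - median(b)
        p <- if (sd(a) == 0 && sd(b) == 0) {
            if (md == 0) 1 else 0
        } else tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
        data.frame(feature = f, contrast = cells$contrast[i],
                   medianChange = md,
                   direction = if (md > 0) "UP" else if (md < 0) "DOWN"
                               else NA_character_,
                   p = p, stringsAsFactors = FALSE)
    })
    stats <- do.call(rbind, res)
    stats$padj <- p.adjust(stats$p, method = adjust)
    if (anyNA(stats$direction))
        warning(sum(is.na(stats$direction)),
                " cell(s) with exactly zero median change flagged NA")
    wide <- data.frame(pathway = features, stringsAsFactors = FALSE)
    if (!is.null(category)) wide$category <- unname(category[features])
    for (nm in names(contrasts))
        wide[[nm]] <- stats$direction[match(paste(features, nm),
                                            paste(stats$feature, stats$contrast))]
    structure(list(direction = wide, stats = stats,
                   contrasts = contrasts),
              class = "ConsensusTable")
}

#' @export
print.ConsensusTable <- function(x, ...) {
    cat(sprintf("ConsensusTable: %d pathways x %d contrasts\n",
                nrow(x$direction), length(x$contrasts)))
    print(head(x$direction, 10), row.names = FALSE)
    if (nrow(x$direction) > 10) cat("...\n")
    invisible(x)
}

#' Write a consensus table (directions + companion statistics) to TSV
#'
#' @param x a \code{ConsensusTable}.
#' @param path output TSV for the UP/DOWN table.
#' @param statsPath optional output TSV for the effect/adjusted-p table.
#' @return \code{path}, invisibly.
#' @export
writeConsensusTable <- function(x, path, statsPath = NULL) {
    stopifnot(inherits(x, "ConsensusTable"))
    write.table(x$direction, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(statsPath))
        write.table(x$stats, statsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    invisible(path)
}
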