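#' Read an expression matrix from TSV
#'
#' Expects a header row with \code{gene} as first column followed by sample
#' ids; values are linear-scale positive intensities.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionTSV <- function(path) {
    d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(d)[1L] != "gene")
        stop("expression TSV must have 'gene' as its first column")
    if (anyDuplicated(d$gene)) stop("duplicated gene symbols in ", path)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$gene
    storage.mode(m) <- "double"
    m
}

#' Read sample annotations from TSV
#'
#' Columns: \code{sample_id}, \code{group} (one of Skin, Nevus,
#' PrimaryMelanoma, MetastaticMelanoma, Reference), \code{dataset_id},
#' \code{platform}.
#'
#' @param path path to the TSV file.
#' @return data.frame of annotations.
#' @export
readAnnotationTSV <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "dataset_id", "platform")
    if (!all(need %in% colnames(d)))
        stop("annotation TSV must have columns: ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(d$group), SAMPLE_GROUPS)
    if (length(bad))
        stop("unknown sample group(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicated sample ids in ", path)
    d
}

#' Bundle an expression matrix and annotations into a SummarizedExperiment
#'
#' Every sample (column) must have exactly one annotation row.
#'
#' @param values genes x samples matrix of positive intensities.
#' @param annot annotation data.frame as from [readAnnotationTSV()].
#' @return a \linkS4class{SummarizedExperiment} with assay \code{"exprs"}.
#' @export
makeStudyExperiment <- function(values, annot) {
    stopifnot(is.matrix(values))
    if (!all(colnames(values) %in% annot$sample_id))
        stop("samples without annotation: ",
             paste(setdiff(colnames(values), annot$sample_id), collapse = ", "))
    annot <- annot[match(colnames(values), annot$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(annot, row.names = annot$sample_id)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample's value distribution onto the cross-sample mean of
#' sorted value vectors (ties averaged), preserving within-sample ranks and
#' the gene/sample ordering. Applied per platform before cross-platform
#' harmonization.
#'
#' @param x genes x samples matrix of strictly positive intensities, or a
#'   \linkS4class{SummarizedExperiment} carrying one.
#' @param ... passed to methods.
#' @return object of the same shape with normalized values.
#' @export
setGeneric("quantileNormalize", function(x, ...)
    standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
    if (any(!is.finite(x)) || any(x <= 0))
        stop("expression values must be strictly positive and finite")
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "SummarizedExperiment", function(x, ...) {
    SummarizedExperiment::assay(x) <-
        quantileNormalize(SummarizedExperiment::assay(x))
    x
})

#' Harmonize expression matrices across platforms
#'
#' Merges per-platform matrices over their shared gene universe (the
#' intersection, so downstream scoring never sees missing values) and
#' removes platform location/scale effects gene by gene: within each
#' platform, log2 values are standardized and rescaled to the pooled
#' per-gene mean and pooled within-platform SD. With a single platform the
#' transform is the identity on the log scale. Full block co-clustering
#' cross-platform normalization is intentionally not attempted; this
#' closed-form transform removes exactly the affine per-gene batch effects
#' the generator (and typical platform pairs) exhibit.
#'
#' @param x either a named list of genes x samples matrices (one per
#'   platform; names used as platform labels) or a single
#'   \linkS4class{SummarizedExperiment} whose \code{colData$platform} labels
#'   the batches.
#' @param platform optional per-sample platform labels when \code{x} is one
#'   matrix.
#' @return same container kind as the input (matrix in, matrix out with a
#'   \code{"platform"} attribute; SummarizedExperiment in,
#'   SummarizedExperiment out), values on the linear intensity scale.
#' @export
harmonizePlatforms <- function(x, platform = NULL) {
    if (is(x, "SummarizedExperiment")) {
        platform <- as.character(SummarizedExperiment::colData(x)$platform)
        m <- harmonizePlatforms(SummarizedExperiment::assay(x), platform)
        SummarizedExperiment::assay(x) <- m
        return(x)
    }
    if (is.list(x) && !is.data.frame(x)) {
        if (length(x) == 0L) stop("no matrices to harmonize")
        genes <- Reduce(intersect, lapply(x, rownames))
        if (length(genes) == 0L)
            stop("empty gene intersection across platforms")
        labels <- names(x)
        if (is.null(labels)) labels <- paste0("platform", seq_along(x))
        platform <- rep(labels, vapply(x, ncol, integer(1)))
        x <- do.call(cbind, lapply(x, function(m) m[genes, , drop = FALSE]))
    }
    stopifnot(is.matrix(x))
    if (is.null(platform)) platform <- rep("platform1", ncol(x))
    stopifnot(length(platform) == ncol(x))
    if (any(!is.finite(x)) || any(x <= 0))
        stop("expression values must be strictly positive and finite")
    L <- log2(x)
    pf <- factor(platform)
    nP <- nlevels(pf)
    ns <- as.integer(table(pf))
    ## per-gene per-platform moments
    means <- vapply(levels(pf), function(p)
        rowMeans(L[, pf == p, drop = FALSE]), numeric(nrow(L)))
    vars <- vapply(levels(pf), function(p) {
        cols <- L[, pf == p, drop = FALSE]
        if (ncol(cols) < 2L) rep(0, nrow(L))
        else apply(cols, 1L, stats::var)
    }, numeric(nrow(L)))
    means <- matrix(means, nrow = nrow(L)); vars <- matrix(vars, nrow = nrow(L))
    pooledMean <- as.vector(means %*% ns) / sum(ns)
    df <- pmax(ns - 1L, 0L)
    pooledSD <- if (sum(df) > 0) sqrt(as.vector(vars %*% df) / sum(df))
                else rep(0, nrow(L))
    H <- L
    for (k in seq_len(nP)) {
        idx <- pf == levels(pf)[k]
        s <- sqrt(vars[, k])
        scale <- ifelse(s > 0 & pooledSD > 0, pooledSD / s, 1)
        H[, idx] <- (L[, idx, drop = FALSE] - means[, k]) * scale + pooledMean
    }
    out <- 2 ^ H
    attr(out, "platform") <- as.character(platform)
    out
}

#' Per-platform quantile normalization followed by harmonization
#'
#' The standard preparation for a multi-platform study: quantile-normalize
#' the samples of each platform separately, then remove per-gene platform
#' location/scale effects with [harmonizePlatforms()].
#'
#' @param se \linkS4class{SummarizedExperiment} with positive intensities
#'   and a \code{platform} column in \code{colData}.
#' @return harmonized \linkS4class{SummarizedExperiment}.
#' @export
normalizeStudy <- function(se) {
    stopifnot(is(se, "SummarizedExperiment"))
    plat <- as.character(SummarizedExperiment::colData(se)$platform)
    for (p in unique(plat)) {
        idx <- plat == p
        SummarizedExperiment::assay(se)[, idx] <-
            quantileNormalize(SummarizedExperiment::assay(se)[, idx,
                                                              drop = FALSE])
    }
    harmonizePlatforms(se)
}

#' Read a dataset manifest TSV
#'
#' Columns: \code{dataset_id}, \code{platform}, \code{n_skin},
#' \code{n_nevus}, \code{n_primary}, \code{n_metastatic}.
#'
#' @param path path to the TSV file.
#' @return data.frame manifest.
#' @export
readManifestTSV <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("dataset_id", "platform", "n_skin", "n_nevus", "n_primary",
              "n_metastatic")
    if (!all(need %in% colnames(d)))
        stop("manifest TSV must have columns: ", paste(need, collapse = ", "))
    d
}

#' Per-class and grand sample totals of a dataset manifest
#'
#' @param manifest data.frame as from [readManifestTSV()].
#' @return list with \code{perClass} (named integer vector over skin, nevus,
#'   primary and metastatic samples) and \code{grandTotal}.
#' @export
manifestTotals <- function(manifest) {
    cols <- c(skin = "n_skin", nevus = "n_nevus", primary = "n_primary",
              metastatic = "n_metastatic")
    stopifnot(all(cols %in% colnames(manifest)))
    counts <- as.matrix(manifest[, cols, drop = FALSE])
    if (any(counts < 0)) stop("negative sample count in manifest")
    perClass <- setNames(as.integer(colSums(counts)), names(cols))
    list(perClass = perClass, grandTotal = sum(perClass))
}

#' Built-in transcriptions of the study's printed tables
#'
#' Returns one of the small tables shipped with the package: the dataset
#' manifest (per-dataset sample counts by class and platform), or the
#' consensus direction signatures for the top metabolic / signaling
#' pathways across the five progression contrasts.
#'
#' @param name one of \code{"datasets"}, \code{"metabolic_directions"},
#'   \code{"signaling_directions"}.
#' @return data.frame.
#' @export
melanomaTableFixture <- function(name = c("datasets", "metabolic_directions",
                                          "signaling_directions")) {
    name <- match.arg(name)
    file <- switch(name,
        datasets = "melanoma_dataset_manifest.tsv",
        metabolic_directions = "metabolic_direction_signatures.tsv",
        signaling_directions = "signaling_direction_signatures.tsv")
    path <- system.file("extdata", file, package = "pasflow", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Census of the pathway database behind the published analysis
#'
#' Named counts of signaling and metabolic pathways in the curated database
#' the melanoma analysis was run against. The package does not ship that
#' proprietary/curated content (see the synthetic generator instead); the
#' census is kept for manifest checks and reporting.
#'
#' @return named integer vector with elements \code{signaling} and
#'   \code{metabolic}.
#' @export
referenceDatabaseCensus <- function() {
    c(signaling = 271L, metabolic = 321L)
}
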