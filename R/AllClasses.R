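#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor cutree dist hclust kruskal.test median p.adjust qnorm
#'   rnorm runif sd t.test predict coef setNames var
#' @importFrom utils head read.delim write.table packageVersion tail combn
NULL

## Discrete activator/repressor role weights: repressor, partial repressor,
## unknown role, partial activator, activator.
ARR_LEVELS <- c(-1, -0.5, 0, 0.5, 1)

PATHWAY_CATEGORIES <- c("signaling", "metabolic")

SAMPLE_GROUPS <- c("Skin", "Nevus", "PrimaryMelanoma", "MetastaticMelanoma",
                   "Reference")

#' Pathway: a gene set with activator/repressor role weights
#'
#' A pathway is a named, categorised gene set in which every member gene
#' carries a discrete activator/repressor role (ARR) weight: -1 (repressor),
#' -0.5 (partial repressor), 0 (role unknown), 0.5 (partial activator) or
#' 1 (activator). The weight multiplies the gene's contribution to the
#' pathway activation strength (PAS).
#'
#' @slot id single pathway identifier.
#' @slot name human-readable pathway name.
#' @slot category either \code{"signaling"} or \code{"metabolic"}.
#' @slot genes character vector of unique member gene symbols.
#' @slot arr numeric vector of ARR weights, parallel to \code{genes}.
#'
#' @aliases Pathway-class
#' @exportClass Pathway
#' @export Pathway
setClass("Pathway",
         representation(id = "character", name = "character",
                        category = "character", genes = "character",
                        arr = "numeric"))

setValidity("Pathway", function(object) {
    msg <- character(0)
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@category) != 1L ||
        !object@category %in% PATHWAY_CATEGORIES)
        msg <- c(msg, sprintf("'category' must be one of: %s",
                              paste(PATHWAY_CATEGORIES, collapse = ", ")))
    if (length(object@genes) == 0L)
        msg <- c(msg, "pathway has no member genes")
    if (anyDuplicated(object@genes))
        msg <- c(msg, sprintf("duplicated gene symbols in pathway '%s': %s",
                              object@id,
                              paste(unique(object@genes[duplicated(object@genes)]),
                                    collapse = ", ")))
    if (length(object@arr) != length(object@genes))
        msg <- c(msg, "'arr' and 'genes' lengths differ")
    bad <- !object@arr %in% ARR_LEVELS
    if (any(bad))
        msg <- c(msg, sprintf("ARR weights outside {%s}: %s",
                              paste(ARR_LEVELS, collapse = ", "),
                              paste(unique(object@arr[bad]), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @param id,name,category,genes,arr see slot descriptions.
#' @return \code{Pathway()} returns a validated \linkS4class{Pathway}.
#' @rdname Pathway-class
Pathway <- function(id, name = id, category, genes,
                    arr = rep(1, length(genes))) {
    genes <- trimws(as.character(genes))
    new("Pathway", id = as.character(id), name = as.character(name),
        category = as.character(category), genes = genes,
        arr = as.numeric(arr))
}

setMethod("show", "Pathway", function(object) {
    cat(sprintf("Pathway '%s' (%s): %d genes [%s]\n", object@id,
                object@category, length(object@genes),
                paste(head(object@genes, 5), collapse = ", ")))
})

#' @describeIn Pathway member gene symbols.
#' @param x a \code{Pathway}.
#' @export
memberGenes <- function(x) {
    stopifnot(is(x, "Pathway"))
    x@genes
}

#' @describeIn Pathway ARR weights named by gene symbol.
#' @export
arrWeights <- function(x) {
    stopifnot(is(x, "Pathway"))
    setNames(x@arr, x@genes)
}

#' @describeIn Pathway pathway category (\code{"signaling"} or
#'   \code{"metabolic"}).
#' @export
pathwayCategory <- function(x) {
    stopifnot(is(x, "Pathway"))
    x@category
}

#' PathwayDatabase: a validated collection of pathways
#'
#' Holds a list of \linkS4class{Pathway} objects with unique identifiers and
#' a manifest of counts per category. Supports \code{length}, \code{names}
#' and \code{[[} (by index or id).
#'
#' @slot pathways list of \linkS4class{Pathway} objects.
#'
#' @aliases PathwayDatabase-class
#' @exportClass PathwayDatabase
#' @export PathwayDatabase
setClass("PathwayDatabase", representation(pathways = "list"))

setValidity("PathwayDatabase", function(object) {
    msg <- character(0)
    if (length(object@pathways) == 0L)
        msg <- c(msg, "no pathways")
    if (!all(vapply(object@pathways, is, logical(1), "Pathway")))
        msg <- c(msg, "all elements must be Pathway objects")
    else {
        ids <- vapply(object@pathways, function(p) p@id, character(1))
        if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicated pathway ids: %s",
                                  paste(unique(ids[duplicated(ids)]),
                                        collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' @param pathways list of \code{Pathway} objects.
#' @return \code{PathwayDatabase()} returns a validated database.
#' @rdname PathwayDatabase-class
PathwayDatabase <- function(pathways) {
    db <- new("PathwayDatabase", pathways = unname(pathways))
    names(db@pathways) <- pathwayIds(db)
    db
}

#' @describeIn PathwayDatabase pathway identifiers.
#' @param db a \code{PathwayDatabase}.
#' @export
pathwayIds <- function(db) {
    stopifnot(is(db, "PathwayDatabase"))
    vapply(db@pathways, function(p) p@id, character(1))
}

#' @describeIn PathwayDatabase per-pathway categories, named by id.
#' @export
pathwayCategories <- function(db) {
    stopifnot(is(db, "PathwayDatabase"))
    setNames(vapply(db@pathways, function(p) p@category, character(1)),
             pathwayIds(db))
}

#' @describeIn PathwayDatabase manifest: pathway counts per category.
#' @export
dbManifest <- function(db) {
    stopifnot(is(db, "PathwayDatabase"))
    cats <- factor(pathwayCategories(db), levels = PATHWAY_CATEGORIES)
    counts <- table(cats)
    setNames(as.integer(counts), names(counts))
}

setMethod("length", "PathwayDatabase", function(x) length(x@pathways))

setMethod("names", "PathwayDatabase", function(x) unname(pathwayIds(x)))

setMethod("[[", "PathwayDatabase", function(x, i, ...) x@pathways[[i]])

setMethod("show", "PathwayDatabase", function(object) {
    m <- dbManifest(object)
    cat(sprintf("PathwayDatabase: %d pathways (%d signaling, %d metabolic)\n",
                length(object), m[["signaling"]], m[["metabolic"]]))
})

#' NormReference: per-gene summary of the reference (norm) samples
#'
#' Stores, per gene, the mean and standard deviation of log2 expression over
#' the reference samples. The mean defines the denominator of the
#' case-to-normal ratio (CNR, a ratio to the geometric-mean norm) and the SD
#' defines the tolerance interval used by the beyond-tolerance-interval flag
#' (BTIF).
#'
#' @slot genes gene symbols.
#' @slot location per-gene mean of log2 expression across reference samples.
#' @slot dispersion per-gene SD of log2 expression across reference samples.
#' @slot nRef number of reference samples.
#' @slot refGroup label of the group the reference was built from.
#'
#' @aliases NormReference-class
#' @exportClass NormReference
setClass("NormReference",
         representation(genes = "character", location = "numeric",
                        dispersion = "numeric", nRef = "integer",
                        refGroup = "character"))

setValidity("NormReference", function(object) {
    msg <- character(0)
    n <- length(object@genes)
    if (length(object@location) != n || length(object@dispersion) != n)
        msg <- c(msg, "'location'/'dispersion' must parallel 'genes'")
    if (object@nRef < 2L)
        msg <- c(msg, "a norm reference needs at least 2 reference samples")
    if (any(object@dispersion < 0, na.rm = TRUE))
        msg <- c(msg, "dispersion must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NormReference", function(object) {
    cat(sprintf("NormReference: %d genes from %d '%s' samples\n",
                length(object@genes), object@nRef, object@refGroup))
})

#' @describeIn NormReference per-gene log2 location, named by gene.
#' @param x a \code{NormReference}.
#' @export
normLocation <- function(x) {
    stopifnot(is(x, "NormReference"))
    setNames(x@location, x@genes)
}

#' @describeIn NormReference per-gene log2 dispersion, named by gene.
#' @export
normDispersion <- function(x) {
    stopifnot(is(x, "NormReference"))
    setNames(x@dispersion, x@genes)
}

#' PASMatrix: pathway activation scores for pathways x samples
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"PAS"} assay holds one
#' pathway activation strength value per (pathway, sample). Row metadata
#' carries the pathway category and member coverage; object metadata records
#' the thresholds and norm reference used (provenance).
#'
#' @aliases PASMatrix-class
#' @exportClass PASMatrix
setClass("PASMatrix", contains = "SummarizedExperiment")

setValidity("PASMatrix", function(object) {
    if (!"PAS" %in% SummarizedExperiment::assayNames(object))
        return("PASMatrix must carry a 'PAS' assay")
    if (!all(is.finite(SummarizedExperiment::assay(object, "PAS"))))
        return("PAS values must all be finite")
    TRUE
})

#' @param scores pathways x samples numeric matrix with dimnames.
#' @param category per-pathway category vector (recycled/validated).
#' @param provenance list of provenance fields (thresholds, norm group, ...).
#' @param colData optional sample annotations.
#' @return \code{PASMatrix()} returns a validated \code{PASMatrix}.
#' @rdname PASMatrix-class
#' @export
PASMatrix <- function(scores, category = NA_character_, provenance = list(),
                      colData = NULL) {
    rd <- S4Vectors::DataFrame(category = rep(category, length.out = nrow(scores)),
                               row.names = rownames(scores))
    args <- list(assays = list(PAS = scores), rowData = rd,
                 metadata = provenance)
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("PASMatrix", se)
}

#' @describeIn PASMatrix the pathways x samples score matrix.
#' @param x a \code{PASMatrix}.
#' @export
pasScores <- function(x) {
    stopifnot(is(x, "PASMatrix"))
    SummarizedExperiment::assay(x, "PAS")
}
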