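#' Build a norm reference from reference samples
#'
#' Summarizes the reference ("norm") samples gene by gene: the mean and SD
#' of log2 expression. The mean is the log2 geometric-mean norm used as the
#' CNR denominator; the SD spans the tolerance interval behind the BTIF
#' gate. By default the norms emulate a universal RNA reference group; pass
#' \code{refGroup = "Skin"} to a higher-level caller to use normal skin as
#' the norm instead.
#'
#' @param x genes x samples matrix of positive intensities restricted to the
#'   reference samples, or a \linkS4class{SummarizedExperiment} with a
#'   \code{group} column in \code{colData}.
#' @param refGroup when \code{x} is a SummarizedExperiment, the group label
#'   whose samples define the norm (default \code{"Reference"}).
#' @return a \linkS4class{NormReference}.
#' @export
buildNormReference <- function(x, refGroup = "Reference") {
    if (is(x, "SummarizedExperiment")) {
        grp <- as.character(SummarizedExperiment::colData(x)$group)
        keep <- which(grp == refGroup)
        if (length(keep) == 0L)
            stop("no samples in reference group '", refGroup, "'")
        x <- SummarizedExperiment::assay(x)[, keep, drop = FALSE]
    } else refGroup <- as.character(refGroup)
    stopifnot(is.matrix(x))
    if (ncol(x) < 2L)
        stop("need at least 2 reference samples to define a tolerance interval")
    if (any(!is.finite(x)) || any(x <= 0))
        stop("reference intensities must be strictly positive and finite")
    L <- log2(x)
    new("NormReference", genes = rownames(x), location = rowMeans(L),
        dispersion = apply(L, 1L, sd), nRef = ncol(x), refGroup = refGroup)
}

#' Case-to-normal ratio (CNR)
#'
#' Ratio of a gene's expression in the case sample to its geometric-mean
#' expression over the reference samples.
#'
#' @param caseValue positive linear-scale intensity (vectorized).
#' @param normLocation log2 mean of the gene over the reference samples.
#' @return positive ratio(s); 1 means "equal to the norm".
#' @export
cnr <- function(caseValue, normLocation) {
    if (any(!is.finite(caseValue)) || any(caseValue <= 0))
        stop("case expression values must be strictly positive")
    caseValue / 2 ^ normLocation
}

#' Beyond-tolerance-interval flag (BTIF)
#'
#' The 0/1 gate on gene-level contributions to PAS. A gene is flagged (1)
#' only when both criteria of significantly differential expression hold:
#' (i) its log2 value lies outside the normal-theory tolerance interval
#' \eqn{location \pm z_{\alpha} \cdot dispersion} of the norms (two-sided,
#' \eqn{z_{0.05} = 1.96}), and (ii) its CNR differs from 1 by at least
#' \code{foldThreshold}-fold in either direction.
#'
#' @param caseValue positive linear-scale intensity (vectorized).
#' @param location log2 mean of the gene over reference samples.
#' @param dispersion log2 SD of the gene over reference samples; must be
#'   defined (at least two reference samples).
#' @param foldThreshold minimal fold change, default 1.5.
#' @param alpha two-sided tolerance level, default 0.05.
#' @return integer 0/1 flag(s).
#' @export
btif <- function(caseValue, location, dispersion, foldThreshold = 1.5,
                 alpha = 0.05) {
    if (any(!is.finite(caseValue)) || any(caseValue <= 0))
        stop("case expression values must be strictly positive")
    if (any(!is.finite(dispersion)) || any(dispersion < 0))
        stop("dispersion undefined: the norm reference needs >= 2 samples")
    z <- qnorm(1 - alpha / 2)
    dev <- log2(caseValue) - location
    outside <- abs(dev) > z * dispersion
    folded <- abs(dev) >= log2(foldThreshold)
    as.integer(outside & folded)
}

#' Pathway activation strength (PAS) of one pathway in one sample
#'
#' \deqn{PAS_p = \sum_{n} ARR_n \cdot BTIF_n \cdot \log_{10}(CNR_n)}
#' summed over the pathway's member genes \eqn{n}: the activator/repressor
#' role weight times the tolerance-gated log10 case-to-normal ratio.
#' Positive PAS marks abnormal activation of the pathway in the sample,
#' negative PAS repression. Member genes absent from the expression vector
#' or the norm reference are skipped and reported in the \code{"coverage"}
#' attribute.
#'
#' @param sampleExpression named vector of positive intensities (names =
#'   gene symbols).
#' @param pathway a \linkS4class{Pathway}.
#' @param ref a \linkS4class{NormReference}.
#' @param foldThreshold,alpha BTIF thresholds (see [btif()]).
#' @return numeric PAS value with attribute \code{coverage} =
#'   c(used, missing) member-gene counts.
#' @examples
#' ref <- new("NormReference", genes = c("A", "B", "C"),
#'            location = c(3, 3, 3), dispersion = rep(0.1, 3), nRef = 5L,
#'            refGroup = "Reference")
#' pw <- Pathway("p1", category = "signaling", genes = c("A", "B", "C"),
#'               arr = c(1, 1, -1))
#' x <- 2 ^ c(A = 4, B = 5, C = 1)  # CNR = 2, 4, 0.25
#' pasScore(x, pw, ref)             # log10(2) + log10(4) - log10(0.25)
#' @export
pasScore <- function(sampleExpression, pathway, ref, foldThreshold = 1.5,
                     alpha = 0.05) {
    stopifnot(is(pathway, "Pathway"), is(ref, "NormReference"))
    genes <- intersect(pathway@genes,
                       intersect(names(sampleExpression), ref@genes))
    if (length(genes) == 0L)
        stop("pathway '", pathway@id,
             "' has no member genes in the expression data")
    loc <- normLocation(ref)[genes]
    disp <- normDispersion(ref)[genes]
    xv <- sampleExpression[genes]
    w <- arrWeights(pathway)[genes]
    flags <- btif(xv, loc, disp, foldThreshold, alpha)
    val <- sum(w * flags * log10(cnr(xv, loc)))
    attr(val, "coverage") <- c(used = length(genes),
                               missing = length(pathway@genes) - length(genes))
    val
}

#' PAS matrix: score every pathway in every sample
#'
#' Vectorized PAS computation over a whole study. The norm reference is
#' built from the samples of \code{refGroup} (or supplied pre-built);
#' all other samples are scored by default. Genes absent from the norm
#' reference are excluded from every pathway (never imputed); pathways left
#' with zero expressed members are dropped with a warning and the run
#' continues.
#'
#' @param se \linkS4class{SummarizedExperiment} with positive intensities
#'   and a \code{group} column in \code{colData}.
#' @param db a \linkS4class{PathwayDatabase}.
#' @param refGroup group label defining the norms (default
#'   \code{"Reference"}; use \code{"Skin"} to score against normal skin).
#' @param foldThreshold,alpha BTIF thresholds (see [btif()]).
#' @param samples sample ids to score; default all non-reference samples.
#' @param ref optional pre-built \linkS4class{NormReference}.
#' @return a \linkS4class{PASMatrix} (pathways x samples) whose metadata
#'   records thresholds and norm provenance and whose rowData carries the
#'   pathway category and member coverage.
#' @export
pasMatrix <- function(se, db, refGroup = "Reference", foldThreshold = 1.5,
                      alpha = 0.05, samples = NULL, ref = NULL) {
    stopifnot(is(se, "SummarizedExperiment"), is(db, "PathwayDatabase"))
    grp <- as.character(SummarizedExperiment::colData(se)$group)
    expr <- SummarizedExperiment::assay(se)
    refSamples <- colnames(se)[grp == refGroup]
    if (is.null(ref)) {
        if (length(refSamples) < 2L)
            stop("reference group '", refGroup,
                 "' needs at least 2 samples (found ", length(refSamples), ")")
        ref <- buildNormReference(expr[, refSamples, drop = FALSE], refGroup)
    }
    if (is.null(samples)) samples <- setdiff(colnames(se), refSamples)
    stopifnot(all(samples %in% colnames(se)))
    genes <- intersect(rownames(expr), ref@genes)
    x <- expr[genes, samples, drop = FALSE]
    if (any(!is.finite(x)) || any(x <= 0))
        stop("expression values must be strictly positive and finite")
    loc <- normLocation(ref)[genes]
    disp <- normDispersion(ref)[genes]
    z <- qnorm(1 - alpha / 2)
    dev <- log2(x) - loc
    gated <- (abs(dev) > z * disp) & (abs(dev) >= log2(foldThreshold))
    contrib <- (dev * log10(2)) * gated   # log10(CNR), tolerance-gated
    ## membership weights: pathways x genes
    ids <- pathwayIds(db)
    W <- matrix(0, nrow = length(db), ncol = length(genes),
                dimnames = list(ids, genes))
    used <- integer(length(db)); total <- integer(length(db))
    for (i in seq_along(db@pathways)) {
        p <- db@pathways[[i]]
        g <- intersect(p@genes, genes)
        W[i, g] <- arrWeights(p)[g]
        used[i] <- length(g); total[i] <- length(p@genes)
    }
    empty <- used == 0L
    if (any(empty)) {
        warning("dropping ", sum(empty),
                " pathway(s) with no member genes in the expression data: ",
                paste(head(ids[empty], 5), collapse = ", "),
                if (sum(empty) > 5) ", ...")
    }
    scores <- W[!empty, , drop = FALSE] %*% contrib
    rd <- data.frame(category = unname(pathwayCategories(db))[!empty],
                     genesUsed = used[!empty], genesTotal = total[!empty])
    out <- PASMatrix(scores, category = rd$category,
                     provenance = list(
                         foldThreshold = foldThreshold, alpha = alpha,
                         refGroup = ref@refGroup, nRef = ref@nRef,
                         dbManifest = as.list(dbManifest(db))),
                     colData = SummarizedExperiment::colData(se)[samples, ,
                                                                 drop = FALSE])
    SummarizedExperiment::rowData(out)$genesUsed <- rd$genesUsed
    SummarizedExperiment::rowData(out)$genesTotal <- rd$genesTotal
    out
}
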