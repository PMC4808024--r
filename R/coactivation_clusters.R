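#' Pearson correlation between pathway activation profiles
#'
#' Functional coordination: how similarly two pathways' PAS values move
#' across samples, irrespective of whether they share genes.
#'
#' @param pas features x samples matrix or \linkS4class{PASMatrix} with at
#'   least 3 samples.
#' @return symmetric correlation matrix with unit diagonal; correlations
#'   involving a zero-variance pathway are \code{NA} with a warning.
#' @export
pathwayCorrelation <- function(pas) {
    m <- if (is(pas, "PASMatrix")) pasScores(pas) else pas
    stopifnot(is.matrix(m))
    if (ncol(m) < 3L) stop("need at least 3 samples to correlate pathways")
    flat <- apply(m, 1L, sd) == 0
    if (any(flat))
        warning("zero-variance pathway(s), correlations undefined: ",
                paste(head(rownames(m)[flat], 5), collapse = ", "))
    cc <- suppressWarnings(cor(t(m)))
    diag(cc) <- 1
    cc
}

#' Detect co-activation modules from a pathway correlation matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' \eqn{1 - |r|} (unsigned: congruent repression counts as coordination),
#' cut at a fixed height; clusters smaller than \code{minSize} are
#' dissolved to unassigned (id 0). Cluster ids are ordered by decreasing
#' size for determinism.
#'
#' @param corr symmetric correlation matrix as from [pathwayCorrelation()].
#' @param minSize minimum module size, default 5.
#' @param cutHeight dendrogram cut height on the \eqn{1 - |r|} scale
#'   (0 = perfectly coordinated, 1 = uncorrelated).
#' @return a \code{ClusterAssignment}: list with \code{assignment} (named
#'   integer vector, 0 = unassigned), \code{clusters} (list of member
#'   vectors) and \code{summary} (per-module size and mean pairwise |r|).
#' @export
detectModules <- function(corr, minSize = 5L, cutHeight = 0.5) {
    stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
    if (minSize < 2L) stop("minSize must be at least 2")
    cc <- corr
    cc[!is.finite(cc)] <- 0
    d <- stats::as.dist(1 - abs(cc))
    hc <- hclust(d, method = "average")
    raw <- cutree(hc, h = cutHeight)
    sizes <- table(raw)
    keepIds <- names(sizes)[sizes >= minSize]
    assignment <- setNames(rep(0L, nrow(corr)), rownames(corr))
    ## renumber retained clusters by decreasing size, ties by first member
    ord <- keepIds[order(-sizes[keepIds],
                         vapply(keepIds, function(k) min(which(raw == k)),
                                integer(1)))]
    for (i in seq_along(ord))
        assignment[raw == ord[i]] <- i
    clusters <- lapply(seq_along(ord), function(i)
        names(assignment)[assignment == i])
    meanAbsR <- vapply(clusters, function(mem) {
        sub <- abs(cc[mem, mem, drop = FALSE])
        mean(sub[upper.tri(sub)])
    }, numeric(1))
    structure(list(assignment = assignment,
                   clusters = clusters,
                   summary = data.frame(cluster = seq_along(ord),
                                        size = lengths(clusters),
                                        meanAbsR = meanAbsR),
                   params = list(minSize = minSize, cutHeight = cutHeight)),
              class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
    cat(sprintf("ClusterAssignment: %d module(s), %d of %d pathways assigned\n",
                length(x$clusters), sum(x$assignment > 0),
                length(x$assignment)))
    if (nrow(x$summary)) print(x$summary, row.names = FALSE)
    invisible(x)
}

#' Filter module members by their correlation to the rest of the module
#'
#' A member is kept iff its mean absolute correlation to the other members
#' exceeds \code{meanCut}, or it has at least one correlation above
#' \code{singleCut} with another member (self-correlation excluded). The
#' rules are evaluated once against the full membership, so the result is
#' invariant to member order.
#'
#' @param members character vector of module member names (at least 2).
#' @param corr correlation matrix covering the members.
#' @param meanCut mean |r| rule threshold, default 0.7.
#' @param singleCut single-link rule threshold, default 0.85.
#' @return the retained members, in input order.
#' @export
filterClusterMembers <- function(members, corr, meanCut = 0.7,
                                 singleCut = 0.85) {
    if (length(members) < 2L)
        stop("cannot correlation-filter a singleton cluster")
    stopifnot(all(members %in% rownames(corr)))
    keep <- vapply(members, function(mm) {
        r <- corr[mm, setdiff(members, mm)]
        mean(abs(r)) > meanCut || max(r) > singleCut
    }, logical(1))
    members[keep]
}

#' Ward clustering of samples on their PAS profiles
#'
#' Ward linkage on Euclidean distances between sample profiles, with a flat
#' cut at the given height. The cut height depends on the scale of the data
#' at hand and is therefore a required choice, not a constant.
#'
#' @param pas features x samples matrix or \linkS4class{PASMatrix} with at
#'   least 2 samples.
#' @param cutHeight positive dendrogram cut height.
#' @return list with the \code{hclust} tree and \code{clusters} (named
#'   integer vector of flat cluster ids).
#' @export
wardSampleClustering <- function(pas, cutHeight) {
    m <- if (is(pas, "PASMatrix")) pasScores(pas) else pas
    stopifnot(is.matrix(m))
    if (ncol(m) < 2L) stop("need at least 2 samples to cluster")
    if (!is.numeric(cutHeight) || cutHeight <= 0)
        stop("cutHeight must be positive")
    hc <- hclust(dist(t(m)), method = "ward.D2")
    list(hclust = hc, clusters = cutree(hc, h = cutHeight))
}

#' Functional coordination versus structural similarity of a module
#'
#' Pairs the PAS correlation matrix of a module with the Jaccard
#' gene-overlap matrix of the same pathways. Modules whose members are
#' strongly correlated yet share few genes are functionally coordinated
#' without structural overlap.
#'
#' @param members module member pathway ids.
#' @param corr PAS correlation matrix covering the members.
#' @param db a \linkS4class{PathwayDatabase} containing every member.
#' @return list with \code{correlation} and \code{jaccard} matrices plus a
#'   \code{summary} vector (mean off-diagonal |r|, mean off-diagonal
#'   Jaccard).
#' @export
coordinationVsStructure <- function(members, corr, db) {
    stopifnot(is(db, "PathwayDatabase"))
    missing <- setdiff(members, pathwayIds(db))
    if (length(missing))
        stop("module member(s) missing from the pathway database: ",
             paste(missing, collapse = ", "))
    stopifnot(all(members %in% rownames(corr)))
    cc <- corr[members, members, drop = FALSE]
    jm <- jaccardMatrix(lapply(members, function(id) db[[id]]))
    offdiag <- function(m) m[upper.tri(m)]
    list(correlation = cc, jaccard = jm,
         summary = c(meanAbsR = mean(abs(offdiag(cc))),
                     meanJaccard = mean(offdiag(jm))))
}
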