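#' Read a pathway database from a tab-separated file
#'
#' The file dialect is one row per (pathway, gene) membership with columns
#' \code{pathway_id}, \code{pathway_name}, \code{category},
#' \code{gene_symbol} and \code{arr} (header required, UTF-8, no quoting).
#' Rows belonging to one pathway are grouped by \code{pathway_id}. A plain
#' GMT gene-set file can be converted to this dialect by writing one row per
#' gene with \code{arr = 1.0} (every member treated as an activator) and a
#' chosen category.
#'
#' @param path path to the TSV file.
#' @return a validated \linkS4class{PathwayDatabase}.
#' @examples
#' f <- system.file("extdata", "example_pathway_db.tsv", package = "pasflow")
#' db <- readPathwayDB(f)
#' dbManifest(db)
#' @export
readPathwayDB <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) <= 1L) stop("no pathways in '", path, "'")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    expected <- c("pathway_id", "pathway_name", "category", "gene_symbol",
                  "arr")
    if (!identical(trimws(header), expected))
        stop("malformed header at line 1: expected columns ",
             paste(expected, collapse = ", "))
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 5L))
        stop("malformed line ", which(nf != 5L)[1L] + 1L,
             ": expected 5 tab-separated fields, got ", nf[nf != 5L][1L])
    rec <- data.frame(
        pathway_id = trimws(vapply(fields, `[[`, character(1), 1L)),
        pathway_name = trimws(vapply(fields, `[[`, character(1), 2L)),
        category = trimws(vapply(fields, `[[`, character(1), 3L)),
        gene_symbol = trimws(vapply(fields, `[[`, character(1), 4L)),
        arr_raw = trimws(vapply(fields, `[[`, character(1), 5L)),
        stringsAsFactors = FALSE)
    arr <- suppressWarnings(as.numeric(rec$arr_raw))
    if (anyNA(arr))
        stop("malformed line ", which(is.na(arr))[1L] + 1L,
             ": ARR weight '", rec$arr_raw[is.na(arr)][1L],
             "' is not a number")
    badArr <- !arr %in% ARR_LEVELS
    if (any(badArr))
        stop("validation error at line ", which(badArr)[1L] + 1L,
             ": ARR weight ", arr[badArr][1L], " outside allowed set {",
             paste(ARR_LEVELS, collapse = ", "), "}")
    badCat <- !rec$category %in% PATHWAY_CATEGORIES
    if (any(badCat))
        stop("validation error at line ", which(badCat)[1L] + 1L,
             ": unknown category '", rec$category[badCat][1L], "'")
    rec$arr <- arr
    split_idx <- split(seq_len(nrow(rec)), rec$pathway_id)
    ## preserve first-appearance order of pathways
    split_idx <- split_idx[order(vapply(split_idx, min, integer(1)))]
    pathways <- lapply(split_idx, function(i) {
        g <- rec$gene_symbol[i]
        if (anyDuplicated(g))
            stop("validation error: duplicated gene '",
                 g[duplicated(g)][1L], "' within pathway '",
                 rec$pathway_id[i[1L]], "'")
        if (length(unique(rec$category[i])) > 1L)
            stop("validation error: pathway '", rec$pathway_id[i[1L]],
                 "' has conflicting categories")
        Pathway(id = rec$pathway_id[i[1L]], name = rec$pathway_name[i[1L]],
                category = rec$category[i[1L]], genes = g, arr = rec$arr[i])
    })
    PathwayDatabase(pathways)
}

#' Write a pathway database to the TSV dialect read by [readPathwayDB()]
#'
#' @param db a \linkS4class{PathwayDatabase}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePathwayDB <- function(db, path) {
    stopifnot(is(db, "PathwayDatabase"))
    rows <- do.call(rbind, lapply(db@pathways, function(p) {
        data.frame(pathway_id = p@id, pathway_name = p@name,
                   category = p@category, gene_symbol = p@genes,
                   arr = p@arr, stringsAsFactors = FALSE)
    }))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Jaccard index between the gene sets of two pathways
#'
#' Structural (gene-content) similarity: size of the gene intersection over
#' the size of the gene union. Compares what the pathways are made of, not
#' whether they are co-activated.
#'
#' @param a,b \linkS4class{Pathway} objects.
#' @return a value in \eqn{[0, 1]}; 1 iff identical gene sets, 0 iff
#'   disjoint.
#' @export
jaccardIndex <- function(a, b) {
    stopifnot(is(a, "Pathway"), is(b, "Pathway"))
    ga <- unique(a@genes); gb <- unique(b@genes)
    if (length(ga) == 0L || length(gb) == 0L)
        stop("cannot compute a Jaccard index for an empty pathway")
    length(intersect(ga, gb)) / length(union(ga, gb))
}

#' Pairwise Jaccard matrix over a set of pathways
#'
#' @param pathways a \linkS4class{PathwayDatabase} or a list of
#'   \linkS4class{Pathway} objects (at least two).
#' @return a symmetric matrix in \eqn{[0, 1]} with unit diagonal, with
#'   pathway ids as dimnames.
#' @export
jaccardMatrix <- function(pathways) {
    if (is(pathways, "PathwayDatabase")) pathways <- pathways@pathways
    stopifnot(is.list(pathways))
    if (length(pathways) < 2L)
        stop("need at least 2 pathways for a Jaccard matrix")
    n <- length(pathways)
    ids <- vapply(pathways, function(p) p@id, character(1))
    m <- diag(nrow = n)
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            m[i, j] <- m[j, i] <- jaccardIndex(pathways[[i]], pathways[[j]])
        }
    }
    dimnames(m) <- list(ids, ids)
    m
}
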