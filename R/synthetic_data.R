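#' Configuration for the synthetic melanoma study generator
#'
#' Describes a fully known ground-truth study: four tissue classes plus a
#' reference-norm group, two platform batches with differing location and
#' scale, log-normally distributed intensities, planted per-pathway
#' activation shifts with known directions across the five progression
#' contrasts, and optional groups of pathways sharing a latent activation
#' factor (co-activation clusters with disjoint gene content).
#'
#' Class structure is generated from per-class pathway-level log2 shifts
#' (deltas), not from per-contrast hacks, so all five contrasts are
#' internally consistent by construction. Nevus samples apply their deltas
#' with a per-sample attenuation factor and extra pathway-level noise,
#' emulating the highly variable, intermediate character of nevi.
#'
#' @param seed RNG seed; a fixed seed makes the generated study
#'   byte-reproducible.
#' @param nGenes number of genes.
#' @param genesPerPathway member genes per pathway; pathways partition the
#'   gene pool when it is large enough, otherwise membership is sampled
#'   with overlap.
#' @param nPathways named counts per category,
#'   \code{c(signaling = , metabolic = )}.
#' @param nPerGroup named sample counts per group (Skin, Nevus,
#'   PrimaryMelanoma, MetastaticMelanoma, Reference).
#' @param nPlanted named counts of planted discriminative pathways per
#'   category (ignored when \code{signatures} is supplied).
#' @param effectSize planted per-class shift magnitude, log2 fold units.
#' @param noiseSD per-gene per-sample log2 noise SD.
#' @param pathwayNoiseSD SD of the per-sample pathway-level activation
#'   jitter shared by a pathway's members (decorrelates pathways that share
#'   a planted pattern).
#' @param nevusAttenuation range of the per-sample multiplier Nevus samples
#'   apply to their planted deltas.
#' @param nevusExtraNoiseSD additional pathway-level jitter SD for Nevus
#'   samples.
#' @param platforms named platform fractions, e.g.
#'   \code{c(GPL96 = 0.3, GPL570 = 0.7)}.
#' @param batchShift,batchScale affine log2 distortion applied to every
#'   platform after the first.
#' @param coordCluster \code{NULL} or a list with \code{size},
#'   \code{factorSD} and \code{category}: a group of non-planted pathways
#'   whose member genes share a per-sample latent activation factor.
#' @param signatures \code{NULL} or a data.frame with columns \code{name},
#'   \code{category}, \code{deltaNevus}, \code{deltaPrimary},
#'   \code{deltaMetastatic} giving explicit planted per-class shifts (see
#'   [plantTableSignatures()]).
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 2000L,
                      genesPerPathway = 10L,
                      nPathways = c(signaling = 100L, metabolic = 100L),
                      nPerGroup = c(Skin = 30L, Nevus = 20L,
                                    PrimaryMelanoma = 30L,
                                    MetastaticMelanoma = 30L,
                                    Reference = 10L),
                      nPlanted = c(signaling = 10L, metabolic = 10L),
                      effectSize = 2,
                      noiseSD = 0.7,
                      pathwayNoiseSD = 0.4,
                      nevusAttenuation = c(0.6, 1.2),
                      nevusExtraNoiseSD = 0.5,
                      platforms = c(GPL96 = 0.3, GPL570 = 0.7),
                      batchShift = 0.5,
                      batchScale = 1.15,
                      coordCluster = list(size = 8L, factorSD = 2,
                                          category = "signaling"),
                      signatures = NULL) {
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                genesPerPathway = as.integer(genesPerPathway),
                nPathways = nPathways, nPerGroup = nPerGroup,
                nPlanted = nPlanted, effectSize = effectSize,
                noiseSD = noiseSD, pathwayNoiseSD = pathwayNoiseSD,
                nevusAttenuation = nevusAttenuation,
                nevusExtraNoiseSD = nevusExtraNoiseSD,
                platforms = platforms, batchShift = batchShift,
                batchScale = batchScale, coordCluster = coordCluster,
                signatures = signatures)
    validateSimConfig(cfg)
    structure(cfg, class = "SimConfig")
}

validateSimConfig <- function(cfg) {
    stopifnot(all(PATHWAY_CATEGORIES %in% names(cfg$nPathways)),
              all(SAMPLE_GROUPS %in% names(cfg$nPerGroup)))
    if (cfg$genesPerPathway > cfg$nGenes)
        stop("contradictory config: a pathway (", cfg$genesPerPathway,
             " genes) cannot exceed the gene pool (", cfg$nGenes, ")")
    if (cfg$effectSize < 0 || cfg$noiseSD < 0 || cfg$pathwayNoiseSD < 0)
        stop("effect sizes and noise SDs must be non-negative")
    if (any(cfg$platforms < 0) || abs(sum(cfg$platforms) - 1) > 1e-8)
        stop("platform fractions must be non-negative and sum to 1")
    if (!is.null(cfg$signatures)) {
        need <- c("name", "category", "deltaNevus", "deltaPrimary",
                  "deltaMetastatic")
        stopifnot(all(need %in% colnames(cfg$signatures)))
        for (cat in PATHWAY_CATEGORIES) {
            np <- sum(cfg$signatures$category == cat)
            if (np > cfg$nPathways[[cat]])
                stop("more planted ", cat, " signatures (", np,
                     ") than pathways (", cfg$nPathways[[cat]], ")")
        }
    } else {
        for (cat in PATHWAY_CATEGORIES)
            if (cfg$nPlanted[[cat]] > cfg$nPathways[[cat]])
                stop("more planted ", cat, " pathways than pathways")
    }
    if (!is.null(cfg$coordCluster)) {
        cc <- cfg$coordCluster
        stopifnot(all(c("size", "factorSD", "category") %in% names(cc)))
    }
    invisible(TRUE)
}

## Least-squares per-class log2 shifts (Skin fixed at 0) reproducing a
## direction pattern over the five progression contrasts; errors when the
## pattern admits no sign-consistent class-mean assignment.
solveClassDeltas <- function(directions, effectSize = 1, label = "pattern") {
    stopifnot(length(directions) == 5L)
    if (!all(directions %in% c("UP", "DOWN")))
        stop("directions must be UP or DOWN")
    X <- rbind(NevusVsSkin = c(1, 0, 0),
               PrimaryVsSkin = c(0, 1, 0),
               MetastaticVsSkin = c(0, 0, 1),
               MetastaticVsPrimary = c(0, -1, 1),
               PrimaryVsNevus = c(-1, 1, 0))
    y <- ifelse(directions == "UP", 1, -1)
    d <- qr.solve(qr(X), y)
    pred <- as.vector(X %*% d)
    if (any(sign(pred) != sign(y)) || any(abs(pred) < 1e-9))
        stop("contradictory direction pattern for '", label,
             "': no per-class mean assignment matches ",
             paste(directions, collapse = " "))
    setNames(d * effectSize, c("Nevus", "PrimaryMelanoma",
                               "MetastaticMelanoma"))
}

deltaDirections <- function(dN, dP, dM) {
    diffs <- c(NevusVsSkin = dN, PrimaryVsSkin = dP, MetastaticVsSkin = dM,
               MetastaticVsPrimary = dM - dP, PrimaryVsNevus = dP - dN)
    ifelse(abs(diffs) < 1e-12, "none", ifelse(diffs > 0, "UP", "DOWN"))
}

#' Plant the published direction signatures into a generator config
#'
#' Converts a transcribed direction table (pathway name plus UP/DOWN cells
#' for the five progression contrasts) into explicit per-class planted
#' shifts, solved by least squares with Skin fixed at zero and verified for
#' sign consistency; a contradictory row raises an error naming it. The
#' resulting config generates pathways named after the table rows whose
#' recovered direction table should reproduce every cell.
#'
#' @param config a \code{SimConfig}.
#' @param table data.frame with a pathway-name first column and the five
#'   contrast columns (as from
#'   \code{melanomaTableFixture("metabolic_directions")}). An empty table
#'   leaves the config unchanged.
#' @param category pathway category to assign to the table's rows.
#' @param effectSize planted shift magnitude; default the config's.
#' @return the updated \code{SimConfig}.
#' @export
plantTableSignatures <- function(config, table,
                                 category = c("metabolic", "signaling"),
                                 effectSize = config$effectSize) {
    stopifnot(inherits(config, "SimConfig"), is.data.frame(table))
    category <- match.arg(category)
    if (nrow(table) == 0L) return(config)
    contrastCols <- c("NevusVsSkin", "PrimaryVsSkin", "MetastaticVsSkin",
                      "MetastaticVsPrimary", "PrimaryVsNevus")
    if (!all(contrastCols %in% colnames(table)))
        stop("table must have contrast columns: ",
             paste(contrastCols, collapse = ", "))
    nameCol <- setdiff(colnames(table), contrastCols)[1L]
    rows <- lapply(seq_len(nrow(table)), function(i) {
        d <- solveClassDeltas(unlist(table[i, contrastCols]), effectSize,
                              label = table[[nameCol]][i])
        data.frame(name = table[[nameCol]][i], category = category,
                   deltaNevus = d[["Nevus"]],
                   deltaPrimary = d[["PrimaryMelanoma"]],
                   deltaMetastatic = d[["MetastaticMelanoma"]],
                   stringsAsFactors = FALSE)
    })
    config$signatures <- rbind(config$signatures, do.call(rbind, rows))
    validateSimConfig(config)
    config
}

#' Generate a synthetic melanoma study with planted ground truth
#'
#' Draws baseline log2 expression per gene (means uniform on 6-12, normal
#' noise), plants per-class pathway shifts consistent with the configured
#' signatures (activator genes move with the pathway, repressor genes
#' against it), adds per-pathway activation jitter, a latent co-activation
#' factor for the configured cluster, and an affine platform batch
#' distortion, then emits linear-scale intensities.
#'
#' @param config a \code{SimConfig}.
#' @return list with \code{se} (a \linkS4class{SummarizedExperiment} of
#'   positive intensities with sample annotations), \code{db} (the
#'   \linkS4class{PathwayDatabase}), and \code{truth} (planted signatures
#'   with per-contrast directions, planted pathway ids, co-activation
#'   cluster members and the gene membership table).
#' @export
simulateStudy <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    validateSimConfig(config)
    withr::with_seed(config$seed, .simulateStudy(config))
}

.simulateStudy <- function(cfg) {
    nG <- cfg$nGenes
    genes <- sprintf("G%04d", seq_len(nG))
    mu <- runif(nG, 6, 12)
    names(mu) <- genes

    ## ---- pathway database -------------------------------------------------
    nPW <- sum(cfg$nPathways[PATHWAY_CATEGORIES])
    cats <- rep(PATHWAY_CATEGORIES, cfg$nPathways[PATHWAY_CATEGORIES])
    prefix <- ifelse(cats == "signaling", "SIG", "MET")
    within <- unlist(lapply(cfg$nPathways[PATHWAY_CATEGORIES], seq_len))
    ids <- sprintf("%s_%03d", prefix, within)
    pwNames <- sprintf("%s pathway %03d",
                       ifelse(cats == "signaling", "Signaling", "Metabolic"),
                       within)
    demand <- nPW * cfg$genesPerPathway
    memberIdx <- if (demand <= nG) {
        split(sample(nG, demand), rep(seq_len(nPW), each = cfg$genesPerPathway))
    } else {
        lapply(seq_len(nPW), function(i) sample(nG, cfg$genesPerPathway))
    }
    arrProb <- c(`-1` = 0.15, `-0.5` = 0.10, `0` = 0.10, `0.5` = 0.15,
                 `1` = 0.50)
    pathways <- vector("list", nPW)
    for (i in seq_len(nPW)) {
        repeat {
            arr <- sample(ARR_LEVELS, cfg$genesPerPathway, replace = TRUE,
                          prob = arrProb)
            if (any(arr != 0)) break
        }
        pathways[[i]] <- Pathway(id = ids[i], name = pwNames[i],
                                 category = cats[i],
                                 genes = genes[memberIdx[[i]]], arr = arr)
    }

    ## ---- planted signatures ----------------------------------------------
    if (!is.null(cfg$signatures)) {
        sig <- cfg$signatures
        plantedIdx <- integer(nrow(sig))
        for (cat in PATHWAY_CATEGORIES) {
            rows <- which(sig$category == cat)
            slots <- which(cats == cat)[seq_along(rows)]
            plantedIdx[rows] <- slots
            for (k in seq_along(rows))  # planted pathways take the row names
                pathways[[slots[k]]]@name <- sig$name[rows[k]]
        }
    } else {
        sig <- NULL; plantedIdx <- integer(0)
        for (cat in PATHWAY_CATEGORIES) {
            np <- cfg$nPlanted[[cat]]
            if (np == 0) next
            slots <- which(cats == cat)[seq_len(np)]
            draws <- do.call(rbind, lapply(slots, function(i) {
                d <- cfg$effectSize * sample(c(-1, 1), 3, TRUE) *
                    runif(3, 0.5, 1.5)
                data.frame(name = pathways[[i]]@name, category = cat,
                           deltaNevus = d[1], deltaPrimary = d[2],
                           deltaMetastatic = d[3], stringsAsFactors = FALSE)
            }))
            sig <- rbind(sig, draws)
            plantedIdx <- c(plantedIdx, slots)
        }
    }
    if (!is.null(sig)) sig$pathway_id <- ids[plantedIdx]

    ## ---- co-activation cluster -------------------------------------------
    coordIds <- character(0)
    coordIdx <- integer(0)
    if (!is.null(cfg$coordCluster)) {
        cc <- cfg$coordCluster
        pool <- setdiff(which(cats == cc$category), plantedIdx)
        if (length(pool) < cc$size)
            stop("not enough non-planted '", cc$category,
                 "' pathways for the co-activation cluster")
        coordIdx <- tail(pool, cc$size)   # deterministic tail of the pool
        coordIds <- ids[coordIdx]
    }

    ## ---- samples ----------------------------------------------------------
    nPer <- cfg$nPerGroup[SAMPLE_GROUPS]
    groups <- rep(SAMPLE_GROUPS, nPer)
    sampleIds <- sprintf("%s_%02d", c(Skin = "SKN", Nevus = "NEV",
                                      PrimaryMelanoma = "PRM",
                                      MetastaticMelanoma = "MET",
                                      Reference = "REF")[groups],
                         unlist(lapply(nPer, seq_len)))
    nS <- length(sampleIds)
    platNames <- names(cfg$platforms)
    platform <- character(nS)
    for (g in SAMPLE_GROUPS) {   # per-group split so batches mix all classes
        idx <- which(groups == g)
        counts <- floor(length(idx) * cfg$platforms)
        counts[1L] <- length(idx) - sum(counts[-1L])
        platform[idx] <- sample(rep(platNames, counts))
    }

    ## ---- log2 expression ---------------------------------------------------
    L <- matrix(rnorm(nG * nS, mean = mu, sd = cfg$noiseSD), nrow = nG,
                dimnames = list(genes, sampleIds))
    nonRef <- groups != "Reference"
    isNevus <- groups == "Nevus"
    nevusMult <- rep(1, nS)
    nevusMult[isNevus] <- runif(sum(isNevus), cfg$nevusAttenuation[1L],
                                cfg$nevusAttenuation[2L])
    deltaFor <- function(row) c(Skin = 0, Nevus = row$deltaNevus,
                                PrimaryMelanoma = row$deltaPrimary,
                                MetastaticMelanoma = row$deltaMetastatic,
                                Reference = 0)
    coordFactor <- if (length(coordIds)) {
        f <- rnorm(nS, 0, cfg$coordCluster$factorSD)
        f[!nonRef] <- 0
        f
    } else NULL
    for (i in seq_len(nPW)) {
        p <- pathways[[i]]
        s <- sign(p@arr)
        rows <- memberIdx[[i]][s != 0]
        sg <- s[s != 0]
        if (!length(rows)) next
        ## pathway-level activation jitter, inflated for nevi
        jitterSD <- ifelse(isNevus, cfg$pathwayNoiseSD + cfg$nevusExtraNoiseSD,
                           cfg$pathwayNoiseSD)
        shift <- rnorm(nS, 0, jitterSD)
        shift[!nonRef] <- 0
        k <- match(ids[i], sig$pathway_id)
        if (!is.na(k))
            shift <- shift + deltaFor(sig[k, ])[groups] * nevusMult
        if (ids[i] %in% coordIds)
            shift <- shift + coordFactor
        L[rows, ] <- L[rows, ] + outer(sg, shift)
    }

    ## ---- platform batch distortion -----------------------------------------
    for (k in seq_along(platNames)[-1L]) {
        idx <- platform == platNames[k]
        L[, idx] <- cfg$batchShift * (k - 1) + cfg$batchScale ^ (k - 1) * L[, idx]
    }

    annot <- data.frame(sample_id = sampleIds, group = groups,
                        dataset_id = paste0("SIM_", platform),
                        platform = platform, stringsAsFactors = FALSE)
    se <- makeStudyExperiment(2 ^ L, annot)
    db <- PathwayDatabase(pathways)

    truth <- list(planted = if (is.null(sig)) character(0) else sig$pathway_id,
                  coordCluster = coordIds,
                  membership = do.call(rbind, lapply(pathways, function(p)
                      data.frame(pathway_id = p@id, gene = p@genes,
                                 arr = p@arr, stringsAsFactors = FALSE))))
    if (!is.null(sig)) {
        dirs <- t(vapply(seq_len(nrow(sig)), function(k)
            deltaDirections(sig$deltaNevus[k], sig$deltaPrimary[k],
                            sig$deltaMetastatic[k]), character(5)))
        truth$signatures <- cbind(sig, as.data.frame(dirs,
                                                     stringsAsFactors = FALSE))
    } else truth$signatures <- NULL

    list(se = se, db = db, truth = truth)
}
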