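smallCfg <- function(seed = 30, ...) {
    defaults <- list(seed = seed, nGenes = 600,
                     nPathways = c(signaling = 15, metabolic = 15),
                     nPerGroup = c(Skin = 15, Nevus = 10,
                                   PrimaryMelanoma = 15,
                                   MetastaticMelanoma = 15, Reference = 6),
                     nPlanted = c(signaling = 3, metabolic = 3))
    user <- list(...)
    defaults[names(user)] <- user
    do.call(simConfig, defaults)
}

test_that("the generator is deterministic and internally consistent", {
    a <- simulateStudy(smallCfg())
    b <- simulateStudy(smallCfg())
    expect_identical(SummarizedExperiment::assay(a$se),
                     SummarizedExperiment::assay(b$se))
    expect_identical(a$truth, b$truth)
    ## emitted database matches the ground-truth membership table
    expect_identical(length(a$db), 30L)
    p1 <- a$db[[a$truth$membership$pathway_id[1]]]
    expect_identical(memberGenes(p1),
                     a$truth$membership$gene[
                         a$truth$membership$pathway_id == p1@id])
    ## intensities are strictly positive (log-normal scale)
    expect_true(all(SummarizedExperiment::assay(a$se) > 0))
    ## annotations cover every sample exactly once
    cd <- SummarizedExperiment::colData(a$se)
    expect_identical(sum(cd$group == "Nevus"), 10L)
    expect_identical(anyDuplicated(rownames(cd)), 0L)
})

test_that("contradictory config and direction patterns are rejected", {
    expect_error(simConfig(nGenes = 5, genesPerPathway = 10),
                 "contradictory config")
    ## Nevus below Skin yet Primary below Nevus cannot give Primary above
    ## Skin: no class-mean assignment realizes this pattern
    bad <- data.frame(Pathway = "impossible",
                      NevusVsSkin = "DOWN", PrimaryVsSkin = "UP",
                      MetastaticVsSkin = "UP", MetastaticVsPrimary = "UP",
                      PrimaryVsNevus = "DOWN")
    expect_error(plantTableSignatures(smallCfg(), bad, "metabolic"),
                 "impossible")
})

test_that("table planting yields 44 consistent signatures with row names", {
    cfg <- simConfig(seed = 31,
                     nPathways = c(signaling = 30, metabolic = 30),
                     nPlanted = c(signaling = 0, metabolic = 0))
    cfg <- plantTableSignatures(cfg,
        melanomaTableFixture("metabolic_directions"), "metabolic")
    expect_identical(nrow(cfg$signatures), 25L)
    cfg <- plantTableSignatures(cfg,
        melanomaTableFixture("signaling_directions"), "signaling")
    expect_identical(nrow(cfg$signatures), 44L)
    ## an empty table changes nothing
    empty <- melanomaTableFixture("metabolic_directions")[0, ]
    expect_identical(plantTableSignatures(cfg, empty, "metabolic"), cfg)
    ## planted deltas reproduce each row's direction pattern exactly
    sim <- simulateStudy(cfg)
    truth <- sim$truth$signatures
    tab <- rbind(melanomaTableFixture("metabolic_directions"),
                 melanomaTableFixture("signaling_directions"))
    ord <- match(truth$name, tab$Pathway)
    for (cc in contrastColumns())
        expect_identical(truth[[cc]], tab[[cc]][ord], label = cc)
})

test_that("a null configuration produces a statistically null PAS matrix", {
    ## cells within a pathway share the reference-location estimation
    ## error, so the honest replication unit is the generator seed
    seeds <- 32:36
    perSeed <- vapply(seeds, function(s) {
        cfg <- smallCfg(seed = s,
                        nPlanted = c(signaling = 0, metabolic = 0),
                        pathwayNoiseSD = 0, nevusExtraNoiseSD = 0,
                        coordCluster = NULL)
        sim <- simulateStudy(cfg)
        pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
        rowMeans(pasScores(pm))
    }, numeric(30))
    grand <- rowMeans(perSeed)                     # per pathway, over seeds
    se <- apply(perSeed, 1, sd) / sqrt(length(seeds))
    expect_lt(abs(mean(perSeed)),
              3 * sd(colMeans(perSeed)) / sqrt(length(seeds)))
    expect_gte(mean(abs(grand) <= 3 * se), 0.85)
    ## one representative draw for the gate false-positive bound
    cfg <- smallCfg(seed = 32, nPlanted = c(signaling = 0, metabolic = 0),
                    pathwayNoiseSD = 0, nevusExtraNoiseSD = 0,
                    coordCluster = NULL)
    sim <- simulateStudy(cfg)
    pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
    v <- pasScores(pm)
    ## fraction of gated-open cells below a Monte-Carlo false-positive
    ## bound for the tolerance gate (independent oracle at the same
    ## reference size and noise level)
    set.seed(1)
    nRef <- cfg$nPerGroup[["Reference"]]; sigma <- cfg$noiseSD
    flags <- replicate(20000, {
        ref <- rnorm(nRef, 0, sigma)
        case <- rnorm(1, 0, sigma)
        dev <- abs(case - mean(ref))
        dev > qnorm(0.975) * sd(ref) && dev >= log2(1.5)
    })
    pGene <- mean(flags)
    bound <- 1 - (1 - pGene) ^ cfg$genesPerPathway
    expect_lt(mean(abs(v) > 0), bound * 1.25)
})

test_that("recovered PAS shifts grow monotonically with the planted effect", {
    med <- vapply(c(0.5, 1, 2), function(es) {
        sim <- simulateStudy(smallCfg(seed = 33, effectSize = es,
                                      coordCluster = NULL))
        pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
        lab <- as.character(SummarizedExperiment::colData(pm)$group)
        planted <- intersect(sim$truth$planted, rownames(pm))
        shift <- abs(rowMeans(pasScores(pm)[planted, lab != "Skin",
                                            drop = FALSE]) -
                     rowMeans(pasScores(pm)[planted, lab == "Skin",
                                            drop = FALSE]))
        median(shift)
    }, numeric(1))
    expect_true(all(diff(med) > 0))
})

test_that("coordinated disjoint pathways co-activate without sharing genes", {
    sim <- simulateStudy(simConfig(seed = 34))
    pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
    coord <- sim$truth$coordCluster
    cc <- suppressWarnings(pathwayCorrelation(pm))
    rep <- coordinationVsStructure(coord, cc, sim$db)
    expect_gte(unname(rep$summary["meanAbsR"]), 0.8)
    expect_identical(unname(rep$summary["meanJaccard"]), 0)
})
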