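## Shared fixtures; heavyweight simulations are memoised so several test
## files can reuse one run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, force(expr), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

toyPathway <- function(id = "p1", genes = c("A", "B", "C"), arr = NULL,
                       category = "signaling") {
    if (is.null(arr)) arr <- rep(1, length(genes))
    Pathway(id, category = category, genes = genes, arr = arr)
}

toyNormReference <- function(genes = c("A", "B", "C"), location = 3,
                             dispersion = 0.1, nRef = 5L) {
    n <- length(genes)
    new("NormReference", genes = genes,
        location = rep(location, length.out = n),
        dispersion = rep(dispersion, length.out = n),
        nRef = as.integer(nRef), refGroup = "Reference")
}

writeDBFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
    writeLines(c("pathway_id\tpathway_name\tcategory\tgene_symbol\tarr",
                 rows), path)
    path
}

## default-condition study shared by the classifier and consensus checks
defaultStudy <- function() {
    cached("defaultStudy", {
        sim <- simulateStudy(simConfig(seed = 20))
        pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
        list(sim = sim, pm = pm,
             labels = as.character(SummarizedExperiment::colData(pm)$group))
    })
}

## classifier panel reports on the default study (filtered features)
defaultPanel <- function() {
    cached("defaultPanel", {
        st <- defaultStudy()
        f1 <- nearZeroVarFilter(st$pm)
        m <- pasScores(st$pm)[f1$retained, , drop = FALSE]
        f2 <- collinearityFilter(m)
        x <- t(m[f2$retained, , drop = FALSE])
        models <- c("svm_linear", "svm_radial", "random_forest",
                    "regularized_logistic", "naive_bayes")
        reports <- lapply(models, function(md) suppressWarnings(
            trainEval(x, st$labels, model = md, folds = 10, repeats = 2,
                      seed = 20)))
        names(reports) <- models
        reports
    })
}

## model fits on the full (unfiltered) PAS features, for selection checks
defaultSelectionRankings <- function() {
    cached("defaultSelectionRankings", {
        st <- defaultStudy()
        x <- t(pasScores(st$pm))
        models <- c("svm_linear", "svm_radial", "random_forest",
                    "regularized_logistic", "naive_bayes")
        reports <- lapply(models, function(md) suppressWarnings(
            trainEval(x, st$labels, model = md, folds = 10, repeats = 1,
                      seed = 20)))
        lapply(reports, variableImportance, seed = 20)
    })
}

## study with the published direction signatures planted at n = 30 per class
plantedTableStudy <- function() {
    cached("plantedTableStudy", {
        cfg <- simConfig(seed = 21,
                         nPathways = c(signaling = 40, metabolic = 50),
                         nPerGroup = c(Skin = 30, Nevus = 30,
                                       PrimaryMelanoma = 30,
                                       MetastaticMelanoma = 30,
                                       Reference = 10),
                         nPlanted = c(signaling = 0, metabolic = 0),
                         coordCluster = NULL)
        cfg <- plantTableSignatures(cfg,
            melanomaTableFixture("metabolic_directions"), "metabolic")
        cfg <- plantTableSignatures(cfg,
            melanomaTableFixture("signaling_directions"), "signaling")
        sim <- simulateStudy(cfg)
        pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
        list(sim = sim, pm = pm,
             labels = as.character(SummarizedExperiment::colData(pm)$group))
    })
}

contrastColumns <- function() {
    c("NevusVsSkin", "PrimaryVsSkin", "MetastaticVsSkin",
      "MetastaticVsPrimary", "PrimaryVsNevus")
}
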