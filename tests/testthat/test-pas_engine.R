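test_that("case-to-normal ratio is a ratio to the geometric-mean norm", {
    expect_equal(cnr(2 ^ 3, 3), 1)
    expect_equal(cnr(2 ^ 4, 3), 2)
    expect_equal(cnr(2 ^ 1, 3), 0.25)
    expect_error(cnr(0, 3), "positive")
    expect_error(cnr(-2, 3), "positive")
})

test_that("BTIF requires both the tolerance interval and the fold criterion", {
    ## CNR = 1.4 fails the 1.5-fold rule no matter the dispersion
    expect_identical(btif(1.4 * 2 ^ 3, 3, 0.001), 0L)
    ## CNR = 2 with tight dispersion passes both
    expect_identical(btif(2 ^ 4, 3, 0.1), 1L)
    ## huge dispersion swallows the same deviation
    expect_identical(btif(2 ^ 4, 3, 10), 0L)
    expect_error(btif(2, 3, NA_real_), "dispersion")
    ## the gate is symmetric for down-regulation
    expect_identical(btif(2 ^ 2, 3, 0.1), 1L)   # CNR = 0.5
})

test_that("norm reference construction needs two samples and positive data", {
    x <- matrix(2 ^ c(3, 3.2, 3.1, 2.9), nrow = 2,
                dimnames = list(c("A", "B"), c("r1", "r2")))
    ref <- buildNormReference(x)
    expect_s4_class(ref, "NormReference")
    expect_equal(unname(normLocation(ref)),
                 c(mean(c(3, 3.1)), mean(c(3.2, 2.9))))
    expect_error(buildNormReference(x[, 1, drop = FALSE]), "at least 2")
    bad <- x; bad[1] <- -1
    expect_error(buildNormReference(bad), "positive")
})

test_that("the three-gene worked example scores 1.505 and flips with ARR", {
    ref <- toyNormReference()
    pw <- toyPathway(arr = c(1, 1, -1))
    x <- 2 ^ c(A = 4, B = 5, C = 1)   # CNR 2, 4, 0.25
    expected <- log10(2) + log10(4) - log10(0.25)
    expect_equal(as.numeric(pasScore(x, pw, ref)), expected,
                 tolerance = 1e-9)
    neg <- toyPathway(arr = c(-1, -1, 1))
    expect_equal(as.numeric(pasScore(x, neg, ref)), -expected,
                 tolerance = 1e-9)
    ## all genes at the norm: everything gated off
    expect_equal(as.numeric(pasScore(2 ^ c(A = 3, B = 3, C = 3), pw, ref)), 0)
    ## coverage diagnostic counts missing members
    partial <- pasScore(2 ^ c(A = 4, B = 5), pw, ref)
    expect_identical(attr(partial, "coverage"), c(used = 2L, missing = 1L))
    expect_error(pasScore(2 ^ c(Z = 4), pw, ref), "no member genes")
})

test_that("PAS is antisymmetric and additive, and small folds never move it", {
    set.seed(7)
    pool <- paste0("g", 1:40)
    ref <- toyNormReference(pool, location = rnorm(40, 8),
                            dispersion = runif(40, 0.05, 0.4))
    for (i in 1:250) {
        genes <- sample(pool, 8)
        arr <- sample(c(-1, -0.5, 0.5, 1), 8, replace = TRUE)
        pw <- Pathway("p", category = "signaling", genes = genes, arr = arr)
        x <- 2 ^ (normLocation(ref)[pool] + rnorm(40, 0, 1.2))
        names(x) <- pool
        v <- as.numeric(pasScore(x, pw, ref))
        ## antisymmetry under ARR negation
        flip <- Pathway("p", category = "signaling", genes = genes,
                        arr = -arr)
        expect_identical(as.numeric(pasScore(x, flip, ref)), -v)
        ## additivity over a disjoint union
        other <- sample(setdiff(pool, genes), 8)
        arr2 <- sample(c(-1, 1), 8, replace = TRUE)
        pw2 <- Pathway("q", category = "signaling", genes = other,
                       arr = arr2)
        un <- Pathway("u", category = "signaling", genes = c(genes, other),
                      arr = c(arr, arr2))
        expect_equal(as.numeric(pasScore(x, un, ref)),
                     v + as.numeric(pasScore(x, pw2, ref)),
                     tolerance = 1e-12)
        ## sub-1.5-fold perturbations are invisible to PAS
        y <- 2 ^ (normLocation(ref)[pool] + runif(40, -0.5, 0.5))
        names(y) <- pool
        expect_identical(as.numeric(pasScore(y, pw, ref)), 0)
    }
})

test_that("vectorized PAS equals an independent per-gene loop oracle", {
    ## oracle: plain arithmetic, written without the package's btif/cnr
    loopPAS <- function(xvec, genes, arr, loc, disp, fold = 1.5,
                        alpha = 0.05) {
        total <- 0
        for (k in seq_along(genes)) {
            g <- genes[k]
            ratio <- xvec[g] / 2 ^ loc[g]
            outside <- abs(log2(xvec[g]) - loc[g]) > qnorm(1 - alpha / 2) * disp[g]
            folded <- ratio >= fold || ratio <= 1 / fold
            flag <- if (outside && folded) 1 else 0
            total <- total + arr[k] * flag * log10(ratio)
        }
        unname(total)
    }
    set.seed(11)
    pool <- paste0("g", 1:60)
    nref <- 6
    refMat <- matrix(2 ^ rnorm(60 * nref, 8, 0.5), nrow = 60,
                     dimnames = list(pool, paste0("r", 1:nref)))
    annot <- data.frame(sample_id = c(paste0("c", 1:20), paste0("r", 1:nref)),
                        group = c(rep("PrimaryMelanoma", 20),
                                  rep("Reference", nref)),
                        dataset_id = "D", platform = "P")
    cases <- matrix(2 ^ rnorm(60 * 20, 8, 1.5), nrow = 60,
                    dimnames = list(pool, paste0("c", 1:20)))
    se <- makeStudyExperiment(cbind(cases, refMat), annot)
    pws <- lapply(1:15, function(i) {
        Pathway(sprintf("pw%02d", i), category = "metabolic",
                genes = sample(pool, 10),
                arr = sample(c(-1, -0.5, 0.5, 1), 10, replace = TRUE))
    })
    db <- PathwayDatabase(pws)
    pm <- pasMatrix(se, db)
    ref <- buildNormReference(refMat)
    loc <- normLocation(ref); disp <- normDispersion(ref)
    for (pw in pws) {
        for (s in colnames(pm)) {
            expect_equal(pasScores(pm)[pw@id, s],
                         loopPAS(cases[, s], memberGenes(pw),
                                 unname(arrWeights(pw)), loc, disp),
                         tolerance = 1e-12)
        }
    }
})

test_that("pasMatrix scores reference samples near zero and flags planted shifts", {
    set.seed(13)
    pool <- paste0("g", 1:30)
    nref <- 8
    refMat <- matrix(2 ^ rnorm(30 * nref, 8, 0.3), nrow = 30,
                     dimnames = list(pool, paste0("r", 1:nref)))
    ## cases: activator genes of pw1 uniformly 4x the norm
    up <- pool[1:10]
    cases <- matrix(2 ^ rnorm(30 * 6, 8, 0.3), nrow = 30,
                    dimnames = list(pool, paste0("c", 1:6)))
    cases[up, ] <- cases[up, ] * 4
    annot <- data.frame(sample_id = c(colnames(cases), colnames(refMat)),
                        group = c(rep("MetastaticMelanoma", 6),
                                  rep("Reference", nref)),
                        dataset_id = "D", platform = "P")
    se <- makeStudyExperiment(cbind(cases, refMat), annot)
    db <- PathwayDatabase(list(
        Pathway("pw1", category = "signaling", genes = up),
        Pathway("pw2", category = "signaling", genes = pool[11:20]),
        Pathway("pw3", category = "metabolic", genes = paste0("absent", 1:3))))
    expect_warning(pm <- pasMatrix(se, db), "no member genes")
    expect_false("pw3" %in% rownames(pm))
    expect_true(all(pasScores(pm)["pw1", ] > 2))
    expect_lt(max(abs(pasScores(pm)["pw2", ])), min(pasScores(pm)["pw1", ]))
    ## scoring the reference against itself stays near zero: an individual
    ## norm sample can clear the gate only by a rare >1.5-fold excursion
    pmRef <- suppressWarnings(pasMatrix(se, db, samples = colnames(refMat)))
    expect_lt(max(abs(pasScores(pmRef))), 0.5)
    expect_error(pasMatrix(se, db, refGroup = "Skin"), "at least 2 samples")
})
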