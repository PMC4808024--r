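## small planted-signal design shared by the importance checks
plantedImportanceFixture <- function(seed = 14, nNoise = 20, n = 60,
                                     duplicate = FALSE) {
    set.seed(seed)
    y <- factor(rep(c("a", "b"), each = n / 2))
    signal <- ifelse(y == "a", 2, -2) + rnorm(n, 0, 0.5)
    x <- cbind(signal = signal,
               matrix(rnorm(n * nNoise), ncol = nNoise,
                      dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
    if (duplicate) x <- cbind(x, signal2 = signal + rnorm(n, 0, 0.3))
    list(x = x, y = y)
}

test_that("planted signal features outrank noise for every model family", {
    fx <- plantedImportanceFixture()
    for (md in c("svm_linear", "svm_radial", "random_forest",
                 "regularized_logistic", "naive_bayes")) {
        rp <- suppressWarnings(trainEval(fx$x, fx$y, model = md, folds = 5,
                                         repeats = 1, seed = 2))
        vi <- variableImportance(rp, seed = 2)
        expect_identical(vi$feature[1], "signal", label = md)
        expect_equal(vi$importance[1], 100, label = md)
    }
    ## duplicated informative features both outrank the noise
    fx2 <- plantedImportanceFixture(duplicate = TRUE)
    rp <- suppressWarnings(trainEval(fx2$x, fx2$y, model = "random_forest",
                                     folds = 5, repeats = 1, seed = 2))
    vi <- variableImportance(rp, seed = 2)
    expect_setequal(vi$feature[1:2], c("signal", "signal2"))
})

test_that("top-k intersection behaves like set intersection with relaxation", {
    mk <- function(f) structure(data.frame(feature = f,
                                           importance = rev(seq_along(f))),
                                class = c("ImportanceRanking", "data.frame"))
    r1 <- mk(c(paste0("s", 1:12), paste0("a", 1:18)))
    r2 <- mk(c(paste0("s", 1:12), paste0("b", 1:18)))
    r3 <- mk(paste0("c", 1:30))
    expect_identical(topKIntersection(list(r1, r1), k = 30),
                     sort(r1$feature))
    expect_identical(topKIntersection(list(r1, r3), k = 30), character(0))
    expect_identical(topKIntersection(list(r1, r2), k = 30),
                     sort(paste0("s", 1:12)))
    ## order-insensitive and idempotent
    expect_identical(topKIntersection(list(r2, r1), k = 30),
                     topKIntersection(list(r1, r2), k = 30))
    ## m-of-M relaxation
    expect_identical(topKIntersection(list(r1, r2, r3), k = 30,
                                      minModels = 2),
                     sort(paste0("s", 1:12)))
    expect_error(topKIntersection(list()), "no rankings")
})

test_that("Kruskal-Wallis filter keeps shifted pathways and drops flat ones", {
    set.seed(15)
    labels <- rep(c("Skin", "Nevus", "PrimaryMelanoma",
                    "MetastaticMelanoma"), each = 12)
    n <- length(labels)
    flat <- rnorm(n)
    shifted <- rnorm(n) + ifelse(labels == "Skin", 0, 3)
    m <- rbind(flat = flat, shifted = shifted)
    kept <- kruskalFilter(m, labels, c("flat", "shifted"))
    expect_identical(kept, "shifted")
    ## vacuous filter at alpha = 1
    expect_setequal(kruskalFilter(m, labels, c("flat", "shifted"),
                                  alpha = 1), c("flat", "shifted"))
    ## pairwise reading is available and agrees here
    expect_identical(kruskalFilter(m, labels, c("flat", "shifted"),
                                   mode = "pairwise"), "shifted")
    expect_error(kruskalFilter(m, c(labels[-1], "Nevus"), "flat",
                               progressions = list(c("Skin", "Missing",
                                                     "Nevus"))),
                 "fewer than 3")
})

test_that("direction table signs median changes and flags exact zeros", {
    set.seed(16)
    labels <- rep(c("Skin", "Nevus", "PrimaryMelanoma",
                    "MetastaticMelanoma"), each = 15)
    n <- length(labels)
    up <- rnorm(n, 0, 0.3) + ifelse(labels == "Nevus", 2, 0)
    const <- rep(1, n)
    m <- rbind(up = up, const = const)
    expect_warning(ct <- directionTable(m, labels), "zero median change")
    expect_identical(ct$direction[ct$direction$pathway == "up",
                                  "NevusVsSkin"], "UP")
    stUp <- ct$stats[ct$stats$feature == "up" &
                     ct$stats$contrast == "NevusVsSkin", ]
    expect_lt(stUp$padj, 0.05)
    stConst <- ct$stats[ct$stats$feature == "const", ]
    expect_true(all(is.na(stConst$direction)))
    expect_true(all(stConst$padj == 1))
    expect_error(directionTable(m, labels,
                                contrasts = list(X = c("Nevus", "Absent"))),
                 "no samples")
})

test_that("planted direction signatures are recovered when shifts are overt", {
    ## no nevus attenuation here: the planted shift magnitudes are the
    ## condition of this power check
    cfg <- simConfig(seed = 17,
                     nPathways = c(signaling = 15, metabolic = 15),
                     nPerGroup = c(Skin = 30, Nevus = 30,
                                   PrimaryMelanoma = 30,
                                   MetastaticMelanoma = 30, Reference = 10),
                     nPlanted = c(signaling = 4, metabolic = 4),
                     nevusAttenuation = c(1, 1), nevusExtraNoiseSD = 0,
                     coordCluster = NULL)
    sim <- simulateStudy(cfg)
    pm <- pasMatrix(normalizeStudy(sim$se), sim$db)
    labels <- as.character(SummarizedExperiment::colData(pm)$group)
    ct <- directionTable(pm, labels, features = sim$truth$planted)
    truth <- sim$truth$signatures
    for (cc in contrastColumns()) {
        rec <- ct$direction[[cc]][match(truth$pathway_id,
                                        ct$direction$pathway)]
        expect_identical(rec, truth[[cc]], label = cc)
    }
    ## every confidently shifted cell is significant after BH correction
    st <- ct$stats[abs(ct$stats$medianChange) >= 0.3, ]
    expect_true(all(st$padj < 0.05))
})
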