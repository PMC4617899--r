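test_that("the five scoring statistics match direct arithmetic", {
    v <- rbind(G1 = c(4.1, 3.9, 2.0, 2.5),
               G2 = c(4, 6, 1, 3),
               G3 = c(2, 2, 2, 2))
    ds <- makePheno(v, c("T", "T", "R", "R"))
    expect_equal(unname(scoreGenes(ds, "T", method = "min-vs-max")["G1"]),
                 3.9 / 2.5)
    expect_equal(unname(scoreGenes(ds, "T", method = "mean-ratio")["G1"]),
                 4.0 / 2.25)
    ## SNR with sample sd: (5 - 2) / (sqrt(2) + sqrt(2))
    expect_equal(unname(scoreGenes(ds, "T", method = "snr")["G2"]),
                 3 / (2 * sqrt(2)), tolerance = 1e-12)
    ## identical values in all samples: zero numerator, floored denominator
    expect_equal(unname(scoreGenes(ds, "T", method = "snr")["G3"]), 0)

    ## two test classes with means 4 and 6, two ref classes with means 2, 3
    v2 <- rbind(G1 = c(4, 4, 6, 6, 2, 2, 3, 3))
    ds2 <- makePheno(v2, c("T1", "T1", "T2", "T2", "R1", "R1", "R2", "R2"))
    expect_equal(unname(scoreGenes(ds2, c("T1", "T2"), c("R1", "R2"),
                                   "min-pairwise-mean-ratio")["G1"]),
                 4 / 3, tolerance = 1e-12)
})

test_that("scoring preconditions are enforced with informative errors", {
    v <- rbind(G1 = c(1, 2, -1, 3))
    ds <- makePheno(v, c("T", "T", "R", "R"))
    expect_error(scoreGenes(ds, "T", method = "mean-ratio"),
                 "non-positive value for gene 'G1', sample 's3'")
    v2 <- rbind(G1 = c(1, 2, 3))
    ds2 <- makePheno(v2, c("T", "R", "R"))
    expect_error(scoreGenes(ds2, "T", method = "snr"), "1 replicate")
    expect_error(scoreGenes(ds, "Z", method = "mean-ratio"), "unknown test class")
    expect_error(scoreGenes(ds, "T", "T", "mean-ratio"), "disjoint")
})

test_that("permutation p-values match an exhaustive enumeration oracle", {
    set.seed(21)
    v <- matrix(2^rnorm(30, 7, 0.5), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    ds <- PhenoSet(v, rep(c("A", "B"), each = 3))
    obs <- scoreGenes(ds, "A", method = "mean-ratio")
    ## oracle: all C(6,3) = 20 test subsets, identity included
    subsets <- combn(6, 3)
    ratios <- apply(subsets, 2L, function(s)
        rowMeans(v[, s, drop = FALSE]) / rowMeans(v[, -s, drop = FALSE]))
    bIncl <- rowSums(ratios >= obs)          # identity counts itself
    oracle <- bIncl / ncol(subsets)           # (b + 1) / (m + 1), m = 19
    p <- permutationPvalues(ds, "A", method = "mean-ratio", nPerm = 100,
                            seed = 1)
    expect_true(attr(p, "exhaustive"))
    expect_equal(attr(p, "nPermUsed"), 19L)
    expect_equal(as.numeric(p), as.numeric(oracle), tolerance = 1e-12)

    ## sampled mode stays within 3 Monte-Carlo SDs of the exhaustive value
    ps <- permutationPvalues(ds, "A", method = "mean-ratio", nPerm = 10,
                             seed = 7)
    expect_false(attr(ps, "exhaustive"))
    q <- oracle
    expected <- (10 * q + 1) / 11
    sdMc <- sqrt(10 * q * (1 - q)) / 11
    expect_true(all(abs(as.numeric(ps) - expected) <= 3 * sdMc + 1e-12))
})

test_that("p-values are never zero and bounded below by 1/(m+1)", {
    for (seed in 1:5) {
        ds <- nullPheno(50, c(A = 3, B = 3, C = 3), seed = seed)
        for (method in c("mean-ratio", "snr", "min-pairwise-mean-ratio")) {
            p <- permutationPvalues(ds, "A", method = method, nPerm = 60,
                                    seed = seed)
            m <- attr(p, "nPermUsed")
            expect_gt(min(p), 0)
            expect_gte(min(p), 1 / (m + 1))
            expect_lte(max(p), 1)
        }
    }
    ## a planted gene with a huge effect hits the floor exactly
    sim <- simulateDataset(simulationSpec(
        nGenes = 60, classes = c(A = 3, B = 3), plantedBlocks = c(A = 5),
        effectLog2 = 6, noiseSd = 0.3, seed = 2))
    p <- permutationPvalues(sim$dataset, "A", method = "mean-ratio",
                            nPerm = 100, seed = 2)
    expect_equal(unname(min(p)), 1 / (attr(p, "nPermUsed") + 1))
})

test_that("permutation p-values are approximately uniform under the null", {
    ds <- nullPheno(2000, c(A = 6, B = 6), seed = 31)
    p <- permutationPvalues(ds, "A", method = "mean-ratio", nPerm = 199,
                            seed = 5)
    ks <- suppressWarnings(stats::ks.test(as.numeric(p), "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH and BY agree with the hand-enumerated step-up examples", {
    p <- c(0.01, 0.04, 0.03, 0.005)
    expect_equal(adjustPvalues(p, "BH"), c(0.02, 0.04, 0.04, 0.02))
    expect_equal(round(adjustPvalues(p, "BY"), 4),
                 c(0.0417, 0.0833, 0.0833, 0.0417))
    expect_equal(adjustPvalues(1, "BH"), 1)
    expect_equal(adjustPvalues(1, "BY"), 1)
    expect_error(adjustPvalues(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(adjustPvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("signature thresholds are strict and rows sorted by score", {
    v <- rbind(G1 = c(4.1, 3.9, 2.0, 2.5),     # min/max = 1.56
               G2 = c(2, 2, 1, 1),             # min/max = 2 exactly
               G3 = c(9, 9, 1, 1))
    ds <- makePheno(v, c("T", "T", "R", "R"))
    sig <- extractSignature(ds, "T", method = "min-vs-max",
                            foldThreshold = 1.5)
    expect_true("G1" %in% geneIds(sig))
    sig2 <- extractSignature(ds, "T", method = "min-vs-max",
                             foldThreshold = 2)
    expect_false("G2" %in% geneIds(sig2))     # strict >
    expect_true("G3" %in% geneIds(sig2))
    expect_false(is.unsorted(rev(signatureTable(sig)$score)))
    expect_error(extractSignature(ds, "T", method = "min-vs-max",
                                  fdrThreshold = 0.05), "min-vs-max")
})

test_that("min-vs-max signature genes satisfy the defining inequality verbatim", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 300, classes = c(A = 3, B = 3, C = 3),
        plantedBlocks = c(A = 20, B = 20), seed = 9))
    thr <- 1.5
    sig <- suppressWarnings(extractSignature(sim$dataset, "A",
                                             method = "min-vs-max",
                                             foldThreshold = thr))
    v <- exprValues(sim$dataset)
    cls <- as.character(phenoClass(sim$dataset))
    for (g in geneIds(sig))
        expect_gt(min(v[g, cls == "A"]), thr * max(v[g, cls != "A"]))
})

test_that("absolute signatures cover every class and tolerate empty ones", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 400, classes = c(A = 3, B = 3, C = 3, D = 3, E = 3, F = 3),
        plantedBlocks = c(A = 15, B = 15, C = 15, D = 15, E = 15),
        seed = 13))
    sigs <- suppressWarnings(absoluteSignatures(sim$dataset, "min-vs-max",
                                                foldThreshold = 1.5))
    expect_length(sigs, 6L)
    expect_named(sigs, classLevels(sim$dataset))
    ## class F has no planted block: an empty signature is legal, not an error
    expect_true(sigs$F@empty)
    expect_equal(length(sigs$F), 0L)
    single <- makePheno(rbind(G1 = c(1, 2)), c("A", "A"))
    expect_error(absoluteSignatures(single, "min-vs-max"), "at least 2 classes")
})

test_that("two-class min-vs-max signatures above fold 1 are disjoint", {
    ds <- nullPheno(200, c(A = 3, B = 3), seed = 17)
    sigs <- suppressWarnings(absoluteSignatures(ds, "min-vs-max",
                                                foldThreshold = 1))
    expect_length(intersect(geneIds(sigs$A), geneIds(sigs$B)), 0L)
})

test_that("minimal-pairwise scores never exceed pooled scores (stringency)", {
    for (seed in 1:3) {
        sim <- simulateDataset(simulationSpec(
            nGenes = 300, classes = c(A = 3, B = 3, C = 3, D = 3),
            plantedBlocks = c(A = 25), seed = seed))
        pooled <- scoreGenes(sim$dataset, "A", method = "mean-ratio")
        pairwise <- scoreGenes(sim$dataset, "A",
                               method = "min-pairwise-mean-ratio")
        expect_true(all(pairwise <= pooled + 1e-12))
        sigPooled <- suppressWarnings(extractSignature(
            sim$dataset, "A", method = "mean-ratio", foldThreshold = 2,
            nPerm = 30, seed = 1))
        sigPair <- suppressWarnings(extractSignature(
            sim$dataset, "A", method = "min-pairwise-mean-ratio",
            foldThreshold = 2, nPerm = 30, seed = 1))
        expect_true(all(geneIds(sigPair) %in% geneIds(sigPooled)))
    }
})

test_that("signatures are bit-identical under identical seeds", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 150, classes = c(A = 3, B = 3, C = 4), # sampled-mode sizes
        plantedBlocks = c(A = 10), seed = 23))
    a <- suppressWarnings(extractSignature(sim$dataset, "A",
        method = "snr", foldThreshold = 0.5, nPerm = 50, seed = 99))
    b <- suppressWarnings(extractSignature(sim$dataset, "A",
        method = "snr", foldThreshold = 0.5, nPerm = 50, seed = 99))
    expect_identical(signatureTable(a), signatureTable(b))
    expect_identical(signatureGeneSet(a)@members, signatureGeneSet(b)@members)
})
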