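test_that("ranking is antisymmetric and matches a brute-force sort oracle", {
    set.seed(7)
    v <- matrix(2^rnorm(5 * 6, 7, 0.8), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    ds <- PhenoSet(v, rep(c("A", "B"), each = 3))
    rl <- rankGenes(ds, "A", "B")
    rl2 <- rankGenes(ds, "B", "A")
    expect_equal(rl2@metrics, -rev(rl@metrics), tolerance = 1e-12)
    expect_equal(rl2@genes, rev(rl@genes))

    ## independent oracle: compute each gene's SNR directly, then sort
    minPos <- min(v)
    snr1 <- vapply(rownames(v), function(g) {
        a <- v[g, 1:3]; b <- v[g, 4:6]
        sa <- max(sd(a), 0.2 * abs(mean(a)), 0.2 * minPos)
        sb <- max(sd(b), 0.2 * abs(mean(b)), 0.2 * minPos)
        (mean(a) - mean(b)) / (sa + sb)
    }, numeric(1))
    expect_equal(rl@genes, names(sort(snr1, decreasing = TRUE)))
    expect_equal(rl@metrics, unname(sort(snr1, decreasing = TRUE)),
                 tolerance = 1e-12)
    expect_error(rankGenes(ds, "A", "Z"), "unknown class")
})

test_that("the hand-enumerated toy running sum gives es = 0.75", {
    rl <- makeRanked(c(3, 2, 1, -1, -2))
    stat <- enrichmentScore(rl, geneSet("s", c("g1", "g3")), weight = 1,
                            minSize = 1)
    ## running sum: 0.75, 0.4167, 0.6667, 0.3333, 0
    expect_equal(stat@es, 0.75)
    expect_equal(stat@hitPositions, c(1L, 3L))
    expect_equal(stat@setSizeUsed, 2L)
    bottom <- enrichmentScore(rl, geneSet("s", c("g4", "g5")), weight = 1,
                              minSize = 1)
    expect_lt(bottom@es, 0)
})

test_that("weight 0 reduces to the classic KS statistic on ranks", {
    set.seed(3)
    for (rep in 1:20) {
        N <- sample(20:60, 1)
        mets <- sort(rnorm(N, 0, 2), decreasing = TRUE)
        K <- sample(2:6, 1)
        pos <- sort(sample(N, K))
        rl <- makeRanked(mets)
        es <- enrichmentScore(rl, paste0("g", pos), weight = 0,
                              minSize = 1)@es
        ## direct KS-form oracle: D+ / D- of hit positions vs uniform ranks
        run <- cumsum(ifelse(seq_len(N) %in% pos, 1 / K, -1 / (N - K)))
        expect_equal(abs(es), max(abs(run)), tolerance = 1e-12)
    }
})

test_that("es agrees with exhaustive dense enumeration for small lists", {
    mets <- c(2.5, 1.5, 0.5, -0.25, -1, -2, -3, -4)
    for (N in 5:8) {
        rl <- makeRanked(mets[seq_len(N)])
        for (K in 1:3) {
            placements <- combn(N, K)
            for (j in seq_len(ncol(placements))) {
                pos <- placements[, j]
                es <- enrichmentScore(rl, paste0("g", pos), weight = 1,
                                      minSize = 1)@es
                o <- denseRunningSum(rl@metrics, seq_len(N) %in% pos, 1)
                expect_equal(abs(es), abs(o$es), tolerance = 1e-12)
                if (!o$tie) expect_equal(es, o$es, tolerance = 1e-12)
                expect_lt(abs(o$end), 1e-9)
                expect_lte(abs(es), 1 + 1e-12)
            }
        }
    }
})

test_that("es matches the independent fgsea implementation", {
    skip_if_not_installed("fgsea")
    set.seed(41)
    for (rep in 1:25) {
        N <- 200
        mets <- sort(rnorm(N, 0, 2), decreasing = TRUE)
        pos <- sort(sample(N, sample(5:40, 1)))
        rl <- makeRanked(mets)
        es <- enrichmentScore(rl, paste0("g", pos), weight = 1,
                              minSize = 1)@es
        ref <- fgsea::calcGseaStat(mets, selectedStats = pos, gseaParam = 1,
                                   scoreType = "std")
        expect_equal(es, ref, tolerance = 1e-9)
    }
})

test_that("set size filtering skips without failing; degenerate sets error", {
    rl <- makeRanked(c(3, 2, 1, -1, -2))
    skipped <- enrichmentScore(rl, geneSet("s", c("g1", "g2")), minSize = 3)
    expect_true("size-skipped" %in% skipped@flags)
    expect_true(is.na(skipped@es))
    expect_error(enrichmentScore(rl, paste0("g", 1:5), minSize = 1),
                 "degenerate")
    ## members absent from the dataset are dropped into setSizeUsed
    stat <- enrichmentScore(rl, c("g1", "g3", "NOT_THERE"), minSize = 1)
    expect_equal(stat@setSizeUsed, 2L)
})

test_that("geneset-permutation nulls are reproducible and centered", {
    ds <- nullPheno(500, c(A = 3, B = 3), seed = 19)
    rl <- rankGenes(ds, "A", "B")
    n1 <- nullEnrichmentScores("geneset", ranked = rl, sizeUsed = 20,
                               nPerm = 1000, seed = 5)
    n2 <- nullEnrichmentScores("geneset", ranked = rl, sizeUsed = 20,
                               nPerm = 1000, seed = 5)
    expect_length(n1, 1000L)
    expect_identical(n1, n2)
    ## under label symmetry the null ES mean sits within 3 SE of 0
    expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
})

test_that("sample permutation enforces the 5-replicate rule", {
    for (r in 2:8) {
        ds <- nullPheno(80, c(A = r, B = r), seed = r)
        gs <- geneSet("s", paste0("gene", sprintf("%04d", 1:15)))
        call <- function() nullEnrichmentScores(
            "sample", dataset = ds, classLeft = "A", classRight = "B",
            geneSet = gs, nPerm = 5, seed = 1)
        if (r < 5) {
            expect_error(call(), "at least 5")
        } else {
            expect_length(call(), 5L)
        }
    }
    ## the override flag allows small designs explicitly
    ds3 <- nullPheno(80, c(A = 3, B = 3), seed = 1)
    gs <- geneSet("s", paste0("gene", sprintf("%04d", 1:15)))
    expect_length(nullEnrichmentScores("sample", dataset = ds3,
        classLeft = "A", classRight = "B", geneSet = gs, nPerm = 5,
        seed = 1, minReplicatesOverride = TRUE), 5L)
})

test_that("NES normalization follows the same-sign-mean definition", {
    nullEs <- c(0.3, 0.3, 0.3, -0.4, -0.4)
    r <- normalizeEs(0.6, nullEs)
    expect_equal(r$nes, 2)
    expect_equal(normalizeEs(-0.4, nullEs)$nes, -1)
    ## normalized null has same-sign mean magnitude 1 by construction
    expect_equal(mean(r$normNull[r$normNull > 0]), 1)
    expect_equal(mean(abs(r$normNull[r$normNull < 0])), 1)
    ## no same-sign null value: undefined NES flag
    u <- normalizeEs(0.5, c(-0.2, -0.3))
    expect_true(is.na(u$nes))
    expect_true("undefined-nes" %in% u$flags)
    expect_error(normalizeEs(0.5, numeric(0)), "empty null")
})

test_that("class swap negates metrics, ES and NES exactly under a fixed seed", {
    ds <- nullPheno(300, c(A = 3, B = 3), seed = 29)
    gs <- geneSet("s", paste0("gene", sprintf("%04d", seq(10, 200, by = 10))))
    for (orient in 1:2) {
        L <- c("A", "B")[orient]; R <- c("B", "A")[orient]
        rl <- rankGenes(ds, L, R)
        stat <- enrichmentScore(rl, gs, minSize = 1)
        nul <- nullEnrichmentScores("geneset", ranked = rl,
                                    sizeUsed = stat@setSizeUsed,
                                    nPerm = 200, seed = 17)
        nes <- normalizeEs(stat@es, nul)$nes
        if (orient == 1) {
            es1 <- stat@es; nes1 <- nes; null1 <- nul
        } else {
            expect_equal(stat@es, -es1, tolerance = 1e-12)
            expect_equal(nes, -nes1, tolerance = 1e-12)
            expect_equal(sort(nul), sort(-null1), tolerance = 1e-12)
        }
    }
})
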