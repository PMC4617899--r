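test_that("comparison enumeration yields n(n-1) directed pairs in order", {
    cmp <- enumerateComparisons(paste0("c", 1:7))
    expect_equal(nrow(cmp), 42L)
    cmp2 <- enumerateComparisons(c("A", "B"))
    expect_equal(nrow(cmp2), 2L)
    expect_equal(cmp2$classLeft, c("A", "B"))
    expect_error(enumerateComparisons("A"), "at least 2")
    ## deterministic order: left class varies slowest, input order preserved
    cmp3 <- enumerateComparisons(c("Z", "M", "A"))
    expect_equal(cmp3$classLeft, rep(c("Z", "M", "A"), each = 2))
})

test_that("map p-values match a brute-force scan of the pooled null", {
    set.seed(13)
    pool <- c(rnorm(400, 0.9, 0.4), -abs(rnorm(350, 0.8, 0.5)))
    obs <- c(2.4, -1.7, 0.3, -0.2, 5.0, NA)
    p <- mapPvalues(obs, pool)
    for (i in seq_along(obs)) {
        if (is.na(obs[i])) {
            expect_true(is.na(p[i]))
            next
        }
        same <- if (obs[i] >= 0) pool[pool > 0] else pool[pool < 0]
        b <- sum(abs(same) >= abs(obs[i]))
        expect_equal(p[i], (b + 1) / (length(same) + 1))
    }
    ## extreme observed value hits the never-zero floor
    mPos <- sum(pool > 0)
    expect_equal(p[5], 1 / (mPos + 1))
    ## no same-sign pool: flagged fallback on the other sign
    pAll <- mapPvalues(c(1.2, -0.5), abs(rnorm(99)) + 0.1)
    expect_true(attr(pAll, "emptyPool")[2])
    expect_equal(pAll[[2]], 1 / 100)
})

test_that("map-wide FDR agrees with a brute-force BY oracle", {
    expect_equal(globalFdr(0.37), 0.37)                  # single cell
    ties <- rep(0.001, 100)
    expect_equal(globalFdr(ties), rep(0.001 * sum(1 / 1:100), 100),
                 tolerance = 1e-12)
    set.seed(8)
    p <- runif(68 * 21)^1.5
    expect_equal(globalFdr(p), bruteStepUp(p, "BY"), tolerance = 1e-12)
    expect_equal(globalFdr(p, "BH"), bruteStepUp(p, "BH"), tolerance = 1e-12)
    ## BY >= BH >= p elementwise
    expect_true(all(globalFdr(p) >= globalFdr(p, "BH") - 1e-15))
    expect_true(all(globalFdr(p, "BH") >= p - 1e-15))
})

test_that("the grid covers every unique pair and mirrors exactly", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 400, classes = c(A = 3, B = 3, C = 3, D = 3),
        plantedBlocks = c(A = 20, B = 20), seed = 3))
    coll <- simulateGeneSets(sim$truth, geneIds(sim$dataset),
                             nRandomSets = 3, sizeRange = c(15, 25), seed = 3)
    res <- runBubbleMap(sim$dataset, coll, nPerm = 100, seed = 5)
    cells <- bubbleCells(res)
    expect_equal(nrow(cells), 5L * 6L)        # 5 sets x C(4,2) pairs
    dir <- bubbleDirected(res)
    expect_equal(nrow(dir), 5L * 12L)         # both orientations
    ## mirrored views: negated es/nes, identical p and fdr
    key <- paste(dir$geneSet, pmin(dir$classLeft, dir$classRight),
                 pmax(dir$classLeft, dir$classRight))
    for (k in unique(key)) {
        two <- dir[key == k, ]
        expect_equal(two$es[1], -two$es[2])
        expect_equal(two$nes[1], -two$nes[2])
        expect_equal(two$p[1], two$p[2])
        expect_equal(two$fdr[1], two$fdr[2])
        expect_equal(two$enrichedSide[1], two$enrichedSide[2])
    }
    ## enriched side is the left class iff nes > 0
    expect_equal(cells$enrichedSide == cells$classLeft, cells$nes > 0)
    ## determinism
    res2 <- runBubbleMap(sim$dataset, coll, nPerm = 100, seed = 5)
    expect_identical(bubbleCells(res2), cells)
    expect_equal(runMetadata(res)$familySize, 30L)
})

test_that("sample mode propagates the replicate rule at map level", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 100, classes = c(A = 3, B = 3), plantedBlocks = integer(0),
        seed = 4))
    coll <- simulateGeneSets(list(), geneIds(sim$dataset), nRandomSets = 2,
                             sizeRange = c(15, 20), seed = 4)
    expect_error(runBubbleMap(sim$dataset, coll, mode = "sample", nPerm = 5),
                 "at least 5")
    sim5 <- simulateDataset(simulationSpec(
        nGenes = 100, classes = c(A = 5, B = 5), plantedBlocks = integer(0),
        seed = 4))
    res <- runBubbleMap(sim5$dataset, coll, mode = "sample", nPerm = 10,
                        seed = 2)
    expect_equal(nrow(bubbleCells(res)), 2L)
})

test_that("removing a gene set leaves the remaining cells' ES/NES untouched", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 300, classes = c(A = 3, B = 3, C = 3),
        plantedBlocks = c(A = 20), seed = 6))
    coll <- simulateGeneSets(sim$truth, geneIds(sim$dataset),
                             nRandomSets = 3, sizeRange = c(15, 25), seed = 6)
    full <- runBubbleMap(sim$dataset, coll, nPerm = 100, seed = 9)
    less <- runBubbleMap(sim$dataset, coll[seq_len(length(coll) - 1L)],
                         nPerm = 100, seed = 9)
    fc <- bubbleCells(full); lc <- bubbleCells(less)
    shared <- merge(lc, fc, by = c("geneSet", "classLeft", "classRight"))
    expect_gt(nrow(shared), 0L)
    expect_equal(shared$es.x, shared$es.y)
    expect_equal(shared$nes.x, shared$nes.y)
    expect_lt(runMetadata(less)$familySize, runMetadata(full)$familySize)
    ## the BY family-size effect alone can only shrink adjusted values
    expect_true(all(bruteStepUp(shared$p.y[1:3], "BY") >=
                    bruteStepUp(shared$p.y[1:3], "BY") - 1e-15))
    sub <- adjustPvalues(fc$p[1:10], "BY")
    fullFam <- adjustPvalues(fc$p, "BY")[1:10]
    expect_true(all(sub <= fullFam + 1e-15))
})

test_that("filtering views never recomputes statistics", {
    fx <- plantedFixture(seed = 2)
    res <- runBubbleMap(fx$sim$dataset, fx$collection, nPerm = 50, seed = 3)
    view <- filterGrid(res, namePattern = "fingerprint")
    expect_equal(sort(unique(bubbleCells(view)$geneSet)),
                 sort(paste0(names(fx$sim$truth), "_fingerprint")))
    expect_equal(nrow(bubbleCells(view)), 6L * 21L)
    ## statistics identical to the unfiltered run
    merged <- merge(bubbleCells(view), bubbleCells(res),
                    by = c("geneSet", "classLeft", "classRight"))
    expect_equal(merged$fdr.x, merged$fdr.y)
    ## empty pattern is the identity view
    ident <- filterGrid(res, namePattern = "")
    expect_equal(nrow(bubbleCells(ident)), nrow(bubbleCells(res)))
    ## reordering rows then restoring is an involution
    sets <- unique(bubbleCells(res)$geneSet)
    flipped <- filterGrid(res, rowOrder = rev(sets))
    restored <- filterGrid(flipped, rowOrder = sets)
    expect_equal(bubbleCells(restored)$geneSet[order(seq_len(nrow(bubbleCells(res))))],
                 bubbleCells(filterGrid(res, rowOrder = sets))$geneSet)
    expect_error(filterGrid(res, comparisons = "X vs Y"),
                 "unknown comparison key")
})

test_that("bubble map TSV and manifest round-trip the run", {
    sim <- simulateDataset(simulationSpec(
        nGenes = 200, classes = c(A = 3, B = 3), plantedBlocks = c(A = 15),
        seed = 10))
    coll <- simulateGeneSets(sim$truth, geneIds(sim$dataset),
                             nRandomSets = 2, sizeRange = c(15, 20), seed = 10)
    res <- runBubbleMap(sim$dataset, coll, nPerm = 60, seed = 12)
    tsv <- tempfile(fileext = ".tsv")
    man <- tempfile(fileext = ".json")
    writeBubbleMap(res, tsv, man)
    back <- read.delim(tsv)
    expect_equal(nrow(back), nrow(bubbleCells(res)))
    expect_equal(back$nes, bubbleCells(res)$nes, tolerance = 1e-10)
    md <- jsonlite::read_json(man, simplifyVector = TRUE)
    expect_equal(md$seed, 12)
    expect_equal(md$familySize, runMetadata(res)$familySize)
})
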