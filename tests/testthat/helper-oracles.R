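## Independent oracles and fixture builders used across the suite.

## Dense running-sum oracle for the weighted enrichment score: walks every
## position of the ranked list.  Returns the full running sum plus the
## extremum; the extremum sign is ambiguous when |max| and |min| tie at
## floating-point resolution, which callers must allow for.
denseRunningSum <- function(metrics, hit, weight) {
    N <- length(metrics)
    absw <- abs(metrics)^weight
    NR <- sum(absw[hit])
    if (NR <= 0) {
        absw[] <- 1
        NR <- sum(hit)
    }
    inc <- ifelse(hit, absw / NR, -1 / (N - sum(hit)))
    run <- cumsum(inc)
    i <- which.max(abs(run))
    list(run = run, es = run[i], end = run[N],
         tie = abs(max(run) + min(run)) < 1e-12)
}

## Brute-force BH / BY step-up, written from the definition.
bruteStepUp <- function(p, procedure = c("BH", "BY")) {
    procedure <- match.arg(procedure)
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    if (procedure == "BY") q <- q * sum(1 / seq_len(m))
    for (i in rev(seq_len(m - 1))) q[i] <- min(q[i], q[i + 1])
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

## Small PhenoSet with explicit values.
makePheno <- function(values, classes) {
    if (is.null(rownames(values)))
        rownames(values) <- paste0("g", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("s", seq_len(ncol(values)))
    PhenoSet(values, classes)
}

## Random strictly-positive dataset under a global null.
nullPheno <- function(nGenes, classes, seed = 1, noiseSd = 0.5) {
    sim <- simulateDataset(simulationSpec(
        nGenes = nGenes, classes = classes, plantedBlocks = integer(0),
        noiseSd = noiseSd, seed = seed))
    sim$dataset
}

## RankedList straight from metric values (assumed sorted descending).
makeRanked <- function(metrics, left = "L", right = "R") {
    new("RankedList", genes = paste0("g", seq_along(metrics)),
        metrics = as.numeric(metrics), classLeft = left, classRight = right)
}

## Default planted fixture at the study scale (7 classes x 3 replicates,
## 2000 genes, 6 blocks of 50 at 4-fold).
plantedFixture <- function(seed = 1) {
    sim <- simulateDataset(simulationSpec(seed = seed))
    coll <- simulateGeneSets(sim$truth, geneIds(sim$dataset), seed = seed)
    list(sim = sim, collection = coll)
}
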