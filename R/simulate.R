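## Synthetic expression datasets with planted class-specific signature blocks
## and matching gene set collections, so every stage of the pipeline is
## testable without external data.

#' Specify a synthetic expression dataset
#'
#' Intensities follow a log-normal model on the log2 scale:
#' `value = 2^(baselineLog2 + effect * planted + Normal(0, noiseSd))`, where
#' `planted` is 1 for a gene belonging to the block planted for the sample's
#' class.  This mirrors the structure of RMA-normalized microarray data
#' (roughly Gaussian log2 intensities, multiplicative noise) without probe
#' or batch effects.  The default mirrors a seven-phenotype, triplicate
#' immune-cell study: 2000 genes, 6 planted blocks of 50 genes at 2.0 log2
#' (4-fold) effect, noise sd 0.5, with the seventh class left without a
#' block as a negative control.
#'
#' @param nGenes total gene count.
#' @param classes named integer vector: replicate count per class (all >= 2).
#' @param plantedBlocks named integer vector: planted gene count per class
#'   (subset of `names(classes)`; blocks are disjoint).  Use an empty vector
#'   for a fully exchangeable global-null dataset.
#' @param effectLog2 log2 effect size of planted genes (positive).
#' @param noiseSd log2-scale noise standard deviation (positive).
#' @param baselineLog2 mean log2 intensity.
#' @param seed integer seed.
#' @return a `simulationSpec` list.
#' @export
simulationSpec <- function(nGenes = 2000,
                           classes = c(cDC1 = 3, cDC2 = 3, pDC = 3,
                                       Bcell = 3, NK = 3, Tcd8 = 3,
                                       neutrophil = 3),
                           plantedBlocks = c(cDC1 = 50, cDC2 = 50, pDC = 50,
                                             Bcell = 50, NK = 50, Tcd8 = 50),
                           effectLog2 = 2.0, noiseSd = 0.5,
                           baselineLog2 = 7, seed = 1) {
    if (any(classes < 2L)) stop("replicate counts must be >= 2")
    if (noiseSd <= 0) stop("noiseSd must be positive")
    if (length(plantedBlocks)) {
        if (effectLog2 <= 0) stop("planted effect must be positive")
        if (is.null(names(plantedBlocks)) ||
            !all(names(plantedBlocks) %in% names(classes)))
            stop("plantedBlocks must be named by classes")
        if (sum(plantedBlocks) > nGenes)
            stop("planted blocks exceed the gene count")
    }
    structure(list(nGenes = nGenes, classes = classes,
                   plantedBlocks = plantedBlocks, effectLog2 = effectLog2,
                   noiseSd = noiseSd, baselineLog2 = baselineLog2,
                   seed = seed),
              class = "simulationSpec")
}

#' Simulate an expression dataset with planted signatures
#'
#' @param spec a [simulationSpec()].
#' @return a list with `dataset` (a [PhenoSet-class]) and `truth` (named list
#'   of planted gene identifiers per class; empty for null specs).
#' @examples
#' sim <- simulateDataset(simulationSpec(nGenes = 200,
#'     classes = c(A = 3, B = 3), plantedBlocks = c(A = 10), seed = 7))
#' sim$dataset
#' @export
simulateDataset <- function(spec) {
    stopifnot(inherits(spec, "simulationSpec"))
    withSeed(spec$seed, {
        nSamples <- sum(spec$classes)
        classOf <- rep(names(spec$classes), spec$classes)
        sampleNames <- paste0(classOf, "_r",
                              unlist(lapply(spec$classes, seq_len)))
        genes <- sprintf("gene%04d", seq_len(spec$nGenes))
        truth <- list()
        planted <- matrix(0, spec$nGenes, nSamples)
        at <- 0L
        for (cl in names(spec$plantedBlocks)) {
            size <- spec$plantedBlocks[[cl]]
            idx <- at + seq_len(size)
            at <- at + size
            truth[[cl]] <- genes[idx]
            planted[idx, classOf == cl] <- spec$effectLog2
        }
        log2v <- spec$baselineLog2 + planted +
            matrix(stats::rnorm(spec$nGenes * nSamples, 0, spec$noiseSd),
                   spec$nGenes, nSamples)
        values <- 2^log2v
        dimnames(values) <- list(genes, sampleNames)
        list(dataset = PhenoSet(values, classOf), truth = truth)
    })
}

#' Build a gene set collection from planted ground truth plus random padding
#'
#' One "fingerprint" set per planted block (named
#' `<class>_fingerprint`, so views can be filtered on the `"fingerprint"`
#' infix) plus `nRandomSets` sets of uniformly drawn genes named
#' `random_<i>`.  Padding a map with random sets keeps the conservative
#' map-wide FDR correction honest when most sets of interest are expected to
#' be enriched; by default twice as many random sets as fingerprints are
#' added.
#'
#' @param truth named list of planted genes per class (from
#'   [simulateDataset()]).
#' @param universe all gene identifiers to draw random members from.
#' @param nRandomSets number of random padding sets (default `2 *
#'   length(truth)`).
#' @param sizeRange inclusive size range of random sets.
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(truth, universe, nRandomSets = 2 * length(truth),
                             sizeRange = c(15, 50), seed = 1) {
    if (sizeRange[1L] < 1L || sizeRange[2L] > length(universe))
        stop("sizeRange exceeds the gene count")
    fingerprints <- lapply(names(truth), function(cl)
        geneSet(paste0(cl, "_fingerprint"), truth[[cl]],
                sprintf("planted signature block of class %s", cl)))
    randoms <- withSeed(seed, lapply(seq_len(nRandomSets), function(i) {
        size <- sample(seq(sizeRange[1L], sizeRange[2L]), 1L)
        geneSet(sprintf("random_%03d", i), sample(universe, size),
                "random padding set")
    }))
    geneSetCollection(c(fingerprints, randoms))
}

#' Write a simulation bundle (GCT + CLS + GMT + ground-truth manifest)
#'
#' @param sim result of [simulateDataset()].
#' @param collection optional [GeneSetCollection-class] to write alongside.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir, collection = NULL,
                            prefix = "synthetic") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gct <- file.path(dir, paste0(prefix, ".gct"))
    cls <- file.path(dir, paste0(prefix, ".cls"))
    writeExpressionGct(sim$dataset, gct, cls)
    paths <- c(gct = gct, cls = cls)
    if (!is.null(collection)) {
        gmt <- file.path(dir, paste0(prefix, ".gmt"))
        writeGeneSetsGmt(collection, gmt)
        paths <- c(paths, gmt = gmt)
    }
    manifest <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(sim$truth, manifest, auto_unbox = FALSE)
    invisible(c(paths, truth = manifest))
}
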