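## Exhaustive pairwise GSEA: every phenotype pair x every gene set, with the
## permutation null pooled across the whole grid and map-wide BY FDR.

comparisonKey <- function(left, right) paste(left, "vs", right)

#' Enumerate all directed pairwise comparisons
#'
#' All ordered pairs of distinct classes, `n (n - 1)` in total, in
#' deterministic order (outer loop over the left class in input order).
#' Downstream computation dedupes mirrored pairs: each unordered pair is
#' computed once and its mirror obtained by sign flip.
#'
#' @param classes ordered vector of at least 2 class labels.
#' @return data.frame with columns `classLeft`, `classRight`, `key`.
#' @examples
#' nrow(enumerateComparisons(letters[1:7]))  # 42
#' @export
enumerateComparisons <- function(classes) {
    classes <- as.character(classes)
    if (length(classes) < 2L)
        stop("validation error: need at least 2 classes")
    if (anyDuplicated(classes)) stop("classes must be unique")
    grid <- expand.grid(classRight = classes, classLeft = classes,
                        stringsAsFactors = FALSE)[, 2:1]
    grid <- grid[grid$classLeft != grid$classRight, , drop = FALSE]
    ord <- order(match(grid$classLeft, classes), match(grid$classRight, classes))
    grid <- grid[ord, , drop = FALSE]
    rownames(grid) <- NULL
    grid$key <- comparisonKey(grid$classLeft, grid$classRight)
    grid
}

#' Pooled-null p-values for the whole map
#'
#' Each cell's NES is compared to the normalized null NES values pooled
#' across every cell of the map, split by sign: for a cell with NES of sign
#' `s`, `b` is the number of pooled same-sign null values with magnitude at
#' least `|nes|` and `m` the same-sign pool size; the never-zero corrected
#' p-value is `(b + 1) / (m + 1)`.  A cell whose same-sign pool is empty is
#' flagged and reported with the fallback `1 / (m_other + 1)`.
#'
#' @param observed numeric vector of cell NES values (`NA` allowed for
#'   skipped cells; returned as `NA`).
#' @param nullPool numeric vector of all normalized null NES values pooled
#'   across every cell.
#' @return numeric vector of p-values with attribute `"emptyPool"` (logical,
#'   `TRUE` where the fallback was used).
#' @export
mapPvalues <- function(observed, nullPool) {
    if (!length(nullPool)) stop("empty null pool")
    posPool <- sort(nullPool[nullPool > 0])
    negPool <- sort(abs(nullPool[nullPool < 0]))
    mPos <- length(posPool); mNeg <- length(negPool)
    p <- rep(NA_real_, length(observed))
    empty <- rep(FALSE, length(observed))
    for (i in seq_along(observed)) {
        nes <- observed[i]
        if (is.na(nes)) next
        if (nes >= 0) { pool <- posPool; m <- mPos; mo <- mNeg }
        else { pool <- negPool; m <- mNeg; mo <- mPos }
        if (m == 0L) {
            p[i] <- 1 / (mo + 1)
            empty[i] <- TRUE
        } else {
            b <- m - findInterval(abs(nes), pool, left.open = TRUE)
            p[i] <- (b + 1) / (m + 1)
        }
    }
    structure(p, emptyPool = empty)
}

#' Map-wide FDR (Benjamini-Yekutieli over the whole grid)
#'
#' Applies the BY step-up to the pooled-null p-values of every unique cell
#' (gene sets x unordered comparisons); mirrored display views are excluded
#' from the family so they do not inflate the correction.
#'
#' @param p p-values of the unique cells (`NA` allowed, passed through).
#' @param procedure `"BY"` (default) or `"BH"`.
#' @return adjusted values, original order.
#' @export
globalFdr <- function(p, procedure = c("BY", "BH")) {
    procedure <- match.arg(procedure)
    ok <- !is.na(p)
    out <- rep(NA_real_, length(p))
    out[ok] <- adjustPvalues(p[ok], procedure)
    out
}

#' Run GSEA over all pairwise phenotype comparisons
#'
#' For every unordered pair of phenotype classes and every gene set that
#' survives the size filter, computes the weighted running-sum enrichment
#' score, a permutation null ([nullEnrichmentScores()]), and the NES
#' ([normalizeEs()]).  Normalized null values are pooled across all cells
#' (per sign) to give map-wide p-values ([mapPvalues()]), which are corrected
#' with the Benjamini-Yekutieli procedure over the whole grid
#' ([globalFdr()]).  Mirrored directed views carry sign-flipped ES/NES and
#' identical p/FDR.
#'
#' In geneset mode the null for a cell depends only on the comparison and the
#' set size, so nulls are drawn from a sub-seed derived from `(seed,
#' comparison, size)` and shared between same-size sets; removing or adding a
#' gene set therefore never perturbs the nulls of the remaining cells.
#'
#' @param dataset a [PhenoSet-class] with at least 2 classes.
#' @param collection a [GeneSetCollection-class].
#' @param mode permutation mode, `"geneset"` (default) or `"sample"` (the
#'   latter requires at least 5 replicates per class).
#' @param nPerm permutations per cell (default 1000).
#' @param seed integer seed; the run is deterministic given it.
#' @param weight ES weight.
#' @param minSize,maxSize gene set size filter (members present in the
#'   dataset).
#' @param procedure map-wide FDR procedure.
#' @param minReplicatesOverride allow sample mode below 5 replicates.
#' @param caseSensitive identifier matching policy.
#' @return a [BubbleMapResult-class].
#' @export
runBubbleMap <- function(dataset, collection, mode = c("geneset", "sample"),
                         nPerm = 1000, seed = 1, weight = 1,
                         minSize = 15, maxSize = 500,
                         procedure = c("BY", "BH"),
                         minReplicatesOverride = FALSE,
                         caseSensitive = FALSE) {
    mode <- match.arg(mode)
    procedure <- match.arg(procedure)
    stopifnot(is(dataset, "PhenoSet"), is(collection, "GeneSetCollection"))
    lv <- classLevels(dataset)
    if (length(lv) < 2L)
        stop("validation error: need at least 2 classes")
    if (mode == "sample" && !minReplicatesOverride) {
        tab <- table(phenoClass(dataset))
        low <- names(tab)[tab < 5L]
        if (length(low))
            stop(sprintf(
                "replicate-count error: class '%s' has %d replicates; sample permutation requires at least 5",
                low[1L], tab[low[1L]]))
    }
    pairs <- t(utils::combn(lv, 2L))
    setNames_ <- names(collection)
    nullCache <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(pairs) * length(collection))
    poolPos <- vector("list", length(rows))
    poolNeg <- vector("list", length(rows))
    k <- 0L
    for (pi in seq_len(nrow(pairs))) {
        L <- pairs[pi, 1L]; R <- pairs[pi, 2L]
        ranked <- rankGenes(dataset, L, R)
        for (si in seq_along(collection@sets)) {
            gs <- collection@sets[[si]]
            stat <- enrichmentScore(ranked, gs, weight = weight,
                                    minSize = minSize, maxSize = maxSize,
                                    caseSensitive = caseSensitive)
            k <- k + 1L
            if ("size-skipped" %in% stat@flags) {
                rows[[k]] <- data.frame(
                    geneSet = gs@name, classLeft = L, classRight = R,
                    es = NA_real_, nes = NA_real_, p = NA_real_,
                    fdr = NA_real_, enrichedSide = NA_character_,
                    sizeUsed = stat@setSizeUsed, flags = "size-skipped",
                    stringsAsFactors = FALSE)
                next
            }
            if (mode == "geneset") {
                key <- paste0(pi, ":", stat@setSizeUsed)
                if (is.null(nullCache[[key]])) {
                    nullCache[[key]] <- nullEnrichmentScores(
                        "geneset", ranked = ranked,
                        sizeUsed = stat@setSizeUsed, nPerm = nPerm,
                        seed = subSeed(seed, "gsnull", pi, stat@setSizeUsed),
                        weight = weight)
                }
                nullEs <- nullCache[[key]]
            } else {
                nullEs <- nullEnrichmentScores(
                    "sample", geneSet = gs, dataset = dataset,
                    classLeft = L, classRight = R, nPerm = nPerm,
                    seed = subSeed(seed, "smpnull", pi, gs@name),
                    weight = weight,
                    minReplicatesOverride = minReplicatesOverride)
            }
            norm <- normalizeEs(stat@es, nullEs)
            poolPos[[k]] <- norm$normNull[norm$normNull > 0]
            poolNeg[[k]] <- norm$normNull[norm$normNull < 0]
            side <- if (stat@es >= 0) L else R
            rows[[k]] <- data.frame(
                geneSet = gs@name, classLeft = L, classRight = R,
                es = stat@es, nes = norm$nes, p = NA_real_, fdr = NA_real_,
                enrichedSide = side, sizeUsed = stat@setSizeUsed,
                flags = paste(norm$flags, collapse = ";"),
                stringsAsFactors = FALSE)
        }
    }
    cells <- do.call(rbind, rows)
    if (all(cells$flags == "size-skipped"))
        stop("empty analysis: every gene set was size-skipped")
    pool <- c(unlist(poolPos), unlist(poolNeg))
    ## cells with undefined NES fall back to the ES sign and the never-zero
    ## floor of the opposite-sign pool
    obs <- ifelse(cells$flags == "undefined-nes", sign(cells$es) * Inf,
                  cells$nes)
    p <- mapPvalues(obs, pool)
    empty <- attr(p, "emptyPool")
    cells$p <- as.numeric(p)
    cells$flags <- ifelse(empty & nzchar(cells$flags),
                          paste(cells$flags, "empty-pool", sep = ";"),
                          ifelse(empty, "empty-pool", cells$flags))
    cells$fdr <- globalFdr(cells$p, procedure)
    familySize <- sum(!is.na(cells$p))
    mirrored <- cells
    mirrored$classLeft <- cells$classRight
    mirrored$classRight <- cells$classLeft
    mirrored$es <- -cells$es
    mirrored$nes <- -cells$nes
    directed <- rbind(cells, mirrored)
    directed$key <- comparisonKey(directed$classLeft, directed$classRight)
    new("BubbleMapResult", cells = cells, directed = directed,
        metadata = list(mode = mode, nPerm = nPerm, seed = seed,
                        weight = weight, minSize = minSize, maxSize = maxSize,
                        procedure = procedure, classes = lv,
                        geneSets = setNames_, familySize = familySize,
                        poolSize = length(pool),
                        datasetDim = dim(dataset)))
}

#' Filter and reorder a bubble-map view
#'
#' Restricts rows to gene sets whose name contains `namePattern`
#' (case-insensitive substring) and columns to the requested comparisons,
#' optionally reordering both.  Statistics are never recomputed: the
#' multiple-testing family is fixed when the map is run, so filtering a view
#' does not change any p-value or FDR.
#'
#' @param result a [BubbleMapResult-class].
#' @param namePattern substring to match in gene set names ("" keeps all).
#' @param comparisons character vector of comparison keys
#'   (`"left vs right"`, either orientation) to keep; `NULL` keeps all.
#' @param rowOrder,colOrder optional explicit ordering of the retained gene
#'   sets / comparisons.
#' @return a [BubbleMapResult-class] view (subset of cells and directed rows).
#' @export
filterGrid <- function(result, namePattern = "", comparisons = NULL,
                       rowOrder = NULL, colOrder = NULL) {
    stopifnot(is(result, "BubbleMapResult"))
    cells <- result@cells
    directed <- result@directed
    sets <- unique(cells$geneSet)
    if (nzchar(namePattern))
        sets <- sets[grepl(namePattern, sets, fixed = TRUE,
                           ignore.case = FALSE) |
                     grepl(tolower(namePattern), tolower(sets), fixed = TRUE)]
    if (!is.null(rowOrder)) {
        unknown <- setdiff(rowOrder, sets)
        if (length(unknown)) stop("unknown gene set in rowOrder: ", unknown[1L])
        sets <- rowOrder
    }
    keys <- unique(comparisonKey(cells$classLeft, cells$classRight))
    mirroredKeys <- unique(comparisonKey(cells$classRight, cells$classLeft))
    if (!is.null(comparisons)) {
        unknown <- setdiff(comparisons, c(keys, mirroredKeys))
        if (length(unknown))
            stop("validation error: unknown comparison key '", unknown[1L], "'")
        keys <- keys[keys %in% comparisons |
                     mirroredKeys %in% comparisons]
    }
    if (!is.null(colOrder)) {
        unknown <- setdiff(colOrder, c(keys, mirroredKeys))
        if (length(unknown))
            stop("validation error: unknown comparison key '", unknown[1L], "'")
        keys <- colOrder
    }
    cellKey <- comparisonKey(cells$classLeft, cells$classRight)
    mirrorKey <- comparisonKey(cells$classRight, cells$classLeft)
    keepCell <- cells$geneSet %in% sets & (cellKey %in% keys |
                                           mirrorKey %in% keys)
    sub <- cells[keepCell, , drop = FALSE]
    if (nrow(sub)) {
        colPos <- pmax(match(comparisonKey(sub$classLeft, sub$classRight),
                             keys, nomatch = 0L),
                       match(comparisonKey(sub$classRight, sub$classLeft),
                             keys, nomatch = 0L))
        sub <- sub[order(match(sub$geneSet, sets), colPos), , drop = FALSE]
    }
    rownames(sub) <- NULL
    keepDir <- directed$geneSet %in% sets & directed$key %in%
        c(keys, mirroredKeys)
    dsub <- directed[keepDir, , drop = FALSE]
    rownames(dsub) <- NULL
    md <- result@metadata
    md$view <- list(namePattern = namePattern, comparisons = keys,
                    geneSets = sets)
    new("BubbleMapResult", cells = sub, directed = dsub, metadata = md)
}

#' Export the unique cells of a bubble map as TSV, plus a JSON run manifest
#'
#' @param result a [BubbleMapResult-class].
#' @param tsvPath,manifestPath output paths (`NULL` skips either).
#' @return invisibly, the paths written.
#' @export
writeBubbleMap <- function(result, tsvPath, manifestPath = NULL) {
    stopifnot(is(result, "BubbleMapResult"))
    if (!is.null(tsvPath)) writeTable(result@cells, tsvPath)
    if (!is.null(manifestPath))
        jsonlite::write_json(result@metadata, manifestPath, auto_unbox = TRUE,
                             digits = NA, null = "null")
    invisible(c(tsv = tsvPath, manifest = manifestPath))
}
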