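#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## PhenoSet: expression matrix + phenotype classes
## ---------------------------------------------------------------------------

#' Expression dataset with phenotype classes
#'
#' `PhenoSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' mandatory per-sample phenotype class (`colData(x)$phenoClass`).  The single
#' assay `"exprs"` holds normalized intensities on linear scale; ratio-based
#' signature statistics additionally require strictly positive values, which
#' is checked at the point of use rather than at construction.
#'
#' @slot .Data inherited SummarizedExperiment slots.
#' @name PhenoSet-class
#' @aliases PhenoSet-class
#' @exportClass PhenoSet
setClass("PhenoSet", contains = "SummarizedExperiment")

setValidity("PhenoSet", function(object) {
    msg <- character()
    ids <- rownames(object)
    smp <- colnames(object)
    if (is.null(ids) || any(!nzchar(ids)))
        msg <- c(msg, "gene identifiers must be non-empty rownames")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate gene identifier: '%s'",
                              ids[duplicated(ids)][1L]))
    if (is.null(smp) || any(!nzchar(smp)))
        msg <- c(msg, "sample names must be non-empty colnames")
    if (anyDuplicated(smp))
        msg <- c(msg, sprintf("duplicate sample name: '%s'",
                              smp[duplicated(smp)][1L]))
    cd <- SummarizedExperiment::colData(object)
    if (!"phenoClass" %in% colnames(cd)) {
        msg <- c(msg, "colData must carry a 'phenoClass' column")
    } else {
        cls <- cd$phenoClass
        if (!is.factor(cls))
            msg <- c(msg, "'phenoClass' must be a factor")
        else if (anyNA(cls))
            msg <- c(msg, "every sample must map to exactly one class")
        else if (any(table(cls) == 0L))
            msg <- c(msg, "every class must have at least one sample")
    }
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else if (!all(is.finite(SummarizedExperiment::assay(object, "exprs"))))
        msg <- c(msg, "expression values must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a PhenoSet
#'
#' @param values numeric matrix of normalized intensities (genes x samples)
#'   with unique rownames and colnames.  Values are taken to be on linear
#'   scale; use `log2Input = TRUE` if they are log2.
#' @param classes character or factor of phenotype class labels, one per
#'   sample (recycled from a named vector matched to colnames when named).
#' @param descriptions optional per-gene description strings.
#' @param log2Input if `TRUE`, values are exponentiated base 2 on entry so
#'   downstream ratios are linear-scale fold changes.
#'
#' @return a [PhenoSet-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 7), 2, 6,
#'             dimnames = list(c("G1", "G2"), paste0("s", 1:6)))
#' ps <- PhenoSet(m, rep(c("A", "B"), each = 3))
#' classLevels(ps)
#' @export
PhenoSet <- function(values, classes, descriptions = NULL, log2Input = FALSE) {
    values <- as.matrix(values)
    if (log2Input) values <- 2^values
    if (!is.null(names(classes)) && !is.null(colnames(values)))
        classes <- classes[colnames(values)]
    classes <- if (is.factor(classes)) droplevels(classes)
               else factor(classes, levels = unique(as.character(classes)))
    cd <- S4Vectors::DataFrame(phenoClass = classes,
                               row.names = colnames(values))
    rd <- S4Vectors::DataFrame(
        description = if (is.null(descriptions)) rep("", nrow(values))
                      else as.character(descriptions),
        row.names = rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd, rowData = rd)
    new("PhenoSet", se)
}

## ---------------------------------------------------------------------------
## GeneSet / GeneSetCollection
## ---------------------------------------------------------------------------

#' Named gene set
#'
#' @slot name unique set name.
#' @slot description free-text description.
#' @slot members deduplicated gene identifiers (at least one).
#' @name GeneSet-class
#' @exportClass GeneSet
setClass("GeneSet", representation(name = "character",
                                   description = "character",
                                   members = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "set name must be a single non-empty string")
    if (length(object@members) < 1L)
        msg <- c(msg, "a gene set needs at least one member")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be deduplicated")
    if (length(msg)) msg else TRUE
})

#' @param name,description,members see slots.
#' @rdname GeneSet-class
#' @export
geneSet <- function(name, members, description = "") {
    members <- unique(as.character(members[nzchar(members)]))
    new("GeneSet", name = as.character(name),
        description = as.character(description), members = members)
}

#' Ordered collection of uniquely named gene sets
#'
#' @slot sets list of [GeneSet-class] objects with unique names.
#' @name GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
        return("all elements must be GeneSet objects")
    nm <- vapply(object@sets, function(s) s@name, character(1))
    if (anyDuplicated(nm))
        return(sprintf("duplicate gene set name: '%s'", nm[duplicated(nm)][1L]))
    TRUE
})

#' @param sets list of [GeneSet-class] objects.
#' @rdname GeneSetCollection-class
#' @export
geneSetCollection <- function(sets) {
    new("GeneSetCollection", sets = as.list(sets))
}

## ---------------------------------------------------------------------------
## Signature
## ---------------------------------------------------------------------------

#' Phenotype molecular signature
#'
#' Genes scored as more highly expressed in the test classes than in the
#' reference classes, with permutation p-values and FDR where the statistic
#' supports them.  `table` has one row per retained gene with columns
#' `gene`, `score`, `p`, `fdr`, `nTest`, `nRef`, sorted by score descending
#' (ties keep dataset row order).
#'
#' @slot name signature name.
#' @slot testClasses,refClasses disjoint phenotype class labels.
#' @slot mode `"absolute"` (reference = all other classes) or `"relative"`.
#' @slot method one of the five scoring statistics, see [scoreGenes()].
#' @slot table data.frame of retained genes.
#' @slot foldThreshold,fdrThreshold thresholds used (fdr may be `NA`).
#' @slot nPerm,seed permutation settings (`NA` when not applicable).
#' @slot empty `TRUE` when no gene passed the thresholds.
#' @name Signature-class
#' @exportClass Signature
setClass("Signature", representation(name = "character",
                                     testClasses = "character",
                                     refClasses = "character",
                                     mode = "character",
                                     method = "character",
                                     table = "data.frame",
                                     foldThreshold = "numeric",
                                     fdrThreshold = "numeric",
                                     nPerm = "numeric",
                                     seed = "numeric",
                                     empty = "logical"))

setValidity("Signature", function(object) {
    msg <- character()
    if (length(intersect(object@testClasses, object@refClasses)))
        msg <- c(msg, "test and reference classes must be disjoint")
    tb <- object@table
    need <- c("gene", "score", "p", "fdr", "nTest", "nRef")
    if (!all(need %in% colnames(tb)))
        msg <- c(msg, paste("signature table needs columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(tb) > 1L && is.unsorted(rev(tb$score)))
        msg <- c(msg, "rows must be sorted by score descending")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RankedList
## ---------------------------------------------------------------------------

#' Ranked gene list for one phenotype pair
#'
#' All dataset genes ordered by the differential metric (signal-to-noise,
#' left minus right) descending; positive metric means higher expression in
#' `classLeft`.
#'
#' @slot genes ordered identifiers.
#' @slot metrics aligned nonincreasing metric values.
#' @slot classLeft,classRight the two phenotype labels.
#' @name RankedList-class
#' @exportClass RankedList
setClass("RankedList", representation(genes = "character",
                                      metrics = "numeric",
                                      classLeft = "character",
                                      classRight = "character"))

setValidity("RankedList", function(object) {
    msg <- character()
    if (length(object@genes) != length(object@metrics))
        msg <- c(msg, "genes and metrics must be aligned")
    if (length(object@metrics) > 1L && is.unsorted(rev(object@metrics)))
        msg <- c(msg, "metrics must be nonincreasing")
    if (identical(object@classLeft, object@classRight))
        msg <- c(msg, "the two classes must differ")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## EnrichmentStat
## ---------------------------------------------------------------------------

#' Enrichment statistic for one gene set on one ranked list
#'
#' @slot es enrichment score in \[-1, 1\] (`NA` when size-skipped).
#' @slot nes normalized enrichment score (`NA` until normalized or when
#'   undefined because no same-sign null value exists).
#' @slot pNominal nominal permutation p-value (`NA` until computed).
#' @slot hitPositions strictly increasing positions of set members in the
#'   ranked list.
#' @slot setSizeUsed members present in the ranked list after filtering.
#' @slot flags quality markers (`"size-skipped"`, `"undefined-nes"`).
#' @name EnrichmentStat-class
#' @exportClass EnrichmentStat
setClass("EnrichmentStat", representation(es = "numeric",
                                          nes = "numeric",
                                          pNominal = "numeric",
                                          hitPositions = "integer",
                                          setSizeUsed = "integer",
                                          flags = "character"))

## ---------------------------------------------------------------------------
## BubbleMapResult
## ---------------------------------------------------------------------------

#' Gene-set x comparison enrichment grid
#'
#' One row of `cells` per (gene set, unordered class pair): columns `geneSet`,
#' `classLeft`, `classRight`, `es`, `nes`, `p`, `fdr`, `enrichedSide`,
#' `sizeUsed`, `flags`.  `directed` carries both orientations of every pair
#' with sign-flipped statistics and identical p/fdr.  `metadata` records
#' mode, permutation count, seed, weight, size filters and the
#' multiple-testing family size, enough to replay the run exactly.
#'
#' @slot cells data.frame of unique cells.
#' @slot directed data.frame of directed display views.
#' @slot metadata named list of run metadata.
#' @name BubbleMapResult-class
#' @exportClass BubbleMapResult
setClass("BubbleMapResult", representation(cells = "data.frame",
                                           directed = "data.frame",
                                           metadata = "list"))

setValidity("BubbleMapResult", function(object) {
    need <- c("geneSet", "classLeft", "classRight", "es", "nes", "p", "fdr",
              "enrichedSide", "sizeUsed", "flags")
    if (!all(need %in% colnames(object@cells)))
        return(paste("cells needs columns:", paste(need, collapse = ", ")))
    key <- paste(object@cells$geneSet, object@cells$classLeft,
                 object@cells$classRight)
    if (anyDuplicated(key))
        return("one cell per (gene set, unordered pair)")
    TRUE
})
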