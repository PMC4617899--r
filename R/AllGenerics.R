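#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("phenoClass", function(x, ...) standardGeneric("phenoClass"))

#' @rdname accessors
#' @export
setGeneric("classLevels", function(x, ...) standardGeneric("classLevels"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("setMembers", function(x, ...) standardGeneric("setMembers"))

#' @rdname accessors
#' @export
setGeneric("signatureTable", function(x, ...) standardGeneric("signatureTable"))

#' @rdname accessors
#' @export
setGeneric("bubbleCells", function(x, ...) standardGeneric("bubbleCells"))

#' @rdname accessors
#' @export
setGeneric("bubbleDirected", function(x, ...) standardGeneric("bubbleDirected"))

#' @rdname accessors
#' @export
setGeneric("runMetadata", function(x, ...) standardGeneric("runMetadata"))

## ------------------------------------------------------------------------
## PhenoSet

#' @rdname accessors
#' @export
setMethod("exprValues", "PhenoSet", function(x, ...)
    SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("phenoClass", "PhenoSet", function(x, ...) {
    cls <- SummarizedExperiment::colData(x)$phenoClass
    stats::setNames(cls, colnames(x))
})

#' @rdname accessors
#' @export
setMethod("classLevels", "PhenoSet", function(x, ...)
    levels(SummarizedExperiment::colData(x)$phenoClass))

#' @rdname accessors
#' @export
setMethod("geneIds", "PhenoSet", function(x, ...) rownames(x))

setMethod("show", "PhenoSet", function(object) {
    cls <- phenoClass(object)
    cat(sprintf("PhenoSet: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(cls)
    cat(sprintf("classes (%d): %s\n", length(tab),
                paste(sprintf("%s[%d]", names(tab), tab), collapse = ", ")))
})

## ------------------------------------------------------------------------
## GeneSet / GeneSetCollection

#' @rdname accessors
#' @export
setMethod("setMembers", "GeneSet", function(x, ...) x@members)

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSet", function(x, ...) x@members)

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' (%d members): %s%s\n", object@name,
                length(object@members),
                paste(utils::head(object@members, 5), collapse = ", "),
                if (length(object@members) > 5) ", ..." else ""))
})

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x)
    vapply(x@sets, function(s) s@name, character(1)))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) i <- match(i, names(x))
    x@sets[[i]]
})

#' @export
setMethod("[", "GeneSetCollection", function(x, i) {
    if (is.character(i)) i <- match(i, names(x))
    geneSetCollection(x@sets[i])
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection of %d sets\n", length(object)))
    for (s in utils::head(object@sets, 5)) show(s)
    if (length(object) > 5) cat("...\n")
})

## ------------------------------------------------------------------------
## Signature

#' @rdname accessors
#' @export
setMethod("signatureTable", "Signature", function(x, ...) x@table)

#' @rdname accessors
#' @export
setMethod("geneIds", "Signature", function(x, ...) x@table$gene)

#' @export
setMethod("length", "Signature", function(x) nrow(x@table))

setMethod("show", "Signature", function(object) {
    cat(sprintf("Signature '%s' [%s, %s]: %s vs %s\n", object@name,
                object@method, object@mode,
                paste(object@testClasses, collapse = "+"),
                paste(object@refClasses, collapse = "+")))
    cat(sprintf("%d genes (score > %g%s)%s\n", nrow(object@table),
                object@foldThreshold,
                if (!is.na(object@fdrThreshold))
                    sprintf(", fdr < %g", object@fdrThreshold) else "",
                if (object@empty) " -- EMPTY" else ""))
})

#' Convert a signature to a gene set
#'
#' @param x a [Signature-class].
#' @return a [GeneSet-class] whose members are the signature genes.
#' @export
signatureGeneSet <- function(x) {
    stopifnot(is(x, "Signature"))
    if (nrow(x@table) == 0L)
        stop("cannot convert an empty signature to a gene set")
    geneSet(x@name, x@table$gene,
            sprintf("%s signature, %s vs %s (%s)", x@method,
                    paste(x@testClasses, collapse = "+"),
                    paste(x@refClasses, collapse = "+"), x@mode))
}

## ------------------------------------------------------------------------
## RankedList / EnrichmentStat / BubbleMapResult

#' @export
setMethod("length", "RankedList", function(x) length(x@genes))

#' @rdname accessors
#' @export
setMethod("geneIds", "RankedList", function(x, ...) x@genes)

setMethod("show", "RankedList", function(object) {
    cat(sprintf("RankedList: %d genes, %s (top) vs %s (bottom)\n",
                length(object@genes), object@classLeft, object@classRight))
})

setMethod("show", "EnrichmentStat", function(object) {
    cat(sprintf("EnrichmentStat: es=%.4f nes=%s p=%s size=%d%s\n", object@es,
                ifelse(is.na(object@nes), "NA", sprintf("%.4f", object@nes)),
                ifelse(is.na(object@pNominal), "NA",
                       sprintf("%.4g", object@pNominal)),
                object@setSizeUsed,
                if (length(object@flags) && any(nzchar(object@flags)))
                    paste0(" [", paste(object@flags, collapse = ","), "]")
                else ""))
})

#' @rdname accessors
#' @export
setMethod("bubbleCells", "BubbleMapResult", function(x, ...) x@cells)

#' @rdname accessors
#' @export
setMethod("bubbleDirected", "BubbleMapResult", function(x, ...) x@directed)

#' @rdname accessors
#' @export
setMethod("runMetadata", "BubbleMapResult", function(x, ...) x@metadata)

setMethod("show", "BubbleMapResult", function(object) {
    md <- object@metadata
    cat(sprintf("BubbleMapResult: %d gene sets x %d unordered pairs (%d cells)\n",
                length(unique(object@cells$geneSet)),
                nrow(unique(object@cells[, c("classLeft", "classRight")])),
                nrow(object@cells)))
    cat(sprintf("mode=%s nPerm=%d seed=%s family=%d\n",
                md$mode %||% "?", md$nPerm %||% NA,
                format(md$seed %||% NA), md$familySize %||% NA))
})
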