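## Weighted running-sum (Kolmogorov-Smirnov style) gene set enrichment for a
## single phenotype pair: ranking metric, enrichment score, permutation
## nulls, NES normalization.

#' Rank all genes for a phenotype pair
#'
#' Genes are ordered by the signal-to-noise ratio of `classLeft` minus
#' `classRight` (sample sd with the same floor as [scoreGenes()]), descending,
#' so genes high in `classLeft` sit at the top.  The sort is stable: ties keep
#' dataset row order.
#'
#' @param dataset a [PhenoSet-class].
#' @param classLeft,classRight two distinct phenotype classes, each with at
#'   least 2 samples.
#' @param metric `"snr"` (default) or `"mean-diff"`.
#' @return a [RankedList-class].
#' @export
rankGenes <- function(dataset, classLeft, classRight,
                      metric = c("snr", "mean-diff")) {
    metric <- match.arg(metric)
    lv <- classLevels(dataset)
    for (cl in c(classLeft, classRight))
        if (!cl %in% lv) stop("unknown class: ", cl)
    if (identical(classLeft, classRight)) stop("the two classes must differ")
    cls <- as.character(phenoClass(dataset))
    x <- exprValues(dataset)
    left <- which(cls == classLeft)
    right <- which(cls == classRight)
    if (metric == "snr" && (length(left) < 2L || length(right) < 2L))
        stop(sprintf("class '%s' has fewer than 2 replicates",
                     if (length(left) < 2L) classLeft else classRight))
    m <- .rankMetric(x, left, right, metric)
    ord <- order(-m, seq_along(m))
    new("RankedList", genes = rownames(x)[ord], metrics = as.numeric(m[ord]),
        classLeft = classLeft, classRight = classRight)
}

.rankMetric <- function(x, left, right, metric = "snr") {
    mL <- rowMeansSub(x, left); mR <- rowMeansSub(x, right)
    if (metric == "mean-diff") return(mL - mR)
    minPos <- smallestPositive(x)
    sL <- floorSd(rowSdsSub(x, left), mL, minPos)
    sR <- floorSd(rowSdsSub(x, right), mR, minPos)
    (mL - mR) / (sL + sR)
}

## Core ES computation from hit positions.
##
## The running sum adds |metric|^weight / NR at each hit (NR = sum over hits)
## and subtracts 1/(N - K) at each miss.  Its maximum is attained at a hit
## position and its minimum just before a hit, so both extrema are available
## from the K hit positions alone.  `pos` is an K x m matrix of sorted hit
## positions (columns = independent sets of the same size); returns the ES
## per column, taking the extremum of larger magnitude and breaking exact
## ties by the earlier position in the ranked list.
.esFromHits <- function(absw, N, pos) {
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
    K <- nrow(pos); m <- ncol(pos)
    w <- matrix(absw[pos], K, m)
    Wc <- if (K == 1L) w else apply(w, 2L, cumsum)
    NR <- Wc[K, ]
    zero <- NR <= 0
    if (any(zero)) {      # all-zero hit weights: fall back to unweighted hits
        w[, zero] <- 1
        Wc[, zero] <- matrix(seq_len(K), K, sum(zero))
        NR[zero] <- K
    }
    d <- 1 / (N - K)
    posdev <- sweep(Wc, 2L, NR, "/") - (pos - seq_len(K)) * d
    negdev <- posdev - sweep(w, 2L, NR, "/")
    cols <- seq_len(m)
    if (K == 1L) {
        imax <- rep(1L, m); imin <- rep(1L, m)
    } else {
        imax <- max.col(t(posdev), ties.method = "first")
        imin <- max.col(t(-negdev), ties.method = "first")
    }
    vmax <- posdev[cbind(imax, cols)]
    vmin <- negdev[cbind(imin, cols)]
    pmaxPos <- pos[cbind(imax, cols)]
    pminPos <- pos[cbind(imin, cols)] - 1L
    es <- ifelse(abs(vmax) > abs(vmin), vmax,
          ifelse(abs(vmin) > abs(vmax), vmin,
          ifelse(pmaxPos <= pminPos, vmax, vmin)))
    as.numeric(es)
}

#' Enrichment score of a gene set on a ranked list
#'
#' Walks the ranked list accumulating `|metric|^weight / N_R` at members
#' ("hits", `N_R` = total hit weight) and `-1 / (N - N_hits)` at non-members;
#' the enrichment score is the running-sum value of maximum absolute
#' deviation from zero (ties broken by the earlier position).  With
#' `weight = 0` this is the classic Kolmogorov-Smirnov statistic.  Members
#' absent from the ranked list are dropped silently and reported via
#' `setSizeUsed`.
#'
#' @param ranked a [RankedList-class].
#' @param geneSet a [GeneSet-class] (or character vector of members).
#' @param weight exponent on `|metric|`; 1 is the conventional weighted form.
#' @param minSize,maxSize inclusive bounds on the number of members present
#'   in the ranked list; sets outside the bounds are skipped (flag
#'   `"size-skipped"`, `es = NA`), which is distinct from an error.
#' @param caseSensitive identifier matching policy.
#' @return an [EnrichmentStat-class] with `es` and `hitPositions` populated.
#' @examples
#' rl <- new("RankedList", genes = paste0("g", 1:5),
#'           metrics = c(3, 2, 1, -1, -2), classLeft = "A", classRight = "B")
#' enrichmentScore(rl, geneSet("s", c("g1", "g3")), minSize = 1)@es  # 0.75
#' @export
enrichmentScore <- function(ranked, geneSet, weight = 1,
                            minSize = 15, maxSize = 500,
                            caseSensitive = FALSE) {
    members <- if (is(geneSet, "GeneSet")) geneSet@members
               else as.character(geneSet)
    pos <- sort(which(normId(ranked@genes, caseSensitive) %in%
                      normId(members, caseSensitive)))
    N <- length(ranked@genes)
    K <- length(pos)
    if (K == N)
        stop("degenerate input: gene set covers every ranked gene")
    if (K < minSize || K > maxSize)
        return(new("EnrichmentStat", es = NA_real_, nes = NA_real_,
                   pNominal = NA_real_, hitPositions = as.integer(pos),
                   setSizeUsed = as.integer(K), flags = "size-skipped"))
    absw <- abs(ranked@metrics)^weight
    es <- .esFromHits(absw, N, matrix(pos, ncol = 1L))
    new("EnrichmentStat", es = es, nes = NA_real_, pNominal = NA_real_,
        hitPositions = as.integer(pos), setSizeUsed = as.integer(K),
        flags = character(0))
}

#' Permutation null distribution of enrichment scores
#'
#' `"geneset"` mode draws `nPerm` random member sets of the same size from
#' the ranked genes (without replacement within each draw) and scores each.
#' `"sample"` mode shuffles the class labels of the pair's samples
#' (preserving group sizes), re-ranks all genes and re-scores the actual
#' set; it requires at least 5 replicates per class unless
#' `minReplicatesOverride = TRUE`, because with fewer samples the distinct
#' label shuffles are too few for a usable null.
#'
#' @param mode `"geneset"` or `"sample"`.
#' @param ranked the observed [RankedList-class] (required for geneset mode).
#' @param geneSet the gene set under test (required for sample mode and used
#'   to fix the set size in geneset mode).
#' @param dataset,classLeft,classRight required for sample mode.
#' @param nPerm,seed permutation count and seed (deterministic given seed).
#' @param weight ES weight, as in [enrichmentScore()].
#' @param minReplicatesOverride allow sample mode below 5 replicates.
#' @param sizeUsed optional explicit set size for geneset mode.
#' @param caseSensitive identifier matching policy.
#' @return numeric vector of `nPerm` null enrichment scores.
#' @export
nullEnrichmentScores <- function(mode = c("geneset", "sample"), ranked = NULL,
                                 geneSet = NULL, dataset = NULL,
                                 classLeft = NULL, classRight = NULL,
                                 nPerm = 1000, seed = 1, weight = 1,
                                 minReplicatesOverride = FALSE,
                                 sizeUsed = NULL, caseSensitive = FALSE) {
    mode <- match.arg(mode)
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (mode == "geneset") {
        if (is.null(ranked)) stop("geneset mode needs the ranked list")
        if (is.null(sizeUsed)) {
            if (is.null(geneSet)) stop("need geneSet or sizeUsed")
            members <- if (is(geneSet, "GeneSet")) geneSet@members
                       else as.character(geneSet)
            sizeUsed <- sum(normId(ranked@genes, caseSensitive) %in%
                            normId(members, caseSensitive))
        }
        N <- length(ranked@genes)
        if (sizeUsed < 1L || sizeUsed >= N)
            stop("set size must lie strictly between 0 and the gene count")
        absw <- abs(ranked@metrics)^weight
        ## draws are gene identities (via the alphabetical index), not ranked
        ## positions, so that swapping the comparison's classes reverses the
        ## list and negates every null ES exactly under the same seed
        alphaOrd <- order(ranked@genes)
        return(withSeed(seed, {
            pos <- vapply(seq_len(nPerm),
                          function(i) sort.int(alphaOrd[sample.int(N, sizeUsed)]),
                          integer(sizeUsed))
            .esFromHits(absw, N, matrix(pos, nrow = sizeUsed))
        }))
    }
    ## sample mode
    if (is.null(dataset) || is.null(classLeft) || is.null(classRight) ||
        is.null(geneSet))
        stop("sample mode needs dataset, both classes and the gene set")
    tab <- table(phenoClass(dataset))
    for (cl in c(classLeft, classRight)) {
        if (!cl %in% names(tab)) stop("unknown class: ", cl)
        if (tab[cl] < 5L && !minReplicatesOverride)
            stop(sprintf(
                "replicate-count error: class '%s' has %d replicates; sample permutation requires at least 5",
                cl, tab[cl]))
        if (tab[cl] < 2L)
            stop(sprintf("class '%s' has fewer than 2 replicates", cl))
    }
    cls <- as.character(phenoClass(dataset))
    cols <- which(cls %in% c(classLeft, classRight))
    x <- exprValues(dataset)[, cols, drop = FALSE]
    isLeft <- cls[cols] == classLeft
    nL <- sum(isLeft)
    members <- if (is(geneSet, "GeneSet")) geneSet@members
               else as.character(geneSet)
    hitIdx <- which(normId(rownames(x), caseSensitive) %in%
                    normId(members, caseSensitive))
    N <- nrow(x)
    K <- length(hitIdx)
    if (K < 1L || K >= N)
        stop("set size must lie strictly between 0 and the gene count")
    withSeed(seed, vapply(seq_len(nPerm), function(i) {
        sh <- sample.int(ncol(x))
        m <- .rankMetric(x, sh[seq_len(nL)], sh[-seq_len(nL)])
        ord <- order(-m, seq_along(m))
        rnk <- integer(N); rnk[ord] <- seq_len(N)
        pos <- sort.int(rnk[hitIdx])
        .esFromHits(abs(m[ord])^weight, N, matrix(pos, ncol = 1L))
    }, numeric(1)))
}

#' Normalize an enrichment score against its permutation null
#'
#' The normalized enrichment score is `es` divided by the mean magnitude of
#' the null values sharing its sign; each null value is normalized by the
#' same-sign null mean in the same way, so the normalized null has same-sign
#' mean magnitude 1 by construction.  When no null value shares the sign of
#' `es`, the NES is flagged undefined and callers report the cell with
#' `p = 1/(m+1)` and a quality flag.
#'
#' @param es observed enrichment score.
#' @param nullEs non-empty numeric vector of null enrichment scores.
#' @return a list with `nes`, `normNull` (normalized null vector), and
#'   `flags` (character, possibly `"undefined-nes"`).
#' @export
normalizeEs <- function(es, nullEs) {
    if (!length(nullEs)) stop("empty null vector")
    posMean <- mean(nullEs[nullEs > 0])
    negMean <- mean(abs(nullEs[nullEs < 0]))
    normNull <- nullEs
    if (!is.nan(posMean)) normNull[nullEs > 0] <- nullEs[nullEs > 0] / posMean
    if (!is.nan(negMean)) normNull[nullEs < 0] <- nullEs[nullEs < 0] / negMean
    flags <- character(0)
    if (es > 0) {
        nes <- if (is.nan(posMean)) NA_real_ else es / posMean
    } else if (es < 0) {
        nes <- if (is.nan(negMean)) NA_real_ else es / negMean
    } else nes <- 0
    if (is.na(nes)) flags <- "undefined-nes"
    list(nes = nes, normNull = normNull, flags = flags)
}
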