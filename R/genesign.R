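## Signature extraction: five differential statistics, sample-permutation
## p-values with the never-zero (b+1)/(m+1) correction, BH/BY FDR.

.SIGNATURE_METHODS <- c("min-vs-max", "mean-ratio", "min-pairwise-mean-ratio",
                        "snr", "min-pairwise-snr")

.isRatioMethod <- function(method)
    method %in% c("min-vs-max", "mean-ratio", "min-pairwise-mean-ratio")

.isSnrMethod <- function(method) method %in% c("snr", "min-pairwise-snr")

## Pooled statistics depend on the test/reference split only, not on which
## class inside the split a sample carries; this collapses the permutation
## space to test-subset choice.
.isPooledMethod <- function(method) method %in% c("mean-ratio", "snr")

.resolveContrast <- function(dataset, testClasses, refClasses) {
    lv <- classLevels(dataset)
    missing <- setdiff(testClasses, lv)
    if (length(missing))
        stop("unknown test class: ", missing[1L])
    if (is.null(refClasses)) {
        refClasses <- setdiff(lv, testClasses)
        mode <- "absolute"
    } else {
        missing <- setdiff(refClasses, lv)
        if (length(missing)) stop("unknown reference class: ", missing[1L])
        mode <- "relative"
    }
    if (length(intersect(testClasses, refClasses)))
        stop("test and reference classes must be disjoint")
    if (!length(refClasses)) stop("reference classes are empty")
    list(test = testClasses, ref = refClasses, mode = mode)
}

.checkPositive <- function(values, method) {
    if (.isRatioMethod(method) && any(values <= 0)) {
        idx <- which(values <= 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
            "validation error: non-positive value for gene '%s', sample '%s' under ratio method",
            rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
    }
}

.checkReplicates <- function(dataset, classes, min, what) {
    tab <- table(phenoClass(dataset))
    low <- classes[tab[classes] < min]
    if (length(low))
        stop(sprintf("validation error: class '%s' has %d replicate(s); %s requires >= %d",
                     low[1L], tab[low[1L]], what, min))
}

## Score all genes for one class split given column index sets per class.
## `byClass` is a named list of column indices (names = class labels).
.scoreSplit <- function(x, byClass, test, ref, method, minPos) {
    testCols <- unlist(byClass[test], use.names = FALSE)
    refCols <- unlist(byClass[ref], use.names = FALSE)
    switch(method,
        "min-vs-max" = {
            mins <- do.call(pmin, lapply(testCols, function(j) x[, j]))
            maxs <- do.call(pmax, lapply(refCols, function(j) x[, j]))
            mins / maxs
        },
        "mean-ratio" = rowMeansSub(x, testCols) / rowMeansSub(x, refCols),
        "min-pairwise-mean-ratio" = {
            mt <- lapply(byClass[test], function(j) rowMeansSub(x, j))
            mr <- lapply(byClass[ref], function(j) rowMeansSub(x, j))
            out <- NULL
            for (a in mt) for (b in mr) {
                r <- a / b
                out <- if (is.null(out)) r else pmin(out, r)
            }
            out
        },
        "snr" = {
            mT <- rowMeansSub(x, testCols); mR <- rowMeansSub(x, refCols)
            sT <- floorSd(rowSdsSub(x, testCols), mT, minPos)
            sR <- floorSd(rowSdsSub(x, refCols), mR, minPos)
            (mT - mR) / (sT + sR)
        },
        "min-pairwise-snr" = {
            st <- lapply(byClass[test], function(j) {
                m <- rowMeansSub(x, j)
                list(m = m, s = floorSd(rowSdsSub(x, j), m, minPos))
            })
            sr <- lapply(byClass[ref], function(j) {
                m <- rowMeansSub(x, j)
                list(m = m, s = floorSd(rowSdsSub(x, j), m, minPos))
            })
            out <- NULL
            for (a in st) for (b in sr) {
                r <- (a$m - b$m) / (a$s + b$s)
                out <- if (is.null(out)) r else pmin(out, r)
            }
            out
        },
        stop("unknown method: ", method))
}

#' Score genes for a test-vs-reference contrast
#'
#' Computes one differential score per gene for the chosen statistic:
#' \describe{
#'   \item{`min-vs-max`}{min over all test samples / max over all reference
#'     samples; very stringent, no permutation p-value.}
#'   \item{`mean-ratio`}{mean of pooled test samples / mean of pooled
#'     reference samples (linear-scale fold change).}
#'   \item{`min-pairwise-mean-ratio`}{minimum of `mean(test class i) /
#'     mean(ref class j)` over all class pairs; more stringent than the
#'     pooled ratio.}
#'   \item{`snr`}{signal-to-noise ratio `(mean_test - mean_ref) /
#'     (sd_test + sd_ref)` on pooled groups, sample sd with a floor of
#'     `max(sd, 0.2 |mean|, 0.2 delta)` where `delta` is the smallest
#'     positive value in the matrix.}
#'   \item{`min-pairwise-snr`}{minimum per-pair SNR over all class pairs.}
#' }
#'
#' @param dataset a [PhenoSet-class].
#' @param testClasses one or more phenotype class labels of interest.
#' @param refClasses reference class labels; `NULL` (absolute mode) uses all
#'   remaining classes.
#' @param method one of the five statistics above.
#'
#' @return named numeric vector, one finite score per gene.
#' @examples
#' m <- rbind(G1 = c(4.1, 3.9, 2.0, 2.5), G2 = c(1, 1, 1, 1))
#' colnames(m) <- paste0("s", 1:4)
#' ps <- PhenoSet(m, c("T", "T", "R", "R"))
#' scoreGenes(ps, "T", method = "min-vs-max")["G1"]  # 3.9 / 2.5
#' @export
scoreGenes <- function(dataset, testClasses, refClasses = NULL,
                       method = .SIGNATURE_METHODS) {
    method <- match.arg(method)
    ct <- .resolveContrast(dataset, testClasses, refClasses)
    cls <- phenoClass(dataset)
    keep <- as.character(cls) %in% c(ct$test, ct$ref)
    x <- exprValues(dataset)[, keep, drop = FALSE]
    labs <- as.character(cls)[keep]
    .checkPositive(x, method)
    if (.isSnrMethod(method))
        .checkReplicates(dataset, c(ct$test, ct$ref), 2L,
                         "the signal-to-noise statistic")
    byClass <- split(seq_len(ncol(x)), factor(labs, levels = c(ct$test, ct$ref)))
    minPos <- smallestPositive(x)
    sc <- .scoreSplit(x, byClass, ct$test, ct$ref, method, minPos)
    stats::setNames(sc, rownames(x))
}

## ---------------------------------------------------------------------------
## Permutation machinery
## ---------------------------------------------------------------------------

## log count of distinct label assignments preserving class sizes
.logDistinctAssignments <- function(counts)
    lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))

## All distinct permutations of a label multiset, as an n x m integer matrix
## of class indices.  Only called when the count is small.
.multisetPermutations <- function(counts) {
    n <- sum(counts)
    k <- length(counts)
    out <- list()
    rec <- function(prefix, left) {
        if (sum(left) == 0L) {
            out[[length(out) + 1L]] <<- prefix
            return(invisible())
        }
        for (c in seq_len(k)) if (left[c] > 0L) {
            left[c] <- left[c] - 1L
            rec(c(prefix, c), left)
            left[c] <- left[c] + 1L
        }
    }
    rec(integer(0), counts)
    matrix(unlist(out), nrow = n)
}

## Permuted score matrix (genes x m) for pooled methods given a logical
## test-membership indicator matrix Tind (n x m).
.pooledScoreMatrix <- function(x, Tind, method, minPos) {
    nT <- sum(Tind[, 1L]); nR <- nrow(Tind) - nT
    Tnum <- Tind + 0; Rnum <- 1 - Tnum
    mT <- (x %*% Tnum) / nT
    mR <- (x %*% Rnum) / nR
    if (method == "mean-ratio") return(mT / mR)
    x2 <- x * x
    vT <- ((x2 %*% Tnum) / nT - mT * mT) * nT / (nT - 1)
    vR <- ((x2 %*% Rnum) / nR - mR * mR) * nR / (nR - 1)
    sT <- floorSd(sqrt(pmax(vT, 0)), mT, minPos)
    sR <- floorSd(sqrt(pmax(vR, 0)), mR, minPos)
    (mT - mR) / (sT + sR)
}

## Permuted score matrix for per-class (min-pairwise) methods given an
## assignment matrix A (n x m of class indices along classOrder).
.pairwiseScoreMatrix <- function(x, A, classOrder, test, ref, method, minPos) {
    counts <- tabulate(A[, 1L], nbins = length(classOrder))
    stats <- lapply(seq_along(classOrder), function(c) {
        Ic <- (A == c) + 0
        m <- (x %*% Ic) / counts[c]
        if (method == "min-pairwise-snr") {
            v <- ((x * x) %*% Ic) / counts[c] - m * m
            v <- v * counts[c] / (counts[c] - 1)
            list(m = m, s = floorSd(sqrt(pmax(v, 0)), m, minPos))
        } else list(m = m)
    })
    names(stats) <- classOrder
    out <- NULL
    for (a in stats[test]) for (b in stats[ref]) {
        r <- if (method == "min-pairwise-snr") (a$m - b$m) / (a$s + b$s)
             else a$m / b$m
        out <- if (is.null(out)) r else pmin(out, r)
    }
    out
}

#' Sample-permutation p-values for signature scores
#'
#' For each gene the observed score is compared to scores obtained after
#' permuting the sample-to-class assignment (restricted to the union of the
#' test and reference samples, preserving every class's replicate count).
#' With `b` permuted scores at least as large as the observed one out of `m`
#' permutations, the never-zero corrected p-value is `(b + 1) / (m + 1)`,
#' bounded below by `1 / (m + 1)`.  When the number of distinct assignments
#' is at most `nPerm` the null is enumerated exhaustively (the identity
#' assignment supplying the `+1`); for the pooled statistics
#' (`mean-ratio`, `snr`) assignments are counted up to the test/reference
#' split they induce, since the score depends on nothing else.
#'
#' @inheritParams scoreGenes
#' @param nPerm number of permutations (at least 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @param nullPool `"genewise"` compares each gene to its own permuted
#'   scores; `"pooled"` compares each gene to the permuted scores of all
#'   genes pooled together (a much finer p-value grid at small sample size).
#' @param scores optional precomputed observed scores (from [scoreGenes()]).
#'
#' @return named numeric vector of p-values in `[1/(m+1), 1]`, with
#'   attribute `"nPermUsed"` giving the realized `m` and `"exhaustive"`.
#' @export
permutationPvalues <- function(dataset, testClasses, refClasses = NULL,
                               method = .SIGNATURE_METHODS, nPerm = 1000,
                               seed = 1, nullPool = c("genewise", "pooled"),
                               scores = NULL) {
    method <- match.arg(method)
    nullPool <- match.arg(nullPool)
    if (method == "min-vs-max")
        stop("min-vs-max has no permutation path")
    if (nPerm < 1) stop("nPerm must be >= 1")
    ct <- .resolveContrast(dataset, testClasses, refClasses)
    if (is.null(scores))
        scores <- scoreGenes(dataset, ct$test, ct$ref, method)
    cls <- phenoClass(dataset)
    keep <- as.character(cls) %in% c(ct$test, ct$ref)
    x <- exprValues(dataset)[, keep, drop = FALSE]
    labs <- as.character(cls)[keep]
    classOrder <- c(ct$test, ct$ref)
    idx0 <- match(labs, classOrder)
    counts <- tabulate(idx0, nbins = length(classOrder))
    n <- length(labs)
    minPos <- smallestPositive(x)
    pooled <- .isPooledMethod(method)
    nTest <- sum(counts[seq_along(ct$test)])

    logDistinct <- if (pooled) lchoose(n, nTest)
                   else .logDistinctAssignments(counts)
    exhaustive <- logDistinct <= log(nPerm + 1)

    if (exhaustive) {
        if (pooled) {
            subsets <- utils::combn(n, nTest)
            identity <- which(apply(subsets, 2L, function(s)
                setequal(s, which(idx0 <= length(ct$test)))))
            subsets <- subsets[, -identity, drop = FALSE]
            Tind <- matrix(FALSE, n, ncol(subsets))
            Tind[cbind(as.vector(subsets),
                       rep(seq_len(ncol(subsets)), each = nTest))] <- TRUE
            perm <- .pooledScoreMatrix(x, Tind, method, minPos)
        } else {
            A <- .multisetPermutations(counts)
            identity <- which(apply(A, 2L, function(a) all(a == idx0)))
            A <- A[, -identity, drop = FALSE]
            perm <- .pairwiseScoreMatrix(x, A, classOrder, ct$test, ct$ref,
                                         method, minPos)
        }
    } else {
        perm <- withSeed(seed, {
            A <- vapply(seq_len(nPerm), function(i) sample(idx0), integer(n))
            if (pooled) {
                .pooledScoreMatrix(x, (A <= length(ct$test)), method, minPos)
            } else {
                .pairwiseScoreMatrix(x, A, classOrder, ct$test, ct$ref,
                                     method, minPos)
            }
        })
    }
    m <- ncol(perm)
    if (nullPool == "genewise") {
        b <- rowSums(perm >= scores)
        p <- (b + 1) / (m + 1)
    } else {
        pool <- sort(as.vector(perm))
        mAll <- length(pool)
        b <- mAll - findInterval(scores, pool, left.open = TRUE)
        p <- (b + 1) / (mAll + 1)
        m <- mAll
    }
    structure(stats::setNames(p, names(scores)),
              nPermUsed = m, exhaustive = exhaustive)
}

#' Adjust p-values for multiple testing (BH / BY step-up)
#'
#' Thin, validated wrapper over [stats::p.adjust()].  Benjamini-Hochberg
#' assumes independence (or positive dependence); Benjamini-Yekutieli
#' multiplies by `c(m) = sum(1/k, k = 1..m)` and is valid under arbitrary
#' dependence, which is the default here because permutation scores of genes
#' measured on the same samples are correlated.
#'
#' @param p p-values in `(0, 1]`.
#' @param procedure `"BY"` (default) or `"BH"`.
#' @return adjusted p-values in `(0, 1]`, original order.
#' @export
adjustPvalues <- function(p, procedure = c("BY", "BH")) {
    procedure <- match.arg(procedure)
    if (any(is.na(p)) || any(p <= 0 | p > 1))
        stop("validation error: p-values must lie in (0, 1]")
    stats::p.adjust(p, method = procedure)
}

#' Extract a molecular signature
#'
#' Scores every gene for the contrast, computes permutation p-values and FDR
#' when the statistic supports them, and retains genes with
#' `score > foldThreshold` (strict) and, when requested, `fdr < fdrThreshold`.
#' Rows are sorted by score descending; ties keep dataset row order.  An empty
#' signature is legal and returned with a warning.
#'
#' @inheritParams permutationPvalues
#' @param foldThreshold positive score threshold (strict `>`).
#' @param fdrThreshold FDR threshold in `(0, 1]`, or `NA` to filter on score
#'   only.  Forbidden with `min-vs-max`.
#' @param procedure FDR procedure, see [adjustPvalues()].
#' @param name signature name; a default is derived from the contrast.
#'
#' @return a [Signature-class].
#' @export
extractSignature <- function(dataset, testClasses, refClasses = NULL,
                             method = .SIGNATURE_METHODS,
                             foldThreshold = 2, fdrThreshold = NA,
                             nPerm = 1000, seed = 1,
                             procedure = c("BY", "BH"),
                             nullPool = c("genewise", "pooled"),
                             name = NULL) {
    method <- match.arg(method)
    procedure <- match.arg(procedure)
    nullPool <- match.arg(nullPool)
    if (foldThreshold <= 0 && .isRatioMethod(method))
        stop("foldThreshold must be positive")
    if (method == "min-vs-max" && !is.na(fdrThreshold))
        stop("min-vs-max carries no p-values; fdrThreshold must be NA")
    if (!is.na(fdrThreshold) && (fdrThreshold <= 0 || fdrThreshold > 1))
        stop("fdrThreshold must lie in (0, 1]")
    ct <- .resolveContrast(dataset, testClasses, refClasses)
    scores <- scoreGenes(dataset, ct$test, ct$ref, method)
    if (method != "min-vs-max" && nPerm >= 1) {
        p <- permutationPvalues(dataset, ct$test, ct$ref, method,
                                nPerm = nPerm, seed = seed,
                                nullPool = nullPool, scores = scores)
        fdr <- adjustPvalues(as.numeric(p), procedure)
    } else {
        p <- rep(NA_real_, length(scores))
        fdr <- rep(NA_real_, length(scores))
    }
    tab <- table(phenoClass(dataset))
    nTest <- sum(tab[ct$test])
    nRef <- sum(tab[ct$ref])
    keep <- scores > foldThreshold
    if (!is.na(fdrThreshold)) keep <- keep & fdr < fdrThreshold
    idx <- which(keep)
    idx <- idx[order(-scores[idx], idx)]
    tb <- data.frame(gene = names(scores)[idx], score = as.numeric(scores[idx]),
                     p = as.numeric(p)[idx], fdr = fdr[idx],
                     nTest = rep(as.integer(nTest), length(idx)),
                     nRef = rep(as.integer(nRef), length(idx)),
                     stringsAsFactors = FALSE, row.names = NULL)
    if (is.null(name))
        name <- sprintf("%s_vs_%s_%s", paste(ct$test, collapse = "+"),
                        if (ct$mode == "absolute") "rest"
                        else paste(ct$ref, collapse = "+"), method)
    empty <- nrow(tb) == 0L
    if (empty) warning("signature '", name, "' is empty")
    new("Signature", name = name, testClasses = ct$test, refClasses = ct$ref,
        mode = ct$mode, method = method, table = tb,
        foldThreshold = foldThreshold, fdrThreshold = as.numeric(fdrThreshold),
        nPerm = if (method == "min-vs-max") NA_real_ else as.numeric(nPerm),
        seed = if (method == "min-vs-max") NA_real_ else as.numeric(seed),
        empty = empty)
}

#' Absolute signatures for every phenotype class
#'
#' For each class `C`, extracts the signature of `C` against all remaining
#' classes (absolute mode).
#'
#' @inheritParams extractSignature
#' @return named list of [Signature-class], one per class.
#' @export
absoluteSignatures <- function(dataset, method = .SIGNATURE_METHODS,
                               foldThreshold = 2, fdrThreshold = NA,
                               nPerm = 1000, seed = 1,
                               procedure = c("BY", "BH"),
                               nullPool = c("genewise", "pooled")) {
    method <- match.arg(method)
    procedure <- match.arg(procedure)
    nullPool <- match.arg(nullPool)
    lv <- classLevels(dataset)
    if (length(lv) < 2L)
        stop("validation error: absolute signatures need at least 2 classes")
    sigs <- lapply(lv, function(cl)
        suppressWarnings(extractSignature(
            dataset, cl, NULL, method, foldThreshold, fdrThreshold,
            nPerm = nPerm, seed = subSeed(seed, cl), procedure = procedure,
            nullPool = nullPool,
            name = sprintf("%s_%s", cl, method))))
    stats::setNames(sigs, lv)
}
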