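## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (!is.null(old)) {
                assign(".Random.seed", old, envir = globalenv())
            } else if (exists(".Random.seed", envir = globalenv(),
                              inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            }
        }, add = TRUE)
        set.seed(seed)
    }
    force(expr)
}

## Derive a reproducible 31-bit sub-seed from a run seed and stream labels,
## so that independent permutation streams do not depend on evaluation order.
subSeed <- function(seed, ...) {
    parts <- c(seed, unlist(lapply(list(...), function(x) {
        if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
    })))
    h <- 0
    for (p in parts) h <- (h * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
    as.integer(h %% 2147483646L) + 1L
}

## Case-normalization policy for identifier matching (gene sets vs datasets).
normId <- function(x, caseSensitive = FALSE) {
    if (caseSensitive) x else toupper(x)
}

## Signal-to-noise denominators never collapse: sample sd is floored at
## 20% of |mean|, and at 20% of the smallest positive value in the matrix
## for means near zero.
floorSd <- function(sd, mean, minPositive) {
    pmax(sd, 0.2 * abs(mean), 0.2 * minPositive)
}

smallestPositive <- function(values) {
    pos <- values[values > 0]
    if (length(pos) == 0L) 1e-8 else min(pos)
}

## Row means / sds over a column subset, vectorized over genes.
rowMeansSub <- function(x, cols) {
    if (length(cols) == 1L) x[, cols] else rowMeans(x[, cols, drop = FALSE])
}

rowSdsSub <- function(x, cols) {
    n <- length(cols)
    m <- rowMeansSub(x, cols)
    sq <- rowMeansSub(x * x, cols)
    v <- (sq - m * m) * n / (n - 1)
    sqrt(pmax(v, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
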