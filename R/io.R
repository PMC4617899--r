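## GSEA-ecosystem file formats: GCT 1.2, categorical CLS, GMT, GMX, TSV.

#' Read an expression dataset (GCT 1.2 or plain tab-delimited)
#'
#' GCT files must carry the `#1.2` version header and a dimension line that
#' matches the body exactly.  Plain `txt` files are a header line (first
#' column = identifier, optional second column named `Description`, remaining
#' columns = samples) followed by one row per identifier.  `NA` cells are
#' rejected in both dialects.
#'
#' @param path file path.
#' @param classes phenotype class labels, typically from [readCls()].  May be
#'   omitted (`NULL`) when only the matrix is needed; a single pseudo-class
#'   `"all"` is then assigned.
#' @param format `"gct"` or `"txt"`; default guesses from the extension.
#' @param log2Input if `TRUE`, values are exponentiated base 2 at load so
#'   ratio statistics operate on linear-scale intensities.
#'
#' @return a [PhenoSet-class].
#' @export
readExpression <- function(path, classes = NULL,
                           format = c("auto", "gct", "txt"),
                           log2Input = FALSE) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "txt"
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (format == "gct") {
        if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
            stop("GCT format error: missing '#1.2' version header in ", path)
        dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
        if (length(dims) < 2L || anyNA(dims[1:2]))
            stop("GCT format error: malformed dimension line in ", path)
        body <- lines[-(1:2)]
        header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
        rows <- body[-1L]
        if (length(rows) != dims[1L])
            stop(sprintf(
                "GCT dimension error: declared %d rows but found %d in %s",
                dims[1L], length(rows), path))
        if (length(header) != dims[2L] + 2L)
            stop(sprintf(
                "GCT dimension error: declared %d samples but header has %d in %s",
                dims[2L], length(header) - 2L, path))
        sampleNames <- header[-(1:2)]
        descCol <- 2L
    } else {
        if (length(lines) < 2L) stop("txt format error: no data rows in ", path)
        header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        rows <- lines[-1L]
        descCol <- if (length(header) >= 2L &&
                       tolower(header[2L]) == "description") 2L else NA_integer_
        sampleNames <- header[-seq_len(if (is.na(descCol)) 1L else 2L)]
    }
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nmeta <- if (is.na(descCol)) 1L else 2L
    width <- nmeta + length(sampleNames)
    bad <- which(lengths(parts) != width)
    if (length(bad))
        stop(sprintf("format error: row %d has %d fields, expected %d (%s)",
                     bad[1L], lengths(parts)[bad[1L]], width, path))
    ids <- vapply(parts, `[`, character(1), 1L)
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop(sprintf("validation error: duplicate identifier '%s' in %s",
                     dup[1L], path))
    desc <- if (is.na(descCol)) NULL else vapply(parts, `[`, character(1), 2L)
    cells <- vapply(parts, function(p) p[-seq_len(nmeta)],
                    character(length(sampleNames)))
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
        idx <- which(is.na(num))[1L]
        col <- (idx - 1L) %% length(sampleNames) + 1L
        row <- (idx - 1L) %/% length(sampleNames) + 1L
        stop(sprintf(
            "parse error: non-numeric cell at gene row %d ('%s'), sample column %d ('%s') in %s",
            row, ids[row], col, sampleNames[col], path))
    }
    values <- matrix(num, nrow = length(ids), ncol = length(sampleNames),
                     byrow = TRUE, dimnames = list(ids, sampleNames))
    if (is.null(classes)) classes <- rep("all", length(sampleNames))
    PhenoSet(values, classes, descriptions = desc, log2Input = log2Input)
}

#' Read categorical CLS phenotype labels
#'
#' Line 1 is `N k 1`, line 2 is `# name1 ... namek`, line 3 carries `N`
#' labels either as class names or as 0-based indices into line 2.
#'
#' @param path file path.
#' @return a character vector of class labels of length `N`, with a
#'   `"classOrder"` attribute preserving the declared class order.
#' @export
readCls <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3L) stop("CLS format error: expected 3 lines in ", path)
    hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
    if (length(hdr) < 2L || anyNA(hdr[1:2]))
        stop("CLS format error: malformed header line in ", path)
    n <- hdr[1L]; k <- hdr[2L]
    nameLine <- strsplit(trimws(lines[2L]), "[ \t]+")[[1L]]
    if (nameLine[1L] != "#")
        stop("CLS format error: class-name line must start with '#' in ", path)
    classNames <- nameLine[-1L]
    if (length(classNames) != k)
        stop(sprintf(
            "CLS header inconsistency: %d classes declared but %d named in %s",
            k, length(classNames), path))
    labels <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    if (length(labels) != n)
        stop(sprintf("CLS format error: %d samples declared but %d labels in %s",
                     n, length(labels), path))
    numeric <- grepl("^[0-9]+$", labels)
    if (all(numeric) && !any(labels %in% classNames)) {
        idx <- as.integer(labels)
        if (any(idx >= k))
            stop(sprintf("CLS format error: numeric label %d >= %d classes in %s",
                         max(idx), k, path))
        labels <- classNames[idx + 1L]
    } else if (!all(labels %in% classNames)) {
        bad <- labels[!labels %in% classNames][1L]
        stop(sprintf("CLS format error: label '%s' not among declared classes in %s",
                     bad, path))
    }
    if (length(unique(labels)) != k)
        stop(sprintf(
            "CLS header inconsistency: %d classes declared but %d distinct labels in %s",
            k, length(unique(labels)), path))
    structure(labels, classOrder = classNames)
}

#' Read a gene set collection (GMT or GMX)
#'
#' GMT is one set per row: name, description, then members.  GMX is one set
#' per column: row 1 names, row 2 descriptions, subsequent rows members.
#' Empty member tokens are dropped and duplicate members deduplicated; file
#' order is preserved.
#'
#' @param path file path.
#' @param format `"gmt"` or `"gmx"`; default guesses from the extension.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(path, format = c("auto", "gmt", "gmx")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gmx$", path, ignore.case = TRUE)) "gmx" else "gmt"
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (format == "gmt") {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        sets <- lapply(seq_along(parts), function(i) {
            p <- parts[[i]]
            if (length(p) < 3L)
                stop(sprintf(
                    "GMT format error: row %d ('%s') has fewer than 3 columns in %s",
                    i, p[1L], path))
            geneSet(p[1L], p[-(1:2)], p[2L])
        })
    } else {
        parts <- strsplit(lines, "\t", fixed = TRUE)
        if (length(parts) < 3L)
            stop("GMX format error: need name, description and member rows in ", path)
        ncols <- length(parts[[1L]])
        grab <- function(row) c(row, rep("", ncols - length(row)))[seq_len(ncols)]
        mat <- do.call(rbind, lapply(parts, grab))
        sets <- lapply(seq_len(ncols), function(j) {
            members <- mat[-(1:2), j]
            members <- members[nzchar(members)]
            if (!length(members))
                stop(sprintf("GMX format error: column %d ('%s') has no members in %s",
                             j, mat[1L, j], path))
            geneSet(mat[1L, j], members, mat[2L, j])
        })
    }
    nm <- vapply(sets, function(s) s@name, character(1))
    if (anyDuplicated(nm))
        stop(sprintf("validation error: duplicate gene set name '%s' in %s",
                     nm[duplicated(nm)][1L], path))
    geneSetCollection(sets)
}

#' Write a gene set collection to GMT
#'
#' @param collection a non-empty [GeneSetCollection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSetsGmt <- function(collection, path) {
    stopifnot(is(collection, "GeneSetCollection"))
    if (length(collection) == 0L)
        stop("validation error: refusing to write an empty collection")
    lines <- vapply(collection@sets, function(s) {
        paste(c(s@name, if (nzchar(s@description)) s@description else "na",
                s@members), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a result table as TSV
#'
#' Writes a header plus one row per record.  For signature exports, pass the
#' dataset so the per-sample normalized expression values are appended after
#' the statistics columns, ready for third-party clustering tools.
#'
#' @param rows a data.frame or a [Signature-class].
#' @param path output path.
#' @param dataset optional [PhenoSet-class]; required to append expression
#'   values when `rows` is a signature.
#' @return `path`, invisibly.
#' @export
writeTable <- function(rows, path, dataset = NULL) {
    if (is(rows, "Signature")) {
        tb <- rows@table
        if (!is.null(dataset)) {
            idx <- match(tb$gene, geneIds(dataset))
            vals <- exprValues(dataset)[idx, , drop = FALSE]
            tb <- cbind(tb, as.data.frame(vals, check.names = FALSE))
        }
        rows <- tb
    }
    if (nrow(rows) == 0L)
        warning("writing a header-only table (no rows) to ", path)
    tryCatch(
        utils::write.table(rows, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE),
        error = function(e) stop("I/O failure writing ", path, ": ",
                                 conditionMessage(e)))
    invisible(path)
}

#' Write a PhenoSet as GCT 1.2 plus categorical CLS
#'
#' @param dataset a [PhenoSet-class].
#' @param gctPath,clsPath output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeExpressionGct <- function(dataset, gctPath, clsPath = NULL) {
    stopifnot(is(dataset, "PhenoSet"))
    v <- exprValues(dataset)
    if (!is.null(gctPath)) {
        desc <- SummarizedExperiment::rowData(dataset)$description
        if (is.null(desc)) desc <- rep("na", nrow(v))
        desc[!nzchar(desc)] <- "na"
        body <- apply(cbind(rownames(v), desc, format(v, trim = TRUE,
                                                      digits = 15)),
                      1L, paste, collapse = "\t")
        writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t"),
                     paste(c("NAME", "Description", colnames(v)),
                           collapse = "\t"), body), gctPath)
    }
    if (!is.null(clsPath)) {
        cls <- as.character(phenoClass(dataset))
        lv <- classLevels(dataset)
        writeLines(c(paste(ncol(v), length(lv), 1), paste(c("#", lv),
                                                          collapse = " "),
                     paste(cls, collapse = " ")), clsPath)
    }
    invisible(c(gct = gctPath, cls = clsPath))
}
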