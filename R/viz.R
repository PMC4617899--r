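## Static publication renderers: the bubble-matrix figure and the 5-color
## signature heatmap.  SVG output is plain text built with fixed-precision
## formatting, so repeated renders of the same grid are byte-identical.

.PALETTE <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
              "#A65628", "#F781BF", "#17BECF", "#666666", "#BCBD22",
              "#8C564B", "#1B9E77")

.classColors <- function(classes, override = NULL) {
    cols <- rep(.PALETTE, length.out = length(classes))
    names(cols) <- classes
    if (!is.null(override)) cols[names(override)] <- override
    cols
}

#' Bubble-map rendering style
#'
#' Bubble area is proportional to `|NES|` (radius proportional to
#' `sqrt(|NES|)`), fill color is the enriched class's color, and fill opacity
#' maps significance: `alpha = clamp(-log10(fdr) / -log10(intensityFloor),
#' alphaMin, 1)`, saturating at `intensityFloor`.  Cells with
#' `fdr > fdrDisplayThreshold` are drawn as outline-only (empty) circles of
#' the same area.
#'
#' @param fdrDisplayThreshold FDR above which a bubble is drawn empty
#'   (default 0.25, the conventional discovery threshold; 0.10 suits
#'   confirmation studies).
#' @param radiusScale pixels per unit `sqrt(|NES|)`.
#' @param intensityFloor FDR at which the fill reaches full opacity.
#' @param alphaMin minimum fill opacity.
#' @param classColors optional named vector overriding per-class colors.
#' @return a `bubbleStyle` list.
#' @export
bubbleStyle <- function(fdrDisplayThreshold = 0.25, radiusScale = 9,
                        intensityFloor = 1e-3, alphaMin = 0.15,
                        classColors = NULL) {
    stopifnot(fdrDisplayThreshold > 0, fdrDisplayThreshold <= 1,
              radiusScale > 0)
    structure(list(fdrDisplayThreshold = fdrDisplayThreshold,
                   radiusScale = radiusScale,
                   intensityFloor = intensityFloor, alphaMin = alphaMin,
                   classColors = classColors),
              class = "bubbleStyle")
}

.fmt <- function(x) sprintf("%.3f", x)

.svgAlpha <- function(fdr, style) {
    a <- -log10(fdr) / -log10(style$intensityFloor)
    pmin(pmax(a, style$alphaMin), 1)
}

#' Render a bubble-map figure
#'
#' One glyph per visible cell: a filled circle colored by the enriched side
#' with area proportional to `|NES|` and opacity increasing with
#' significance; cells with `fdr` above the display threshold become
#' outline-only circles of the same area; cells with undefined NES are drawn
#' as crossed markers and listed in a sidecar log (`<path>.log`).
#' Size-skipped cells draw no glyph.  Output is byte-stable SVG; `.png`
#' paths are rasterized through [grDevices::png()].
#'
#' @param result a [BubbleMapResult-class] (or a [filterGrid()] view).
#' @param path output path ending in `.svg` or `.png`.
#' @param style a [bubbleStyle()].
#' @param directed render both orientations of every pair; default shows
#'   each unordered pair once with a "left vs right" header.
#' @return invisibly, `path`.
#' @export
renderBubbleMap <- function(result, path, style = bubbleStyle(),
                            directed = FALSE) {
    stopifnot(is(result, "BubbleMapResult"))
    cells <- if (directed) result@directed else result@cells
    if (nrow(cells) == 0L)
        stop("validation error: empty grid view")
    sets <- unique(cells$geneSet)
    keys <- unique(comparisonKey(cells$classLeft, cells$classRight))
    classes <- result@metadata$classes %||%
        unique(c(cells$classLeft, cells$classRight))
    colors <- .classColors(classes, style$classColors)
    cellPx <- ceiling(2 * style$radiusScale * sqrt(3)) + 6
    labelW <- max(nchar(sets)) * 7 + 10
    headerH <- max(nchar(keys)) * 6 + 10
    legendH <- 70
    W <- labelW + length(keys) * cellPx + 20
    H <- headerH + length(sets) * cellPx + legendH + 20
    cx <- function(j) labelW + (j - 0.5) * cellPx
    cy <- function(i) headerH + (i - 0.5) * cellPx
    out <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="Helvetica,sans-serif">',
        W, H),
        sprintf('<rect width="%d" height="%d" fill="white"/>', W, H))
    for (j in seq_along(keys))
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="10" text-anchor="start" transform="rotate(-60 %s %s)">%s</text>',
            .fmt(cx(j)), .fmt(headerH - 4), .fmt(cx(j)), .fmt(headerH - 4),
            keys[j]))
    for (i in seq_along(sets))
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="10" text-anchor="end">%s</text>',
            .fmt(labelW - 4), .fmt(cy(i) + 3), sets[i]))
    sidecar <- character(0)
    nGlyphs <- 0L
    for (r in seq_len(nrow(cells))) {
        cell <- cells[r, ]
        i <- match(cell$geneSet, sets)
        j <- match(comparisonKey(cell$classLeft, cell$classRight), keys)
        x <- cx(j); y <- cy(i)
        flags <- strsplit(cell$flags %||% "", ";")[[1L]]
        if ("size-skipped" %in% flags) {
            sidecar <- c(sidecar, sprintf("size-skipped\t%s\t%s",
                                          cell$geneSet,
                                          comparisonKey(cell$classLeft,
                                                        cell$classRight)))
            next
        }
        if ("undefined-nes" %in% flags) {
            s <- style$radiusScale * 0.7
            out <- c(out, sprintf(
                '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1.2"/>',
                .fmt(x - s), .fmt(y - s), .fmt(x + s), .fmt(y + s)),
                sprintf(
                '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1.2"/>',
                .fmt(x - s), .fmt(y + s), .fmt(x + s), .fmt(y - s)))
            sidecar <- c(sidecar, sprintf("undefined-nes\t%s\t%s",
                                          cell$geneSet,
                                          comparisonKey(cell$classLeft,
                                                        cell$classRight)))
            nGlyphs <- nGlyphs + 1L
            next
        }
        radius <- style$radiusScale * sqrt(abs(cell$nes))
        color <- colors[[cell$enrichedSide]]
        if (cell$fdr > style$fdrDisplayThreshold) {
            out <- c(out, sprintf(
                '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="1"/>',
                .fmt(x), .fmt(y), .fmt(radius), color))
        } else {
            out <- c(out, sprintf(
                '<circle cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s" stroke="%s" stroke-width="0.5"/>',
                .fmt(x), .fmt(y), .fmt(radius), color,
                .fmt(.svgAlpha(cell$fdr, style)), color))
        }
        nGlyphs <- nGlyphs + 1L
    }
    ## legend: size references, intensity references, class colors
    ly <- headerH + length(sets) * cellPx + 20
    out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="10">|NES|:</text>', .fmt(10), .fmt(ly)))
    lx <- 55
    for (nes in c(1, 2, 3)) {
        out <- c(out, sprintf(
            '<circle cx="%s" cy="%s" r="%s" fill="#888888" stroke="#444444" stroke-width="0.5"/>',
            .fmt(lx), .fmt(ly - 4), .fmt(style$radiusScale * sqrt(nes))),
            sprintf('<text x="%s" y="%s" font-size="9">%d</text>',
                    .fmt(lx + style$radiusScale * sqrt(nes) + 2),
                    .fmt(ly), nes))
        lx <- lx + 2 * style$radiusScale * sqrt(nes) + 18
    }
    out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="10">FDR:</text>', .fmt(10),
        .fmt(ly + 28)))
    lx <- 55
    for (f in c(0.25, 0.05, 0.001)) {
        out <- c(out, sprintf(
            '<circle cx="%s" cy="%s" r="%s" fill="#444444" fill-opacity="%s"/>',
            .fmt(lx), .fmt(ly + 24), .fmt(style$radiusScale),
            .fmt(.svgAlpha(f, style))),
            sprintf('<text x="%s" y="%s" font-size="9">%s</text>',
                    .fmt(lx + style$radiusScale + 2), .fmt(ly + 28),
                    format(f)))
        lx <- lx + 2 * style$radiusScale + 40
    }
    usedClasses <- unique(c(cells$classLeft, cells$classRight))
    for (ci in seq_along(usedClasses)) {
        out <- c(out, sprintf(
            '<rect x="%s" y="%s" width="10" height="10" fill="%s"/>',
            .fmt(10 + (ci - 1) * 90), .fmt(ly + 40),
            colors[[usedClasses[ci]]]),
            sprintf('<text x="%s" y="%s" font-size="9">%s</text>',
                    .fmt(24 + (ci - 1) * 90), .fmt(ly + 49),
                    usedClasses[ci]))
    }
    out <- c(out, "</svg>")
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
        .renderBubblePng(cells, sets, keys, colors, style, path, cellPx,
                         labelW, headerH)
    } else {
        con <- file(path, open = "wb")
        on.exit(close(con))
        writeLines(out, con, sep = "\n")
    }
    if (length(sidecar))
        writeLines(sidecar, paste0(path, ".log"))
    attr(path, "nGlyphs") <- nGlyphs
    invisible(path)
}

.renderBubblePng <- function(cells, sets, keys, colors, style, path, cellPx,
                             labelW, headerH, dpi = 150) {
    W <- labelW + length(keys) * cellPx + 20
    H <- headerH + length(sets) * cellPx + 20
    grDevices::png(path, width = W, height = H, res = dpi,
                   units = "px", type = "cairo")
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(NA, xlim = c(0, W), ylim = c(H, 0), xaxs = "i",
                   yaxs = "i", axes = FALSE, xlab = "", ylab = "")
    for (r in seq_len(nrow(cells))) {
        cell <- cells[r, ]
        if (is.na(cell$nes)) next
        i <- match(cell$geneSet, sets)
        j <- match(comparisonKey(cell$classLeft, cell$classRight), keys)
        x <- labelW + (j - 0.5) * cellPx
        y <- headerH + (i - 0.5) * cellPx
        radius <- style$radiusScale * sqrt(abs(cell$nes))
        col <- colors[[cell$enrichedSide]]
        filled <- cell$fdr <= style$fdrDisplayThreshold
        graphics::symbols(x, y, circles = radius, inches = FALSE, add = TRUE,
                          fg = col,
                          bg = if (filled)
                              grDevices::adjustcolor(col,
                                  .svgAlpha(cell$fdr, style)) else NA)
    }
    graphics::text(rep(labelW - 4, length(sets)),
                   headerH + (seq_along(sets) - 0.5) * cellPx, sets,
                   adj = 1, cex = 0.6)
    graphics::text(labelW + (seq_along(keys) - 0.5) * cellPx,
                   rep(headerH - 4, length(keys)), keys, srt = 60,
                   adj = 0, cex = 0.6)
}

#' Render a 5-color signature heatmap
#'
#' Rows are the signature genes in signature order, columns the samples
#' grouped by class.  Each gene row is standardized across samples (a
#' constant row maps to z = 0) and binned into 5 colors at z cut-points
#' -1.5, -0.5, 0.5, 1.5; a class annotation bar tops the columns.  SVG
#' output is byte-stable.
#'
#' @param signature a non-empty [Signature-class].
#' @param dataset the [PhenoSet-class] the signature was extracted from (all
#'   signature genes must be present).
#' @param path output path ending in `.svg`.
#' @param colors 5 fill colors, low to high.
#' @param zCuts 4 increasing z cut-points.
#' @return invisibly, `path`.
#' @export
renderHeatmap <- function(signature, dataset, path,
                          colors = c("#2166AC", "#92C5DE", "#F7F7F7",
                                     "#F4A582", "#B2182B"),
                          zCuts = c(-1.5, -0.5, 0.5, 1.5)) {
    stopifnot(is(signature, "Signature"), is(dataset, "PhenoSet"),
              length(colors) == 5L, length(zCuts) == 4L)
    genes <- signature@table$gene
    if (!length(genes)) stop("validation error: empty signature")
    missing <- setdiff(genes, geneIds(dataset))
    if (length(missing))
        stop("gene missing from dataset: ", missing[1L])
    cls <- phenoClass(dataset)
    colOrd <- order(as.integer(cls), seq_along(cls))
    x <- exprValues(dataset)[genes, colOrd, drop = FALSE]
    classOf <- as.character(cls)[colOrd]
    mu <- rowMeans(x)
    sd <- apply(x, 1L, stats::sd)
    z <- (x - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    bin <- matrix(findInterval(z, zCuts) + 1L, nrow(z), ncol(z))
    cw <- 14; ch <- 12
    labelW <- max(nchar(genes)) * 7 + 10
    annH <- 14
    headerH <- max(nchar(colnames(x))) * 6 + annH + 8
    W <- labelW + ncol(x) * cw + 10
    H <- headerH + nrow(x) * ch + 10
    colorsByClass <- .classColors(classLevels(dataset))
    out <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="Helvetica,sans-serif">',
        W, H),
        sprintf('<rect width="%d" height="%d" fill="white"/>', W, H))
    for (j in seq_len(ncol(x))) {
        xpx <- labelW + (j - 1) * cw
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="8" text-anchor="start" transform="rotate(-60 %s %s)">%s</text>',
            .fmt(xpx + cw / 2), .fmt(headerH - annH - 4),
            .fmt(xpx + cw / 2), .fmt(headerH - annH - 4), colnames(x)[j]),
            sprintf('<rect x="%s" y="%s" width="%d" height="%d" fill="%s"/>',
                    .fmt(xpx), .fmt(headerH - annH), cw, annH - 2,
                    colorsByClass[[classOf[j]]]))
    }
    for (i in seq_len(nrow(x))) {
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="9" text-anchor="end">%s</text>',
            .fmt(labelW - 4), .fmt(headerH + (i - 0.5) * ch + 3), genes[i]))
        for (j in seq_len(ncol(x)))
            out <- c(out, sprintf(
                '<rect x="%s" y="%s" width="%d" height="%d" fill="%s" stroke="white" stroke-width="0.5"/>',
                .fmt(labelW + (j - 1) * cw), .fmt(headerH + (i - 1) * ch),
                cw, ch, colors[bin[i, j]]))
    }
    out <- c(out, "</svg>")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(out, con, sep = "\n")
    invisible(path)
}
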