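# Rendering of the extended logo: stacked base glyphs scaled by base IC on
# a 0-2 bit axis, with gray bars at the intervening phosphate linkage
# positions whose height is the normalized linkage IC and whose fill shade
# encodes mean TRX flexibility (black = 0, white = 43).  Bars are drawn
# behind the letters and outlined so near-white bars stay visible.
# The SVG backend emits fully deterministic markup (no timestamps):
# identical profile + style give byte-identical files.

#' Construct a LogoStyle
#'
#' Defaults are tuned for motif sets around 20 bp: the first bar sits at
#' 1.5 (between the first two columns) and bars advance by one column.
#'
#' @param barStart x-position of the first linkage bar, in column units.
#' @param barIncrement spacing between bars, in column units.
#' @param barWidth bar width, in column units (0 < barWidth < 1).
#' @param yMax top of the bits axis.
#' @param colors named fill colors for A, C, G, T (conventional palette).
#' @param format default output format: "svg" (default), "png" or "pdf".
#' @param width,height output size in pixels (svg/png) or inches (pdf);
#'   \code{width = NA} sizes automatically from the sequence length.
#' @return A \linkS4class{LogoStyle}.
#' @export
LogoStyle <- function(barStart = 1.5, barIncrement = 1, barWidth = 0.35,
                      yMax = 2, colors = c(A = "#109648", C = "#255C99",
                                           G = "#F7B32B", T = "#D62839"),
                      format = "svg", width = NA_real_, height = 260) {
    new("LogoStyle", barStart = barStart, barIncrement = barIncrement,
        barWidth = barWidth, yMax = yMax, colors = colors, format = format,
        width = width, height = height)
}

#' Letter stack geometry of one logo column
#'
#' Heights are \code{p(letter) * IC}; letters are ordered by ascending
#' frequency so the most frequent base sits on top of the stack.  The
#' heights sum to the column IC.
#'
#' @param freq named base frequencies (A, C, G, T) summing to 1.
#' @param ic column information content in bits.
#' @return data.frame with columns \code{letter} and \code{height},
#'   bottom of the stack first; empty when IC is 0.
#' @examples
#' letterStack(c(A = 0.5, C = 0.5, G = 0, T = 0), 1)
#' @export
letterStack <- function(freq, ic) {
    if (abs(sum(freq) - 1) > 1e-6)
        validationError("frequencies must sum to 1")
    if (is.null(names(freq)))
        names(freq) <- c("A", "C", "G", "T")[seq_along(freq)]
    ord <- order(freq, names(freq))
    freq <- freq[ord]
    keep <- freq > 0 & freq * ic > 0
    data.frame(letter = names(freq)[keep],
               height = unname(freq[keep] * ic),
               stringsAsFactors = FALSE)
}

# glyph outlines in the unit box; each letter is a list of subpaths plus a
# fill rule ("evenodd" carves the hole in A)
.letterPolys <- function() {
    arc <- function(from, to, rx, ry, n = 24) {
        t <- seq(from, to, length.out = n) * pi / 180
        cbind(0.5 + rx * cos(t), 0.5 + ry * sin(t))
    }
    ring <- function(open) {
        rbind(arc(open, 360 - open, 0.5, 0.5),
              arc(360 - open, open, 0.28, 0.30))
    }
    list(
        A = list(rule = "evenodd", paths = list(
            rbind(c(0, 0), c(0.38, 1), c(0.62, 1), c(1, 0), c(0.78, 0),
                  c(0.66, 0.32), c(0.34, 0.32), c(0.22, 0)),
            rbind(c(0.38, 0.44), c(0.62, 0.44), c(0.575, 0.56),
                  c(0.425, 0.56)))),
        C = list(rule = "nonzero", paths = list(ring(35))),
        G = list(rule = "nonzero", paths = list(
            ring(40),
            rbind(c(0.55, 0.30), c(0.95, 0.30), c(0.95, 0.44),
                  c(0.55, 0.44)),
            rbind(c(0.82, 0.16), c(0.95, 0.16), c(0.95, 0.44),
                  c(0.82, 0.44)))),
        T = list(rule = "nonzero", paths = list(
            rbind(c(0, 0.84), c(1, 0.84), c(1, 1), c(0, 1)),
            rbind(c(0.38, 0), c(0.62, 0), c(0.62, 0.84), c(0.38, 0.84))))
    )
}

# shared drawing model: a list of shapes in plot coordinates
# (x in column units, y in bits)
.logoShapes <- function(profile, style) {
    L <- profile@L
    J <- L - 1L
    barX <- style@barStart + (seq_len(J) - 1L) * style@barIncrement
    if (J > 0L && (min(barX) <= 1 || max(barX) >= L))
        validationError(
            "style places bars outside the letter columns; adjust barStart/barIncrement")
    shapes <- list()
    shade <- trxShade(profile@meanTRX)
    for (j in seq_len(J)) {
        h <- profile@icLinkNorm[j]
        if (is.na(shade[j]) || h <= 0) next
        g <- sprintf("#%02x%02x%02x", round(shade[j] * 255),
                     round(shade[j] * 255), round(shade[j] * 255))
        shapes[[length(shapes) + 1L]] <- list(
            type = "rect", x0 = barX[j] - style@barWidth / 2, y0 = 0,
            x1 = barX[j] + style@barWidth / 2, y1 = h,
            fill = g, stroke = "#000000")
    }
    glyphs <- .letterPolys()
    for (i in seq_len(L)) {
        stack <- letterStack(profile@baseFreq[, i], profile@icBase[i])
        y0 <- 0
        for (r in seq_len(nrow(stack))) {
            h <- stack$height[r]
            gl <- glyphs[[stack$letter[r]]]
            paths <- lapply(gl$paths, function(m)
                cbind(i - 0.45 + m[, 1] * 0.9, y0 + m[, 2] * h))
            shapes[[length(shapes) + 1L]] <- list(
                type = "path", paths = paths, rule = gl$rule,
                fill = unname(style@colors[stack$letter[r]]), stroke = NA)
            y0 <- y0 + h
        }
    }
    shapes
}

.fmt <- function(v) formatC(v, format = "f", digits = 2)

.renderSVG <- function(profile, style, path) {
    L <- profile@L
    mL <- 46; mR <- 12; mT <- 12; mB <- 34
    colW <- 28
    W <- if (is.na(style@width)) mL + mR + colW * L else style@width
    H <- style@height
    plotW <- W - mL - mR
    plotH <- H - mT - mB
    px <- function(x) mL + (x - 0.5) / L * plotW
    py <- function(y) mT + plotH - y / style@yMax * plotH
    out <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
        .fmt(W), .fmt(H), .fmt(W), .fmt(H)))
    for (s in .logoShapes(profile, style)) {
        if (s$type == "rect") {
            out <- c(out, sprintf(
                '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="1"/>',
                .fmt(px(s$x0)), .fmt(py(s$y1)),
                .fmt(px(s$x1) - px(s$x0)), .fmt(py(s$y0) - py(s$y1)),
                s$fill, s$stroke))
        } else {
            d <- vapply(s$paths, function(m) {
                pts <- paste0(.fmt(px(m[, 1])), ",", .fmt(py(m[, 2])))
                paste0("M", pts[1], "L", paste(pts[-1], collapse = "L"), "Z")
            }, "")
            out <- c(out, sprintf(
                '<path d="%s" fill="%s" fill-rule="%s"/>',
                paste(d, collapse = ""), s$fill, s$rule))
        }
    }
    # axes
    ax <- "#333333"
    out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
        .fmt(px(0.5)), .fmt(py(0)), .fmt(px(L + 0.5)), .fmt(py(0)), ax))
    out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
        .fmt(px(0.5)), .fmt(py(0)), .fmt(px(0.5)), .fmt(py(style@yMax)), ax))
    for (v in seq(0, style@yMax, by = 0.5)) {
        out <- c(out, sprintf(
            '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
            .fmt(px(0.5) - 4), .fmt(py(v)), .fmt(px(0.5)), .fmt(py(v)), ax),
            sprintf(
            '<text x="%s" y="%s" font-size="10" text-anchor="end" fill="%s">%s</text>',
            .fmt(px(0.5) - 7), .fmt(py(v) + 3), ax, .fmt(v)))
    }
    step <- max(1L, ceiling(L / 25))
    for (i in seq(1L, L, by = step)) {
        out <- c(out, sprintf(
            '<text x="%s" y="%s" font-size="10" text-anchor="middle" fill="%s">%d</text>',
            .fmt(px(i)), .fmt(py(0) + 14), ax, i))
    }
    out <- c(out, sprintf(
        '<text x="12" y="%s" font-size="11" fill="%s" transform="rotate(-90 12 %s)">bits</text>',
        .fmt(py(style@yMax / 2)), ax, .fmt(py(style@yMax / 2))),
        "</svg>")
    con <- tryCatch(file(path, "wb"),
                    error = function(e) ioError(sprintf(
                        "cannot write '%s': %s", path, conditionMessage(e))))
    on.exit(close(con))
    writeLines(out, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

.renderDevice <- function(profile, style, path, format) {
    L <- profile@L
    W <- if (is.na(style@width)) 46 + 12 + 28 * L else style@width
    if (format == "png")
        grDevices::png(path, width = W, height = style@height)
    else
        grDevices::pdf(path, width = W / 72, height = style@height / 72)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(3, 4, 1, 1))
    graphics::plot(NA, xlim = c(0.5, L + 0.5), ylim = c(0, style@yMax),
                   xlab = "", ylab = "bits", axes = FALSE, xaxs = "i",
                   yaxs = "i")
    graphics::axis(1, at = seq_len(L))
    graphics::axis(2, at = seq(0, style@yMax, by = 0.5), las = 1)
    for (s in .logoShapes(profile, style)) {
        if (s$type == "rect") {
            graphics::rect(s$x0, s$y0, s$x1, s$y1, col = s$fill,
                           border = s$stroke)
        } else {
            xs <- unlist(lapply(s$paths, function(m) c(m[, 1], NA)))
            ys <- unlist(lapply(s$paths, function(m) c(m[, 2], NA)))
            graphics::polypath(xs[-length(xs)], ys[-length(ys)],
                               col = s$fill, border = NA,
                               rule = if (s$rule == "evenodd") "evenodd"
                                      else "winding")
        }
    }
    invisible(path)
}

#' Render an extended logo plot
#'
#' Writes the logo image: stacked base letters whose total height is the
#' column's base IC on a 0-2 bit axis, and a gray bar between columns
#' \code{j} and \code{j+1} whose height is the normalized linkage IC and
#' whose fill runs from black (mean TRX 0, stiff) to white (mean TRX 43,
#' flexible).  SVG output is deterministic: the same profile and style
#' always produce byte-identical files.
#'
#' @param profile a \linkS4class{LogoProfile}.
#' @param style a \linkS4class{LogoStyle}.
#' @param path output file.
#' @param format "svg" (default), "png" or "pdf"; defaults to the style's
#'   format tag.
#' @return \code{path}, invisibly.
#' @examples
#' ss <- SequenceSet(c("CATGA", "CATGT", "CATGA"))
#' f <- tempfile(fileext = ".svg")
#' renderLogo(logoProfile(ss), LogoStyle(), f)
#' @export
renderLogo <- function(profile, style = LogoStyle(), path,
                       format = style@format) {
    if (!format %in% c("svg", "png", "pdf"))
        usageError(sprintf("unrecognized format '%s'", format))
    dir <- dirname(path)
    if (!dir.exists(dir))
        ioError(sprintf("output directory does not exist: '%s'", dir))
    if (format == "svg")
        .renderSVG(profile, style, path)
    else
        .renderDevice(profile, style, path, format)
    invisible(path)
}
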