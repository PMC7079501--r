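## Rendering backends for FigureSpec: an SVG writer (one drawable element
## per glyph) and a PNG writer via the grid device. Both consume a shared
## pixel layout computed from the spec, so the two backends cannot drift.

# compute pixel-space drawing elements for a figure.
# Returns a data.frame with one row per element; rows with isGlyph=TRUE
# correspond one-to-one with the spec's glyphs.
layoutFigure <- function(fig, width = 1000, panelHeight = 110,
                         marginLeft = 60, marginRight = 160) {
  w0 <- fig@windowStart; w1 <- fig@windowEnd
  plotW <- width - marginLeft - marginRight
  sx <- function(x) marginLeft + (x - w0) / (w1 - w0) * plotW
  headerH <- 34; axisH <- 28
  els <- list()
  add <- function(type, isGlyph, x = NA, y = NA, w = NA, h = NA,
                  x2 = NA, y2 = NA, color = "#000000", text = "") {
    els[[length(els) + 1L]] <<- data.frame(
      type = type, isGlyph = isGlyph, x = x, y = y, w = w, h = h,
      x2 = x2, y2 = y2, color = color, text = text, stringsAsFactors = FALSE)
  }
  add("text", FALSE, x = marginLeft, y = 22, color = "#000000",
      text = fig@header)
  yTop <- headerH
  for (p in fig@panels) {
    g <- p@glyphs
    lanes <- unique(g$lane)
    if (!length(lanes)) lanes <- "default"
    laneH <- (panelHeight - 18) / length(lanes)
    add("text", FALSE, x = marginLeft, y = yTop + 12, color = "#404040",
        text = p@title)
    maxH <- if (nrow(g)) max(c(g$height[g$kind %in% c("bar", "area")], 1))
            else 1
    if (nrow(g)) for (i in seq_len(nrow(g))) {
      lane <- match(g$lane[i], lanes)
      ly0 <- yTop + 16 + (lane - 1) * laneH
      x <- sx(g$xstart[i]); xw <- max(sx(g$xend[i]) - x, 0.5)
      kind <- g$kind[i]
      if (kind %in% c("box", "heatcell")) {
        frac <- g$height[i]
        hh <- laneH * frac
        add("rect", TRUE, x = x, y = ly0 + (laneH - hh) / 2, w = xw, h = hh,
            color = g$color[i])
      } else if (kind == "bar") {
        hh <- laneH * g$height[i] / maxH
        add("rect", TRUE, x = x, y = ly0 + laneH - hh, w = xw, h = hh,
            color = g$color[i])
      } else if (kind == "area") {
        hh <- laneH * g$height[i] / maxH
        add("polygon", TRUE, x = x, y = ly0 + laneH - hh, w = xw, h = hh,
            color = g$color[i])
      } else if (kind == "line") {
        add("line", TRUE, x = x, y = ly0 + laneH / 2, x2 = x + xw,
            y2 = ly0 + laneH / 2, color = g$color[i])
      } else if (kind == "letter") {
        add("gtext", TRUE, x = x + xw / 2, y = ly0 + laneH / 2 + 4,
            color = g$color[i], text = g$label[i])
      }
    }
    if (nrow(p@legend)) for (j in seq_len(nrow(p@legend))) {
      lx <- width - marginRight + 10
      ly <- yTop + 14 + (j - 1) * 14
      add("rect", FALSE, x = lx, y = ly - 8, w = 10, h = 10,
          color = p@legend$color[j])
      add("text", FALSE, x = lx + 14, y = ly, color = "#000000",
          text = p@legend$name[j])
    }
    yTop <- yTop + panelHeight
  }
  # axis: ticks labelled in original genomic coordinates
  axisY <- yTop + 12
  add("line", FALSE, x = sx(w0), y = axisY, x2 = sx(w1), y2 = axisY,
      color = "#000000")
  ticks <- pretty(c(w0, w1), n = 5)
  ticks <- ticks[ticks >= w0 & ticks <= w1]
  for (t in ticks) {
    lab <- if (fig@strand == "-") w0 + w1 - t else t
    add("line", FALSE, x = sx(t), y = axisY, x2 = sx(t), y2 = axisY + 4,
        color = "#000000")
    add("text", FALSE, x = sx(t), y = axisY + 16, color = "#000000",
        text = format(lab, scientific = FALSE))
  }
  list(width = width, height = yTop + axisH,
       elements = do.call(rbind, els))
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a FigureSpec as SVG
#'
#' Every glyph of the spec becomes exactly one drawable SVG element
#' carrying `class="glyph"`; titles, legends and the axis are additional
#' undecorated elements.
#'
#' @param fig a [FigureSpec-class].
#' @param width figure width in pixels.
#' @param panelHeight height of each panel in pixels.
#' @return a single SVG document as a character scalar.
#' @export
figureToSVG <- function(fig, width = 1000, panelHeight = 110) {
  lay <- layoutFigure(fig, width, panelHeight)
  e <- lay$elements
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    lay$width, round(lay$height), lay$width, round(lay$height)),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>',
            lay$width, round(lay$height)))
  for (i in seq_len(nrow(e))) {
    cls <- if (e$isGlyph[i]) ' class="glyph"' else ""
    out <- c(out, switch(e$type[i],
      rect = sprintf('<rect%s x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s"/>',
                     cls, e$x[i], e$y[i], e$w[i], e$h[i], e$color[i]),
      polygon = sprintf('<polygon%s points="%.2f,%.2f %.2f,%.2f %.2f,%.2f %.2f,%.2f" fill="%s"/>',
                        cls, e$x[i], e$y[i] + e$h[i], e$x[i], e$y[i],
                        e$x[i] + e$w[i], e$y[i], e$x[i] + e$w[i],
                        e$y[i] + e$h[i], e$color[i]),
      line = sprintf('<line%s x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="1.5"/>',
                     cls, e$x[i], e$y[i], e$x2[i], e$y2[i], e$color[i]),
      gtext = sprintf('<text%s x="%.2f" y="%.2f" fill="%s" font-family="monospace" font-size="10" text-anchor="middle">%s</text>',
                      cls, e$x[i], e$y[i], e$color[i], xmlEscape(e$text[i])),
      text = sprintf('<text x="%.2f" y="%.2f" fill="%s" font-family="sans-serif" font-size="11">%s</text>',
                     e$x[i], e$y[i], e$color[i], xmlEscape(e$text[i]))))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

# draw the layout on the current grid device
drawLayoutGrid <- function(lay) {
  grid::grid.newpage()
  W <- lay$width; H <- lay$height
  px <- function(x) grid::unit(x / W, "npc")
  py <- function(y) grid::unit(1 - y / H, "npc")
  e <- lay$elements
  for (i in seq_len(nrow(e))) {
    switch(e$type[i],
      rect = ,
      polygon = grid::grid.rect(
        x = px(e$x[i]), y = py(e$y[i]), width = grid::unit(e$w[i] / W, "npc"),
        height = grid::unit(e$h[i] / H, "npc"), just = c("left", "top"),
        gp = grid::gpar(fill = e$color[i], col = NA)),
      line = grid::grid.lines(
        x = grid::unit(c(e$x[i], e$x2[i]) / W, "npc"),
        y = grid::unit(1 - c(e$y[i], e$y2[i]) / H, "npc"),
        gp = grid::gpar(col = e$color[i])),
      gtext = ,
      text = grid::grid.text(
        e$text[i], x = px(e$x[i]), y = py(e$y[i]),
        just = c("left", "bottom"),
        gp = grid::gpar(col = e$color[i], fontsize = 9)))
  }
}

#' Export a figure as PNG or SVG bytes
#'
#' @param fig a [FigureSpec-class].
#' @param format `"PNG"` or `"SVG"` (case-insensitive).
#' @param width figure width in pixels.
#' @param panelHeight panel height in pixels.
#' @return raw vector with the image document.
#' @export
exportFigure <- function(fig, format = c("SVG", "PNG"), width = 1000,
                         panelHeight = 110) {
  if (!toupper(format[1L]) %in% c("SVG", "PNG"))
    stop(sprintf("unsupported export format '%s' (use PNG or SVG)",
                 format[1L]))
  format <- toupper(format[1L])
  if (format == "SVG")
    return(charToRaw(figureToSVG(fig, width, panelHeight)))
  lay <- layoutFigure(fig, width, panelHeight)
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path))
  grDevices::png(path, width = lay$width, height = ceiling(lay$height),
                 type = "cairo")
  ok <- tryCatch({ drawLayoutGrid(lay); TRUE },
                 finally = grDevices::dev.off())
  readBin(path, "raw", n = file.info(path)$size)
}
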