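## Declarative track specification: pure functions turning an oriented
## GenomeView into a FigureSpec. All of the rendering conventions live
## here — thick/thin gene-model glyphs, strand coloring, sequence display
## modes, splice-event color modes — so the web layer and the SVG/PNG
## writers contain no genomics logic.

#' Default color scheme
#'
#' Same-strand gene models are black, opposite-strand models grey. Splice
#' event classes follow the conventional map: A3 (alternative 3' splice
#' site) blue, A5 (alternative 5' splice site) red, RI (intron retention)
#' green; annotation bars default to blue in uniform mode, and the score
#' gradient runs light to dark blue. Glyph height classes are
#' full = 1.0, half = 0.5, thin = 0.1 in panel-relative units.
#'
#' @param trackColors optional named per-dataset colors.
#' @return a [ColorScheme-class].
#' @export
defaultColorScheme <- function(trackColors = character(0)) {
  new("ColorScheme",
      trackColors = trackColors,
      sameStrandColor = "#000000",
      oppositeStrandColor = "#808080",
      nucleotideColors = c(A = "#2E8B57", C = "#1E64C8", G = "#E69F00",
                           T = "#D62728", U = "#9467BD", N = "#A0A0A0"),
      eventClassColors = c(A3 = "#0000FF", A5 = "#FF0000", RI = "#008000"),
      defaultBarColor = "#0000FF",
      gradientLow = "#C6DBEF", gradientHigh = "#08306B",
      fallbackPalette = c("#8C564B", "#E377C2", "#7F7F7F", "#BCBD22",
                          "#17BECF", "#AA40FC"),
      heights = c(full = 1.0, half = 0.5, thin = 0.1))
}

# color for a named dataset; deterministic assignment from the fallback
# palette (sorted name order) when the scheme does not name the dataset
trackColor <- function(scheme, name, allNames = name) {
  if (name %in% names(scheme@trackColors))
    return(unname(scheme@trackColors[[name]]))
  pool <- sort(unique(allNames))
  scheme@fallbackPalette[(match(name, pool) - 1L) %%
                           length(scheme@fallbackPalette) + 1L]
}

glyphRow <- function(kind, xstart, xend, height, heightClass, color,
                     label = "", lane = "") {
  data.frame(kind = kind, xstart = as.numeric(xstart),
             xend = as.numeric(xend), height = as.numeric(height),
             heightClass = heightClass, color = color, label = label,
             lane = lane, stringsAsFactors = FALSE)
}

bindGlyphs <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d), list(...))
  if (!length(parts)) return(emptyGlyphs())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Glyphs for one gene model
#'
#' Introns (gaps between exons) become thin lines. For coding models,
#' exon-within-CDS pieces are full-height boxes and UTR pieces (exon
#' outside the CDS) half-height boxes; non-coding models draw every exon
#' full height. Geometry is independent of strand class — only the color
#' differs (black for same-strand, grey for opposite).
#'
#' @param model a (display-oriented) [GeneModel-class].
#' @param scheme a [ColorScheme-class].
#' @param strandClass `"same"` or `"opposite"`.
#' @param window optional c(start, end); glyphs are clamped to it.
#' @return data.frame of glyphs in left-to-right order.
#' @export
geneModelGlyphs <- function(model, scheme = defaultColorScheme(),
                            strandClass = c("same", "opposite"),
                            window = NULL) {
  strandClass <- match.arg(strandClass)
  color <- if (strandClass == "same") scheme@sameStrandColor
           else scheme@oppositeStrandColor
  h <- scheme@heights
  cds <- cdsSpan(model)
  lane <- model@transcriptId
  rows <- list()
  n <- length(model@exonStarts)
  for (k in seq_len(n)) {
    s <- model@exonStarts[k]; e <- model@exonEnds[k]
    if (is.null(cds)) {
      rows[[length(rows) + 1L]] <-
        glyphRow("box", s, e, h[["full"]], "full", color, lane = lane)
    } else {
      cs <- cds[["start"]]; ce <- cds[["end"]]
      if (s < min(ce, e) && cs > s) {
        utrEnd <- min(cs, e)
        if (utrEnd > s)
          rows[[length(rows) + 1L]] <-
            glyphRow("box", s, utrEnd, h[["half"]], "half", color, lane = lane)
      } else if (cs <= s) {
        # no left UTR piece in this exon
      }
      a <- max(s, cs); b <- min(e, ce)
      if (a < b)
        rows[[length(rows) + 1L]] <-
          glyphRow("box", a, b, h[["full"]], "full", color, lane = lane)
      if (e > ce && max(s, ce) < e) {
        utrStart <- max(s, ce)
        rows[[length(rows) + 1L]] <-
          glyphRow("box", utrStart, e, h[["half"]], "half", color, lane = lane)
      }
    }
    if (k < n)
      rows[[length(rows) + 1L]] <-
        glyphRow("line", e, model@exonStarts[k + 1L], h[["thin"]], "thin",
                 color, lane = lane)
  }
  g <- do.call(bindGlyphs, rows)
  if (!is.null(window) && nrow(g)) {
    g$xstart <- pmax(g$xstart, window[1L])
    g$xend <- pmin(g$xend, window[2L])
    g <- g[g$xstart < g$xend, , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

#' iCLIP signal panel
#'
#' One bar glyph per nonzero position of the dense crosslink-count array,
#' with significant sites drawn as a bar row beneath the signal. The sum
#' of bar heights equals the sum of the count array.
#'
#' @param counts dense numeric array over the window (oriented).
#' @param windowStart display coordinate of the first array element.
#' @param sites BED6 data.frame of significant sites clipped to the
#'   window, or NULL.
#' @param scheme a [ColorScheme-class].
#' @param datasetName dataset label (panel title and legend entry).
#' @param allNames all iCLIP dataset names (for deterministic coloring).
#' @return a [TrackPanel-class] of kind `iclip-signal`.
#' @export
iclipPanel <- function(counts, windowStart, sites = NULL,
                       scheme = defaultColorScheme(),
                       datasetName = "iCLIP", allNames = datasetName) {
  col <- trackColor(scheme, datasetName, allNames)
  nz <- which(counts != 0)
  bars <- if (length(nz))
    glyphRow("bar", windowStart + nz - 1L, windowStart + nz, counts[nz],
             "full", col, lane = "signal")
  else NULL
  siteGlyphs <- if (!is.null(sites) && nrow(sites))
    glyphRow("box", sites$start, sites$end, scheme@heights[["half"]],
             "half", col, label = sites$name, lane = "sites")
  else NULL
  TrackPanel(datasetName, "iclip-signal", bindGlyphs(bars, siteGlyphs),
             legend = data.frame(name = datasetName, color = col,
                                 stringsAsFactors = FALSE))
}

#' Sequence panel
#'
#' Heatmap mode draws one colored cell per base, text mode one letter per
#' base, and hidden mode yields no panel (NULL).
#'
#' @param sequence window sequence (display-oriented).
#' @param mode `"heatmap"`, `"text"` or `"hidden"`.
#' @param scheme a [ColorScheme-class].
#' @param windowStart display coordinate of the first base.
#' @param windowLength expected sequence length; a mismatch is an error.
#' @return a [TrackPanel-class] of kind `sequence`, or NULL.
#' @export
sequencePanel <- function(sequence, mode = c("heatmap", "text", "hidden"),
                          scheme = defaultColorScheme(), windowStart = 0L,
                          windowLength = nchar(sequence)) {
  mode <- match.arg(mode)
  if (mode == "hidden" || is.na(sequence)) return(NULL)
  if (nchar(sequence) != windowLength)
    stop(sprintf("sequence length %d does not match window length %d",
                 nchar(sequence), windowLength))
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  up <- toupper(bases)
  cols <- scheme@nucleotideColors[up]
  cols[is.na(cols)] <- scheme@nucleotideColors[["N"]]
  x <- windowStart + seq_along(bases) - 1L
  kind <- if (mode == "heatmap") "heatcell" else "letter"
  g <- glyphRow(kind, x, x + 1L, scheme@heights[["full"]], "full",
                unname(cols), label = bases, lane = "sequence")
  TrackPanel("sequence", "sequence", g)
}

# linear score -> color interpolation over the displayed score range
scoreGradientColors <- function(scores, scheme) {
  lo <- min(scores); hi <- max(scores)
  t <- if (hi > lo) (scores - lo) / (hi - lo) else rep(0.5, length(scores))
  ramp <- grDevices::colorRamp(c(scheme@gradientLow, scheme@gradientHigh))
  rgb <- ramp(t)
  grDevices::rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L], maxColorValue = 255)
}

# colors for event bars under the three display modes
eventBarColors <- function(events, mode, scheme) {
  if (mode == "uniform")
    return(rep(scheme@defaultBarColor, nrow(events)))
  if (mode == "by-name") {
    cols <- scheme@eventClassColors[events$name]
    unknown <- sort(unique(events$name[is.na(cols)]))
    if (length(unknown)) {
      fb <- scheme@fallbackPalette[(match(events$name, unknown) - 1L) %%
                                     length(scheme@fallbackPalette) + 1L]
      cols[is.na(cols)] <- fb[is.na(cols)]
    }
    return(unname(cols))
  }
  # by-score
  if (anyNA(events$score)) {
    bad <- events$name[is.na(events$score)][1L]
    stop(sprintf("by-score coloring requires a score for every event (missing for '%s')",
                 bad))
  }
  scoreGradientColors(events$score, scheme)
}

#' RNA-seq coverage panel with splice-event bars
#'
#' Coverage is drawn as a sequence of area glyphs (one per maximal
#' constant nonzero run). Event bars below the coverage are colored by
#' `mode`: `"uniform"` (default blue), `"by-name"` (event-class map:
#' A3 blue, A5 red, RI green; unknown classes get a deterministic
#' fallback), or `"by-score"` (linear color gradient over the min-max
#' score range of the displayed events).
#'
#' @param coverage dense numeric coverage array (oriented).
#' @param windowStart display coordinate of the first array element.
#' @param events BED6 data.frame of splice events clipped to the window,
#'   or NULL.
#' @param mode event color mode.
#' @param scheme a [ColorScheme-class].
#' @param sampleName sample label.
#' @param allNames all RNA-seq sample names (for deterministic coloring).
#' @return a [TrackPanel-class] of kind `coverage`.
#' @export
rnaseqPanel <- function(coverage, windowStart, events = NULL,
                        mode = c("uniform", "by-name", "by-score"),
                        scheme = defaultColorScheme(),
                        sampleName = "RNA-seq", allNames = sampleName) {
  mode <- match.arg(mode)
  col <- trackColor(scheme, sampleName, allNames)
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  nz <- which(r$values != 0)
  areas <- if (length(nz))
    glyphRow("area", windowStart + starts[nz], windowStart + ends[nz],
             r$values[nz], "full", col, lane = "coverage")
  else NULL
  bars <- NULL
  if (!is.null(events) && nrow(events)) {
    cols <- eventBarColors(events, mode, scheme)
    bars <- glyphRow("box", events$start, events$end,
                     scheme@heights[["half"]], "half", cols,
                     label = events$name, lane = "events")
  }
  legend <- data.frame(name = sampleName, color = col,
                       stringsAsFactors = FALSE)
  if (!is.null(bars)) {
    extra <- unique(data.frame(name = bars$label, color = bars$color,
                               stringsAsFactors = FALSE))
    legend <- rbind(legend, extra)
  }
  TrackPanel(sampleName, "coverage", bindGlyphs(areas, bars), legend = legend)
}

#' Gene-models panel
#'
#' One lane per isoform: same-strand models first (black), then
#' opposite-strand models (grey), each drawn with [geneModelGlyphs()].
#'
#' @param view an oriented [GenomeView-class].
#' @param scheme a [ColorScheme-class].
#' @return a [TrackPanel-class] of kind `gene-models`.
#' @export
geneModelsPanel <- function(view, scheme = defaultColorScheme()) {
  win <- c(view@windowStart, view@windowEnd)
  gsame <- lapply(view@sameStrand, geneModelGlyphs, scheme, "same", win)
  gopp <- lapply(view@oppositeStrand, geneModelGlyphs, scheme, "opposite", win)
  glyphs <- do.call(bindGlyphs, c(gsame, gopp))
  legend <- data.frame(
    name = c(vapply(view@sameStrand, transcriptId, ""),
             vapply(view@oppositeStrand, transcriptId, "")),
    color = c(rep(scheme@sameStrandColor, length(view@sameStrand)),
              rep(scheme@oppositeStrandColor, length(view@oppositeStrand))),
    stringsAsFactors = FALSE)
  TrackPanel("gene models", "gene-models", glyphs, legend = legend)
}

# site/event set paired with a track: by exact name, else by position
matchAnnotationSet <- function(sets, name, position) {
  if (name %in% names(sets)) return(sets[[name]])
  if (position <= length(sets) && is.null(names(sets))) return(sets[[position]])
  NULL
}

#' Assemble the figure for one oriented view
#'
#' Panel order follows the dashboard layout: per-dataset signal panels
#' (iCLIP tab: crosslink signal with significant-site bars, then the
#' sequence panel; RNA-seq tab: coverage with event bars per sample),
#' and the gene-models panel last. The header carries the gene id and its
#' strand in brackets, e.g. `"AT5G15960 (+)"`.
#'
#' @param view an oriented [GenomeView-class] (see [orientView()]).
#' @param scheme a [ColorScheme-class].
#' @param options list with any of: `tab` (`"iclip"` or `"rnaseq"`),
#'   `sequenceMode` (`"heatmap"`, `"text"`, `"hidden"`), `eventColorMode`
#'   (`"uniform"`, `"by-name"`, `"by-score"`), `datasets` / `samples`
#'   (character subsets to display; default all).
#' @return a [FigureSpec-class].
#' @export
assembleFigure <- function(view, scheme = defaultColorScheme(),
                           options = list()) {
  tab <- if (is.null(options$tab)) "iclip" else options$tab
  stopifnot(tab %in% c("iclip", "rnaseq"))
  seqMode <- if (is.null(options$sequenceMode)) "heatmap"
             else options$sequenceMode
  evMode <- if (is.null(options$eventColorMode)) "uniform"
            else options$eventColorMode
  panels <- list()
  if (tab == "iclip") {
    names <- names(view@iclipValues)
    wanted <- if (is.null(options$datasets)) names
              else intersect(names, options$datasets)
    for (nm in wanted) {
      sites <- matchAnnotationSet(view@siteSets, nm, match(nm, names))
      panels[[length(panels) + 1L]] <-
        iclipPanel(view@iclipValues[[nm]], view@windowStart, sites, scheme,
                   nm, allNames = names)
    }
    sp <- sequencePanel(view@sequence, seqMode, scheme, view@windowStart,
                        view@windowEnd - view@windowStart)
    if (!is.null(sp)) panels[[length(panels) + 1L]] <- sp
  } else {
    names <- names(view@rnaseqValues)
    wanted <- if (is.null(options$samples)) names
              else intersect(names, options$samples)
    for (nm in wanted) {
      events <- matchAnnotationSet(view@eventSets, nm, match(nm, names))
      panels[[length(panels) + 1L]] <-
        rnaseqPanel(view@rnaseqValues[[nm]], view@windowStart, events,
                    evMode, scheme, nm, allNames = names)
    }
  }
  panels[[length(panels) + 1L]] <- geneModelsPanel(view, scheme)
  new("FigureSpec",
      header = sprintf("%s (%s)", view@geneId, view@strand),
      geneId = view@geneId, strand = view@strand,
      windowStart = view@windowStart, windowEnd = view@windowEnd,
      panels = panels)
}

#' Serialize a FigureSpec to JSON
#'
#' The JSON form is the golden-file test surface decoupled from any
#' plotting backend.
#'
#' @param fig a [FigureSpec-class].
#' @param pretty pretty-print the JSON.
#' @return a JSON string.
#' @export
figureToJSON <- function(fig, pretty = FALSE) {
  x <- list(
    header = fig@header, geneId = fig@geneId, strand = fig@strand,
    window = list(start = fig@windowStart, end = fig@windowEnd),
    panels = lapply(fig@panels, function(p)
      list(title = p@title, kind = p@kind, glyphs = p@glyphs,
           legend = p@legend)))
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, dataframe = "rows")
}

#' Total number of glyphs in a figure
#' @param fig a [FigureSpec-class].
#' @export
glyphCount <- function(fig) {
  sum(vapply(fig@panels, function(p) nrow(p@glyphs), 0L))
}
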