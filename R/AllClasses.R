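#' @import methods
#' @importFrom stats setNames
NULL

## All genomic coordinates inside the package are 0-based half-open [start, end).
## GTF input is converted on read; BED-family formats are stored as-is.
## Strand is one of "+", "-", "*" ("*" = unstranded, never coerced to "+").

setClassUnion("DataFrameOrNULL", c("data.frame", "NULL"))
setClassUnion("CharacterOrNULL", c("character", "NULL"))

#' GeneModel: one transcript isoform
#'
#' A single transcript isoform: its genomic span, ordered disjoint exon
#' blocks, and an optional CDS span (`NA` for non-coding transcripts).
#' Coordinates are 0-based half-open.
#'
#' @slot transcriptId transcript identifier.
#' @slot geneId gene identifier the transcript belongs to.
#' @slot chrom chromosome name.
#' @slot strand one of `"+"`, `"-"`, `"*"`.
#' @slot start,end genomic span (equal to the span of the exons).
#' @slot exonStarts,exonEnds parallel integer vectors of exon blocks,
#'   sorted ascending and pairwise disjoint.
#' @slot cdsStart,cdsEnd CDS span (thickStart/thickEnd) or `NA_integer_`.
#'
#' @export
setClass("GeneModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    chrom        = "character",
    strand       = "character",
    start        = "integer",
    end          = "integer",
    exonStarts   = "integer",
    exonEnds     = "integer",
    cdsStart     = "integer",
    cdsEnd       = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "chrom must be a single non-empty string")
  if (!object@strand %in% c("+", "-", "*"))
    msg <- c(msg, "strand must be one of '+', '-', '*'")
  s <- object@exonStarts; e <- object@exonEnds
  if (length(s) != length(e) || length(s) < 1L)
    msg <- c(msg, "exonStarts/exonEnds must be non-empty parallel vectors")
  else {
    if (any(s >= e)) msg <- c(msg, "exons must be non-empty intervals")
    if (any(s < 0L)) msg <- c(msg, "exon coordinates must be non-negative")
    if (length(s) > 1L) {
      if (is.unsorted(s, strictly = TRUE))
        msg <- c(msg, "exons must be sorted ascending")
      else if (any(s[-1L] < e[-length(e)]))
        msg <- c(msg, "exons must be pairwise disjoint")
    }
    if (object@start != s[1L] || object@end != e[length(e)])
      msg <- c(msg, "model span must run from first exon start to last exon end")
  }
  if (!is.na(object@cdsStart)) {
    if (is.na(object@cdsEnd) || object@cdsStart > object@cdsEnd)
      msg <- c(msg, "cdsStart must be <= cdsEnd")
    else if (object@cdsStart < object@start || object@cdsEnd > object@end)
      msg <- c(msg, "CDS must lie within the model span")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param transcriptId,geneId identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param exonStarts,exonEnds exon blocks, 0-based half-open.
#' @param cdsStart,cdsEnd optional CDS span; both `NA` for non-coding.
#' @return A [GeneModel-class] object.
#' @examples
#' GeneModel("tx1", "g1", "chr1", "+", c(100L, 400L), c(200L, 500L), 150L, 450L)
#' @export
GeneModel <- function(transcriptId, geneId, chrom, strand,
                      exonStarts, exonEnds,
                      cdsStart = NA_integer_, cdsEnd = NA_integer_) {
  new("GeneModel",
      transcriptId = as.character(transcriptId),
      geneId = as.character(geneId),
      chrom = as.character(chrom),
      strand = as.character(strand),
      start = as.integer(exonStarts[1L]),
      end = as.integer(exonEnds[length(exonEnds)]),
      exonStarts = as.integer(exonStarts),
      exonEnds = as.integer(exonEnds),
      cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd))
}

#' CoverageTrack: sparse per-base signal over chromosomes
#'
#' Non-negative signal stored as per-chromosome runs (0-based half-open,
#' sorted, non-overlapping, zero runs dropped, adjacent equal-valued runs
#' merged). Any position not covered by a run has value 0.
#'
#' @slot name dataset label.
#' @slot runs named list (by chromosome) of data.frames with columns
#'   `start`, `end`, `value`.
#' @export
setClass("CoverageTrack",
  representation(name = "character", runs = "list")
)

setValidity("CoverageTrack", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  for (chrom in names(object@runs)) {
    r <- object@runs[[chrom]]
    if (!all(c("start", "end", "value") %in% names(r))) {
      msg <- c(msg, sprintf("runs[['%s']] lacks start/end/value", chrom)); next
    }
    if (nrow(r) == 0L) next
    if (any(r$start >= r$end)) msg <- c(msg, sprintf("%s: empty runs", chrom))
    if (any(!is.finite(r$value)) || any(r$value < 0))
      msg <- c(msg, sprintf("%s: values must be finite and >= 0", chrom))
    if (any(r$value == 0)) msg <- c(msg, sprintf("%s: zero runs must be dropped", chrom))
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
      msg <- c(msg, sprintf("%s: runs must be sorted and non-overlapping", chrom))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack from run intervals
#'
#' Runs are canonicalized: sorted per chromosome, zero-valued runs dropped,
#' adjacent runs with equal value merged. Overlapping runs are an error.
#'
#' @param name dataset label.
#' @param chrom,start,end,value parallel vectors of runs (0-based half-open).
#' @return A [CoverageTrack-class].
#' @export
CoverageTrack <- function(name, chrom = character(0), start = integer(0),
                          end = integer(0), value = numeric(0)) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  df <- df[df$value != 0, , drop = FALSE]
  runs <- lapply(split(df[c("start", "end", "value")], df$chrom), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
      stop("overlapping runs within a chromosome")
    rownames(r) <- NULL
    mergeAdjacentRuns(r)
  })
  new("CoverageTrack", name = name, runs = runs)
}

# merge touching runs of equal value into canonical form
mergeAdjacentRuns <- function(r) {
  if (nrow(r) < 2L) return(r)
  keep <- logical(nrow(r))
  keep[1L] <- TRUE
  j <- 1L
  for (i in 2:nrow(r)) {
    if (r$start[i] == r$end[j] && r$value[i] == r$value[j]) {
      r$end[j] <- r$end[i]
    } else {
      j <- i; keep[i] <- TRUE
    }
  }
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DataBundle: one dashboard's worth of parsed inputs
#'
#' The minimal bundle is a single annotation set; every other member is
#' optional. Annotation sets are lists of [GeneModel-class] objects;
#' site/event sets are data.frames with columns
#' `chrom,start,end,name,score,strand` (BED6 semantics, 0-based half-open).
#'
#' @slot annotations list of annotation sets (each a list of GeneModel).
#' @slot descriptions,extendedDescriptions optional data.frames keyed by
#'   gene id (first column).
#' @slot iclipTracks,rnaseqTracks lists of [CoverageTrack-class].
#' @slot siteSets,eventSets named lists of BED6 data.frames.
#' @slot sequences optional named character vector of per-transcript
#'   sequences (alphabet ACGTUN, case preserved).
#' @export
setClass("DataBundle",
  representation(
    annotations          = "list",
    descriptions         = "DataFrameOrNULL",
    extendedDescriptions = "DataFrameOrNULL",
    iclipTracks          = "list",
    siteSets             = "list",
    sequences            = "CharacterOrNULL",
    rnaseqTracks         = "list",
    eventSets            = "list"
  ),
  prototype(
    annotations = list(), descriptions = NULL, extendedDescriptions = NULL,
    iclipTracks = list(), siteSets = list(), sequences = NULL,
    rnaseqTracks = list(), eventSets = list()
  )
)

setValidity("DataBundle", function(object) {
  if (length(object@annotations) < 1L)
    return("a DataBundle requires at least one annotation set")
  TRUE
})

#' Construct a DataBundle
#'
#' @param annotations list of annotation sets (each a list of GeneModel), or
#'   a single annotation set (detected and wrapped).
#' @param descriptions,extendedDescriptions optional gene description tables.
#' @param iclipTracks,rnaseqTracks lists of CoverageTrack.
#' @param siteSets,eventSets named lists of BED6 data.frames.
#' @param sequences optional named character vector keyed by transcript id.
#' @return A [DataBundle-class].
#' @export
DataBundle <- function(annotations, descriptions = NULL,
                       extendedDescriptions = NULL,
                       iclipTracks = list(), siteSets = list(),
                       sequences = NULL, rnaseqTracks = list(),
                       eventSets = list()) {
  if (length(annotations) && methods::is(annotations[[1L]], "GeneModel"))
    annotations <- list(annotations)
  new("DataBundle", annotations = annotations, descriptions = descriptions,
      extendedDescriptions = extendedDescriptions, iclipTracks = iclipTracks,
      siteSets = siteSets, sequences = sequences,
      rnaseqTracks = rnaseqTracks, eventSets = eventSets)
}

#' GeneIndex: gene-level lookup over an annotation set
#'
#' Maps gene ids to their transcripts and overall span and answers
#' window-overlap queries (backed by a GRanges index).
#'
#' @slot models list of GeneModel (one annotation set).
#' @slot geneSpans data.frame gene/chrom/start/end/strand, one row per gene.
#' @slot txRanges GRanges of transcript spans (1-based internally) with
#'   transcript and gene ids in mcols, used for overlap queries.
#' @export
setClass("GeneIndex",
  representation(models = "list", geneSpans = "data.frame", txRanges = "ANY")
)

#' GenomeView: one oriented display window
#'
#' Everything needed to draw one gene: the window, the focus strand, models
#' split by strand, dense per-track arrays over the window, clipped
#' site/event sets, and the window sequence. Until [orientView()] is applied
#' all members are in genomic coordinates; afterwards minus-strand views are
#' mirrored so display coordinates run 5'->3' of the focus gene.
#'
#' @slot geneId focus gene.
#' @slot chrom,windowStart,windowEnd the window (0-based half-open).
#' @slot strand focus strand, `"+"` or `"-"`.
#' @slot sameStrand,oppositeStrand lists of (window-clipped) GeneModel.
#' @slot iclipValues,rnaseqValues named lists of dense numeric arrays of
#'   length `windowEnd - windowStart`.
#' @slot siteSets,eventSets named lists of BED6 data.frames clipped to the
#'   window.
#' @slot sequence window sequence or `NA_character_`.
#' @slot oriented logical; TRUE once expressed in display coordinates.
#' @export
setClass("GenomeView",
  representation(
    geneId = "character", chrom = "character",
    windowStart = "integer", windowEnd = "integer", strand = "character",
    sameStrand = "list", oppositeStrand = "list",
    iclipValues = "list", rnaseqValues = "list",
    siteSets = "list", eventSets = "list",
    sequence = "character", oriented = "logical"
  )
)

setValidity("GenomeView", function(object) {
  msg <- character(0)
  len <- object@windowEnd - object@windowStart
  if (len <= 0L) msg <- c(msg, "window must be non-empty")
  for (nm in names(object@iclipValues))
    if (length(object@iclipValues[[nm]]) != len)
      msg <- c(msg, sprintf("iclip array '%s' length != window length", nm))
  for (nm in names(object@rnaseqValues))
    if (length(object@rnaseqValues[[nm]]) != len)
      msg <- c(msg, sprintf("rnaseq array '%s' length != window length", nm))
  if (!is.na(object@sequence) && nchar(object@sequence) != len)
    msg <- c(msg, "sequence length != window length")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "focus strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' ColorScheme: all rendering colors and glyph height classes
#'
#' @slot trackColors named per-dataset colors (hex).
#' @slot sameStrandColor,oppositeStrandColor gene-model colors
#'   (defaults black / grey).
#' @slot nucleotideColors named map over A,C,G,T,U,N.
#' @slot eventClassColors named map for splice-event classes
#'   (A3 blue, A5 red, RI green); unknown classes receive a deterministic
#'   fallback from `fallbackPalette`.
#' @slot defaultBarColor uniform-mode annotation bar color (blue).
#' @slot gradientLow,gradientHigh endpoints of the score gradient.
#' @slot fallbackPalette categorical palette for unknown event classes.
#' @slot heights named numeric: full, half, thin glyph heights in
#'   panel-relative units.
#' @export
setClass("ColorScheme",
  representation(
    trackColors = "character",
    sameStrandColor = "character", oppositeStrandColor = "character",
    nucleotideColors = "character", eventClassColors = "character",
    defaultBarColor = "character",
    gradientLow = "character", gradientHigh = "character",
    fallbackPalette = "character", heights = "numeric"
  )
)

isHexColor <- function(x) grepl("^#[0-9A-Fa-f]{6}$", x)

setValidity("ColorScheme", function(object) {
  cols <- c(object@trackColors, object@sameStrandColor,
            object@oppositeStrandColor, object@nucleotideColors,
            object@eventClassColors, object@defaultBarColor,
            object@gradientLow, object@gradientHigh, object@fallbackPalette)
  if (!all(isHexColor(cols))) return("all colors must be #RRGGBB hex triplets")
  if (!all(c("full", "half", "thin") %in% names(object@heights)))
    return("heights must name full, half and thin")
  TRUE
})

#' TrackPanel: one horizontal panel of a figure
#'
#' @slot title panel title.
#' @slot kind one of iclip-signal, site-bars, sequence, coverage,
#'   event-bars, gene-models.
#' @slot glyphs data.frame with columns kind, xstart, xend, height,
#'   heightClass, color, label, lane (display coordinates).
#' @slot legend data.frame with columns name, color.
#' @export
setClass("TrackPanel",
  representation(title = "character", kind = "character",
                 glyphs = "data.frame", legend = "data.frame")
)

panelKinds <- c("iclip-signal", "site-bars", "sequence", "coverage",
                "event-bars", "gene-models")
glyphKinds <- c("box", "line", "bar", "area", "letter", "heatcell")

setValidity("TrackPanel", function(object) {
  msg <- character(0)
  if (!object@kind %in% panelKinds)
    msg <- c(msg, sprintf("unknown panel kind '%s'", object@kind))
  g <- object@glyphs
  if (nrow(g)) {
    if (!all(g$kind %in% glyphKinds)) msg <- c(msg, "unknown glyph kind")
    if (!all(isHexColor(g$color))) msg <- c(msg, "glyph colors must be hex")
    if (any(g$xstart >= g$xend)) msg <- c(msg, "glyph x-ranges must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

emptyGlyphs <- function() {
  data.frame(kind = character(0), xstart = numeric(0), xend = numeric(0),
             height = numeric(0), heightClass = character(0),
             color = character(0), label = character(0), lane = character(0),
             stringsAsFactors = FALSE)
}

TrackPanel <- function(title, kind, glyphs = emptyGlyphs(),
                       legend = data.frame(name = character(0),
                                           color = character(0))) {
  new("TrackPanel", title = title, kind = kind, glyphs = glyphs,
      legend = legend)
}

#' FigureSpec: backend-agnostic description of one figure
#'
#' An ordered list of [TrackPanel-class]s plus the header (gene id and
#' strand tag) and the axis mapping from display to genomic coordinates.
#' The web layer, the SVG writer and the PNG writer all consume this and
#' nothing else.
#'
#' @slot header e.g. `"AT5G15960 (+)"`.
#' @slot geneId,strand focus gene and strand.
#' @slot windowStart,windowEnd display window (0-based half-open).
#' @slot panels ordered list of TrackPanel.
#' @export
setClass("FigureSpec",
  representation(header = "character", geneId = "character",
                 strand = "character", windowStart = "integer",
                 windowEnd = "integer", panels = "list")
)

setValidity("FigureSpec", function(object) {
  msg <- character(0)
  w0 <- object@windowStart; w1 <- object@windowEnd
  for (p in object@panels) {
    if (!methods::is(p, "TrackPanel")) { msg <- c(msg, "panels must be TrackPanel"); next }
    g <- p@glyphs
    if (nrow(g) && (any(g$xstart < w0) || any(g$xend > w1)))
      msg <- c(msg, sprintf("panel '%s' has glyphs outside the window", p@title))
  }
  if (length(msg)) msg else TRUE
})

## show methods -------------------------------------------------------------

setMethod("show", "GeneModel", function(object) {
  cds <- if (is.na(object@cdsStart)) "non-coding"
         else sprintf("CDS [%d,%d)", object@cdsStart, object@cdsEnd)
  cat(sprintf("GeneModel %s (gene %s) %s:%d-%d(%s), %d exon(s), %s\n",
              object@transcriptId, object@geneId, object@chrom,
              object@start, object@end, object@strand,
              length(object@exonStarts), cds))
})

setMethod("show", "CoverageTrack", function(object) {
  n <- sum(vapply(object@runs, nrow, 0L))
  cat(sprintf("CoverageTrack '%s': %d run(s) on %d chromosome(s), total signal %g\n",
              object@name, n, length(object@runs), totalSignal(object)))
})

setMethod("show", "DataBundle", function(object) {
  cat("DataBundle\n")
  cat(sprintf("  annotation sets: %d (%s models in set 1)\n",
              length(object@annotations),
              length(object@annotations[[1L]])))
  cat(sprintf("  iCLIP tracks: %d | site sets: %d | RNA-seq tracks: %d | event sets: %d\n",
              length(object@iclipTracks), length(object@siteSets),
              length(object@rnaseqTracks), length(object@eventSets)))
  cat(sprintf("  sequences: %s | descriptions: %s | extended: %s\n",
              if (is.null(object@sequences)) "none" else length(object@sequences),
              if (is.null(object@descriptions)) "none" else nrow(object@descriptions),
              if (is.null(object@extendedDescriptions)) "none"
              else nrow(object@extendedDescriptions)))
})

setMethod("show", "GenomeView", function(object) {
  cat(sprintf("GenomeView %s %s:%d-%d(%s) [%s], %d+%d models, %d iCLIP, %d RNA-seq\n",
              object@geneId, object@chrom, object@windowStart,
              object@windowEnd, object@strand,
              if (object@oriented) "display 5'->3'" else "genomic",
              length(object@sameStrand), length(object@oppositeStrand),
              length(object@iclipValues), length(object@rnaseqValues)))
})

setMethod("show", "FigureSpec", function(object) {
  cat(sprintf("FigureSpec '%s' window [%d,%d): %d panel(s) (%s)\n",
              object@header, object@windowStart, object@windowEnd,
              length(object@panels),
              paste(vapply(object@panels, function(p) p@kind, ""),
                    collapse = ", ")))
})

## accessors ----------------------------------------------------------------

#' Transcript id of a model
#' @param x a GeneModel.
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname transcriptId
#' @export
setMethod("transcriptId", "GeneModel", function(x) x@transcriptId)

#' Gene id of a model
#' @param x a GeneModel.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname geneId
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' Exon blocks of a model as a data.frame
#' @param x a GeneModel.
#' @return data.frame with columns start, end (0-based half-open).
#' @export
exonBlocks <- function(x) {
  data.frame(start = x@exonStarts, end = x@exonEnds)
}

#' CDS span of a model, or NULL for non-coding models
#' @param x a GeneModel.
#' @export
cdsSpan <- function(x) {
  if (is.na(x@cdsStart)) NULL else c(start = x@cdsStart, end = x@cdsEnd)
}

#' Total signal of a coverage track (sum of value x run length)
#' @param x a CoverageTrack.
#' @export
totalSignal <- function(x) {
  sum(vapply(x@runs, function(r) sum(r$value * (r$end - r$start)), 0))
}

#' Track name accessor
#' @param x a CoverageTrack.
#' @export
trackName <- function(x) x@name
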