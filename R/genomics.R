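## Gene-centric computations: the gene index, display windows, strand
## classification, coverage slicing, 5'->3' orientation and the crosslink
## pile-up. Overlap queries go through GenomicRanges.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

lookupError <- function(message) {
  stop(structure(class = c("clipViewLookupError", "error", "condition"),
                 list(message = message, call = NULL)))
}

#' Build a gene index over one annotation set
#'
#' @param models list of [GeneModel-class] (one annotation set).
#' @return a [GeneIndex-class] supporting [geneWindow()] and
#'   [modelsInWindow()].
#' @export
buildGeneIndex <- function(models) {
  if (!length(models)) lookupError("cannot index an empty annotation set")
  tx <- vapply(models, transcriptId, "")
  gene <- vapply(models, geneId, "")
  chrom <- vapply(models, function(m) m@chrom, "")
  start <- vapply(models, function(m) m@start, 0L)
  end <- vapply(models, function(m) m@end, 0L)
  strand <- vapply(models, function(m) m@strand, "")
  spans <- do.call(rbind, lapply(split(seq_along(models), gene), function(idx) {
    if (length(unique(chrom[idx])) > 1L)
      lookupError(sprintf("gene '%s' has transcripts on multiple chromosomes",
                          gene[idx[1L]]))
    s <- strand[idx]
    s <- if (any(s != "*")) s[s != "*"][1L] else "*"
    data.frame(gene = gene[idx[1L]], chrom = chrom[idx[1L]],
               start = min(start[idx]), end = max(end[idx]), strand = s,
               stringsAsFactors = FALSE)
  }))
  rownames(spans) <- spans$gene
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = ifelse(strand == "*", "*", strand))
  S4Vectors::mcols(gr)$tx <- tx
  S4Vectors::mcols(gr)$gene <- gene
  new("GeneIndex", models = models, geneSpans = spans, txRanges = gr)
}

setMethod("show", "GeneIndex", function(object) {
  cat(sprintf("GeneIndex: %d transcript(s), %d gene(s) on %d chromosome(s)\n",
              length(object@models), nrow(object@geneSpans),
              length(unique(object@geneSpans$chrom))))
})

#' Genes known to an index
#' @param index a [GeneIndex-class].
#' @export
indexGenes <- function(index) sort(rownames(index@geneSpans))

#' Span of one gene (union of its isoform intervals)
#' @param index a GeneIndex.
#' @param geneId gene identifier.
#' @return list with chrom, start, end, strand.
#' @export
geneSpan <- function(index, geneId) {
  if (!geneId %in% rownames(index@geneSpans))
    lookupError(sprintf("unknown gene id '%s'", geneId))
  as.list(index@geneSpans[geneId, ])
}

#' Display window for a gene
#'
#' The gene span extended by `padding` bases on both sides, floored at 0.
#'
#' @inheritParams geneSpan
#' @param padding non-negative bases added on each side (default 0: the
#'   window is the gene span itself).
#' @return list with chrom, start, end.
#' @export
geneWindow <- function(index, geneId, padding = 0L) {
  stopifnot(padding >= 0L)
  sp <- geneSpan(index, geneId)
  list(chrom = sp$chrom, start = max(0L, sp$start - as.integer(padding)),
       end = sp$end + as.integer(padding))
}

#' Models overlapping a window
#' @param index a GeneIndex.
#' @param chrom,start,end the query window (0-based half-open).
#' @return list of GeneModel overlapping the window.
#' @export
modelsInWindow <- function(index, chrom, start, end) {
  if (start >= end) return(list())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, index@txRanges, ignore.strand = TRUE)
  index@models[sort(S4Vectors::subjectHits(hits))]
}

#' Partition models by strand relative to a focus strand
#'
#' Same-strand models are drawn black, opposite-strand models grey.
#' Unstranded models count as same-strand.
#'
#' @param models list of GeneModel.
#' @param focusStrand `"+"` or `"-"`.
#' @return list with elements `same` and `opposite`.
#' @export
classifyModels <- function(models, focusStrand) {
  stopifnot(focusStrand %in% c("+", "-"))
  same <- vapply(models, function(m) m@strand == focusStrand || m@strand == "*",
                 TRUE)
  list(same = models[same], opposite = models[!same])
}

#' Dense per-base values of a track over a window
#'
#' @param track a [CoverageTrack-class].
#' @param chrom,start,end the window.
#' @return numeric vector of length `end - start`; positions without a
#'   run are 0.
#' @export
sliceCoverage <- function(track, chrom, start, end) {
  stopifnot(end > start)
  out <- numeric(end - start)
  r <- track@runs[[chrom]]
  if (is.null(r) || !nrow(r)) return(out)
  keep <- r$end > start & r$start < end
  r <- r[keep, , drop = FALSE]
  for (k in seq_len(nrow(r))) {
    a <- max(r$start[k], start) - start + 1L
    b <- min(r$end[k], end) - start
    out[a:b] <- r$value[k]
  }
  out
}

# clip a model to a window; NULL when no exon intersects the window
clipModelToWindow <- function(m, w0, w1) {
  keep <- m@exonEnds > w0 & m@exonStarts < w1
  if (!any(keep)) return(NULL)
  s <- pmax(m@exonStarts[keep], w0)
  e <- pmin(m@exonEnds[keep], w1)
  cds <- cdsSpan(m)
  if (!is.null(cds)) {
    cs <- max(cds[["start"]], s[1L]); ce <- min(cds[["end"]], e[length(e)])
    if (cs >= ce) cds <- NULL else cds <- c(cs, ce)
  }
  GeneModel(m@transcriptId, m@geneId, m@chrom, m@strand, s, e,
            if (is.null(cds)) NA_integer_ else cds[1L],
            if (is.null(cds)) NA_integer_ else cds[2L])
}

# clip BED6-style records to a window
clipIntervalsToWindow <- function(df, w0, w1) {
  keep <- df$end > w0 & df$start < w1
  df <- df[keep, , drop = FALSE]
  df$start <- pmax(df$start, w0)
  df$end <- pmin(df$end, w1)
  rownames(df) <- NULL
  df
}

# assemble the window sequence from per-transcript records (N-padded)
windowSequence <- function(sequences, models, geneId, w0, w1) {
  if (is.null(sequences)) return(NA_character_)
  chars <- rep("N", w1 - w0)
  found <- FALSE
  for (m in models) {
    if (m@geneId != geneId) next
    if (!m@transcriptId %in% names(sequences)) next
    s <- sequences[[m@transcriptId]]
    if (nchar(s) != m@end - m@start) next
    a <- max(m@start, w0); b <- min(m@end, w1)
    if (a >= b) next
    found <- TRUE
    piece <- substring(s, a - m@start + 1L, b - m@start)
    idx <- (a - w0 + 1L):(b - w0)
    fill <- chars[idx] == "N"
    chars[idx[fill]] <- strsplit(piece, "", fixed = TRUE)[[1L]][fill]
  }
  if (!found) return(NA_character_)
  paste(chars, collapse = "")
}

#' Build the display view for one gene
#'
#' Collects everything within the gene's window: overlapping models
#' (clipped to the window and partitioned by strand), dense arrays for
#' every iCLIP and RNA-seq track, site/event sets clipped to the window,
#' and the window sequence assembled from per-transcript records
#' (N-padded where no record covers a position). The view is returned in
#' genomic coordinates; apply [orientView()] before rendering.
#'
#' @param index a [GeneIndex-class].
#' @param bundle a [DataBundle-class].
#' @param geneId focus gene.
#' @param padding window padding in bases (default 0).
#' @return a [GenomeView-class].
#' @export
buildGenomeView <- function(index, bundle, geneId, padding = 0L) {
  win <- geneWindow(index, geneId, padding)
  sp <- geneSpan(index, geneId)
  focusStrand <- if (sp$strand == "*") "+" else sp$strand
  models <- modelsInWindow(index, win$chrom, win$start, win$end)
  clipped <- Filter(Negate(is.null),
                    lapply(models, clipModelToWindow, win$start, win$end))
  parts <- classifyModels(clipped, focusStrand)
  sliceAll <- function(tracks)
    stats::setNames(lapply(tracks, sliceCoverage, win$chrom, win$start,
                           win$end),
                    vapply(tracks, trackName, ""))
  clipSets <- function(sets)
    lapply(sets, function(df) {
      df <- df[df$chrom == win$chrom, , drop = FALSE]
      clipIntervalsToWindow(df, win$start, win$end)
    })
  new("GenomeView",
      geneId = geneId, chrom = win$chrom,
      windowStart = as.integer(win$start), windowEnd = as.integer(win$end),
      strand = focusStrand,
      sameStrand = parts$same, oppositeStrand = parts$opposite,
      iclipValues = sliceAll(bundle@iclipTracks),
      rnaseqValues = sliceAll(bundle@rnaseqTracks),
      siteSets = clipSets(bundle@siteSets),
      eventSets = clipSets(bundle@eventSets),
      sequence = windowSequence(bundle@sequences, models, geneId,
                                win$start, win$end),
      oriented = FALSE)
}

# mirror an interval [s,e) inside window [w0,w1)
mirrorCoords <- function(s, e, w0, w1) {
  list(start = w0 + (w1 - e), end = w0 + (w1 - s))
}

mirrorModel <- function(m, w0, w1) {
  mc <- mirrorCoords(m@exonStarts, m@exonEnds, w0, w1)
  ord <- order(mc$start)
  cds <- cdsSpan(m)
  if (!is.null(cds)) {
    cc <- mirrorCoords(cds[["start"]], cds[["end"]], w0, w1)
    cds <- c(cc$start, cc$end)
  }
  GeneModel(m@transcriptId, m@geneId, m@chrom, m@strand,
            mc$start[ord], mc$end[ord],
            if (is.null(cds)) NA_integer_ else cds[1L],
            if (is.null(cds)) NA_integer_ else cds[2L])
}

mirrorIntervalDf <- function(df, w0, w1) {
  if (!nrow(df)) return(df)
  mc <- mirrorCoords(df$start, df$end, w0, w1)
  df$start <- mc$start; df$end <- mc$end
  df[order(df$start), , drop = FALSE]
}

reverseComplement <- function(x) {
  rc <- chartr("ACGTUNacgtun", "TGCAANtgcaan", x)
  vapply(rc, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

#' Orient a view 5'->3' of its focus gene
#'
#' Plus-strand views are returned unchanged. For minus-strand views every
#' dense array is reversed, every interval `[s,e)` inside the window
#' `[w0,w1)` is mapped to `[w0+(w1-e), w0+(w1-s))`, and the window
#' sequence is reverse-complemented. Applying the function twice to a
#' minus-strand view restores the original (the mirror is an involution).
#'
#' @param view a [GenomeView-class].
#' @return the oriented [GenomeView-class].
#' @export
orientView <- function(view) {
  if (view@strand == "+") return(view)
  w0 <- view@windowStart; w1 <- view@windowEnd
  view@sameStrand <- lapply(view@sameStrand, mirrorModel, w0, w1)
  view@oppositeStrand <- lapply(view@oppositeStrand, mirrorModel, w0, w1)
  view@iclipValues <- lapply(view@iclipValues, rev)
  view@rnaseqValues <- lapply(view@rnaseqValues, rev)
  view@siteSets <- lapply(view@siteSets, mirrorIntervalDf, w0, w1)
  view@eventSets <- lapply(view@eventSets, mirrorIntervalDf, w0, w1)
  if (!is.na(view@sequence))
    view@sequence <- reverseComplement(view@sequence)
  view@oriented <- !view@oriented
  view
}

#' Pile up crosslink sites from stranded reads
#'
#' iCLIP reads truncate at the crosslinked nucleotide, so each uniquely
#' mapped read is reduced to the position one nucleotide upstream of its
#' 5' end: a `+` strand read `[s,e)` contributes one count at `s-1`, a
#' `-` strand read at `e`. Reads whose crosslink position would be
#' negative are dropped; their number is available as the
#' `droppedReads` attribute.
#'
#' @param reads data.frame with columns `chrom,start,end,strand`
#'   (0-based half-open; strand must be `+` or `-`).
#' @param name label for the resulting track.
#' @param rule `"stranded"` applies the strand-aware rule above;
#'   `"ignore-strand"` uses `s-1` for every read (for comparison).
#' @return a [CoverageTrack-class] of per-position counts.
#' @export
crosslinkPileup <- function(reads, name = "crosslinks",
                            rule = c("stranded", "ignore-strand")) {
  rule <- match.arg(rule)
  if (nrow(reads) && !all(reads$strand %in% c("+", "-")))
    stop("crosslinkPileup requires stranded reads ('+' or '-')")
  pos <- if (rule == "stranded")
    ifelse(reads$strand == "+", reads$start - 1L, reads$end)
  else reads$start - 1L
  keep <- pos >= 0L
  dropped <- sum(!keep)
  if (dropped > 0L)
    warning(sprintf("%d read(s) dropped: crosslink position would be negative",
                    dropped))
  chrom <- reads$chrom[keep]; pos <- pos[keep]
  if (length(pos)) {
    key <- paste(chrom, pos, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    track <- CoverageTrack(name,
                           chrom = vapply(parts, `[[`, "", 1L),
                           start = as.integer(vapply(parts, `[[`, "", 2L)),
                           end = as.integer(vapply(parts, `[[`, "", 2L)) + 1L,
                           value = as.numeric(tab))
  } else {
    track <- CoverageTrack(name)
  }
  attr(track@runs, "droppedReads") <- dropped
  track
}
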