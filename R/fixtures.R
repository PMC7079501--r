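## Seeded synthetic-data generator: emits one complete, mutually
## consistent miniature input bundle (annotation as BED12+map and as
## equivalent GTF, per-transcript FASTA, iCLIP BEDGRAPH tracks with
## counts concentrated near exon boundaries of target genes, significant
## sites at the highest-count positions, RNA-seq coverage with one gene
## showing elevated intronic coverage, splice-event BED6 with float
## scores, description TSVs) plus a defect catalogue with one broken
## file per validator error code. Same seed, same spec: byte-identical
## files. No biological realism is claimed for the sequences: they are
## uniform-random nucleotides.

#' Fixture generation parameters
#'
#' @param seed RNG seed; all stochastic choices flow from it.
#' @param nGenes number of genes (before the optional antisense gene).
#' @param chromLengths named integer vector of chromosome lengths.
#' @param minusFraction expected fraction of minus-strand genes.
#' @param antisensePair also emit a gene overlapping gene 1 on the
#'   opposite strand.
#' @param nIclip number of iCLIP datasets.
#' @param nRnaseq number of RNA-seq samples.
#' @param eventClasses splice-event classes to emit.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, nGenes = 6L,
                        chromLengths = c(chr1 = 40000L, chr2 = 30000L),
                        minusFraction = 1 / 3, antisensePair = TRUE,
                        nIclip = 2L, nRnaseq = 2L,
                        eventClasses = c("A3", "A5", "RI")) {
  structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                 chromLengths = chromLengths,
                 minusFraction = minusFraction,
                 antisensePair = isTRUE(antisensePair),
                 nIclip = as.integer(nIclip), nRnaseq = as.integer(nRnaseq),
                 eventClasses = eventClasses),
            class = "FixtureSpec")
}

withFixtureSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

# sum possibly overlapping (chrom,start,end,value) contributions into
# disjoint runs (overlaps arise where genes overlap, e.g. antisense pairs)
flattenRuns <- function(chrom, start, end, value) {
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bp <- sort(unique(c(start[idx], end[idx])))
    if (length(bp) < 2L) next
    s <- bp[-length(bp)]; e <- bp[-1L]
    v <- vapply(seq_along(s), function(k)
      sum(value[idx][start[idx] <= s[k] & end[idx] >= e[k]]), 0)
    keep <- v != 0
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = s[keep], end = e[keep],
                              value = v[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

descWords <- c("glycine-rich RNA-binding protein",
               "serine/threonine protein kinase",
               "cold-inducible protein KIN1-like",
               "splicing factor subunit",
               "zinc finger transcription factor",
               "chloroplast membrane transporter",
               "heat shock chaperone",
               "polypyrimidine tract binding protein")

# invent the gene models for one fixture spec
fixtureModels <- function(spec) {
  models <- list()
  genes <- list()
  chroms <- names(spec$chromLengths)
  cursors <- stats::setNames(rep(600L, length(chroms)), chroms)
  minus <- stats::runif(spec$nGenes) < spec$minusFraction
  for (g in seq_len(spec$nGenes)) {
    chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
    geneId <- sprintf("G%03d", g)
    strand <- if (minus[g]) "-" else "+"
    nEx <- sample(2:4, 1L)
    exLen <- sample(80:300, nEx, replace = TRUE)
    inLen <- if (nEx > 1L) sample(60:200, nEx - 1L, replace = TRUE)
             else integer(0)
    start <- cursors[[chrom]] + sample(200:800, 1L)
    s <- integer(nEx); e <- integer(nEx)
    pos <- start
    for (k in seq_len(nEx)) {
      s[k] <- pos; e[k] <- pos + exLen[k]
      pos <- e[k] + if (k < nEx) inLen[k] else 0L
    }
    cursors[[chrom]] <- e[nEx]
    coding <- stats::runif(1) < 0.75
    cds <- c(NA_integer_, NA_integer_)
    if (coding) {
      cs <- s[1L] + as.integer(floor(exLen[1L] * 0.4))
      ce <- e[nEx] - as.integer(floor(exLen[nEx] * 0.4))
      if (cs < ce) cds <- c(cs, ce)
    }
    txs <- list(GeneModel(sprintf("%s.1", geneId), geneId, chrom, strand,
                          s, e, cds[1L], cds[2L]))
    if (nEx >= 3L && stats::runif(1) < 0.5) {
      inner <- seq(2L, nEx - 1L)
      drop <- inner[sample.int(length(inner), 1L)]
      txs <- c(txs, list(GeneModel(sprintf("%s.2", geneId), geneId, chrom,
                                   strand, s[-drop], e[-drop],
                                   cds[1L], cds[2L])))
    }
    models <- c(models, txs)
    genes[[geneId]] <- list(chrom = chrom, start = s[1L], end = e[nEx],
                            strand = strand, exonStarts = s, exonEnds = e)
  }
  if (spec$antisensePair) {
    g1 <- genes[[1L]]
    geneId <- "GAS1"
    strand <- if (g1$strand == "+") "-" else "+"
    span <- g1$end - g1$start
    s0 <- g1$start + as.integer(floor(span * 0.3))
    ex1 <- c(s0, s0 + 220L + sample(40:160, 1L))
    gap <- sample(60:150, 1L)
    ex2 <- c(ex1[2L] + gap, ex1[2L] + gap + sample(100:240, 1L))
    m <- GeneModel(sprintf("%s.1", geneId), geneId, g1$chrom, strand,
                   c(ex1[1L], ex2[1L]), c(ex1[2L], ex2[2L]))
    models <- c(models, list(m))
    genes[[geneId]] <- list(chrom = g1$chrom, start = m@start, end = m@end,
                            strand = strand, exonStarts = m@exonStarts,
                            exonEnds = m@exonEnds)
  }
  names(models) <- vapply(models, transcriptId, "")
  list(models = models, genes = genes)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every file the dashboard can consume into `outDir` (see the
#' module comment for the inventory) plus a `defects/` catalogue with
#' one deliberately broken file per validator error code, and a
#' `manifest.tsv` listing everything. Output is byte-identical for the
#' same spec.
#'
#' @param spec a [fixtureSpec()].
#' @param outDir output directory (created if missing).
#' @return (invisibly) a list with the manifest data.frame, the emitted
#'   models, the per-dataset ground-truth iCLIP totals, and the target
#'   gene ids.
#' @export
generateFixtureBundle <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "defects"), showWarnings = FALSE)
  withFixtureSeed(spec$seed, {
    mg <- fixtureModels(spec)
    models <- mg$models
    genes <- mg$genes
    geneIds <- names(genes)
    chroms <- names(spec$chromLengths)

    manifest <- list()
    noteFile <- function(kind, rel) manifest[[length(manifest) + 1L]] <<-
      data.frame(kind = kind, path = rel, stringsAsFactors = FALSE)
    outPath <- function(rel) file.path(outDir, rel)

    ## annotation in both renderings + map
    writeBed12(models, outPath("annotation.bed12"))
    noteFile("annotation-bed12", "annotation.bed12")
    writeGeneTranscriptMap(models, outPath("tx2gene.tsv"))
    noteFile("tx2gene", "tx2gene.tsv")
    writeGtf(models, outPath("annotation.gtf"))
    noteFile("annotation-gtf", "annotation.gtf")

    ## chromosome sequences, then per-transcript genomic slices
    chromSeq <- lapply(spec$chromLengths, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
    txSeqs <- vapply(models, function(m)
      substring(chromSeq[[m@chrom]], m@start + 1L, m@end), "")
    writeFasta(txSeqs, outPath("transcripts.fa"))
    noteFile("fasta", "transcripts.fa")

    ## iCLIP tracks: counts concentrated near exon boundaries of targets
    targets <- geneIds[seq(1L, length(geneIds), by = 2L)]
    targets <- setdiff(targets, "GAS1")
    iclipTotals <- numeric(spec$nIclip)
    siteFiles <- character(0)
    for (d in seq_len(spec$nIclip)) {
      pos <- integer(0); chrom <- character(0); cnt <- integer(0)
      for (gid in targets) {
        gn <- genes[[gid]]
        bounds <- unique(c(gn$exonStarts, gn$exonEnds))
        for (b in bounds) {
          k <- sample(1:3, 1L)
          p <- b + sample(-4:4, k, replace = TRUE)
          p <- p[p >= gn$start & p < gn$end]
          pos <- c(pos, p)
          chrom <- c(chrom, rep(gn$chrom, length(p)))
          cnt <- c(cnt, 1L + stats::rpois(length(p), 4))
        }
      }
      df <- data.frame(chrom = chrom, pos = pos, cnt = cnt)
      agg <- stats::aggregate(cnt ~ chrom + pos, df, sum)
      track <- CoverageTrack(sprintf("iclip_rep%d", d), agg$chrom, agg$pos,
                             agg$pos + 1L, agg$cnt)
      iclipTotals[d] <- totalSignal(track)
      rel <- sprintf("iclip_rep%d.bedgraph", d)
      writeBedgraph(track, outPath(rel))
      noteFile("iclip", rel)
      ## significant sites = highest-count positions
      top <- agg[order(-agg$cnt, agg$chrom, agg$pos), ][
        seq_len(min(6L, nrow(agg))), ]
      strandOf <- vapply(top$chrom, function(ch) "+", "")
      for (r in seq_len(nrow(top))) {
        hit <- Filter(function(g) g$chrom == top$chrom[r] &&
                        g$start <= top$pos[r] && top$pos[r] < g$end, genes)
        strandOf[r] <- if (length(hit)) hit[[1L]]$strand else "+"
      }
      sites <- data.frame(chrom = top$chrom, start = top$pos,
                          end = top$pos + 1L, name = "xlsite",
                          score = round(top$cnt / max(top$cnt), 3),
                          strand = strandOf, stringsAsFactors = FALSE)
      sites <- sites[order(sites$chrom, sites$start), ]
      rel <- sprintf("iclip_rep%d_sites.bed", d)
      writeBed6(sites, outPath(rel))
      siteFiles <- c(siteFiles, rel)
      noteFile("sites", rel)
    }

    ## RNA-seq coverage: exonic steps; first multi-intron gene keeps
    ## elevated intronic coverage (a retained-intron signature)
    riGene <- geneIds[vapply(geneIds, function(g)
      length(genes[[g]]$exonStarts) >= 3L, TRUE)][1L]
    if (is.na(riGene)) riGene <- geneIds[1L]
    for (sm in seq_len(spec$nRnaseq)) {
      chrom <- character(0); s <- integer(0); e <- integer(0)
      v <- numeric(0)
      for (gid in geneIds) {
        gn <- genes[[gid]]
        base <- sample(20:100, 1L)
        for (k in seq_along(gn$exonStarts)) {
          chrom <- c(chrom, gn$chrom)
          s <- c(s, gn$exonStarts[k]); e <- c(e, gn$exonEnds[k])
          v <- c(v, base + sample(-5:5, 1L))
        }
        if (gid == riGene && length(gn$exonStarts) > 1L) {
          nIn <- length(gn$exonStarts) - 1L
          chrom <- c(chrom, rep(gn$chrom, nIn))
          s <- c(s, gn$exonEnds[-length(gn$exonEnds)])
          e <- c(e, gn$exonStarts[-1L])
          v <- c(v, rep(round(base * 0.6), nIn))
        }
      }
      flat <- flattenRuns(chrom, s, e, v)
      track <- CoverageTrack(sprintf("rnaseq_sample%d", sm), flat$chrom,
                             flat$start, flat$end, flat$value)
      rel <- sprintf("rnaseq_sample%d.bedgraph", sm)
      writeBedgraph(track, outPath(rel))
      noteFile("rnaseq", rel)

      ## splice events with floating-point scores
      ev <- list()
      for (gid in geneIds) {
        gn <- genes[[gid]]
        if (length(gn$exonStarts) < 2L) next
        k <- sample(seq_len(length(gn$exonStarts) - 1L), 1L)
        intron <- c(gn$exonEnds[k], gn$exonStarts[k + 1L])
        cls <- sample(spec$eventClasses, 1L)
        iv <- switch(cls,
          A3 = c(max(gn$start, intron[2L] - 25L), intron[2L] + 15L),
          A5 = c(intron[1L] - 15L, min(gn$end, intron[1L] + 25L)),
          RI = intron,
          c(intron[1L], intron[2L]))
        ev[[length(ev) + 1L]] <- data.frame(
          chrom = gn$chrom, start = iv[1L], end = iv[2L], name = cls,
          score = round(stats::runif(1, 0.1, 0.95), 3), strand = gn$strand,
          stringsAsFactors = FALSE)
      }
      events <- do.call(rbind, ev)
      events <- events[order(events$chrom, events$start), ]
      rel <- sprintf("rnaseq_sample%d_events.bed", sm)
      writeBed6(events, outPath(rel))
      noteFile("events", rel)
    }

    ## descriptions
    descs <- data.frame(
      gene_id = geneIds,
      description = descWords[(seq_along(geneIds) - 1L) %%
                                length(descWords) + 1L],
      stringsAsFactors = FALSE)
    writeTsv(descs, outPath("descriptions.tsv"))
    noteFile("descriptions", "descriptions.tsv")
    adv <- data.frame(
      gene_id = geneIds,
      description = paste(descs$description, "(full annotation)"),
      synonyms = paste0("SYN-", geneIds),
      go_terms = sprintf("GO:%07d", 5000L + seq_along(geneIds)),
      interactors = c(geneIds[-1L], geneIds[1L]),
      stringsAsFactors = FALSE)
    writeTsv(adv, outPath("extended_descriptions.tsv"))
    noteFile("extended-descriptions", "extended_descriptions.tsv")

    ## compressed copy of one input (exercises the decompression layer)
    bedLines <- readLines(outPath("annotation.bed12"))
    gzCon <- gzfile(outPath("annotation.bed12.gz"), "wb")
    writeLines(bedLines, gzCon)
    close(gzCon)
    noteFile("annotation-bed12-gz", "annotation.bed12.gz")
    writeZipSingle(bedLines, "annotation.bed12",
                   outPath("annotation.bed12.zip"))
    noteFile("annotation-bed12-zip", "annotation.bed12.zip")

    ## defect catalogue: one file per validator error code
    defects <- list()
    noteDefect <- function(rel, code) defects[[length(defects) + 1L]] <<-
      data.frame(file = rel, code = code, stringsAsFactors = FALSE)
    dup <- bedLines[!startsWith(bedLines, "#")][1L]
    writeLines(c(dup, dup), outPath("defects/duplicate-transcript.bed12"))
    noteDefect("defects/duplicate-transcript.bed12", "duplicate-transcript")
    writeLines("# deliberately empty annotation",
               outPath("defects/empty-annotation.bed12"))
    noteDefect("defects/empty-annotation.bed12", "empty-annotation")
    writeLines("chrX\t100\t101\t5",
               outPath("defects/chrom-unknown.bedgraph"))
    noteDefect("defects/chrom-unknown.bedgraph", "chrom-unknown")
    writeFasta(c(txSeqs, ORPHAN.9 = "ACGTACGT"),
               outPath("defects/sequence-orphan.fa"))
    noteDefect("defects/sequence-orphan.fa", "sequence-orphan")
    writeFasta(txSeqs[-1L], outPath("defects/sequence-missing.fa"))
    noteDefect("defects/sequence-missing.fa", "sequence-missing")
    writeTsv(rbind(descs, data.frame(gene_id = "G999",
                                     description = "phantom gene",
                                     stringsAsFactors = FALSE)),
             outPath("defects/description-unknown-gene.tsv"))
    noteDefect("defects/description-unknown-gene.tsv",
               "description-unknown-gene")
    writeBed6(data.frame(chrom = chroms[1L], start = 10L, end = 40L,
                         name = "stray", score = 1, strand = "+",
                         stringsAsFactors = FALSE),
              outPath("defects/site-outside-genes.bed"))
    noteDefect("defects/site-outside-genes.bed", "site-outside-genes")
    defectDf <- do.call(rbind, defects)
    writeTsv(defectDf, outPath("defects/catalogue.tsv"))

    manifestDf <- do.call(rbind, manifest)
    writeTsv(manifestDf, outPath("manifest.tsv"))
    invisible(list(manifest = manifestDf, defects = defectDf,
                   models = models, iclipTotals = iclipTotals,
                   targets = targets, riGene = riGene, genes = genes,
                   dir = outDir))
  })
}

#' LaunchConfig pointing at a generated fixture bundle
#'
#' @param dir directory written by [generateFixtureBundle()].
#' @param ... overrides for config fields (port, pwd, strict, ...).
#' @return a `LaunchConfig` list as from [parseLaunchArgs()].
#' @export
fixtureLaunchConfig <- function(dir, ...) {
  manifest <- readTsvTable(file.path(dir, "manifest.tsv"), keyColumn = "path")
  pick <- function(kind) file.path(dir, manifest$path[manifest$kind == kind])
  cfg <- list(gtf = character(0), bed12 = pick("annotation-bed12"),
              map = pick("tx2gene"), desc = pick("descriptions"),
              adv_descr = pick("extended-descriptions"),
              iclip = pick("iclip"), sites = pick("sites"),
              fasta = pick("fasta"), rnaseq = pick("rnaseq"),
              events = pick("events"), port = 8060L, host = "127.0.0.1",
              pwd = NULL, cache_dir = file.path(dir, ".clipview-cache"),
              strict = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "LaunchConfig")
}
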