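# Reader/writer contracts: coordinate conventions, compression handling,
# malformed-input diagnostics, and cross-format agreement.

writeTemp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("openTextSource decompresses by suffix and streams identically", {
  lines <- c("chr1\t10\t20\tA3\t0.35\t+", "chr1\t30\t40\tA5\t0.5\t-",
             "chr2\t0\t7")
  plain <- writeTemp(lines, ".bed")

  gz <- tempfile(fileext = ".bed.gz")
  con <- gzfile(gz, "wb"); writeLines(lines, con); close(con)
  bz <- tempfile(fileext = ".bed.bz2")
  con <- bzfile(bz, "wb"); writeLines(lines, con); close(con)
  zp <- tempfile(fileext = ".bed.zip")
  writeZipSingle(lines, "member.bed", zp)

  for (f in c(plain, gz, bz, zp)) {
    con <- openTextSource(f)
    got <- readLines(con)
    close(con)
    expect_identical(got, lines, info = f)
  }
})

test_that("zip archives with other than one member are rejected", {
  none <- tempfile(fileext = ".zip")
  writeZipSingle(character(0), "x", none, nMembers = 0L)
  expect_error(openTextSource(none), class = "clipViewValidationError")
  two <- tempfile(fileext = ".zip")
  writeZipSingle("a\tb", "x.tsv", two, nMembers = 2L)
  expect_error(openTextSource(two), "exactly one member")
  expect_error(openTextSource(tempfile()), "no such file")
})

test_that("readBed6 maps columns, defaults missing fields, skips headers", {
  f <- writeTemp(c("track name=demo", "browser position chr1",
                   "# a comment", "chr1\t10\t20\tA3\t0.35\t+",
                   "chr2\t0\t7"))
  df <- readBed6(f)
  expect_equal(nrow(df), 2L)
  expect_equal(df$chrom, c("chr1", "chr2"))
  expect_equal(df$start, c(10L, 0L))
  expect_equal(df$end, c(20L, 7L))
  expect_equal(df$name, c("A3", "."))
  expect_equal(df$score, c(0.35, NA_real_))
  expect_equal(df$strand, c("+", "*"))
})

test_that("readBed6 rejects malformed records with line numbers", {
  expect_error(readBed6(writeTemp("chr1\t5\t5\tX\t0\t+")),
               ":1: .*empty or inverted")
  expect_error(readBed6(writeTemp(c("chr1\t1\t2", "chr1\tx\t9"))),
               ":2: .*non-integer")
  expect_error(readBed6(writeTemp("chr1\t1\t2\tn\t0\tz")), "invalid strand")
  expect_error(readBed6(writeTemp("chr1\t1")), "at least 3")
})

test_that("readBed12 reconstructs exons and CDS from block arithmetic", {
  map <- c(tx1 = "g1")
  f <- writeTemp("chr1\t100\t500\ttx1\t0\t+\t150\t450\t0\t2\t100,100\t0,300")
  m <- readBed12(f, map)[[1L]]
  expect_equal(m@exonStarts, c(100L, 400L))
  expect_equal(m@exonEnds, c(200L, 500L))
  expect_equal(unname(cdsSpan(m)), c(150L, 450L))
  expect_equal(geneId(m), "g1")

  # zero-width thick region means non-coding
  f2 <- writeTemp("chr1\t100\t500\ttx1\t0\t+\t100\t100\t0\t2\t100,100\t0,300")
  expect_null(cdsSpan(readBed12(f2, map)[[1L]]))
})

test_that("readBed12 rejects inconsistent block structure", {
  map <- c(tx1 = "g1")
  bad <- list(
    arity = "chr1\t100\t500\ttx1\t0\t+\t150\t450\t0\t2\t100\t0,300",
    firstStart = "chr1\t100\t500\ttx1\t0\t+\t150\t450\t0\t2\t100,100\t10,300",
    lastEnd = "chr1\t100\t500\ttx1\t0\t+\t150\t450\t0\t2\t100,50\t0,300",
    overlap = "chr1\t100\t500\ttx1\t0\t+\t150\t450\t0\t2\t350,100\t0,300")
  msgs <- c("blockCount 2 does not match", "first blockStart",
            "last block must end", "ascending and non-overlapping")
  for (k in seq_along(bad))
    expect_error(readBed12(writeTemp(bad[[k]]), map), msgs[k])
  expect_error(
    readBed12(writeTemp("chr1\t0\t10\tzz\t0\t+\t0\t0\t0\t1\t10\t0"), map),
    "absent from gene-transcript map")
})

test_that("readGtf converts 1-based inclusive coordinates and groups exons", {
  f <- writeTemp(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\tsrc\texon\t401\t500\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\tsrc\tCDS\t151\t450\t.\t+\t0\tgene_id "g1"; transcript_id "tx1";'))
  m <- readGtf(f)[[1L]]
  expect_equal(m@start, 100L)
  expect_equal(m@end, 500L)
  expect_equal(m@exonStarts, c(100L, 400L))
  expect_equal(m@exonEnds, c(200L, 500L))
  expect_equal(unname(cdsSpan(m)), c(150L, 450L))

  # unquoted attribute values are accepted
  f2 <- writeTemp("chr1\tsrc\texon\t11\t20\t.\t-\t.\tgene_id g2; transcript_id tx2")
  m2 <- readGtf(f2)[[1L]]
  expect_equal(m2@exonStarts, 10L)
  expect_equal(geneId(m2), "g2")
})

test_that("readGtf rejects inconsistent transcripts", {
  mixed <- writeTemp(c(
    'chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";',
    'chr2\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";'))
  expect_error(readGtf(mixed), "mixed chromosomes or strands")
  noTx <- writeTemp('chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g";')
  expect_error(readGtf(noTx), "lacks transcript_id")
})

test_that("readBedgraph builds canonical sparse tracks", {
  f <- writeTemp(c("chr1\t9\t12\t1", "chr1\t5\t6\t3"))
  tr <- readBedgraph(f, "demo")
  expect_equal(sliceCoverage(tr, "chr1", 0L, 13L),
               c(0, 0, 0, 0, 0, 3, 0, 0, 0, 1, 1, 1, 0))
  # unsorted input equals sorted input
  tr2 <- readBedgraph(writeTemp(c("chr1\t5\t6\t3", "chr1\t9\t12\t1")), "demo")
  expect_identical(tr@runs[["chr1"]], tr2@runs[["chr1"]])
  # zero runs vanish, adjacent equal values merge
  tr3 <- readBedgraph(writeTemp(c("chr1\t0\t5\t2", "chr1\t5\t9\t2",
                                  "chr1\t20\t30\t0")), "m")
  expect_equal(nrow(tr3@runs[["chr1"]]), 1L)
  expect_equal(tr3@runs[["chr1"]]$end, 9L)
  expect_equal(totalSignal(tr3), 18)
})

test_that("readBedgraph rejects overlaps and negative values", {
  expect_error(readBedgraph(writeTemp(c("chr1\t5\t8\t2", "chr1\t7\t9\t1"))),
               "overlapping runs")
  expect_error(readBedgraph(writeTemp("chr1\t5\t8\t-2")), "negative value")
  expect_error(readBedgraph(writeTemp("chr1\t5\t8")), "needs 4")
})

test_that("FASTA records concatenate lines and require unique ids", {
  f <- writeTemp(c(">tx1 some description", "ACGT", "acgU", ">tx2", "NNN"))
  seqs <- readFastaSequences(f)
  expect_identical(unname(seqs["tx1"]), "ACGTacgU")
  expect_identical(unname(seqs["tx2"]), "NNN")
  expect_error(readFastaSequences(writeTemp(c(">tx1", "AC", ">tx1", "GG"))),
               "duplicate FASTA id")
  expect_error(readFastaSequences(writeTemp(c(">tx1", "ACXT"))),
               "outside A,C,G,T,U,N")
})

test_that("TSV tables key rows and reject duplicate keys", {
  map <- readGeneTranscriptMap(writeTemp(c("transcript\tgene", "tx1\tg1")))
  expect_identical(unname(map["tx1"]), "g1")
  expect_error(
    readTsvTable(writeTemp(c("gene\tdesc", "g1\ta", "g1\tb"))),
    "duplicate key")
  tab <- readTsvTable(writeTemp(c("gene\tdesc\textra", "g1\thello\tx")))
  expect_identical(attr(tab, "keyColumn"), "gene")
  expect_identical(tab$desc, "hello")
})

test_that("BED12 write/read is the identity and matches the GTF rendering", {
  set.seed(42)
  for (rep in 1:20) {
    models <- randomModelSet(sample(1:5, 1L))
    bed <- tempfile(fileext = ".bed12")
    writeBed12(models, bed)
    mapFile <- tempfile(fileext = ".tsv")
    writeGeneTranscriptMap(models, mapFile)
    back <- readBed12(bed, readGeneTranscriptMap(mapFile))
    expect_true(modelsEqual(models, back))

    gtf <- tempfile(fileext = ".gtf")
    writeGtf(models, gtf)
    fromGtf <- readGtf(gtf)
    expect_true(modelsEqual(models, fromGtf[names(models)]))
  }
})

test_that("readers agree with rtracklayer on the fixture annotation", {
  skip_if_not_installed("rtracklayer")
  d <- fixtureDir()
  bed <- file.path(d, "annotation.bed12")
  ours <- readBed12(bed, readGeneTranscriptMap(file.path(d, "tx2gene.tsv")))
  ref <- rtracklayer::import(bed, format = "BED")
  expect_equal(length(ours), length(ref))
  refStarts <- GenomicRanges::start(ref) - 1L
  refEnds <- GenomicRanges::end(ref)
  ord <- match(names(ours), ref$name)
  expect_equal(vapply(ours, function(m) m@start, 0L), refStarts[ord],
               ignore_attr = TRUE)
  expect_equal(vapply(ours, function(m) m@end, 0L), refEnds[ord],
               ignore_attr = TRUE)
  nBlocks <- vapply(ref$blocks, length, 0L)[ord]
  expect_equal(vapply(ours, function(m) length(m@exonStarts), 0L), nBlocks,
               ignore_attr = TRUE)

  bg <- file.path(d, "iclip_rep1.bedgraph")
  oursTrack <- readBedgraph(bg, "r1")
  refBg <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(totalSignal(oursTrack),
               sum(refBg$score * GenomicRanges::width(refBg)))
})
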