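# Gene-centric computations: index queries against brute force, window
# arithmetic, strand partition, coverage slicing against a positionwise
# oracle, orientation as an involution, and the crosslink pile-up rule.

test_that("gene spans are the union of isoform intervals", {
  models <- list(
    GeneModel("t1", "g1", "chr1", "+", c(100L, 400L), c(200L, 500L)),
    GeneModel("t2", "g1", "chr1", "+", c(150L, 600L), c(250L, 700L)),
    GeneModel("t3", "g2", "chr1", "-", c(900L), c(1000L)))
  idx <- buildGeneIndex(models)
  sp <- geneSpan(idx, "g1")
  expect_equal(sp$start, 100L)
  expect_equal(sp$end, 700L)
  expect_equal(sp$strand, "+")
  expect_error(geneSpan(idx, "nope"), "unknown gene",
               class = "clipViewLookupError")
})

test_that("window queries agree with a brute-force scan", {
  set.seed(11)
  models <- randomModelSet(12L)
  idx <- buildGeneIndex(models)
  for (rep in 1:25) {
    w0 <- sample(0:6000, 1L); w1 <- w0 + sample(10:2000, 1L)
    got <- modelsInWindow(idx, "chr1", w0, w1)
    want <- Filter(function(m) m@start < w1 && m@end > w0, models)
    expect_setequal(unname(vapply(got, transcriptId, "")),
                    unname(vapply(want, transcriptId, "")))
  }
  expect_identical(modelsInWindow(idx, "chr1", 10L, 10L), list())
})

test_that("gene windows extend by padding and floor at zero", {
  models <- list(GeneModel("t1", "g1", "chr1", "+", c(100L, 400L),
                           c(200L, 500L)),
                 GeneModel("t2", "g2", "chr1", "+", 10L, 90L))
  idx <- buildGeneIndex(models)
  expect_equal(geneWindow(idx, "g1", 50L)[c("start", "end")],
               list(start = 50L, end = 550L))
  expect_equal(geneWindow(idx, "g2", 50L)[c("start", "end")],
               list(start = 0L, end = 140L))
  expect_equal(geneWindow(idx, "g1", 0L)[c("start", "end")],
               list(start = 100L, end = 500L))
})

test_that("strand partition is exhaustive, disjoint, and focus-relative", {
  plus <- GeneModel("p", "gp", "chr1", "+", 0L, 10L)
  minus <- GeneModel("m", "gm", "chr1", "-", 5L, 15L)
  un <- GeneModel("u", "gu", "chr1", "*", 8L, 20L)
  models <- list(plus, minus, un)
  onPlus <- classifyModels(models, "+")
  expect_setequal(vapply(onPlus$same, transcriptId, ""), c("p", "u"))
  expect_setequal(vapply(onPlus$opposite, transcriptId, ""), "m")
  # the partition swaps with the focus strand, unstranded stays "same"
  onMinus <- classifyModels(models, "-")
  expect_setequal(vapply(onMinus$same, transcriptId, ""), c("m", "u"))
  expect_setequal(vapply(onMinus$opposite, transcriptId, ""), "p")
  expect_length(c(onPlus$same, onPlus$opposite), length(models))
})

test_that("sliceCoverage matches the positionwise oracle", {
  tr <- CoverageTrack("t", "chr1", 5L, 6L, 3)
  expect_equal(sliceCoverage(tr, "chr1", 0L, 10L),
               c(0, 0, 0, 0, 0, 3, 0, 0, 0, 0))
  expect_equal(sliceCoverage(CoverageTrack("e"), "chr1", 0L, 4L), rep(0, 4))
  expect_equal(sliceCoverage(CoverageTrack("r", "chr1", 5L, 8L, 2),
                             "chr1", 5L, 8L), c(2, 2, 2))
  set.seed(13)
  for (rep in 1:200) {
    rt <- randomTrack()
    w0 <- sample(0:450, 1L); w1 <- w0 + sample(1:80, 1L)
    expect_equal(sliceCoverage(rt$track, "chr1", w0, w1),
                 oracleSlice(rt$runs, w0, w1))
  }
})

test_that("total signal survives canonical merging", {
  # the same signal expressed as split runs and as merged runs
  split <- CoverageTrack("s", rep("chr1", 3), c(0L, 4L, 10L),
                         c(4L, 9L, 12L), c(2, 2, 5))
  merged <- CoverageTrack("s", rep("chr1", 2), c(0L, 10L), c(9L, 12L),
                          c(2, 5))
  expect_identical(split@runs, merged@runs)
  expect_equal(totalSignal(split), 2 * 9 + 5 * 2)
})

test_that("orientView mirrors minus-strand views and is an involution", {
  set.seed(17)
  v <- randomMinusView()
  o <- orientView(v)
  w0 <- v@windowStart; w1 <- v@windowEnd
  expect_equal(o@iclipValues$x, rev(v@iclipValues$x))
  expect_equal(sort(o@siteSets$s$start), sort(w0 + (w1 - v@siteSets$s$end)))
  expect_true(o@oriented)
  for (rep in 1:30) {
    v <- randomMinusView()
    twice <- orientView(orientView(v))
    expect_equal(twice, v)
    once <- orientView(v)
    expect_equal(sort(once@iclipValues$x), sort(v@iclipValues$x))
    expect_equal(sum(once@iclipValues$x), sum(v@iclipValues$x))
  }
})

test_that("plus-strand views orient to themselves", {
  b <- fixtureBundle()
  idx <- buildGeneIndex(b@annotations[[1L]])
  plusGene <- Filter(function(g) geneSpan(idx, g)$strand == "+",
                     indexGenes(idx))[[1L]]
  v <- buildGenomeView(idx, b, plusGene)
  expect_identical(orientView(v), v)
})

test_that("minus-strand interval mirroring follows the window formula", {
  v <- randomMinusView()
  w0 <- v@windowStart; w1 <- v@windowEnd
  df <- data.frame(chrom = "chr1", start = w0, end = w0 + 1L, name = "x",
                   score = 1, strand = "-", stringsAsFactors = FALSE)
  v@siteSets <- list(one = df)
  o <- orientView(v)
  expect_equal(o@siteSets$one$start, w1 - 1L)
  expect_equal(o@siteSets$one$end, w1)
})

test_that("crosslink pile-up reduces reads to 1 nt upstream of the start", {
  reads <- data.frame(chrom = "chr1", start = 100L, end = 120L, strand = "+",
                      stringsAsFactors = FALSE)
  tr <- crosslinkPileup(reads)
  expect_equal(sliceCoverage(tr, "chr1", 99L, 100L), 1)
  minus <- transform(reads, strand = "-")
  expect_equal(sliceCoverage(crosslinkPileup(minus), "chr1", 120L, 121L), 1)
  three <- reads[rep(1L, 3L), ]
  expect_equal(sliceCoverage(crosslinkPileup(three), "chr1", 99L, 100L), 3)
  # the alternative reading ignores strand
  expect_equal(sliceCoverage(crosslinkPileup(minus, rule = "ignore-strand"),
                             "chr1", 99L, 100L), 1)
})

test_that("pile-up matches a per-read oracle and conserves counts", {
  set.seed(19)
  n <- 200L
  reads <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(0:500, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  reads$end <- reads$start + sample(20:40, n, replace = TRUE)
  tr <- suppressWarnings(crosslinkPileup(reads))
  oracle <- new.env()
  retained <- 0L
  for (i in seq_len(n)) {
    p <- if (reads$strand[i] == "+") reads$start[i] - 1L else reads$end[i]
    if (p < 0L) next
    retained <- retained + 1L
    key <- paste(reads$chrom[i], p)
    prev <- if (is.null(oracle[[key]])) 0 else oracle[[key]]
    oracle[[key]] <- prev + 1
  }
  expect_equal(totalSignal(tr), retained)
  for (key in ls(oracle)) {
    parts <- strsplit(key, " ")[[1L]]
    p <- as.integer(parts[2L])
    expect_equal(sliceCoverage(tr, parts[1L], p, p + 1L), oracle[[key]],
                 info = key)
  }
  # order invariance
  perm <- reads[sample.int(n), ]
  expect_identical(suppressWarnings(crosslinkPileup(perm))@runs[],
                   tr@runs[])
})

test_that("reads with negative crosslink positions are dropped loudly", {
  reads <- data.frame(chrom = "chr1", start = c(0L, 10L), end = c(20L, 30L),
                      strand = "+", stringsAsFactors = FALSE)
  expect_warning(tr <- crosslinkPileup(reads), "1 read")
  expect_equal(totalSignal(tr), 1)
  expect_error(crosslinkPileup(transform(reads, strand = "*")),
               "stranded reads")
})
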