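# Shared fixtures: one generated bundle per test run, plus small random
# object generators used by the property-style suites.

fixtureDir <- local({
  dir <- NULL
  info <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "clipview-fixture")
      info <<- generateFixtureBundle(fixtureSpec(seed = 101L), dir)
    }
    dir
  }
})

fixtureInfo <- function() {
  d <- fixtureDir()
  # regenerating with the same seed is byte-identical, so re-deriving the
  # metadata is cheap and keeps the helper stateless across files
  generateFixtureBundle(fixtureSpec(seed = 101L), d)
}

fixtureBundle <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle))
      bundle <<- loadBundle(fixtureLaunchConfig(fixtureDir()),
                            useCache = FALSE)
    bundle
  }
})

# a random valid GeneModel (used by round-trip and glyph properties)
randomModel <- function(id = "tx", gene = "g", chrom = "chr1") {
  nEx <- sample(1:4, 1L)
  lens <- sample(30:200, nEx, replace = TRUE)
  gaps <- if (nEx > 1L) sample(20:150, nEx - 1L, replace = TRUE) else integer(0)
  start <- sample(0:5000, 1L)
  s <- integer(nEx); e <- integer(nEx); pos <- start
  for (k in seq_len(nEx)) {
    s[k] <- pos; e[k] <- pos + lens[k]
    pos <- e[k] + if (k < nEx) gaps[k] else 0L
  }
  strand <- sample(c("+", "-", "*"), 1L, prob = c(.45, .45, .1))
  cds <- c(NA_integer_, NA_integer_)
  if (stats::runif(1) < 0.6) {
    cs <- s[1L] + sample.int(lens[1L], 1L) - 1L
    ce <- e[nEx] - sample.int(lens[nEx], 1L) + 1L
    if (cs < ce) cds <- c(cs, ce)
  }
  GeneModel(id, gene, chrom, strand, s, e, cds[1L], cds[2L])
}

randomModelSet <- function(n = 3L, prefix = "tx") {
  models <- lapply(seq_len(n), function(k)
    randomModel(sprintf("%s%d", prefix, k), sprintf("g%d", k)))
  names(models) <- vapply(models, transcriptId, "")
  models
}

# a random CoverageTrack plus its run table (for positionwise oracles)
randomTrack <- function(maxPos = 500L) {
  n <- sample(1:12, 1L)
  starts <- sort(sample(0:(maxPos - 2L), n))
  ends <- pmin(starts + sample(1:30, n, replace = TRUE), maxPos)
  keep <- !duplicated(starts) & ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) > 1L)
    ends <- pmin(ends, c(starts[-1L], maxPos))
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  vals <- sample(0:9, length(starts), replace = TRUE)
  list(track = CoverageTrack("rand", rep("chr1", length(starts)),
                             starts, ends, vals),
       runs = data.frame(start = starts, end = ends, value = vals))
}

# positionwise coverage oracle over a run table
oracleSlice <- function(runs, start, end) {
  vapply(start:(end - 1L), function(p) {
    hit <- runs$value[runs$start <= p & p < runs$end & runs$value != 0]
    if (length(hit)) sum(hit) else 0
  }, 0)
}

# a random minus-strand GenomeView built directly (for the orientation
# involution property)
randomMinusView <- function() {
  w0 <- sample(0:1000, 1L)
  len <- sample(50:400, 1L)
  w1 <- w0 + len
  nEx <- sample(1:3, 1L)
  bp <- sort(sample(w0:(w1 - 1L), 2L * nEx))
  model <- GeneModel("tx1", "g1", "chr1", "-",
                     bp[seq(1L, 2L * nEx, 2L)], bp[seq(2L, 2L * nEx, 2L)])
  sites <- data.frame(chrom = "chr1",
                      start = sample(w0:(w1 - 5L), 2L),
                      end = 0L, name = c("a", "b"), score = c(0.1, 0.9),
                      strand = "-", stringsAsFactors = FALSE)
  sites$end <- sites$start + sample(1:4, 2L, replace = TRUE)
  sites$end <- pmin(sites$end, w1)
  sites <- sites[order(sites$start), ]
  rownames(sites) <- NULL
  new("GenomeView", geneId = "g1", chrom = "chr1",
      windowStart = as.integer(w0), windowEnd = as.integer(w1),
      strand = "-",
      sameStrand = list(model), oppositeStrand = list(),
      iclipValues = list(x = round(stats::runif(len) * 10)),
      rnaseqValues = list(),
      siteSets = list(s = sites), eventSets = list(),
      sequence = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""),
      oriented = FALSE)
}

modelsEqual <- function(a, b) {
  isTRUE(all.equal(
    lapply(a, function(m) list(m@transcriptId, m@geneId, m@chrom, m@strand,
                               m@exonStarts, m@exonEnds, m@cdsStart,
                               m@cdsEnd)),
    lapply(b, function(m) list(m@transcriptId, m@geneId, m@chrom, m@strand,
                               m@exonStarts, m@exonEnds, m@cdsStart,
                               m@cdsEnd))))
}
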