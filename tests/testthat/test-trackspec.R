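# Rendering conventions: gene-model glyph rules, panel construction,
# event color modes, and figure assembly order.

test_that("coding models split exons into UTR and CDS height classes", {
  m <- GeneModel("tx1", "g1", "chr1", "+", c(100L, 400L), c(200L, 500L),
                 150L, 450L)
  g <- geneModelGlyphs(m)
  expect_equal(g$heightClass, c("half", "full", "thin", "full", "half"))
  expect_equal(g$xstart, c(100, 150, 200, 400, 450))
  expect_equal(g$xend, c(150, 200, 400, 450, 500))
  expect_equal(g$kind, c("box", "box", "line", "box", "box"))
})

test_that("non-coding models draw full exons and thin introns", {
  m <- GeneModel("tx2", "g2", "chr1", "-", c(10L, 60L), c(40L, 90L))
  g <- geneModelGlyphs(m)
  expect_equal(g$kind, c("box", "line", "box"))
  expect_equal(g$heightClass, c("full", "thin", "full"))
})

test_that("strand class changes only the color, never the geometry", {
  m <- GeneModel("tx1", "g1", "chr1", "+", c(100L, 400L), c(200L, 500L),
                 150L, 450L)
  same <- geneModelGlyphs(m, strandClass = "same")
  opp <- geneModelGlyphs(m, strandClass = "opposite")
  expect_identical(same[c("kind", "xstart", "xend", "heightClass")],
                   opp[c("kind", "xstart", "xend", "heightClass")])
  expect_true(all(same$color == "#000000"))
  expect_true(all(opp$color == "#808080"))
})

test_that("glyphs clamp to the display window", {
  m <- GeneModel("tx1", "g1", "chr1", "+", c(100L, 400L), c(200L, 500L))
  g <- geneModelGlyphs(m, window = c(150L, 450L))
  expect_true(all(g$xstart >= 150 & g$xend <= 450))
})

test_that("iclip panels draw one bar per nonzero position, sites below", {
  counts <- c(0, 0, 3, 0, 1)
  sites <- data.frame(chrom = "chr1", start = c(101L, 104L),
                      end = c(103L, 105L), name = "xl", score = 1,
                      strand = "+", stringsAsFactors = FALSE)
  p <- iclipPanel(counts, 100L, sites, datasetName = "LL36")
  bars <- p@glyphs[p@glyphs$lane == "signal", ]
  expect_equal(nrow(bars), 2L)
  expect_equal(sum(bars$height), sum(counts))
  expect_equal(bars$xstart, c(102, 104))
  expect_equal(nrow(p@glyphs[p@glyphs$lane == "sites", ]), 2L)
  expect_equal(p@legend$name, "LL36")

  empty <- iclipPanel(rep(0, 5), 100L, NULL, datasetName = "LL24")
  expect_s4_class(empty, "TrackPanel")
  expect_equal(nrow(empty@glyphs), 0L)
  expect_equal(empty@title, "LL24")
})

test_that("sequence panels honor the three display modes", {
  heat <- sequencePanel("ACGT", "heatmap", windowStart = 10L)
  expect_equal(heat@glyphs$kind, rep("heatcell", 4))
  expect_equal(length(unique(heat@glyphs$color)), 4L)
  txt <- sequencePanel("ACGN", "text", windowStart = 10L)
  expect_equal(txt@glyphs$kind, rep("letter", 4))
  expect_equal(txt@glyphs$label, c("A", "C", "G", "N"))
  expect_null(sequencePanel("ACGT", "hidden"))
  expect_error(sequencePanel("ACGT", "heatmap", windowLength = 10L),
               "does not match window length")
})

test_that("event bars color by class in by-name mode per the legend map", {
  events <- data.frame(chrom = "chr1", start = c(0L, 10L, 20L),
                       end = c(5L, 15L, 25L), name = c("A3", "A5", "RI"),
                       score = c(0.2, 0.4, 0.6), strand = "+",
                       stringsAsFactors = FALSE)
  p <- rnaseqPanel(rep(0, 30), 0L, events, "by-name", sampleName = "wt")
  bars <- p@glyphs[p@glyphs$lane == "events", ]
  expect_equal(bars$color[match(c("A3", "A5", "RI"), bars$label)],
               c("#0000FF", "#FF0000", "#008000"))
  # uniform mode paints everything default blue
  pu <- rnaseqPanel(rep(0, 30), 0L, events, "uniform", sampleName = "wt")
  expect_true(all(pu@glyphs[pu@glyphs$lane == "events", "color"] ==
                    "#0000FF"))
})

test_that("unknown event classes get a deterministic fallback color", {
  events <- data.frame(chrom = "c", start = c(0L, 10L), end = c(5L, 15L),
                       name = c("MX", "AF"), score = c(1, 2), strand = "+",
                       stringsAsFactors = FALSE)
  p1 <- rnaseqPanel(rep(0, 20), 0L, events, "by-name")
  p2 <- rnaseqPanel(rep(0, 20), 0L, events[2:1, ], "by-name")
  c1 <- p1@glyphs[p1@glyphs$lane == "events", c("label", "color")]
  c2 <- p2@glyphs[p2@glyphs$lane == "events", c("label", "color")]
  expect_identical(c1[order(c1$label), "color"], c2[order(c2$label), "color"])
  expect_false(any(c1$color %in% c("#0000FF", "#FF0000", "#008000")))
})

test_that("by-score coloring interpolates linearly and is monotone", {
  scheme <- defaultColorScheme()
  events <- data.frame(chrom = "c", start = c(0L, 10L, 20L),
                       end = c(5L, 15L, 25L), name = "e",
                       score = c(0, 0.5, 1), strand = "+",
                       stringsAsFactors = FALSE)
  p <- rnaseqPanel(rep(0, 30), 0L, events, "by-score", scheme)
  cols <- p@glyphs[p@glyphs$lane == "events", "color"]
  ramp <- grDevices::colorRamp(c(scheme@gradientLow, scheme@gradientHigh))
  want <- apply(ramp(c(0, 0.5, 1)), 1, function(v)
    grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255))
  expect_identical(toupper(cols), toupper(want))
  # equal scores -> equal colors
  eq <- transform(events, score = 0.3)
  pe <- rnaseqPanel(rep(0, 30), 0L, eq, "by-score", scheme)
  expect_length(unique(pe@glyphs[pe@glyphs$lane == "events", "color"]), 1L)
  # a missing score is a contract error naming the event
  bad <- events; bad$score[2L] <- NA
  expect_error(rnaseqPanel(rep(0, 30), 0L, bad, "by-score", scheme),
               "missing for 'e'")
})

test_that("coverage renders as area glyphs conserving the dense array", {
  cov <- c(0, 2, 2, 5, 0, 0, 1)
  p <- rnaseqPanel(cov, 100L, NULL, "uniform", sampleName = "s1")
  areas <- p@glyphs[p@glyphs$kind == "area", ]
  expect_equal(nrow(areas), 3L)
  expect_equal(sum(areas$height * (areas$xend - areas$xstart)), sum(cov))
})

test_that("figures assemble panels in dashboard order with a strand header", {
  b <- fixtureBundle()
  idx <- buildGeneIndex(b@annotations[[1L]])
  genes <- indexGenes(idx)
  minusGene <- Filter(function(g) geneSpan(idx, g)$strand == "-", genes)[[1L]]
  v <- orientView(buildGenomeView(idx, b, minusGene))
  fig <- assembleFigure(v)
  kinds <- vapply(fig@panels, function(p) p@kind, "")
  expect_equal(kinds, c("iclip-signal", "iclip-signal", "sequence",
                        "gene-models"))
  expect_match(fig@header, "\\(-\\)$")

  rfig <- assembleFigure(v, options = list(tab = "rnaseq"))
  expect_equal(vapply(rfig@panels, function(p) p@kind, ""),
               c("coverage", "coverage", "gene-models"))

  # a bundle with no tracks still yields a models-only figure
  bare <- DataBundle(annotations = b@annotations)
  v2 <- orientView(buildGenomeView(buildGeneIndex(bare@annotations[[1L]]),
                                   bare, genes[[1L]]))
  f2 <- assembleFigure(v2)
  expect_equal(vapply(f2@panels, function(p) p@kind, ""), "gene-models")
})

test_that("every glyph of every panel stays inside the window", {
  b <- fixtureBundle()
  idx <- buildGeneIndex(b@annotations[[1L]])
  for (g in indexGenes(idx)) {
    v <- orientView(buildGenomeView(idx, b, g))
    for (tab in c("iclip", "rnaseq")) {
      fig <- assembleFigure(v, options = list(tab = tab,
                                              eventColorMode = "by-name"))
      for (p in fig@panels) {
        if (!nrow(p@glyphs)) next
        expect_true(all(p@glyphs$xstart >= fig@windowStart), info = g)
        expect_true(all(p@glyphs$xend <= fig@windowEnd), info = g)
      }
    }
  }
})

test_that("figure JSON is parseable and faithful", {
  b <- fixtureBundle()
  idx <- buildGeneIndex(b@annotations[[1L]])
  fig <- assembleFigure(orientView(buildGenomeView(idx, b, "G001")))
  parsed <- jsonlite::fromJSON(figureToJSON(fig), simplifyVector = FALSE)
  expect_equal(parsed$header, fig@header)
  expect_length(parsed$panels, length(fig@panels))
  expect_equal(sum(vapply(parsed$panels, function(p) length(p$glyphs), 0L)),
               glyphCount(fig))
})
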