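# Dashboard layer: search ranking, details rows, pure state transitions,
# and the multi-user HTTP service.

test_that("search ranks exact id, id prefix, id substring, description", {
  entries <- data.frame(
    geneId = c("AT1G10", "AT1G10500", "XAT1G10", "ZZZ9"),
    description = c("", "", "", "mentions at1g10 protein"),
    stringsAsFactors = FALSE)
  got <- searchGenes("at1g10", entries)
  expect_equal(got, c("AT1G10", "AT1G10500", "XAT1G10", "ZZZ9"))
  expect_equal(searchGenes("", entries, 2L), c("AT1G10", "AT1G10500"))
  expect_equal(searchGenes("nothing-matches", entries), character(0))
})

test_that("free-text description search surfaces the described gene first", {
  b <- fixtureBundle()
  idx <- buildGeneIndex(b@annotations[[1L]])
  entries <- searchEntries(idx, b@descriptions)
  hit <- searchGenes("kin1", entries)
  expect_gte(length(hit), 1L)
  desc <- entries$description[entries$geneId == hit[1L]]
  expect_match(tolower(desc), "kin1")
})

test_that("details rows follow table column order, excluding the key", {
  b <- fixtureBundle()
  rows <- detailsRows("G001", b@extendedDescriptions)
  expect_equal(rows$column,
               setdiff(names(b@extendedDescriptions), "gene_id"))
  expect_false(any(rows$value == ""))
  missing <- detailsRows("G999", b@extendedDescriptions)
  expect_equal(nrow(missing), 0L)
  expect_match(attr(missing, "notice"), "G999")
  absent <- detailsRows("G001", NULL)
  expect_equal(nrow(absent), 0L)
  expect_match(attr(absent, "notice"), "No extended")
})

test_that("state transitions are pure and replayable", {
  b <- fixtureBundle()
  s0 <- newAppState(b)
  log <- list(
    list(type = "select-gene", gene = "G002"),
    list(type = "select-tab", tab = "rnaseq"),
    list(type = "set-sequence-mode", mode = "text"),
    list(type = "set-event-color-mode", mode = "by-name"),
    list(type = "set-datasets", datasets = "iclip_rep1"))
  replay <- function() Reduce(updateAppState, log, s0)
  s1 <- replay(); s2 <- replay()
  expect_identical(s1, s2)
  expect_equal(s1$geneId, "G002")
  expect_equal(s1$tab, "rnaseq")
  expect_equal(s1$datasets, "iclip_rep1")
  # invalid events leave the state unchanged
  expect_identical(updateAppState(s1, list(type = "select-tab", tab = "x")),
                   s1)
  expect_identical(updateAppState(s1, list(type = "set-datasets",
                                           datasets = "nope"))$datasets,
                   character(0))
})

test_that("the service isolates sessions and reuses the figure pipeline", {
  b <- fixtureBundle()
  port <- freeTestPort()
  h <- serveDashboard(b, host = "127.0.0.1", port = port)
  on.exit(h$stop())
  base <- sprintf("http://127.0.0.1:%d", port)

  root <- httpRequest(paste0(base, "/"))
  expect_equal(root$status, 200L)

  jarA <- tempfile(); jarB <- tempfile()
  httpRequest(sprintf("%s/figure.json?gene=G001", base), cookieJar = jarA)
  httpRequest(sprintf("%s/figure.json?gene=G002", base), cookieJar = jarB)
  # parameterless requests now reflect each session's own selection
  figA <- httpRequest(paste0(base, "/figure.json"), cookieJar = jarA)
  figB <- httpRequest(paste0(base, "/figure.json"), cookieJar = jarB)
  expect_match(figA$body, '"G001 \\(')
  expect_match(figB$body, '"G002 \\(')

  # the served figure equals the directly computed specification
  idx <- buildGeneIndex(b@annotations[[1L]])
  st <- updateAppState(newAppState(b), list(type = "select-gene",
                                            gene = "G001"))
  expect_equal(figA$body, as.character(figureToJSON(
    stateFigure(idx, b, st))))

  res <- httpRequest(sprintf("%s/search?q=kin1", base))
  expect_equal(res$status, 200L)
  expect_match(res$body, "G0")

  det <- httpRequest(sprintf("%s/details?gene=G001", base))
  expect_match(det$body, "synonyms")
})

test_that("password protection denies access until login succeeds", {
  b <- fixtureBundle()
  port <- freeTestPort()
  h <- serveDashboard(b, host = "127.0.0.1", port = port, password = "tea")
  on.exit(h$stop())
  base <- sprintf("http://127.0.0.1:%d", port)
  jar <- tempfile()
  expect_equal(httpRequest(paste0(base, "/"), cookieJar = jar)$status, 401L)
  expect_equal(httpRequest(paste0(base, "/login"), cookieJar = jar,
                           postData = "pwd=coffee")$status, 401L)
  expect_equal(httpRequest(paste0(base, "/login"), cookieJar = jar,
                           postData = "pwd=tea")$status, 303L)
  expect_equal(httpRequest(paste0(base, "/"), cookieJar = jar)$status, 200L)
})

test_that("an occupied port raises a startup error naming the port", {
  b <- fixtureBundle()
  port <- freeTestPort()
  h <- serveDashboard(b, host = "127.0.0.1", port = port)
  on.exit(h$stop())
  expect_error(serveDashboard(b, host = "127.0.0.1", port = port),
               as.character(port))
})

test_that("figure exports are served in both formats", {
  b <- fixtureBundle()
  port <- freeTestPort()
  h <- serveDashboard(b, host = "127.0.0.1", port = port)
  on.exit(h$stop())
  base <- sprintf("http://127.0.0.1:%d", port)
  svg <- httpRequest(sprintf("%s/figure.svg?gene=G001", base))
  expect_match(svg$body, "<svg")
  png <- httpRequest(sprintf("%s/figure.png?gene=G001", base))
  expect_identical(as.integer(png$bytes[1:4]),
                   c(0x89L, 0x50L, 0x4EL, 0x47L))
})
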