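## The dashboard layer: free-text gene search, the details tab, pure
## AppState transitions, and an httpuv-backed multi-user web service.
## Every figure the service returns is computed by
## assembleFigure(orientView(buildGenomeView(...))) on the session state;
## no genomics logic lives in the routes.

#' Search entries for the gene dropdown
#'
#' @param index a [GeneIndex-class].
#' @param descriptions optional description table (gene id key, first
#'   text column used as the searchable description).
#' @return data.frame with columns geneId, description.
#' @export
searchEntries <- function(index, descriptions = NULL) {
  ids <- indexGenes(index)
  desc <- rep("", length(ids))
  if (!is.null(descriptions) && ncol(descriptions) >= 2L) {
    key <- attr(descriptions, "keyColumn") %||% names(descriptions)[1L]
    textCol <- setdiff(names(descriptions), key)[1L]
    m <- match(ids, descriptions[[key]])
    desc[!is.na(m)] <- descriptions[[textCol]][m[!is.na(m)]]
  }
  data.frame(geneId = ids, description = desc, stringsAsFactors = FALSE)
}

#' Free-text gene search
#'
#' Case-insensitive substring matching over gene ids and descriptions.
#' Rank order: exact id match, id prefix, id substring, description
#' substring; ties break alphabetically by id. An empty query returns the
#' first `limit` ids alphabetically.
#'
#' @param query free text.
#' @param entries data.frame from [searchEntries()].
#' @param limit maximum number of results.
#' @return character vector of ranked gene ids.
#' @export
searchGenes <- function(query, entries, limit = 10L) {
  ids <- entries$geneId
  ord <- order(ids)
  ids <- ids[ord]
  desc <- entries$description[ord]
  q <- tolower(trimws(query))
  if (!nzchar(q)) return(utils::head(ids, limit))
  lid <- tolower(ids); ldesc <- tolower(desc)
  tier <- ifelse(lid == q, 1L,
          ifelse(startsWith(lid, q), 2L,
          ifelse(grepl(q, lid, fixed = TRUE), 3L,
          ifelse(grepl(q, ldesc, fixed = TRUE), 4L, NA_integer_))))
  keep <- !is.na(tier)
  utils::head(ids[keep][order(tier[keep], ids[keep])], limit)
}

#' Details rows for one gene
#'
#' The gene's row of the extended description table rendered as
#' (column, value) pairs in table column order, the key column excluded.
#'
#' @param geneId gene id.
#' @param extended extended description table, or NULL when none was
#'   supplied.
#' @return data.frame with columns column, value; when the gene (or the
#'   whole table) is absent the frame is empty and carries a `notice`
#'   attribute with the text the dashboard displays.
#' @export
detailsRows <- function(geneId, extended) {
  none <- data.frame(column = character(0), value = character(0),
                     stringsAsFactors = FALSE)
  if (is.null(extended)) {
    attr(none, "notice") <- "No extended gene descriptions were supplied."
    return(none)
  }
  key <- attr(extended, "keyColumn") %||% names(extended)[1L]
  hit <- which(extended[[key]] == geneId)
  if (!length(hit)) {
    attr(none, "notice") <-
      sprintf("No extended description available for %s.", geneId)
    return(none)
  }
  cols <- setdiff(names(extended), key)
  data.frame(column = cols,
             value = vapply(cols, function(cn)
               as.character(extended[[cn]][hit[1L]]), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

## AppState -----------------------------------------------------------------

appTabs <- c("iclip", "rnaseq", "details", "settings")
sequenceModes <- c("heatmap", "text", "hidden")
eventColorModes <- c("uniform", "by-name", "by-score")

#' Initial application state for a bundle
#'
#' @param bundle a [DataBundle-class].
#' @param geneId initially selected gene (default: alphabetically first).
#' @return an AppState list.
#' @export
newAppState <- function(bundle, geneId = NULL) {
  datasets <- vapply(bundle@iclipTracks, trackName, "")
  samples <- vapply(bundle@rnaseqTracks, trackName, "")
  structure(list(
    geneId = geneId, tab = "iclip",
    datasets = datasets, samples = samples,
    sequenceMode = "heatmap", eventColorMode = "uniform",
    allDatasets = datasets, allSamples = samples),
    class = "AppState")
}

#' Pure state transition
#'
#' `(state, event) -> state`; replaying an event log reproduces the final
#' state. Events are lists with a `type` and a payload: `select-gene`
#' (gene), `select-tab` (tab), `set-datasets` (datasets), `set-samples`
#' (samples), `set-sequence-mode` (mode), `set-event-color-mode` (mode).
#' Invalid payloads leave the state unchanged.
#'
#' @param state an AppState.
#' @param event event list.
#' @return the next AppState.
#' @export
updateAppState <- function(state, event) {
  type <- event$type
  if (identical(type, "select-gene") && is.character(event$gene))
    state$geneId <- event$gene
  else if (identical(type, "select-tab") && event$tab %in% appTabs)
    state$tab <- event$tab
  else if (identical(type, "set-datasets"))
    state$datasets <- intersect(state$allDatasets, event$datasets)
  else if (identical(type, "set-samples"))
    state$samples <- intersect(state$allSamples, event$samples)
  else if (identical(type, "set-sequence-mode") &&
           event$mode %in% sequenceModes)
    state$sequenceMode <- event$mode
  else if (identical(type, "set-event-color-mode") &&
           event$mode %in% eventColorModes)
    state$eventColorMode <- event$mode
  state
}

# figure options derived from a state
stateFigureOptions <- function(state) {
  list(tab = if (state$tab %in% c("iclip", "rnaseq")) state$tab else "iclip",
       sequenceMode = state$sequenceMode,
       eventColorMode = state$eventColorMode,
       datasets = state$datasets, samples = state$samples)
}

#' Compute the figure a state describes
#'
#' The single path from state to picture, used by the web routes and by
#' tests asserting that served figures equal directly computed ones.
#'
#' @param index a [GeneIndex-class].
#' @param bundle a [DataBundle-class].
#' @param state an AppState with a selected gene.
#' @param scheme a [ColorScheme-class].
#' @return a [FigureSpec-class].
#' @export
stateFigure <- function(index, bundle, state,
                        scheme = defaultColorScheme()) {
  stopifnot(!is.null(state$geneId))
  view <- orientView(buildGenomeView(index, bundle, state$geneId))
  assembleFigure(view, scheme, stateFigureOptions(state))
}

## HTTP service -------------------------------------------------------------

parseQuery <- function(qs) {
  qs <- sub("^\\?", "", qs %||% "")
  if (!nzchar(qs)) return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p)
    httpuv::decodeURIComponent(if (length(p) > 1L)
      paste(p[-1L], collapse = "=") else ""))
  stats::setNames(vals, vapply(kv, `[[`, "", 1L))
}

parseCookies <- function(header) {
  if (is.null(header) || !nzchar(header)) return(list())
  parts <- trimws(strsplit(header, ";", fixed = TRUE)[[1L]])
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1L], collapse = "=")),
                  vapply(kv, `[[`, "", 1L))
}

randomToken <- function() {
  paste(format(as.hexmode(sample.int(256L, 24L, replace = TRUE) - 1L),
               width = 2), collapse = "")
}

httpResponse <- function(body, status = 200L,
                         contentType = "text/html; charset=utf-8",
                         headers = list()) {
  headers[["Content-Type"]] <- contentType
  list(status = status, headers = headers,
       body = if (is.raw(body)) body else paste(body, collapse = "\n"))
}

dashboardPage <- function(title) {
  paste0(
    "<!DOCTYPE html><html><head><title>", title, "</title></head><body>",
    "<h1>", title, "</h1>",
    "<p><input id='q' placeholder='search genes'>",
    "<button onclick=\"fetch('/search?q='+encodeURIComponent(document.getElementById('q').value)",
    ".then(r=>r.json()).then(g=>{if(g.length)location='/?gene='+g[0]})\">Go</button>",
    " <a href='/help'>Help</a></p>",
    "<div id='figure'></div>",
    "<script>fetch('/figure.svg'+location.search).then(r=>r.text())",
    ".then(t=>{document.getElementById('figure').innerHTML=t})</script>",
    "</body></html>")
}

helpPage <- function() {
  paste0("<!DOCTYPE html><html><body><h1>Help</h1>",
         "<p>Select a gene with the search box (free text over ids and ",
         "descriptions). Tabs: iCLIP crosslink signal with significant ",
         "sites, RNA-seq coverage with splice events, gene details, and ",
         "settings. Figures can be exported via /figure.svg and ",
         "/figure.png.</p></body></html>")
}

loginPage <- function(failed = FALSE) {
  paste0("<!DOCTYPE html><html><body><h1>Login</h1>",
         if (failed) "<p>Access denied: wrong password.</p>" else "",
         "<form method='POST' action='/login'>",
         "<input type='password' name='pwd'>",
         "<button type='submit'>Enter</button></form></body></html>")
}

#' Serve the dashboard
#'
#' Starts a multi-user HTTP service. Each client session (cookie-keyed)
#' holds its own AppState: one client's selections never mutate
#' another's view. When `password` is set, every route except the login
#' form requires a session that passed the shared-secret challenge.
#'
#' Routes: `/` (dashboard page), `/search?q=`, `/figure.svg`,
#' `/figure.png`, `/figure.json` (all accepting `gene`, `tab`,
#' `sequence`, `events`, `datasets`, `samples` parameters that update the
#' session state), `/details?gene=`, `/help`, `POST /login`.
#'
#' @param bundle a validated [DataBundle-class] (zero errors).
#' @param host interface to bind (default all interfaces).
#' @param port TCP port (default 8060).
#' @param password optional shared password.
#' @param scheme a [ColorScheme-class].
#' @param annotationSet which annotation set to index (default first).
#' @return a handle with fields `host`, `port`, `url`, `server` and
#'   functions `stop()` and `serviceLoop()`.
#' @export
serveDashboard <- function(bundle, host = "0.0.0.0", port = 8060L,
                           password = NULL,
                           scheme = defaultColorScheme(),
                           annotationSet = 1L) {
  index <- buildGeneIndex(bundle@annotations[[annotationSet]])
  entries <- searchEntries(index, bundle@descriptions)
  sessions <- new.env(parent = emptyenv())
  defaultGene <- utils::head(indexGenes(index), 1L)

  getSession <- function(req) {
    cookies <- parseCookies(req$HTTP_COOKIE)
    sid <- cookies[["cvsid"]] %||% ""
    isNew <- !nzchar(sid) || !exists(sid, envir = sessions)
    if (isNew) {
      sid <- randomToken()
      assign(sid, list(state = newAppState(bundle, defaultGene),
                       authed = FALSE), envir = sessions)
    }
    list(id = sid, new = isNew, data = get(sid, envir = sessions))
  }
  saveSession <- function(sid, data) assign(sid, data, envir = sessions)

  applyQueryToState <- function(state, q) {
    if (!is.null(q$gene))
      state <- updateAppState(state, list(type = "select-gene",
                                          gene = q$gene))
    if (!is.null(q$tab))
      state <- updateAppState(state, list(type = "select-tab", tab = q$tab))
    if (!is.null(q$sequence))
      state <- updateAppState(state, list(type = "set-sequence-mode",
                                          mode = q$sequence))
    if (!is.null(q$events))
      state <- updateAppState(state, list(type = "set-event-color-mode",
                                          mode = q$events))
    if (!is.null(q$datasets))
      state <- updateAppState(state, list(
        type = "set-datasets",
        datasets = strsplit(q$datasets, ",", fixed = TRUE)[[1L]]))
    if (!is.null(q$samples))
      state <- updateAppState(state, list(
        type = "set-samples",
        samples = strsplit(q$samples, ",", fixed = TRUE)[[1L]]))
    state
  }

  handler <- function(req) {
    path <- req$PATH_INFO
    q <- parseQuery(req$QUERY_STRING)
    ses <- getSession(req)
    cookieHeader <- list("Set-Cookie" =
                           sprintf("cvsid=%s; HttpOnly; Path=/", ses$id))
    finish <- function(resp) {
      if (ses$new) resp$headers <- c(resp$headers, cookieHeader)
      resp
    }

    if (!is.null(password)) {
      if (identical(path, "/login") && identical(req$REQUEST_METHOD, "POST")) {
        body <- rawToChar(req$rook.input$read())
        form <- parseQuery(body)
        if (identical(form$pwd, password)) {
          ses$data$authed <- TRUE
          saveSession(ses$id, ses$data)
          return(finish(httpResponse("", status = 303L,
                                     headers = list(Location = "/"))))
        }
        return(finish(httpResponse(loginPage(failed = TRUE), status = 401L)))
      }
      if (!isTRUE(ses$data$authed))
        return(finish(httpResponse(loginPage(), status = 401L)))
    }

    state <- applyQueryToState(ses$data$state, q)
    ses$data$state <- state
    saveSession(ses$id, ses$data)

    resp <- tryCatch(switch(path,
      "/" = httpResponse(dashboardPage(sprintf("%s crosslink viewer",
                                               state$geneId %||% ""))),
      "/help" = httpResponse(helpPage()),
      "/search" = httpResponse(
        jsonlite::toJSON(searchGenes(q$q %||% "", entries, 20L)),
        contentType = "application/json"),
      "/details" = {
        rows <- detailsRows(q$gene %||% state$geneId,
                            bundle@extendedDescriptions)
        out <- list(rows = rows)
        if (!is.null(attr(rows, "notice"))) out$notice <- attr(rows, "notice")
        httpResponse(jsonlite::toJSON(out, dataframe = "rows",
                                      auto_unbox = TRUE),
                     contentType = "application/json")
      },
      "/figure.json" = httpResponse(
        figureToJSON(stateFigure(index, bundle, state, scheme)),
        contentType = "application/json"),
      "/figure.svg" = httpResponse(
        figureToSVG(stateFigure(index, bundle, state, scheme)),
        contentType = "image/svg+xml"),
      "/figure.png" = httpResponse(
        exportFigure(stateFigure(index, bundle, state, scheme), "PNG"),
        contentType = "image/png"),
      httpResponse("<h1>404</h1>", status = 404L)),
      error = function(e)
        httpResponse(paste0("<h1>500</h1><pre>",
                            xmlEscape(conditionMessage(e)), "</pre>"),
                     status = 500L))
    finish(resp)
  }

  server <- tryCatch(
    httpuv::startServer(host, as.integer(port), list(call = handler)),
    error = function(e)
      stop(sprintf("cannot start dashboard: port %d unavailable (%s)",
                   as.integer(port), conditionMessage(e))))
  handle <- list(
    host = host, port = as.integer(port),
    url = sprintf("http://%s:%d", if (host == "0.0.0.0") "127.0.0.1" else host,
                  as.integer(port)),
    server = server,
    stop = function() httpuv::stopServer(server),
    serviceLoop = function(timeoutMs = 50) httpuv::service(timeoutMs))
  class(handle) <- "clipViewServer"
  handle
}

#' @export
print.clipViewServer <- function(x, ...) {
  cat(sprintf("clipView dashboard listening on %s\n", x$url))
  invisible(x)
}
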