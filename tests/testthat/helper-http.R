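# HTTP test client: issues a curl request from a background process while
# pumping the httpuv event loop of the in-process server.

httpRequest <- function(url, cookieJar = NULL, postData = NULL,
                        timeoutS = 10) {
  out <- tempfile(); codeFile <- tempfile()
  args <- c("-s", "-o", shQuote(out), "-w", "%{http_code}")
  if (!is.null(cookieJar))
    args <- c(args, "-b", shQuote(cookieJar), "-c", shQuote(cookieJar))
  if (!is.null(postData)) args <- c(args, "-d", shQuote(postData))
  cmd <- sprintf("curl %s %s > %s 2>/dev/null",
                 paste(args, collapse = " "), shQuote(url), shQuote(codeFile))
  system(cmd, wait = FALSE)
  deadline <- Sys.time() + timeoutS
  while (Sys.time() < deadline) {
    httpuv::service(25)
    if (file.exists(codeFile) && file.size(codeFile) >= 3) break
  }
  httpuv::service(25)
  Sys.sleep(0.05)
  httpuv::service(25)
  status <- suppressWarnings(as.integer(readLines(codeFile, warn = FALSE)[1]))
  body <- if (file.exists(out))
    paste(readLines(out, warn = FALSE), collapse = "\n") else ""
  list(status = status, body = body,
       bytes = if (file.exists(out))
         readBin(out, "raw", n = file.info(out)$size) else raw(0))
}

freeTestPort <- function() sample(20000:45000, 1L)
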