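## Binary cache of parsed inputs keyed by a source fingerprint, so that
## dashboard restarts skip re-parsing large annotation and track files.
## Cache files are private to this package (serialized R objects plus a
## format version); they are not an interchange format and deleting the
## cache directory is always safe.

CACHE_FORMAT_VERSION <- 2L

#' Fingerprint of a source file
#'
#' Content digest (md5 of the raw, possibly compressed bytes) plus size
#' and modification time; recompressing or touching the file invalidates
#' the fingerprint.
#'
#' @param path file path.
#' @return a character scalar.
#' @export
sourceFingerprint <- function(path) {
  info <- file.info(path)
  sprintf("%s:%.0f:%.6f", unname(tools::md5sum(path)), info$size,
          as.numeric(info$mtime))
}

cacheEntryPath <- function(cacheDir, path) {
  key <- gsub("[^A-Za-z0-9._-]", "_", normalizePath(path, mustWork = FALSE))
  key <- sub("^_+", "", key)
  file.path(cacheDir, paste0(key, ".rds"))
}

#' Parse a file through the binary cache
#'
#' On a fingerprint hit the deserialized payload is returned; on a miss
#' the file is parsed with `parser`, stored and returned. Either way the
#' returned object is structurally identical. A corrupt or stale entry is
#' discarded and the file reparsed; an unwritable cache directory
#' downgrades to parse-only with a warning. Startup never fails because
#' of the cache.
#'
#' @param path source file path.
#' @param parser function of `path` returning the parsed object.
#' @param cacheDir cache directory (created if missing).
#' @return the parsed (or cached) object.
#' @export
loadOrParse <- function(path, parser, cacheDir) {
  ok <- dir.exists(cacheDir) || dir.create(cacheDir, recursive = TRUE,
                                           showWarnings = FALSE)
  if (!ok || file.access(cacheDir, 2L) != 0L) {
    warning(sprintf("cache directory '%s' not writable; parsing without cache",
                    cacheDir))
    return(parser(path))
  }
  fp <- sourceFingerprint(path)
  entry <- cacheEntryPath(cacheDir, path)
  if (file.exists(entry)) {
    cached <- tryCatch(readRDS(entry), error = function(e) NULL)
    if (!is.null(cached) && is.list(cached) &&
        identical(cached$version, CACHE_FORMAT_VERSION) &&
        identical(cached$fingerprint, fp)) {
      return(cached$payload)
    }
    if (is.null(cached))
      warning(sprintf("discarding corrupt cache entry '%s'", entry))
  }
  obj <- parser(path)
  tryCatch(saveRDS(list(version = CACHE_FORMAT_VERSION, fingerprint = fp,
                        payload = obj), entry),
           error = function(e)
             warning(sprintf("could not write cache entry '%s': %s", entry,
                             conditionMessage(e))))
  obj
}
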