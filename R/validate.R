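## The bundle validator: every input bundle passes through it before the
## dashboard starts. Intra-file syntax errors are raised by the readers;
## this layer checks cross-file consistency and emits a structured,
## deterministic report. Errors block startup; warnings do not (unless
## promoted by --strict). The check catalogue:
##
##   duplicate-transcript      error    duplicated transcript ids within a set
##   empty-annotation          error    annotation set with no models
##   chrom-unknown             warning  track/site chromosome absent from the
##                                      annotation
##   sequence-orphan           warning  FASTA id matching no transcript
##   sequence-missing          warning  transcript with no FASTA record
##   description-unknown-gene  warning  description row for an unknown gene
##   site-outside-genes        warning  BED6 record outside every gene span

issueRow <- function(severity, file, line, code, message) {
  data.frame(severity = severity, file = file,
             line = if (is.null(line)) NA_integer_ else as.integer(line),
             code = code, message = message, stringsAsFactors = FALSE)
}

emptyIssues <- function() {
  data.frame(severity = character(0), file = character(0),
             line = integer(0), code = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

memberFile <- function(x, fallback) {
  p <- attr(x, "sourcePath")
  if (is.null(p) || is.na(p)) fallback else p
}

#' Validate a data bundle
#'
#' Pure cross-file consistency check: the report is the output and the
#' same bundle always yields the same report (ordered by file, then
#' line, then code). Cross-file id mismatches are warnings because
#' partial bundles are supported; only defects that would corrupt the
#' display (duplicate transcript ids, an empty annotation set) are
#' errors.
#'
#' @param bundle a [DataBundle-class].
#' @param strict promote warnings to errors.
#' @return data.frame with columns severity, file, line, code, message.
#' @export
validateBundle <- function(bundle, strict = FALSE) {
  issues <- list()
  push <- function(...) issues[[length(issues) + 1L]] <<- issueRow(...)

  allTx <- character(0); allGenes <- character(0); allChroms <- character(0)
  for (k in seq_along(bundle@annotations)) {
    set <- bundle@annotations[[k]]
    label <- memberFile(set, sprintf("annotation:%d", k))
    if (!length(set)) {
      push("error", label, NULL, "empty-annotation",
           "annotation set contains no gene models")
      next
    }
    tx <- vapply(set, transcriptId, "")
    dup <- unique(tx[duplicated(tx)])
    for (d in dup)
      push("error", label, NULL, "duplicate-transcript",
           sprintf("transcript id '%s' occurs more than once", d))
    allTx <- c(allTx, tx)
    allGenes <- c(allGenes, vapply(set, geneId, ""))
    allChroms <- c(allChroms, vapply(set, function(m) m@chrom, ""))
  }
  allGenes <- unique(allGenes); allChroms <- unique(allChroms)

  checkChroms <- function(chroms, label) {
    for (ch in sort(setdiff(unique(chroms), allChroms)))
      push("warning", label, NULL, "chrom-unknown",
           sprintf("chromosome '%s' is absent from the annotation", ch))
  }
  for (k in seq_along(bundle@iclipTracks)) {
    tr <- bundle@iclipTracks[[k]]
    checkChroms(names(tr@runs), memberFile(tr@runs, sprintf("iclip:%s",
                                                            trackName(tr))))
  }
  for (k in seq_along(bundle@rnaseqTracks)) {
    tr <- bundle@rnaseqTracks[[k]]
    checkChroms(names(tr@runs), memberFile(tr@runs, sprintf("rnaseq:%s",
                                                            trackName(tr))))
  }
  setLabel <- function(sets, k, prefix) {
    nm <- names(sets)[k]
    memberFile(sets[[k]], sprintf("%s:%s", prefix,
                                  if (is.null(nm) || !nzchar(nm)) k else nm))
  }
  for (k in seq_along(bundle@siteSets))
    checkChroms(bundle@siteSets[[k]]$chrom,
                setLabel(bundle@siteSets, k, "sites"))
  for (k in seq_along(bundle@eventSets))
    checkChroms(bundle@eventSets[[k]]$chrom,
                setLabel(bundle@eventSets, k, "events"))

  if (!is.null(bundle@sequences)) {
    label <- memberFile(bundle@sequences, "sequences")
    for (id in sort(setdiff(names(bundle@sequences), allTx)))
      push("warning", label, NULL, "sequence-orphan",
           sprintf("sequence id '%s' matches no transcript", id))
    for (id in sort(setdiff(allTx, names(bundle@sequences))))
      push("warning", label, NULL, "sequence-missing",
           sprintf("transcript '%s' has no sequence record", id))
  }

  checkDescriptions <- function(tab, fallback) {
    if (is.null(tab)) return()
    label <- memberFile(tab, fallback)
    keys <- tab[[attr(tab, "keyColumn") %||% 1L]]
    for (g in sort(setdiff(keys, allGenes)))
      push("warning", label, NULL, "description-unknown-gene",
           sprintf("description row for unknown gene '%s'", g))
  }
  checkDescriptions(bundle@descriptions, "descriptions")
  checkDescriptions(bundle@extendedDescriptions, "extended-descriptions")

  # gene spans for the site containment check
  spans <- NULL
  if (length(allTx)) {
    models <- do.call(c, bundle@annotations)
    spans <- data.frame(
      chrom = vapply(models, function(m) m@chrom, ""),
      start = vapply(models, function(m) m@start, 0L),
      end = vapply(models, function(m) m@end, 0L))
  }
  for (k in seq_along(bundle@siteSets)) {
    df <- bundle@siteSets[[k]]
    label <- setLabel(bundle@siteSets, k, "sites")
    for (i in seq_len(nrow(df))) {
      inside <- !is.null(spans) && any(
        spans$chrom == df$chrom[i] & spans$start < df$end[i] &
          spans$end > df$start[i])
      if (!inside)
        push("warning", label, i, "site-outside-genes",
             sprintf("site %s:%d-%d overlaps no annotated gene",
                     df$chrom[i], df$start[i], df$end[i]))
    }
  }

  out <- if (length(issues)) do.call(rbind, issues) else emptyIssues()
  if (strict) out$severity[out$severity == "warning"] <- "error"
  out <- out[order(out$file, out$line, out$code, out$message,
                   na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a validation report as TSV
#'
#' @param issues report from [validateBundle()].
#' @param con connection (default standard error).
#' @param file optional path to also write the report to.
#' @export
writeValidationReport <- function(issues, con = stderr(), file = NULL) {
  lines <- c("severity\tfile\tline\tcode\tmessage",
             if (nrow(issues))
               paste(issues$severity, issues$file,
                     ifelse(is.na(issues$line), "", issues$line),
                     issues$code, issues$message, sep = "\t"))
  writeLines(lines, con)
  if (!is.null(file)) writeLines(lines, file)
  invisible(issues)
}

#' Does a report block startup?
#' @param issues report from [validateBundle()].
#' @return TRUE when the report contains at least one error.
#' @export
hasBlockingErrors <- function(issues) any(issues$severity == "error")
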