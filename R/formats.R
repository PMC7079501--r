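## Format layer: line-oriented readers for BED6, BED12, GTF, BEDGRAPH,
## FASTA and TSV, plus writers used by the fixture generator and the
## round-trip tests. Every reader normalizes to 0-based half-open
## coordinates and raises classed validation errors carrying file and
## line number.

validationError <- function(message, file = NA_character_, line = NA) {
  stop(structure(
    class = c("clipViewValidationError", "error", "condition"),
    list(message = if (is.na(line)) sprintf("%s: %s", file, message)
                   else sprintf("%s:%d: %s", file, line, message),
         call = NULL, file = file, line = line)))
}

#' Open a possibly compressed text source
#'
#' Returns an unopened line-oriented connection, transparently
#' decompressing by file suffix: `.gz`, `.bz2`, or `.zip` (which must
#' contain exactly one member). Any other suffix is read raw.
#'
#' @param path path to an existing file.
#' @return an unopened connection.
#' @export
openTextSource <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open '%s': no such file", path))
  lower <- tolower(path)
  if (endsWith(lower, ".gz")) return(gzfile(path, "r"))
  if (endsWith(lower, ".bz2")) return(bzfile(path, "r"))
  if (endsWith(lower, ".zip")) {
    members <- tryCatch(utils::unzip(path, list = TRUE),
                        error = function(e)
                          validationError("not a readable zip archive", path))
    if (nrow(members) != 1L)
      validationError(sprintf("zip archive must contain exactly one member (found %d)",
                              nrow(members)), path)
    return(unz(path, members$Name[1L]))
  }
  file(path, "r")
}

# read all lines from a path (with decompression) or an open-able connection
sourceLines <- function(source) {
  if (is.character(source)) {
    con <- openTextSource(source)
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    attr(lines, "sourcePath") <- source
    return(lines)
  }
  if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
    attr(lines, "sourcePath") <- NA_character_
    return(lines)
  }
  stop("source must be a file path or a connection")
}

# TRUE for comment/track/browser/empty lines that BED-family readers skip
isSkippableLine <- function(line) {
  !nzchar(line) || startsWith(line, "#") ||
    startsWith(line, "track") || startsWith(line, "browser")
}

parseIntField <- function(x) {
  v <- suppressWarnings(as.integer(x))
  v[is.na(v) | as.character(v) != sub("^\\+", "", x)] <- NA_integer_
  v
}

parseStrand <- function(x, file, line) {
  if (x %in% c("+", "-")) return(x)
  if (x == ".") return("*")
  validationError(sprintf("invalid strand '%s'", x), file, line)
}

#' Read a BED6 file of annotated intervals
#'
#' Columns beyond chrom/start/end are optional: a missing name becomes
#' `"."`, a missing score `NA`, a missing strand unstranded (`"*"`).
#' `track`, `browser` and `#` lines are skipped.
#'
#' @param source file path (optionally compressed) or connection.
#' @return data.frame with columns `chrom,start,end,name,score,strand`
#'   (0-based half-open) and a `sourcePath` attribute.
#' @export
readBed6 <- function(source) {
  lines <- sourceLines(source)
  path <- attr(lines, "sourcePath")
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (isSkippableLine(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      validationError("BED line needs at least 3 tab-separated columns", path, i)
    start <- parseIntField(f[2L]); end <- parseIntField(f[3L])
    if (is.na(start) || is.na(end))
      validationError("non-integer coordinates", path, i)
    if (start < 0L) validationError("negative start coordinate", path, i)
    if (start >= end)
      validationError(sprintf("empty or inverted interval [%d,%d)", start, end),
                      path, i)
    name <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else "."
    score <- NA_real_
    if (length(f) >= 5L && f[5L] != ".") {
      score <- suppressWarnings(as.numeric(f[5L]))
      if (is.na(score) || !is.finite(score))
        validationError(sprintf("invalid score '%s'", f[5L]), path, i)
    }
    strand <- if (length(f) >= 6L) parseStrand(f[6L], path, i) else "*"
    out[[length(out) + 1L]] <- list(chrom = f[1L], start = start, end = end,
                                    name = name, score = score, strand = strand)
  }
  df <- if (length(out)) {
    data.frame(chrom = vapply(out, `[[`, "", "chrom"),
               start = vapply(out, `[[`, 0L, "start"),
               end = vapply(out, `[[`, 0L, "end"),
               name = vapply(out, `[[`, "", "name"),
               score = vapply(out, `[[`, 0, "score"),
               strand = vapply(out, `[[`, "", "strand"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
  }
  attr(df, "sourcePath") <- path
  df
}

#' Read gene models from a BED12 file
#'
#' Exons are reconstructed from the blockCount/blockSizes/blockStarts
#' columns; the thickStart/thickEnd span becomes the CDS (absent when
#' thickStart == thickEnd). The BED name column is the transcript id and
#' must resolve through `txMap`.
#'
#' @param source file path (optionally compressed) or connection.
#' @param txMap named character vector mapping transcript id -> gene id
#'   (see [readGeneTranscriptMap()]).
#' @return list of [GeneModel-class], named by transcript id (duplicates
#'   are preserved for the validator to flag).
#' @export
readBed12 <- function(source, txMap) {
  lines <- sourceLines(source)
  path <- attr(lines, "sourcePath")
  models <- list()
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (isSkippableLine(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L)
      validationError(sprintf("BED12 line must have 12 columns (found %d)",
                              length(f)), path, i)
    start <- parseIntField(f[2L]); end <- parseIntField(f[3L])
    thickStart <- parseIntField(f[7L]); thickEnd <- parseIntField(f[8L])
    blockCount <- parseIntField(f[10L])
    if (anyNA(c(start, end, thickStart, thickEnd, blockCount)))
      validationError("non-integer coordinates", path, i)
    if (start < 0L || start >= end)
      validationError("invalid chromStart/chromEnd", path, i)
    tx <- f[4L]
    strand <- parseStrand(f[6L], path, i)
    sizes <- parseIntField(strsplit(sub(",$", "", f[11L]), ",", fixed = TRUE)[[1L]])
    offs <- parseIntField(strsplit(sub(",$", "", f[12L]), ",", fixed = TRUE)[[1L]])
    if (anyNA(sizes) || anyNA(offs))
      validationError("non-integer blockSizes/blockStarts", path, i)
    if (length(sizes) != blockCount || length(offs) != blockCount)
      validationError(sprintf(
        "blockCount %d does not match blockSizes (%d) / blockStarts (%d)",
        blockCount, length(sizes), length(offs)), path, i)
    if (blockCount < 1L) validationError("blockCount must be >= 1", path, i)
    if (offs[1L] != 0L)
      validationError("first blockStart must be 0", path, i)
    exonStarts <- start + offs
    exonEnds <- exonStarts + sizes
    if (exonEnds[blockCount] != end)
      validationError("last block must end at chromEnd", path, i)
    if (any(sizes <= 0L))
      validationError("blockSizes must be positive", path, i)
    if (blockCount > 1L &&
        (is.unsorted(exonStarts, strictly = TRUE) ||
         any(exonStarts[-1L] < exonEnds[-blockCount])))
      validationError("blocks must be ascending and non-overlapping", path, i)
    if (any(exonStarts < start) || any(exonEnds > end))
      validationError("blocks must lie within [chromStart, chromEnd)", path, i)
    if (thickStart > thickEnd || thickStart < start || thickEnd > end)
      validationError("invalid thickStart/thickEnd", path, i)
    if (!tx %in% names(txMap))
      validationError(sprintf("transcript id '%s' absent from gene-transcript map",
                              tx), path, i)
    cds <- if (thickStart == thickEnd) c(NA_integer_, NA_integer_)
           else c(thickStart, thickEnd)
    models[[length(models) + 1L]] <-
      GeneModel(tx, unname(txMap[[tx]]), f[1L], strand, exonStarts, exonEnds,
                cds[1L], cds[2L])
  }
  names(models) <- vapply(models, transcriptId, "")
  attr(models, "sourcePath") <- path
  models
}

# split one GTF attribute column into a named character vector; accepts
# quoted and unquoted values, ignores unknown keys downstream
parseGtfAttributes <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  keys <- sub("\\s.*$", "", parts)
  vals <- sub("^\\S+\\s+", "", parts)
  vals <- gsub('^"|"$', "", vals)
  stats::setNames(vals, keys)
}

#' Read gene models from a GTF file
#'
#' Exon features are grouped by their `transcript_id` attribute; GTF's
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. CDS features, when present, define the CDS span
#' of their transcript.
#'
#' @inheritParams readBed6
#' @return list of [GeneModel-class], named by transcript id.
#' @export
readGtf <- function(source) {
  lines <- sourceLines(source)
  path <- attr(lines, "sourcePath")
  exons <- list(); cdss <- list()
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      validationError("GTF line needs 9 tab-separated columns", path, i)
    feature <- f[3L]
    if (!feature %in% c("exon", "CDS")) next
    s <- parseIntField(f[4L]); e <- parseIntField(f[5L])
    if (is.na(s) || is.na(e) || s < 1L || e < s)
      validationError("invalid GTF coordinates", path, i)
    attrs <- parseGtfAttributes(f[9L])
    if (!"transcript_id" %in% names(attrs))
      validationError(sprintf("%s feature lacks transcript_id attribute", feature),
                      path, i)
    if (!"gene_id" %in% names(attrs))
      validationError(sprintf("%s feature lacks gene_id attribute", feature),
                      path, i)
    rec <- list(chrom = f[1L], start = s - 1L, end = e,
                strand = parseStrand(f[7L], path, i),
                tx = attrs[["transcript_id"]], gene = attrs[["gene_id"]],
                line = i)
    if (feature == "exon") exons[[length(exons) + 1L]] <- rec
    else cdss[[length(cdss) + 1L]] <- rec
  }
  txIds <- unique(vapply(exons, `[[`, "", "tx"))
  models <- vector("list", length(txIds))
  for (k in seq_along(txIds)) {
    tx <- txIds[[k]]
    ex <- Filter(function(r) r$tx == tx, exons)
    chroms <- unique(vapply(ex, `[[`, "", "chrom"))
    strands <- unique(vapply(ex, `[[`, "", "strand"))
    genes <- unique(vapply(ex, `[[`, "", "gene"))
    if (length(chroms) > 1L || length(strands) > 1L)
      validationError(sprintf(
        "transcript '%s' has exons on mixed chromosomes or strands", tx),
        path, ex[[length(ex)]]$line)
    if (length(genes) > 1L)
      validationError(sprintf("transcript '%s' maps to multiple gene_ids", tx),
                      path, ex[[length(ex)]]$line)
    starts <- vapply(ex, `[[`, 0L, "start")
    ends <- vapply(ex, `[[`, 0L, "end")
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]
    if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))
      validationError(sprintf("transcript '%s' has overlapping exons", tx),
                      path, ex[[length(ex)]]$line)
    cd <- Filter(function(r) r$tx == tx, cdss)
    cds <- if (length(cd))
      c(min(vapply(cd, `[[`, 0L, "start")), max(vapply(cd, `[[`, 0L, "end")))
    else c(NA_integer_, NA_integer_)
    models[[k]] <- GeneModel(tx, genes, chroms, strands, starts, ends,
                             cds[1L], cds[2L])
  }
  names(models) <- txIds
  attr(models, "sourcePath") <- path
  models
}

#' Read a BEDGRAPH signal file into a CoverageTrack
#'
#' Runs are sorted per chromosome; overlapping runs and negative values
#' are rejected; zero-valued runs are dropped (they equal the implicit
#' background) and adjacent equal-valued runs merged.
#'
#' @inheritParams readBed6
#' @param name dataset label for the resulting track.
#' @return a [CoverageTrack-class].
#' @export
readBedgraph <- function(source, name = "track") {
  lines <- sourceLines(source)
  path <- attr(lines, "sourcePath")
  recs <- list()
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (isSkippableLine(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L)
      validationError("BEDGRAPH line needs 4 tab-separated columns", path, i)
    start <- parseIntField(f[2L]); end <- parseIntField(f[3L])
    if (is.na(start) || is.na(end))
      validationError("non-integer coordinates", path, i)
    if (start < 0L || start >= end)
      validationError("invalid interval", path, i)
    value <- suppressWarnings(as.numeric(f[4L]))
    if (is.na(value) || !is.finite(value))
      validationError(sprintf("invalid value '%s'", f[4L]), path, i)
    if (value < 0)
      validationError(sprintf("negative value %g", value), path, i)
    recs[[length(recs) + 1L]] <- list(chrom = f[1L], start = start, end = end,
                                      value = value, line = i)
  }
  chrom <- vapply(recs, `[[`, "", "chrom")
  start <- vapply(recs, `[[`, 0L, "start")
  end <- vapply(recs, `[[`, 0L, "end")
  value <- vapply(recs, `[[`, 0, "value")
  lineNo <- vapply(recs, `[[`, 0L, "line")
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ord <- idx[order(start[idx])]
    if (length(ord) > 1L) {
      ov <- which(start[ord][-1L] < end[ord][-length(ord)])
      if (length(ov))
        validationError(sprintf("overlapping runs on %s", ch),
                        path, lineNo[ord][ov[1L] + 1L])
    }
  }
  track <- CoverageTrack(name, chrom, start, end, value)
  attr(track@runs, "sourcePath") <- path
  track
}

#' Read per-transcript sequences from FASTA
#'
#' The record id is the first whitespace-delimited token of the header;
#' multi-line sequences are concatenated with case preserved. The alphabet
#' is restricted to A,C,G,T,U,N (case-insensitive).
#'
#' @inheritParams readBed6
#' @return named character vector of sequences, with a `sourcePath`
#'   attribute.
#' @export
readFastaSequences <- function(source) {
  lines <- sourceLines(source)
  path <- attr(lines, "sourcePath")
  ids <- character(0); seqs <- character(0); cur <- NULL; buf <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(buf, collapse = ""))
    }
  }
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (startsWith(line, ">")) {
      flush()
      cur <- strsplit(sub("^>", "", line), "\\s+")[[1L]][1L]
      if (is.na(cur) || !nzchar(cur))
        validationError("FASTA header without an id", path, i)
      buf <- character(0)
    } else if (nzchar(line)) {
      if (is.null(cur))
        validationError("sequence data before any FASTA header", path, i)
      if (grepl("[^ACGTUNacgtun]", line))
        validationError("sequence contains characters outside A,C,G,T,U,N",
                        path, i)
      buf <- c(buf, line)
    }
  }
  flush()
  if (anyDuplicated(ids))
    validationError(sprintf("duplicate FASTA id '%s'",
                            ids[duplicated(ids)][1L]), path)
  out <- stats::setNames(seqs, ids)
  attr(out, "sourcePath") <- path
  out
}

#' Read a TSV table with a header row
#'
#' Rows are keyed by `keyColumn` (name or index); duplicate keys are a
#' validation error. All values are kept as character.
#'
#' @inheritParams readBed6
#' @param keyColumn column holding the unique key (default: first).
#' @return data.frame of character columns with attributes `keyColumn`
#'   and `sourcePath`.
#' @export
readTsvTable <- function(source, keyColumn = 1L) {
  lines <- sourceLines(source)
  path <- attr(lines, "sourcePath")
  lines <- sub("\r$", "", unclass(lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) validationError("TSV file has no header row", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (is.character(keyColumn)) {
    keyIdx <- match(keyColumn, header)
    if (is.na(keyIdx))
      validationError(sprintf("key column '%s' not in header", keyColumn), path)
  } else keyIdx <- as.integer(keyColumn)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- length(header)
    f[is.na(f)] <- ""
    f
  })
  df <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (!nrow(df))
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- header
  keys <- df[[keyIdx]]
  if (anyDuplicated(keys))
    validationError(sprintf("duplicate key '%s' in column '%s'",
                            keys[duplicated(keys)][1L], header[keyIdx]), path)
  attr(df, "keyColumn") <- header[keyIdx]
  attr(df, "sourcePath") <- path
  df
}

#' Read a gene-transcript map TSV
#'
#' A two-column table (transcript id, gene id) as required alongside BED12
#' annotation.
#'
#' @inheritParams readBed6
#' @return named character vector: transcript id -> gene id.
#' @export
readGeneTranscriptMap <- function(source) {
  df <- readTsvTable(source, keyColumn = 1L)
  if (ncol(df) < 2L)
    validationError("gene-transcript map needs two columns",
                    attr(df, "sourcePath"))
  out <- stats::setNames(df[[2L]], df[[1L]])
  attr(out, "sourcePath") <- attr(df, "sourcePath")
  out
}

## writers ------------------------------------------------------------------

fmtNum <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write gene models as BED12
#' @param models list of [GeneModel-class].
#' @param path output path.
#' @export
writeBed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    sizes <- m@exonEnds - m@exonStarts
    offs <- m@exonStarts - m@start
    cds <- cdsSpan(m)
    thick <- if (is.null(cds)) c(m@start, m@start) else cds
    paste(m@chrom, m@start, m@end, m@transcriptId, 0,
          if (m@strand == "*") "." else m@strand,
          thick[1L], thick[2L], 0, length(sizes),
          paste(sizes, collapse = ","), paste(offs, collapse = ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write the gene-transcript map for a model list
#' @param models list of GeneModel.
#' @param path output path.
#' @export
writeGeneTranscriptMap <- function(models, path) {
  lines <- c("transcript\tgene",
             vapply(models, function(m)
               paste(m@transcriptId, m@geneId, sep = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as GTF (exon + CDS features)
#' @param models list of GeneModel.
#' @param path output path.
#' @export
writeGtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m@geneId,
                     m@transcriptId)
    strand <- if (m@strand == "*") "." else m@strand
    for (k in seq_along(m@exonStarts))
      lines <- c(lines, paste(m@chrom, "clipView", "exon",
                              m@exonStarts[k] + 1L, m@exonEnds[k], ".",
                              strand, ".", attrs, sep = "\t"))
    cds <- cdsSpan(m)
    if (!is.null(cds) && cds[2L] > cds[1L])
      lines <- c(lines, paste(m@chrom, "clipView", "CDS",
                              cds[1L] + 1L, cds[2L], ".", strand, "0", attrs,
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a CoverageTrack as BEDGRAPH
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @export
writeBedgraph <- function(track, path) {
  lines <- character(0)
  for (chrom in names(track@runs)) {
    r <- track@runs[[chrom]]
    if (nrow(r))
      lines <- c(lines, paste(chrom, r$start, r$end, fmtNum(r$value),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write annotated intervals as BED6
#' @param df data.frame with columns chrom,start,end,name,score,strand.
#' @param path output path.
#' @export
writeBed6 <- function(df, path) {
  score <- ifelse(is.na(df$score), ".", fmtNum(df$score))
  strand <- ifelse(df$strand == "*", ".", df$strand)
  writeLines(paste(df$chrom, df$start, df$end, df$name, score, strand,
                   sep = "\t"), path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a data.frame as TSV with header
#' @param df data.frame.
#' @param path output path.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

## minimal stored-entry zip writer ------------------------------------------
## Used by the fixture generator so that .zip reading is testable without
## shipping binary files or requiring a system zip tool.

crc32Table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L)) bitwXor(bitwShiftR(c, 1L), -306674912L)
               else bitwShiftR(c, 1L)
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(raw) {
  tab <- crc32Table()
  crc <- -1L
  for (b in as.integer(raw))
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

#' Write a single-member (stored, uncompressed) zip archive
#'
#' @param lines character vector of text lines for the member.
#' @param member member file name inside the archive.
#' @param path output `.zip` path.
#' @param nMembers number of members to write (values other than 1 produce
#'   deliberately degenerate archives for testing the single-member rule;
#'   0 writes an empty archive).
#' @export
writeZipSingle <- function(lines, member, path, nMembers = 1L) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  body <- raw(0); central <- raw(0); offset <- 0L
  if (nMembers > 0L) {
    for (k in seq_len(nMembers)) {
      nm <- charToRaw(if (nMembers == 1L) member
                      else sprintf("%d_%s", k, member))
      data <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
      crc <- crc32(data)
      localHdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0),
                    u16(0), u16(0), u16(0), u32(crc), u32(length(data)),
                    u32(length(data)), u16(length(nm)), u16(0), nm)
      central <- c(central,
                   as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20),
                   u16(0), u16(0), u16(0), u16(0), u32(crc),
                   u32(length(data)), u32(length(data)), u16(length(nm)),
                   u16(0), u16(0), u16(0), u16(0), u32(0L), u32(offset), nm)
      body <- c(body, localHdr, data)
      offset <- length(body)
    }
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(max(nMembers, 0L)), u16(max(nMembers, 0L)),
            u32(length(central)), u32(length(body)), u16(0))
  writeBin(c(body, central, eocd), path)
  invisible(path)
}
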