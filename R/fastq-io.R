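## FASTQ I/O: 4-line records, Phred+33 assumed throughout. Qualities are
## carried but never used for filtering, so they stay as ASCII strings.

.VALID_SEQ_RE <- "^[ACGTN]+$"

#' Open a chunked FASTQ reader
#'
#' Returns a closure that yields successive chunks of a FASTQ file as read
#' data frames, so arbitrarily large files can be processed with bounded
#' memory. Gzip compression is auto-detected from the magic bytes unless
#' `gzipped` is given.
#'
#' @param path Path to a FASTQ file, plain or gzip-compressed.
#' @param chunk_size Number of records per chunk (default 100000).
#' @param gzipped Logical; force (de)compression instead of sniffing the
#'   two-byte gzip magic number. Default `NULL` (auto-detect).
#' @return A function of no arguments. Each call returns a data frame with
#'   columns `read_id`, `sequence`, `quality` (Phred+33 string) holding up to
#'   `chunk_size` records, or `NULL` once the file is exhausted (the
#'   connection is then closed).
#' @details Records are validated as they are read: the header must start
#'   with `@`, the separator line with `+`, the sequence must be non-empty
#'   over `{A,C,G,T,N}` (lowercase is uppercased), and the quality string
#'   must match the sequence length. A violation raises an error naming the
#'   1-based record index.
#' @seealso [read_fastq()] for small files, [write_fastq()].
#' @export
fastq_reader <- function(path, chunk_size = 1e5, gzipped = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (is.null(gzipped)) gzipped <- .is_gzip(path)
  con <- if (gzipped) gzfile(path, "rt") else file(path, "rt")
  done <- FALSE
  rec_offset <- 0L
  finish <- function() {
    if (!done) {
      done <<- TRUE
      try(close(con), silent = TRUE)
    }
    invisible(NULL)
  }
  nxt <- function() {
    if (done) return(NULL)
    lines <- readLines(con, n = 4L * as.integer(chunk_size), warn = FALSE)
    if (length(lines) == 0L) {
      finish()
      return(NULL)
    }
    if (length(lines) %% 4L != 0L) {
      finish()
      stop("truncated FASTQ record at record index ",
           rec_offset + length(lines) %/% 4L + 1L, " in ", path)
    }
    chunk <- tryCatch(.parse_fastq_lines(lines, rec_offset, path),
                      error = function(e) { finish(); stop(e) })
    rec_offset <<- rec_offset + nrow(chunk)
    ## short read => EOF; close eagerly so callers need not drain
    if (nrow(chunk) < chunk_size) finish()
    chunk
  }
  attr(nxt, "close") <- finish
  nxt
}

.parse_fastq_lines <- function(lines, rec_offset, path) {
  n <- length(lines) %/% 4L
  idx <- 4L * (seq_len(n) - 1L)
  hdr <- lines[idx + 1L]
  seq <- toupper(lines[idx + 2L])
  sep <- lines[idx + 3L]
  qual <- lines[idx + 4L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ header (no '@') at record index ",
         rec_offset + bad[1L], " in ", path)
  bad <- which(!startsWith(sep, "+"))
  if (length(bad))
    stop("malformed FASTQ separator (no '+') at record index ",
         rec_offset + bad[1L], " in ", path)
  bad <- which(!grepl(.VALID_SEQ_RE, seq))
  if (length(bad))
    stop("empty or non-{A,C,G,T,N} sequence at record index ",
         rec_offset + bad[1L], " in ", path)
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad))
    stop("sequence/quality length mismatch at record index ",
         rec_offset + bad[1L], " in ", path)
  data.frame(read_id = sub("^@", "", hdr),
             sequence = seq,
             quality = qual,
             stringsAsFactors = FALSE)
}

.is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Read a FASTQ file into a data frame
#'
#' Convenience wrapper around [fastq_reader()] that materializes the whole
#' file. Suitable for libraries that fit in memory; use the reader directly
#' (or [tally_fastq()]) to stream larger files.
#'
#' @inheritParams fastq_reader
#' @param n Maximum number of records to read (default all).
#' @return Data frame with columns `read_id`, `sequence`, `quality`. An empty
#'   file yields a zero-row data frame.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "CCCTAACCCTAA", "+", "IIIIIIIIIIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, gzipped = NULL, n = Inf) {
  nxt <- fastq_reader(path, chunk_size = min(n, 1e5), gzipped = gzipped)
  on.exit(attr(nxt, "close")())
  out <- list()
  got <- 0
  while (got < n && !is.null(chunk <- nxt())) {
    if (got + nrow(chunk) > n) chunk <- chunk[seq_len(n - got), , drop = FALSE]
    got <- got + nrow(chunk)
    out[[length(out) + 1L]] <- chunk
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `read_id`, `sequence` and optionally
#'   `quality` (Phred+33 string; defaults to constant Q40, i.e. `"I"`).
#' @param path Output path.
#' @param gzip Compress the output with gzip (default `TRUE` when `path` ends
#'   in `.gz`).
#' @return The number of records written, invisibly. The output re-parses to
#'   an identical stream of (id, sequence, quality).
#' @export
write_fastq <- function(reads, path, gzip = grepl("\\.gz$", path)) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality
          else strrep("I", nchar(reads$sequence))
  if (any(nchar(qual) != nchar(reads$sequence)))
    stop("quality strings must match sequence lengths")
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0L) {
    lines <- character(4L * n)
    idx <- 4L * (seq_len(n) - 1L)
    lines[idx + 1L] <- paste0("@", reads$read_id)
    lines[idx + 2L] <- reads$sequence
    lines[idx + 3L] <- "+"
    lines[idx + 4L] <- qual
    writeLines(lines, con)
  }
  invisible(n)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}
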