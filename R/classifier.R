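## Strand classification by consecutive-repeat scanning. A read is telomeric
## when it contains the repeat unit concatenated k times as an exact
## contiguous substring; N never matches, and no reverse-complement search is
## performed because END-seq reads carry strand identity directly (the first
## sequenced base is the first base of the blunted end).

TELOMERE_UNIT_G <- "TTAGGG"
TELOMERE_UNIT_C <- "CCCTAA"

STRAND_CLASSES <- c("G_RICH", "C_RICH", "AMBIGUOUS", "NON_TELOMERIC")

#' Classifier parameters
#'
#' @param unit_g Repeat unit of the G-rich strand (default `TTAGGG`).
#' @param unit_c Repeat unit of the C-rich strand (default `CCCTAA`, the
#'   reverse complement of `unit_g`). Other unit pairs (e.g. a centromeric
#'   consensus) run through the same machinery.
#' @param min_repeats Minimum number of consecutive repeat units, `k`
#'   (default 4).
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(unit_g = TELOMERE_UNIT_G,
                              unit_c = TELOMERE_UNIT_C,
                              min_repeats = 4L) {
  stopifnot(nchar(unit_g) >= 1L, nchar(unit_c) >= 1L, min_repeats >= 1L)
  structure(list(unit_g = toupper(unit_g), unit_c = toupper(unit_c),
                 min_repeats = as.integer(min_repeats)),
            class = "classifier_params")
}

#' Find a run of k consecutive repeat units
#'
#' Tests whether each sequence contains the exact string `unit` concatenated
#' `k` times as a contiguous substring (any position; no mismatches; `N`
#' never matches).
#'
#' @param sequence Character vector of DNA sequences.
#' @param unit Repeat unit (e.g. `"TTAGGG"`).
#' @param k Minimum number of consecutive units.
#' @return A data frame with logical `found` and integer `start` (0-based
#'   position of the leftmost run, `NA` when absent).
#' @examples
#' has_repeat_run(strrep("TTAGGG", 4), "TTAGGG", 4)
#' @export
has_repeat_run <- function(sequence, unit, k) {
  stopifnot(nchar(unit) >= 1L, k >= 1L)
  pat <- strrep(toupper(unit), k)
  pos <- regexpr(pat, toupper(sequence), fixed = TRUE)
  found <- pos != -1L
  data.frame(found = found,
             start = ifelse(found, as.integer(pos) - 1L, NA_integer_))
}

#' Classify reads by telomeric strand
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `sequence` column (as returned by [read_fastq()]).
#' @param params A [classifier_params()] object.
#' @return Factor with levels `G_RICH`, `C_RICH`, `AMBIGUOUS`,
#'   `NON_TELOMERIC`. A read containing runs of both units is `AMBIGUOUS`;
#'   classification uses the sequenced orientation only.
#' @export
classify_reads <- function(reads, params = classifier_params()) {
  seqs <- .seqs(reads)
  g <- has_repeat_run(seqs, params$unit_g, params$min_repeats)$found
  c_ <- has_repeat_run(seqs, params$unit_c, params$min_repeats)$found
  cls <- rep("NON_TELOMERIC", length(seqs))
  cls[g & !c_] <- "G_RICH"
  cls[c_ & !g] <- "C_RICH"
  cls[g & c_] <- "AMBIGUOUS"
  factor(cls, levels = STRAND_CLASSES)
}

.seqs <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("sequence" %in% names(reads))
    reads$sequence
  } else as.character(reads)
}

#' Tally a library into strand counts
#'
#' Classifies every read and returns the per-library tallies with
#' reads-per-million (RPM) normalization against the total read count of the
#' library (telomeric and non-telomeric alike).
#'
#' @inheritParams classify_reads
#' @return A `strand_counts` object: counts `total_reads`, `g_rich`,
#'   `c_rich`, `ambiguous`, `non_telomeric`; normalized `rpm_g`, `rpm_c`; and
#'   the per-read classification factor in `$classes` for downstream stages.
#' @export
tally_library <- function(reads, params = classifier_params()) {
  cls <- classify_reads(reads, params)
  strand_counts(table(cls), classes = cls, params = params)
}

strand_counts <- function(tab, classes = NULL, params = NULL) {
  counts <- as.integer(tab[STRAND_CLASSES])
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  if (total == 0L)
    stop("empty library: RPM normalization is undefined for 0 reads")
  structure(list(total_reads = total,
                 g_rich = counts[1L], c_rich = counts[2L],
                 ambiguous = counts[3L], non_telomeric = counts[4L],
                 rpm_g = 1e6 * counts[1L] / total,
                 rpm_c = 1e6 * counts[2L] / total,
                 classes = classes, params = params),
            class = "strand_counts")
}

#' Tally a FASTQ library by streaming
#'
#' Streams a FASTQ file chunk by chunk, accumulating strand counts without
#' loading the whole library, and retaining only the telomeric reads for the
#' downstream terminal-end and VTR stages.
#'
#' @inheritParams fastq_reader
#' @param params A [classifier_params()] object.
#' @param keep_reads Which classified reads to retain (default the telomeric
#'   classes); set to `character()` to keep none.
#' @return A `strand_counts` object whose `$reads` element holds the retained
#'   reads (data frame with `read_id`, `sequence`, `quality`, `class`).
#' @export
tally_fastq <- function(path, params = classifier_params(), chunk_size = 1e5,
                        keep_reads = c("G_RICH", "C_RICH"), gzipped = NULL) {
  nxt <- fastq_reader(path, chunk_size = chunk_size, gzipped = gzipped)
  tab <- integer(0)
  kept <- list()
  while (!is.null(chunk <- nxt())) {
    cls <- classify_reads(chunk, params)
    t2 <- table(cls)
    tab <- if (length(tab)) tab + as.integer(t2[STRAND_CLASSES]) else
      as.integer(t2[STRAND_CLASSES])
    sel <- cls %in% keep_reads
    if (any(sel)) {
      sub <- chunk[sel, , drop = FALSE]
      sub$class <- as.character(cls[sel])
      kept[[length(kept) + 1L]] <- sub
    }
  }
  if (length(tab) == 0L)
    stop("empty library: RPM normalization is undefined for 0 reads")
  names(tab) <- STRAND_CLASSES
  sc <- strand_counts(tab, params = params)
  sc$reads <- if (length(kept)) do.call(rbind, kept) else NULL
  sc
}

#' @export
print.strand_counts <- function(x, ...) {
  cat("Strand counts (", x$total_reads, " reads)\n", sep = "")
  cat(sprintf("  G-rich:        %10d  (%.3f RPM)\n", x$g_rich, x$rpm_g))
  cat(sprintf("  C-rich:        %10d  (%.3f RPM)\n", x$c_rich, x$rpm_c))
  cat(sprintf("  ambiguous:     %10d\n", x$ambiguous))
  cat(sprintf("  non-telomeric: %10d\n", x$non_telomeric))
  tel <- x$g_rich + x$c_rich
  if (tel > 0)
    cat(sprintf("  C-strand fraction (C/(C+G)): %.4f\n", x$c_rich / tel))
  invisible(x)
}

#' @export
as.data.frame.strand_counts <- function(x, ...) {
  data.frame(total_reads = x$total_reads, g_rich = x$g_rich,
             c_rich = x$c_rich, ambiguous = x$ambiguous,
             non_telomeric = x$non_telomeric,
             rpm_g = x$rpm_g, rpm_c = x$rpm_c)
}
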