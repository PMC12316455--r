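## The 5'-terminal hexamer of the chromosome's C-rich strand. Because the
## first sequenced base of an END-seq read is the first base of the blunted
## end, a C-rich read's first six bases ARE the chromosome terminus read
## inward; reversing them gives the field's "-5'" display convention, where
## the canonical terminus reads CCAATC-5' (terminal trinucleotide ATC-5').

#' The six terminal-hexamer categories
#'
#' The six cyclic rotations of the C-strand repeat `CCCTAA`, each written
#' reversed (3'→5' left-to-right toward the terminus). `CCAATC` is the
#' canonical chromosome 5' end; an `OTHER` bin absorbs hexamers that match no
#' rotation (sequencing error, adapter remnants, N bases).
#'
#' @format Character vector of length 6, canonical label first.
#' @export
END_CATEGORIES <- c("CCAATC", "CAATCC", "AATCCC", "ATCCCA", "TCCCAA", "CCCAAT")

#' Members of the display-only "Rest" grouping
#' @format Character vector of length 3.
#' @export
REST_CATEGORIES <- c("CCCAAT", "TCCCAA", "ATCCCA")

.revstr <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

## rotations of CCCTAA such that reverse(rotation) enumerates END_CATEGORIES;
## a read whose prefix is .READ_PREFIXES[i] has terminal category END_CATEGORIES[i]
.READ_PREFIXES <- .revstr(END_CATEGORIES)

#' Extract the chromosome-terminal hexamer category of C-rich reads
#'
#' Takes the first six bases of each read (the chromosome 5' terminus under
#' the END-seq orientation guarantee), reverses them, and matches against the
#' six cyclic-permutation labels.
#'
#' @param reads Character vector of C-rich read sequences (or a data frame
#'   with a `sequence` column). All reads must be at least 6 nt long.
#' @return Factor over [END_CATEGORIES] plus `OTHER`.
#' @examples
#' terminal_hexamer("CTAACCCTAACCCTAACC")  # canonical CCAATC
#' @export
terminal_hexamer <- function(reads) {
  seqs <- .seqs(reads)
  if (length(seqs) == 0L) stop("no reads supplied")
  if (any(nchar(seqs) < 6L)) stop("all reads must be at least 6 nt long")
  hex <- .revstr(substr(toupper(seqs), 1L, 6L))
  hex[!hex %in% END_CATEGORIES] <- "OTHER"
  factor(hex, levels = c(END_CATEGORIES, "OTHER"))
}

#' Terminal-hexamer distribution of a C-rich library
#'
#' @inheritParams terminal_hexamer
#' @return An `end_distribution` object: `counts` and `frequencies` over the
#'   six permutations plus `OTHER` (frequencies sum to 1 across all bins),
#'   `n_reads`, and the display grouping `rest` (summed frequency of
#'   [REST_CATEGORIES]).
#' @export
end_distribution <- function(reads) {
  cat <- if (is.factor(reads) &&
             identical(levels(reads), c(END_CATEGORIES, "OTHER"))) reads
         else terminal_hexamer(reads)
  counts <- table(cat)
  n <- sum(counts)
  if (n == 0L) stop("no reads supplied")
  freq <- as.numeric(counts) / n
  names(freq) <- names(counts)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 frequencies = freq,
                 n_reads = as.integer(n),
                 rest = sum(freq[REST_CATEGORIES])),
            class = "end_distribution")
}

#' @export
print.end_distribution <- function(x, ...) {
  cat("Terminal-hexamer distribution (", x$n_reads, " C-rich reads)\n", sep = "")
  for (lab in names(x$counts))
    cat(sprintf("  %-6s-5': %8d  (%6.2f%%)\n", lab, x$counts[[lab]],
                100 * x$frequencies[[lab]]))
  cat(sprintf("  Rest (CCCAAT+TCCCAA+ATCCCA): %.2f%%\n", 100 * x$rest))
  invisible(x)
}

#' @export
as.data.frame.end_distribution <- function(x, ...) {
  data.frame(category = names(x$counts),
             count = as.integer(x$counts),
             frequency = as.numeric(x$frequencies))
}

#' Per-position information content of the terminal hexamer
#'
#' For each of the six terminal positions (terminal-most first, i.e. read
#' base 1 first), computes the information content
#' `bits = 2 - H`, where `H = -sum(f_b * log2(f_b))` over the observed
#' A/C/G/T frequencies at that position; `N` bases are skipped per position.
#' This is the per-column height of a standard sequence logo, without
#' small-sample correction.
#'
#' @inheritParams terminal_hexamer
#' @return An `information_profile` object: `bits` (numeric length 6, each in
#'   `[0, 2]`) and the 4 x 6 base-frequency matrix `base_freq`.
#' @export
position_information <- function(reads) {
  seqs <- .seqs(reads)
  if (length(seqs) == 0L) stop("no reads supplied")
  if (any(nchar(seqs) < 6L)) stop("all reads must be at least 6 nt long")
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, nrow = 4L, ncol = 6L, dimnames = list(bases, NULL))
  for (i in 1:6) {
    b <- substr(toupper(seqs), i, i)
    tab <- table(factor(b[b %in% bases], levels = bases))
    if (sum(tab) == 0L) stop("position ", i, " has no unambiguous bases")
    m[, i] <- as.numeric(tab) / sum(tab)
  }
  ent <- apply(m, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(bits = 2 - ent, base_freq = m),
            class = "information_profile")
}

#' @export
print.information_profile <- function(x, ...) {
  cat("Per-position information content (terminal-most first):\n")
  cat(sprintf("  position %d: %.3f bits\n", 1:6, x$bits), sep = "")
  invisible(x)
}

#' @export
plot.information_profile <- function(x, ...) {
  graphics::barplot(x$bits, names.arg = 1:6, ylim = c(0, 2),
                    xlab = "terminal position (5' terminus first)",
                    ylab = "information (bits)", ...)
  invisible(x)
}
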