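## Variant telomeric repeats (VTRs) within the first W nucleotides of
## telomeric reads. Counting is unit-level: within the window, tile complete
## hexamer units starting at the phase offset (0..5) that maximizes exact
## canonical matches for that read, so a terminal phase shift does not flag
## every unit; any tiled unit differing from the canonical unit in >= 1
## position is a variant. Units containing N are excluded from numerator and
## denominator alike.

#' Variant telomeric repeat frequency within a 5'-proximal window
#'
#' @param reads Character vector of telomeric read sequences, or a data
#'   frame with `sequence` (and optionally `class`) columns.
#' @param class Strand class per read (`"C_RICH"` or `"G_RICH"`), recycled
#'   if length 1; taken from `reads$class` when present. Determines the
#'   canonical unit (`CCCTAA` for C-rich, `TTAGGG` for G-rich).
#' @param window Window size `W` in nucleotides from the read 5' end; must
#'   be a positive multiple of 6 (default 30, i.e. 5 tiled units at offset
#'   0).
#' @return A `vtr_result` list: `units_total`, `units_variant`, `frequency`
#'   (`units_variant / units_total`), and `reads_skipped` (reads shorter
#'   than `window`, skipped without error).
#' @examples
#' vtr_frequency(strrep("CCCTAA", 13), class = "C_RICH")
#' @export
vtr_frequency <- function(reads, class = NULL, window = 30L) {
  if (window < 6L || window %% 6L != 0L)
    stop("window must be a positive multiple of 6")
  seqs <- toupper(.seqs(reads))
  if (is.null(class)) {
    if (is.data.frame(reads) && "class" %in% names(reads)) class <- reads$class
    else stop("strand class must be supplied (or present as reads$class)")
  }
  class <- as.character(class)
  if (length(class) == 1L) class <- rep(class, length(seqs))
  stopifnot(length(class) == length(seqs),
            all(class %in% c("C_RICH", "G_RICH")))
  skip <- nchar(seqs) < window
  seqs <- substr(seqs[!skip], 1L, window)
  class <- class[!skip]
  units_total <- 0L
  units_variant <- 0L
  for (cl in unique(class)) {
    unit <- if (cl == "C_RICH") TELOMERE_UNIT_C else TELOMERE_UNIT_G
    res <- .vtr_count(seqs[class == cl], unit, window)
    units_total <- units_total + res[["total"]]
    units_variant <- units_variant + res[["variant"]]
  }
  structure(list(units_total = units_total,
                 units_variant = units_variant,
                 frequency = if (units_total > 0)
                   units_variant / units_total else NA_real_,
                 reads_skipped = sum(skip),
                 window = as.integer(window)),
            class = "vtr_result")
}

## per-offset tiling over a window: offsets 0..5, floor((W - off)/6)
## complete units each
.vtr_count <- function(seqs, unit, window) {
  if (length(seqs) == 0L) return(c(total = 0L, variant = 0L))
  ## units per offset as a list of character matrices (reads x tiles)
  per_offset <- lapply(0:5, function(off) {
    n_tiles <- (window - off) %/% 6L
    if (n_tiles == 0L) return(NULL)
    starts <- off + 6L * (seq_len(n_tiles) - 1L) + 1L
    vapply(starts, function(s) substr(seqs, s, s + 5L),
           character(length(seqs)))
  })
  match_mat <- matrix(vapply(per_offset, function(m) {
    if (is.null(m)) return(rep(0L, length(seqs)))
    as.integer(rowSums(matrix(m == unit, nrow = length(seqs))))
  }, integer(length(seqs))), nrow = length(seqs))
  best <- max.col(match_mat, ties.method = "first") # smallest offset on ties
  total <- 0L
  variant <- 0L
  for (off in sort(unique(best))) {
    sel <- best == off
    m <- matrix(per_offset[[off]], nrow = length(seqs))[sel, , drop = FALSE]
    ok <- !grepl("N", m, fixed = TRUE)          # N units leave both tallies
    total <- total + sum(ok)
    variant <- variant + sum(ok & m != unit)
  }
  c(total = total, variant = variant)
}

#' @export
print.vtr_result <- function(x, ...) {
  cat(sprintf(
    "VTR scan (first %d nt): %d/%d variant units (%.3f%%); %d reads skipped\n",
    x$window, x$units_variant, x$units_total,
    100 * if (is.na(x$frequency)) 0 else x$frequency, x$reads_skipped))
  invisible(x)
}

#' @export
as.data.frame.vtr_result <- function(x, ...) {
  data.frame(units_total = x$units_total, units_variant = x$units_variant,
             frequency = x$frequency, reads_skipped = x$reads_skipped)
}
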