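## End-counting model for S1-END-seq. Every chromosome end contributes one
## C-readable end (the natural terminus); every S1 cut of an internal ssDNA
## region contributes one C-readable and one G-readable end. With n internal
## ssDNA regions per chromosome end, the expected C-strand read fraction is
## f = (n + 1) / (2n + 1); inverting gives n = (1 - f) / (2f - 1). Because
## capture/sequencing losses can only hide ends, the inversion is reported as
## a MINIMUM (ceiling, not rounding).

#' C-strand read fraction of a library
#'
#' @param counts A `strand_counts` object (see [tally_library()]), or a list
#'   with `c_rich` and `g_rich` counts. Ambiguous reads are excluded from the
#'   denominator.
#' @return `f = c_rich / (c_rich + g_rich)` in `[0, 1]`.
#' @export
c_strand_fraction <- function(counts) {
  cc <- counts$c_rich
  gg <- counts$g_rich
  if (is.null(cc) || is.null(gg)) stop("counts must provide c_rich and g_rich")
  if (cc + gg <= 0) stop("no telomeric reads: C-strand fraction is undefined")
  cc / (cc + gg)
}

#' Minimum number of internal ssDNA regions per chromosome end
#'
#' Inverts the end-counting model `f = (n + 1) / (2n + 1)` at an observed
#' C-strand fraction `f`, returning the real-valued solution
#' `n_raw = (1 - f) / (2f - 1)` and its ceiling `n_min`, a lower bound on the
#' number of internal single-stranded regions per chromosome end.
#'
#' @param f C-strand read fraction, in `(0.5, 1]` (see
#'   [c_strand_fraction()]). A fraction at or below 0.5 violates the
#'   one-ended-terminus assumption (it would require infinitely many cuts)
#'   and raises an error.
#' @param alt_thresholds Passed to [classify_alt_status()].
#' @return An `ssdna_estimate` object: `f`, `n_raw`, `n_min`, `alt_call`.
#' @examples
#' min_ssdna_regions(0.55)  # n_raw = 4.5 -> minimum 5 regions
#' min_ssdna_regions(0.70)  # n_raw = 0.75 -> minimum 1 region
#' @export
min_ssdna_regions <- function(f, alt_thresholds = c(alt_positive = 0.58,
                                                    alt_negative = 0.98)) {
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("f must be a single fraction in [0, 1]")
  if (f <= 0.5)
    stop("C-strand fraction f = ", format(f), " <= 0.5 violates the ",
         "one-ended counting model (cut count is unbounded); the library is ",
         "not consistent with one natural C-readable terminus per end")
  n_raw <- (1 - f) / (2 * f - 1)
  ## tolerance absorbs floating-point error so model-exact fractions
  ## f = (n+1)/(2n+1) invert to exactly n
  n_min <- max(0, ceiling(n_raw - 1e-9))
  structure(list(f = f, n_raw = n_raw, n_min = as.integer(n_min),
                 alt_call = classify_alt_status(f, alt_thresholds),
                 alt_thresholds = alt_thresholds,
                 assumptions = "equal capture efficiency of C- and G-readable ends"),
            class = "ssdna_estimate")
}

#' Call ALT status from the C-strand fraction
#'
#' ALT-positive cell lines show near-balanced C/G telomeric reads in
#' S1-END-seq (fractions of roughly 0.4-0.58), whereas ALT-negative lines
#' are almost purely C-strand (0.98-0.99). The default thresholds are the
#' boundaries of those observed ranges.
#'
#' @param f C-strand read fraction in `[0, 1]`.
#' @param thresholds Named pair: `alt_positive` ceiling (call ALT-positive
#'   when `f <=` it) and `alt_negative` floor (ALT-negative when `f >=` it).
#' @return One of `"ALT_positive"`, `"ALT_negative"`, `"indeterminate"`.
#' @export
classify_alt_status <- function(f, thresholds = c(alt_positive = 0.58,
                                                  alt_negative = 0.98)) {
  stopifnot(all(c("alt_positive", "alt_negative") %in% names(thresholds)),
            thresholds[["alt_positive"]] < thresholds[["alt_negative"]])
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  ifelse(f <= thresholds[["alt_positive"]], "ALT_positive",
         ifelse(f >= thresholds[["alt_negative"]], "ALT_negative",
                "indeterminate"))
}

#' @export
print.ssdna_estimate <- function(x, ...) {
  cat(sprintf("C-strand read fraction f = %.4f\n", x$f))
  cat(sprintf("Model inversion n = (1 - f)/(2f - 1) = %.4f\n", x$n_raw))
  cat(sprintf("Minimum internal ssDNA regions per chromosome end: %d\n",
              x$n_min))
  cat("ALT call:", x$alt_call, "\n")
  invisible(x)
}

#' @export
as.data.frame.ssdna_estimate <- function(x, ...) {
  data.frame(f = x$f, n_raw = x$n_raw, n_min = x$n_min, alt_call = x$alt_call)
}
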