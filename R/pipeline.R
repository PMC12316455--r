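## Consolidated per-library report: classify -> terminal ends -> mixture ->
## ssDNA inversion -> VTR, with structured "insufficient data" statuses when
## a stage cannot run (e.g. no telomeric reads).

#' Run the full analysis pipeline on one library
#'
#' Executes, in order: strand classification and tallying, terminal-hexamer
#' distribution and information content, canonical-fraction estimation by KL
#' grid matching, the ssDNA end-counting inversion with ALT call, and the
#' VTR scan. Stages that cannot run on the given library (no C-rich reads,
#' C-strand fraction at or below 0.5, ...) are reported with a structured
#' status instead of failing the pipeline.
#'
#' @param input Path to a FASTQ file (plain or gzip), or a data frame of
#'   reads with a `sequence` column (e.g. from [read_fastq()] or
#'   [simulate_library()]).
#' @param params A [classifier_params()].
#' @param vtr_window Window for [vtr_frequency()] (default 30).
#' @param grid_step,epsilon Passed to [estimate_canonical_fraction()] /
#'   [kl_divergence()].
#' @param alt_thresholds Passed to [classify_alt_status()].
#' @param chunk_size Records per chunk when `input` is a path.
#' @return A `teloend_report`: `strand_counts`, `end_distribution`,
#'   `information`, `mixture`, `ssdna`, `vtr`, `status` (named character;
#'   `"ok"` or the reason a stage was skipped) and `provenance`.
#' @export
run_pipeline <- function(input,
                         params = classifier_params(),
                         vtr_window = 30L,
                         grid_step = 0.01,
                         epsilon = 1e-9,
                         alt_thresholds = c(alt_positive = 0.58,
                                            alt_negative = 0.98),
                         chunk_size = 1e5) {
  if (is.character(input) && length(input) == 1L) {
    sc <- tally_fastq(input, params = params, chunk_size = chunk_size)
    tel <- sc$reads
    source_desc <- input
  } else {
    sc <- tally_library(input, params = params)
    keep <- sc$classes %in% c("C_RICH", "G_RICH")
    tel <- data.frame(sequence = .seqs(input)[keep],
                      class = as.character(sc$classes[keep]),
                      stringsAsFactors = FALSE)
    source_desc <- "<in-memory reads>"
  }
  status <- c(ends = "ok", mixture = "ok", ssdna = "ok", vtr = "ok")
  c_reads <- if (!is.null(tel)) tel$sequence[tel$class == "C_RICH"]
             else character(0)

  ends <- info <- mixture <- NULL
  if (length(c_reads) > 0L && all(nchar(c_reads) >= 6L)) {
    ends <- end_distribution(c_reads)
    info <- position_information(c_reads)
    mixture <- estimate_canonical_fraction(ends, grid_step = grid_step,
                                           epsilon = epsilon)
  } else {
    status[c("ends", "mixture")] <- "insufficient data: no C-rich reads"
  }

  ssdna <- NULL
  if (sc$c_rich + sc$g_rich == 0L) {
    status["ssdna"] <- "insufficient data: no telomeric reads"
  } else {
    f <- c_strand_fraction(sc)
    if (f <= 0.5) {
      status["ssdna"] <- sprintf(
        "model violation: C-strand fraction %.4f <= 0.5", f)
    } else {
      ssdna <- min_ssdna_regions(f, alt_thresholds = alt_thresholds)
    }
  }

  vtr <- NULL
  if (!is.null(tel) && nrow(tel) > 0L) {
    vtr <- vtr_frequency(tel, window = vtr_window)
  } else {
    status["vtr"] <- "insufficient data: no telomeric reads"
  }

  structure(list(strand_counts = sc,
                 end_distribution = ends,
                 information = info,
                 mixture = mixture,
                 ssdna = ssdna,
                 vtr = vtr,
                 status = status,
                 provenance = list(
                   input = source_desc,
                   params = unclass(params),
                   vtr_window = as.integer(vtr_window),
                   grid_step = grid_step, epsilon = epsilon,
                   alt_thresholds = as.list(alt_thresholds),
                   kl_direction = "D(sample || reference)",
                   package_version = as.character(
                     utils::packageVersion("teloend")))),
            class = "teloend_report")
}

#' @export
print.teloend_report <- function(x, ...) {
  cat("== teloend pipeline report ==\n")
  print(x$strand_counts)
  for (stage in names(x$status))
    if (x$status[[stage]] != "ok")
      cat(sprintf("  [%s] %s\n", stage, x$status[[stage]]))
  if (!is.null(x$end_distribution)) print(x$end_distribution)
  if (!is.null(x$mixture)) print(x$mixture)
  if (!is.null(x$ssdna)) print(x$ssdna)
  if (!is.null(x$vtr)) print(x$vtr)
  invisible(x)
}

#' @export
summary.teloend_report <- function(object, ...) {
  sc <- object$strand_counts
  data.frame(
    total_reads = sc$total_reads, g_rich = sc$g_rich, c_rich = sc$c_rich,
    rpm_g = sc$rpm_g, rpm_c = sc$rpm_c,
    canonical_frequency = if (!is.null(object$end_distribution))
      object$end_distribution$frequencies[["CCAATC"]] else NA_real_,
    p_hat = if (!is.null(object$mixture)) object$mixture$p_hat else NA_real_,
    f = if (!is.null(object$ssdna)) object$ssdna$f else NA_real_,
    n_min_ssdna = if (!is.null(object$ssdna)) object$ssdna$n_min else NA_integer_,
    alt_call = if (!is.null(object$ssdna)) object$ssdna$alt_call else NA_character_,
    vtr_frequency = if (!is.null(object$vtr)) object$vtr$frequency else NA_real_)
}

#' Write a pipeline report to disk
#'
#' Writes the consolidated JSON report plus TSV tables (strand counts,
#' terminal-category distribution with the display-only `Rest` grouping,
#' per-position base frequencies and bits, mixture profile, ssDNA estimate,
#' VTR counts).
#'
#' @param report A `teloend_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param name Basename prefix for the output files.
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(report, dir, name = "library") {
  stopifnot(inherits(report, "teloend_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  out <- function(fn) file.path(dir, paste0(name, ".", fn))
  tsv <- function(df, fn) {
    utils::write.table(df, out(fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, out(fn))
  }
  tsv(as.data.frame(report$strand_counts), "strand_counts.tsv")
  if (!is.null(report$end_distribution)) {
    df <- as.data.frame(report$end_distribution)
    df <- rbind(df, data.frame(category = "Rest", count = NA_integer_,
                               frequency = report$end_distribution$rest))
    tsv(df, "end_categories.tsv")
  }
  if (!is.null(report$information)) {
    ip <- report$information
    df <- data.frame(position = 1:6, bits = ip$bits,
                     t(ip$base_freq))
    names(df)[3:6] <- paste0("freq_", rownames(ip$base_freq))
    tsv(df, "information.tsv")
  }
  if (!is.null(report$mixture)) tsv(report$mixture$profile, "mixture_profile.tsv")
  if (!is.null(report$ssdna)) tsv(as.data.frame(report$ssdna), "ssdna.tsv")
  if (!is.null(report$vtr)) tsv(as.data.frame(report$vtr), "vtr.tsv")

  js <- list(
    strand_counts = as.data.frame(report$strand_counts),
    end_distribution = if (!is.null(report$end_distribution)) list(
      counts = as.list(report$end_distribution$counts),
      frequencies = as.list(report$end_distribution$frequencies),
      rest = report$end_distribution$rest,
      n_reads = report$end_distribution$n_reads),
    information_bits = if (!is.null(report$information))
      report$information$bits,
    mixture = if (!is.null(report$mixture)) list(
      p_hat = report$mixture$p_hat, kl_at_min = report$mixture$kl_at_min,
      grid_step = report$mixture$grid_step),
    ssdna = if (!is.null(report$ssdna)) list(
      f = report$ssdna$f, n_raw = report$ssdna$n_raw,
      n_min = report$ssdna$n_min, alt_call = report$ssdna$alt_call,
      thresholds = as.list(report$ssdna$alt_thresholds)),
    vtr = if (!is.null(report$vtr)) as.data.frame(report$vtr),
    status = as.list(report$status),
    provenance = report$provenance)
  jf <- out("report.json")
  jsonlite::write_json(js, jf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  written <- c(written, jf)
  invisible(written)
}
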