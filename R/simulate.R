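## Parametric simulator of END-seq / S1-END-seq telomere libraries.
##
## Model: each chromosome end carries a pure-repeat telomeric tract of
## uniformly drawn length whose C-strand 5' terminus sits at one of the six
## rotational phases of CCCTAA. The natural terminus yields one C-strand
## read starting at the terminal base (so its prefix is the reversed
## terminal category, e.g. CTAACC... for the canonical CCAATC-5' end). Each
## internal cut (S1 cleavage of an ssDNA region, or a nuclease-induced DSB)
## yields one C-strand read on the centromere-proximal fragment and one
## G-strand read on the terminus-proximal fragment. Fragments shorter than
## min_fragment are lost to size selection and yield no reads. Variant
## repeat units are substituted at the repeat phase of each read; per-base
## substitution errors and uniform-random background reads complete the
## library. Reads are sequenced strictly from the end inward.

## C-strand variant units (reverse complements of the common G-strand
## variants TCAGGG, TGAGGG, TTGGGG)
VTR_UNITS_C <- c("CCCTGA", "CCCTCA", "CCCCAA")

#' Simulation parameters for a synthetic telomere library
#'
#' Defaults emulate an untreated telomerase-positive END-seq library:
#' 5-15 kb telomeric tracts, 75-bp reads, ~70% canonical `CCAATC-5'`
#' termini with the remainder uniformly randomized over the six rotations,
#' a 2% per-unit variant-repeat rate, no internal cuts, and half the
#' library made of non-telomeric background reads.
#'
#' @param n_telomeres Number of chromosome ends simulated.
#' @param telomere_length Length range in bp; tract lengths are drawn
#'   uniformly from `[min, max]` (default `c(5000, 15000)`).
#' @param p_canonical Probability that a terminus retains the canonical
#'   phase (before the uniform-rotation remainder, which also lands on the
#'   canonical phase 1/6 of the time): the expected canonical category
#'   frequency is `p + (1 - p)/6`, matching [mixture_distribution()].
#' @param terminal_randomization `"uniform_rotation"` (non-canonical termini
#'   uniform over the six phases; models POT1 depletion or 5'→3' exonuclease
#'   resection) or `"none"` (every terminus canonical, ignoring
#'   `p_canonical`).
#' @param mode `"endseq"` or `"s1"`; recorded in the truth sidecar. Internal
#'   cuts behave identically in both (blunt DSBs are sequenced two-endedly
#'   either way); in `endseq` mode cuts model nuclease-induced breaks, in
#'   `s1` mode S1-cleaved ssDNA regions.
#' @param cuts_per_telomere Internal cuts per telomere: a fixed count when
#'   `cuts_law = "fixed"`, or a Poisson mean when `cuts_law = "poisson"`.
#' @param cuts_law `"fixed"` or `"poisson"`.
#' @param vtr_rate Per-unit probability that a repeat unit is replaced by a
#'   variant unit.
#' @param vtr_alphabet C-strand variant units (G-strand reads use their
#'   reverse complements).
#' @param background_fraction Fraction of the final library that is uniform
#'   random non-telomeric sequence, in `[0, 1)`.
#' @param read_length Read length in bp (default 75).
#' @param error_rate Per-base substitution error probability.
#' @param min_fragment Minimum readable fragment length in bp (default 36);
#'   shorter fragments are dropped by size selection.
#' @param g_capture_efficiency Probability that a G-readable end yields a
#'   read (default 1, i.e. equal capture of C- and G-readable ends).
#' @param seed Integer seed; the same config is guaranteed to reproduce the
#'   same library byte for byte.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_telomeres = 1000L,
                              telomere_length = c(5000L, 15000L),
                              p_canonical = 0.7,
                              terminal_randomization = c("uniform_rotation",
                                                         "none"),
                              mode = c("endseq", "s1"),
                              cuts_per_telomere = 0,
                              cuts_law = c("fixed", "poisson"),
                              vtr_rate = 0.02,
                              vtr_alphabet = VTR_UNITS_C,
                              background_fraction = 0.5,
                              read_length = 75L,
                              error_rate = 0,
                              min_fragment = 36L,
                              g_capture_efficiency = 1,
                              seed = 1L) {
  terminal_randomization <- match.arg(terminal_randomization)
  mode <- match.arg(mode)
  cuts_law <- match.arg(cuts_law)
  cfg <- list(n_telomeres = as.integer(n_telomeres),
              telomere_length = as.integer(telomere_length),
              p_canonical = p_canonical,
              terminal_randomization = terminal_randomization,
              mode = mode,
              cuts_per_telomere = cuts_per_telomere,
              cuts_law = cuts_law,
              vtr_rate = vtr_rate,
              vtr_alphabet = toupper(vtr_alphabet),
              background_fraction = background_fraction,
              read_length = as.integer(read_length),
              error_rate = error_rate,
              min_fragment = as.integer(min_fragment),
              g_capture_efficiency = g_capture_efficiency,
              seed = as.integer(seed))
  bad <- character(0)
  chk <- function(ok, field) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk(cfg$n_telomeres >= 1L, "n_telomeres")
  chk(length(cfg$telomere_length) == 2L &&
        cfg$telomere_length[1L] <= cfg$telomere_length[2L] &&
        cfg$telomere_length[1L] >= cfg$min_fragment, "telomere_length")
  chk(is.finite(p_canonical) && p_canonical >= 0 && p_canonical <= 1,
      "p_canonical")
  chk((cuts_law == "fixed" && cuts_per_telomere >= 0 &&
         cuts_per_telomere == round(cuts_per_telomere)) ||
        (cuts_law == "poisson" && cuts_per_telomere >= 0),
      "cuts_per_telomere")
  chk(vtr_rate >= 0 && vtr_rate <= 1, "vtr_rate")
  chk(all(nchar(cfg$vtr_alphabet) == 6L) &&
        !any(cfg$vtr_alphabet == TELOMERE_UNIT_C), "vtr_alphabet")
  chk(background_fraction >= 0 && background_fraction < 1,
      "background_fraction")
  chk(cfg$read_length >= 6L, "read_length")
  chk(error_rate >= 0 && error_rate <= 1, "error_rate")
  chk(cfg$min_fragment >= 1L, "min_fragment")
  chk(g_capture_efficiency >= 0 && g_capture_efficiency <= 1,
      "g_capture_efficiency")
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "simulation_config")
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""),
         function(ch) paste(rev(unname(.COMP[ch])), collapse = ""), "")
}

## periodic template starting at phase r (0-based) of `unit`, long enough
## for any read
.phase_templates <- function(unit, max_len) {
  reps <- strrep(unit, ceiling((max_len + 6L) / 6L))
  vapply(0:5, function(r) substr(reps, r + 1L, r + max_len), "")
}

#' Simulate an END-seq or S1-END-seq telomere library
#'
#' Generates reads under the end-counting model (see [min_ssdna_regions()])
#' together with a ground-truth sidecar holding the generating parameters,
#' the per-telomere truth (tract length, terminal phase, cut positions) and
#' the emitted read counts, so recovery tests can compare pipeline output
#' with closed-form expectations via [describe_truth()].
#'
#' @param config A [simulation_config()].
#' @param fastq_path Optional path; when given, reads are also written as
#'   FASTQ (gzip-compressed when the path ends in `.gz`) and the sidecar as
#'   JSON next to it (`<path>.truth.json`).
#' @return Invisible list with `reads` (data frame `read_id`, `sequence`,
#'   `quality`, `source`), `truth` (the sidecar), and `fastq_path`.
#' @details All randomness derives from `config$seed`; the caller's RNG
#'   state is left untouched. Qualities are constant Q40. Reads are emitted
#'   in shuffled order.
#' @export
simulate_library <- function(config = simulation_config(), fastq_path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_telomeres
  rl <- config$read_length
  L <- sample.int(config$telomere_length[2L] - config$telomere_length[1L] + 1L,
                  n, replace = TRUE) + config$telomere_length[1L] - 1L

  ## terminal phase r in 0..5 over CCCTAA, chosen so that positions 0..5 of
  ## the C strand read CTAACC... when canonical (phase 2 of CCCTAA)
  canon_phase <- 2L
  phases <- 0:5
  if (config$terminal_randomization == "none") {
    r <- rep(canon_phase, n)
  } else {
    canonical <- stats::runif(n) < config$p_canonical
    r <- ifelse(canonical, canon_phase, sample(phases, n, replace = TRUE))
  }

  k <- switch(config$cuts_law,
              fixed = rep(as.integer(config$cuts_per_telomere), n),
              poisson = stats::rpois(n, config$cuts_per_telomere))
  ## cuts only fit where [min_fragment, L - min_fragment] is non-empty
  k[L < 2L * config$min_fragment] <- 0L
  cuts <- vector("list", n)
  has <- which(k > 0L)
  for (i in has) {
    lo <- config$min_fragment
    hi <- L[i] - config$min_fragment
    cuts[[i]] <- sort(lo + sample.int(hi - lo + 1L, k[i], replace = TRUE) - 1L)
  }

  ## flat per-fragment vectors: fragment j of telomere i spans
  ## [starts, ends); `ends` is a cut for all but the last fragment
  tel <- rep.int(seq_len(n), k + 1L)
  starts <- unlist(lapply(seq_len(n), function(i) c(0L, cuts[[i]])),
                   use.names = FALSE)
  ends <- unlist(lapply(seq_len(n), function(i) c(cuts[[i]], L[i])),
                 use.names = FALSE)
  is_cut_end <- unlist(lapply(k, function(ki) c(rep(TRUE, ki), FALSE)),
                       use.names = FALSE)
  frag_len <- ends - starts
  keep <- frag_len >= config$min_fragment

  tmpl_c <- .phase_templates(TELOMERE_UNIT_C, rl)
  tmpl_g <- .phase_templates("TTAGGG", rl)

  ## C-strand reads: start at fragment start, read centromere-ward
  cc <- keep
  c_phase <- (starts[cc] + r[tel[cc]]) %% 6L
  c_len <- pmin(rl, frag_len[cc])
  c_seq <- substr(tmpl_c[c_phase + 1L], 1L, c_len)
  c_tel <- tel[cc]

  ## G-strand reads: start at the cut, read terminus-ward on the complement;
  ## walking the C template backwards from s = (end - 1 + r) mod 6 equals
  ## walking TTAGGG forward from (5 - s) mod 6
  gg <- keep & is_cut_end
  if (config$g_capture_efficiency < 1) {
    drop <- stats::runif(sum(gg)) > config$g_capture_efficiency
    gg[which(gg)[drop]] <- FALSE
  }
  s <- (ends[gg] - 1L + r[tel[gg]]) %% 6L
  g_phase <- (5L - s) %% 6L
  g_len <- pmin(rl, frag_len[gg])
  g_seq <- substr(tmpl_g[g_phase + 1L], 1L, g_len)
  g_tel <- tel[gg]

  ## variant repeat units, substituted at each read's own repeat phase
  if (config$vtr_rate > 0) {
    c_seq <- .inject_vtr(c_seq, c_phase, config$vtr_rate, config$vtr_alphabet)
    g_alpha <- .revcomp(config$vtr_alphabet)
    g_seq <- .inject_vtr(g_seq, g_phase, config$vtr_rate, g_alpha,
                         unit_len_to_first = function(ph) (6L - ph) %% 6L)
  }

  n_tel_reads <- length(c_seq) + length(g_seq)
  bf <- config$background_fraction
  n_bg <- if (bf > 0) round(bf / (1 - bf) * n_tel_reads) else 0L
  bg_seq <- if (n_bg > 0) .random_reads(n_bg, rl) else character(0)

  seqs <- c(c_seq, g_seq, bg_seq)
  src <- rep(c("telC", "telG", "background"),
             c(length(c_seq), length(g_seq), n_bg))
  src_tel <- c(c_tel, g_tel, rep(NA_integer_, n_bg))

  if (config$error_rate > 0) seqs <- .apply_errors(seqs, config$error_rate)

  ord <- sample.int(length(seqs))
  reads <- data.frame(
    read_id = sprintf("sim%08d/%s", seq_along(seqs),
                      c(telC = "C", telG = "G", background = "bg")[src[ord]]),
    sequence = seqs[ord],
    quality = strrep("I", nchar(seqs[ord])),
    source = src[ord],
    telomere = src_tel[ord],
    stringsAsFactors = FALSE)

  truth <- list(
    config = unclass(config),
    telomeres = data.frame(length = L,
                           terminal_phase = r,
                           terminal_category = END_CATEGORIES[
                             match(.revstr(substr(tmpl_c[r + 1L], 1L, 6L)),
                                   END_CATEGORIES)],
                           n_cuts = k),
    cut_positions = data.frame(
      telomere = rep.int(seq_len(n), k),
      position = if (any(k > 0L)) unlist(cuts, use.names = FALSE)
                 else integer(0)),
    emitted = list(c_reads = length(c_seq), g_reads = length(g_seq),
                   background_reads = n_bg,
                   fragments_dropped = sum(!keep)))

  if (!is.null(fastq_path)) {
    write_fastq(reads, fastq_path)
    jsonlite::write_json(truth, paste0(fastq_path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(list(reads = reads, truth = truth, fastq_path = fastq_path))
}

## substitute whole canonical-phase units by variant units at rate v; `phase`
## is the rotation phase of the read start, so the first complete canonical
## unit begins at 0-based offset (6 - phase) %% 6
.inject_vtr <- function(seqs, phase, v, alphabet,
                        unit_len_to_first = function(ph) (6L - ph) %% 6L) {
  if (length(seqs) == 0L) return(seqs)
  off <- unit_len_to_first(phase)
  n_tiles <- pmax(0L, (nchar(seqs) - off) %/% 6L)
  n_var <- stats::rbinom(length(seqs), n_tiles, v)
  hit <- which(n_var > 0L)
  for (i in hit) {
    tiles <- sample.int(n_tiles[i], n_var[i])
    units <- sample(alphabet, n_var[i], replace = TRUE)
    for (j in seq_along(tiles)) {
      a <- off[i] + 6L * (tiles[j] - 1L) + 1L
      substr(seqs[i], a, a + 5L) <- units[j]
    }
  }
  seqs
}

.random_reads <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.apply_errors <- function(seqs, rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Closed-form expectations from a simulation truth sidecar
#'
#' @param truth The `truth` element returned by [simulate_library()].
#' @return List: `expected_f` (expected C-strand read fraction, computed
#'   from the emitted end counts), `expected_end_frequencies` (terminal
#'   category distribution implied by the generating `p_canonical`),
#'   `expected_vtr_rate`, and the emitted read counts.
#' @export
describe_truth <- function(truth) {
  stopifnot(is.list(truth), !is.null(truth$emitted), !is.null(truth$config))
  cfg <- truth$config
  em <- truth$emitted
  p_eff <- if (cfg$terminal_randomization == "none") 1 else cfg$p_canonical
  list(expected_f = em$c_reads / (em$c_reads + em$g_reads),
       expected_end_frequencies = mixture_distribution(p_eff),
       expected_vtr_rate = cfg$vtr_rate,
       c_reads = em$c_reads, g_reads = em$g_reads,
       background_reads = em$background_reads)
}
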