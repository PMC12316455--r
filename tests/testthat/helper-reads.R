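## shared fixture builders

random_seqs <- function(n, len = 75L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## brute-force repeat-run finder: tests every start position
naive_repeat_run <- function(sequence, unit, k) {
  pat <- strrep(unit, k)
  w <- nchar(pat)
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n >= w)
      for (i in seq_len(n - w + 1L))
        if (substr(s, i, i + w - 1L) == pat) return(i - 1L)
    NA_integer_
  }, integer(1L), USE.NAMES = FALSE)
}

make_reads <- function(seqs, ids = sprintf("r%04d", seq_along(seqs))) {
  data.frame(read_id = ids, sequence = seqs,
             quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

write_tmp_fastq <- function(reads, gzip = FALSE) {
  path <- tempfile(fileext = if (gzip) ".fastq.gz" else ".fastq")
  write_fastq(reads, path, gzip = gzip)
  path
}
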