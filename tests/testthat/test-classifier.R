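test_that("has_repeat_run finds exact k-unit runs and their leftmost start", {
  seq75 <- paste0(strrep("A", 10), strrep("TTAGGG", 4), strrep("C", 41))
  hit <- has_repeat_run(seq75, "TTAGGG", 4)
  expect_true(hit$found)
  expect_identical(hit$start, 10L)

  expect_false(has_repeat_run(strrep("TTAGGG", 3), "TTAGGG", 4)$found)
  # a single mismatch breaks the run: longest run here is 3
  expect_false(
    has_repeat_run("TTAGGGTTAGCGTTAGGGTTAGGGTTAGGG", "TTAGGG", 4)$found)
  # N never matches
  expect_false(has_repeat_run(paste0(strrep("TTAGGG", 2), "TTANGG",
                                     strrep("TTAGGG", 2)), "TTAGGG", 4)$found)
  # short sequence is simply false, not an error
  expect_false(has_repeat_run("TTA", "TTAGGG", 1)$found)
})

test_that("classify_reads applies the only-G / only-C / both / neither rule", {
  reads <- c(paste0(strrep("CCCTAA", 12), "GAT"),
             paste0(strrep("TTAGGG", 4), strrep("CCCTAA", 4)),
             strrep("TTAGGG", 13),
             strrep("ACGT", 19))
  cls <- classify_reads(reads)
  expect_identical(as.character(cls),
                   c("C_RICH", "AMBIGUOUS", "G_RICH", "NON_TELOMERIC"))
})

test_that("has_repeat_run agrees with the brute-force position scan", {
  set.seed(101)
  # random sequences plus seeded true runs at random positions
  seqs <- random_seqs(400, 75L)
  for (i in seq(1, 400, by = 4)) {
    k <- sample(1:5, 1)
    unit <- sample(c("TTAGGG", "CCCTAA"), 1)
    run <- strrep(unit, k)
    pos <- sample(75L - nchar(run) + 1L, 1)
    substr(seqs[i], pos, pos + nchar(run) - 1L) <- run
  }
  for (unit in c("TTAGGG", "CCCTAA"))
    for (k in 1:5) {
      got <- has_repeat_run(seqs, unit, k)
      want <- naive_repeat_run(seqs, unit, k)
      expect_identical(got$found, !is.na(want))
      expect_identical(got$start, want)
    }
})

test_that("the same machinery works for non-telomeric unit pairs", {
  unit <- "AAGCTT"  # arbitrary consensus
  params <- classifier_params(unit_g = unit, unit_c = "CCGGTA",
                              min_repeats = 3)
  reads <- c(strrep(unit, 5), strrep("CCGGTA", 3), random_seqs(5, 40L))
  cls <- classify_reads(reads, params)
  expect_identical(as.character(cls[1:2]), c("G_RICH", "C_RICH"))
})

test_that("tally_library enforces the partition invariant and RPM arithmetic", {
  set.seed(7)
  reads <- c(rep(strrep("CCCTAA", 5), 10), rep(strrep("TTAGGG", 5), 4),
             rep(paste0(strrep("TTAGGG", 4), strrep("CCCTAA", 4)), 2),
             random_seqs(34, 75L))
  sc <- tally_library(reads)
  expect_identical(sc$g_rich + sc$c_rich + sc$ambiguous + sc$non_telomeric,
                   sc$total_reads)
  expect_equal(sc$rpm_c, 1e6 * sc$c_rich / sc$total_reads)
  expect_equal(sc$rpm_g, 1e6 * sc$g_rich / sc$total_reads)
  expect_identical(sc$c_rich, 10L)
  expect_identical(sc$ambiguous, 2L)
})

test_that("all-non-telomeric library yields zero RPM; empty library errors", {
  set.seed(8)
  sc <- tally_library(random_seqs(50, 30L))
  expect_identical(sc$rpm_g, 0)
  expect_identical(sc$rpm_c, 0)
  expect_error(tally_library(character(0)), "empty library")
})

test_that("streaming tally matches the in-memory tally and keeps telomeric reads", {
  sim <- simulate_library(simulation_config(n_telomeres = 300, mode = "s1",
                                            cuts_per_telomere = 2, seed = 5))
  path <- write_tmp_fastq(sim$reads, gzip = TRUE)
  streamed <- tally_fastq(path, chunk_size = 100)
  direct <- tally_library(sim$reads)
  expect_identical(as.data.frame(streamed), as.data.frame(direct))
  expect_identical(nrow(streamed$reads), streamed$g_rich + streamed$c_rich)
  expect_setequal(unique(streamed$reads$class), c("G_RICH", "C_RICH"))
})
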