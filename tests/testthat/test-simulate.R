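test_that("identical seeds reproduce the library byte for byte", {
  cfg <- simulation_config(n_telomeres = 200, mode = "s1",
                           cuts_per_telomere = 2, error_rate = 0.001,
                           seed = 77)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  c <- simulate_library(simulation_config(n_telomeres = 200, mode = "s1",
                                          cuts_per_telomere = 2,
                                          error_rate = 0.001, seed = 78))
  expect_false(identical(a$reads$sequence, c$reads$sequence))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(3)
  set.seed(123)
  invisible(stats::runif(1))
  sim <- simulate_library(simulation_config(n_telomeres = 20, seed = 5))
  expect_identical(stats::runif(2), before[2:3])
})

test_that("END-seq mode with no cuts yields only C-strand telomeric reads", {
  sim <- simulate_library(simulation_config(n_telomeres = 500,
                                            cuts_per_telomere = 0,
                                            vtr_rate = 0, error_rate = 0,
                                            background_fraction = 0,
                                            seed = 3))
  cls <- classify_reads(sim$reads)
  expect_true(all(cls == "C_RICH"))
  expect_equal(c_strand_fraction(tally_library(sim$reads)), 1)
})

test_that("S1 mode with fixed cuts matches an independent recount of the sidecar", {
  cfg <- simulation_config(n_telomeres = 400, mode = "s1",
                           cuts_per_telomere = 3, vtr_rate = 0,
                           error_rate = 0, background_fraction = 0, seed = 19)
  sim <- simulate_library(cfg)
  # brute-force recount from the per-telomere truth: fragment ends between
  # consecutive boundaries; fragments >= min_fragment keep one C read, plus
  # one G read when their distal boundary is a cut
  tel <- sim$truth$telomeres
  cuts <- split(sim$truth$cut_positions$position,
                sim$truth$cut_positions$telomere)
  expected_c <- 0L; expected_g <- 0L
  for (i in seq_len(nrow(tel))) {
    cs <- cuts[[as.character(i)]]
    bounds <- c(0L, sort(cs), tel$length[i])
    lens <- diff(bounds)
    keep <- lens >= cfg$min_fragment
    is_cut_end <- c(rep(TRUE, length(cs)), FALSE)
    expected_c <- expected_c + sum(keep)
    expected_g <- expected_g + sum(keep & is_cut_end)
  }
  sc <- tally_library(sim$reads)
  expect_identical(sc$c_rich, expected_c)
  expect_identical(sc$g_rich, expected_g)
  expect_identical(sim$truth$emitted$c_reads, expected_c)
  expect_identical(sim$truth$emitted$g_reads, expected_g)
  # and the counting argument: close to (n+1)N : nN up to dropped fragments
  expect_lte(abs(sc$c_rich - 4L * 400L), sim$truth$emitted$fragments_dropped)
})

test_that("fully canonical error-free termini all read CCAATC-5'", {
  sim <- simulate_library(simulation_config(n_telomeres = 300,
                                            p_canonical = 1, vtr_rate = 0,
                                            error_rate = 0,
                                            background_fraction = 0,
                                            seed = 4))
  cat <- terminal_hexamer(sim$reads$sequence[sim$reads$source == "telC"])
  expect_true(all(cat == "CCAATC"))
})

test_that("strand orientation is correct: G reads carry TTAGGG only", {
  sim <- simulate_library(simulation_config(n_telomeres = 300, mode = "s1",
                                            cuts_per_telomere = 2,
                                            vtr_rate = 0, error_rate = 0,
                                            background_fraction = 0, seed = 6))
  g <- sim$reads$sequence[sim$reads$source == "telG"]
  c_ <- sim$reads$sequence[sim$reads$source == "telC"]
  expect_true(all(has_repeat_run(g, "TTAGGG", 4)$found))
  expect_false(any(has_repeat_run(g, "CCCTAA", 1)$found))
  expect_true(all(has_repeat_run(c_, "CCCTAA", 4)$found))
  expect_false(any(has_repeat_run(c_, "TTAGGG", 1)$found))
})

test_that("describe_truth returns the closed-form expectations", {
  sim <- simulate_library(simulation_config(n_telomeres = 500, mode = "s1",
                                            cuts_per_telomere = 3,
                                            vtr_rate = 0,
                                            background_fraction = 0,
                                            seed = 8))
  dt <- describe_truth(sim$truth)
  expect_equal(dt$expected_f, 4 / 7, tolerance = 0.01)
  expect_equal(dt$expected_vtr_rate, 0)

  sim2 <- simulate_library(simulation_config(n_telomeres = 10,
                                             p_canonical = 0.7, seed = 9))
  dt2 <- describe_truth(sim2$truth)
  expect_equal(dt2$expected_end_frequencies[["CCAATC"]], 0.75)
})

test_that("background fraction and read geometry are respected", {
  cfg <- simulation_config(n_telomeres = 400, background_fraction = 0.5,
                           seed = 10)
  sim <- simulate_library(cfg)
  src <- table(sim$reads$source)
  expect_equal(unname(src[["background"]]) / nrow(sim$reads), 0.5,
               tolerance = 0.01)
  expect_true(all(nchar(sim$reads$sequence) <= 75))
  expect_true(all(nchar(sim$reads$sequence) >= cfg$min_fragment))
  expect_identical(sim$reads$quality, strrep("I", nchar(sim$reads$sequence)))
})

test_that("invalid configurations name the offending fields", {
  expect_error(simulation_config(p_canonical = 1.5, error_rate = -1),
               "p_canonical.*error_rate")
  expect_error(simulation_config(background_fraction = 1),
               "background_fraction")
  expect_error(simulation_config(cuts_per_telomere = 2.5),
               "cuts_per_telomere")
})

test_that("reduced G-end capture efficiency depletes G reads", {
  base <- simulate_library(simulation_config(n_telomeres = 500, mode = "s1",
                                             cuts_per_telomere = 2,
                                             background_fraction = 0,
                                             seed = 11))
  half <- simulate_library(simulation_config(n_telomeres = 500, mode = "s1",
                                             cuts_per_telomere = 2,
                                             background_fraction = 0,
                                             g_capture_efficiency = 0.5,
                                             seed = 11))
  expect_lt(half$truth$emitted$g_reads, 0.7 * base$truth$emitted$g_reads)
  expect_identical(half$truth$emitted$c_reads, base$truth$emitted$c_reads)
})

test_that("FASTQ and truth sidecar are written when a path is given", {
  path <- tempfile(fileext = ".fastq.gz")
  sim <- simulate_library(simulation_config(n_telomeres = 30, seed = 12),
                          fastq_path = path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".truth.json")))
  back <- read_fastq(path)
  expect_identical(back$sequence, sim$reads$sequence)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_identical(truth$config$n_telomeres, 30L)
})
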