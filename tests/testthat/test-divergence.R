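point_mass <- stats::setNames(c(1, 0, 0, 0, 0, 0), END_CATEGORIES)
uniform6 <- stats::setNames(rep(1 / 6, 6), END_CATEGORIES)

test_that("KL divergence is zero on identical distributions", {
  set.seed(31)
  for (i in 1:5) {
    v <- stats::setNames(stats::runif(6), END_CATEGORIES)
    expect_lt(kl_divergence(v, v), 1e-6)
  }
  expect_gte(kl_divergence(uniform6, point_mass), 0)
})

test_that("point mass vs uniform approaches log2(6) as epsilon shrinks", {
  d <- kl_divergence(point_mass, uniform6, epsilon = 1e-12)
  expect_equal(d, log2(6), tolerance = 1e-6)
})

test_that("uniform vs point mass at epsilon 1e-9 matches a direct hand evaluation", {
  eps <- 1e-9
  # independent evaluation of the formula on the pseudocounted cells
  p <- (uniform6 + eps) / sum(uniform6 + eps)
  q <- (point_mass + eps) / sum(point_mass + eps)
  expected <- sum(p * log2(p / q))
  got <- kl_divergence(uniform6, point_mass, epsilon = eps)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_gt(got, 10)  # dominated by the five near-zero reference cells
})

test_that("KL uses only the six permutations: OTHER is dropped and renormalized", {
  a <- end_distribution(c(rep("CTAACCCTAACC", 50), rep("NNNNNNCTAACC", 50)))
  b <- end_distribution(rep("CTAACCCTAACC", 10))
  expect_lt(kl_divergence(a, b), 1e-6)
})

test_that("zero-count distributions are rejected", {
  none <- stats::setNames(rep(0, 6), END_CATEGORIES)
  expect_error(kl_divergence(none, uniform6), "zero total")
})

test_that("dot categories follow the thresholds, boundaries going up", {
  dot <- "\u25cf"
  expect_identical(as.character(dot_category(0.10)), "ns")
  expect_identical(as.character(dot_category(0.30)), strrep(dot, 2))
  expect_identical(as.character(dot_category(0.40)), strrep(dot, 3))
  expect_identical(as.character(dot_category(c(0.125, 0.25, 0.375))),
                   c(dot, strrep(dot, 2), strrep(dot, 3)))
  expect_error(dot_category(-0.1), "non-negative")
})

test_that("mixture_distribution arithmetic", {
  expect_equal(unname(mixture_distribution(1)), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(mixture_distribution(0)), rep(1 / 6, 6))
  m <- mixture_distribution(0.7)
  expect_equal(m[["CCAATC"]], 0.75)
  expect_equal(unname(m[-1]), rep(0.05, 5))
  expect_error(mixture_distribution(1.2), "\\[0, 1\\]")
})

test_that("canonical fraction is recovered exactly on every noiseless grid mixture", {
  grid <- seq(0, 1, by = 0.01)
  for (p in grid) {
    est <- estimate_canonical_fraction(mixture_distribution(p))
    expect_equal(est$p_hat, p, tolerance = 1e-12)
  }
})

test_that("grid ties resolve to the smallest p and the profile is recorded", {
  est <- estimate_canonical_fraction(point_mass)
  expect_equal(est$p_hat, 1)
  expect_identical(nrow(est$profile), 101L)
  expect_equal(est$kl_at_min, min(est$profile$divergence_bits))
})

test_that("divergence from the pure-canonical mixture decreases as p grows", {
  p_grid <- seq(0, 0.99, by = 0.03)
  d <- vapply(p_grid, function(p)
    kl_divergence(mixture_distribution(p), mixture_distribution(1)),
    numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("compare_end_distributions reports divergence, category and direction", {
  cmp <- compare_end_distributions(mixture_distribution(0.4),
                                   mixture_distribution(1))
  expect_identical(cmp$direction, "D(sample || reference)")
  expect_identical(cmp$dot_category,
                   as.character(dot_category(cmp$divergence_bits)))
})
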