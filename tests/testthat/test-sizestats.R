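test_that("CV is the sample-SD/mean ratio in percent and is scale free", {
  expect_equal(cvPct(c(5, 5, 5, 5)), 0)
  expect_equal(cvPct(c(10, 12, 14)), 100 * 2 / 12)
  x <- c(3.2, 5.5, 8.1, 9.7, 12.0)
  expect_equal(cvPct(x), cvPct(3 * x), tolerance = 1e-12)
  expect_error(cvPct(c(1)), "n >= 2")
  expect_error(cvPct(c(-2, -4)), "positive mean")
})

test_that("CQV uses interpolated quartiles and resists outliers", {
  expect_equal(cqvPct(1:7), 37.5)  # Q1 = 2.5, Q3 = 5.5
  expect_equal(cqvPct(rep(4, 10)), 0)
  # bounded in [0, 100] for positive data
  set.seed(1)
  for (i in 1:20) {
    v <- stats::rlnorm(30, 1, 0.8)
    expect_gte(cqvPct(v), 0)
    expect_lte(cqvPct(v), 100)
  }
  # one outlier at 10x the median moves CQV < 10% but CV > 50% (relative)
  set.seed(7)
  base <- stats::rnorm(100, 14, 1.1)
  out <- c(base, 10 * stats::median(base))
  expect_lt(abs(cqvPct(out) - cqvPct(base)) / cqvPct(base), 0.10)
  expect_gt(abs(cvPct(out) - cvPct(base)) / cvPct(base), 0.50)
  expect_error(cqvPct(1:3), "n >= 4")
})

test_that("skewness is the g1 moment ratio with 1/n moments", {
  expect_equal(sampleSkewness(c(1, 2, 3)), 0)
  expect_equal(sampleSkewness(c(0, 0, 1)), sqrt(2) / 2, tolerance = 1e-10)
  x <- c(1.2, 1.9, 2.4, 7.7, 3.1)
  expect_equal(sampleSkewness(10 - x), -sampleSkewness(x))
  expect_error(sampleSkewness(rep(2, 5)), "variance")
})

test_that("the asymptotic CV-equality statistic matches its closed form", {
  a <- exactCVVector(51, 0.05)
  b <- exactCVVector(51, 0.15)
  res <- cvEqualityTest(list(wt = a, mut = b))
  # D_AD = 50*(0.05^2 + 0.05^2) / (0.1^2 * (0.5 + 0.1^2))
  expect_equal(res@statistic, 0.25 / (0.01 * 0.51), tolerance = 1e-6)
  expect_equal(res@df, 1L)
  expect_lt(res@p_value, 1e-10)
  expect_equal(res@cv, c(0.05, 0.15), tolerance = 1e-10)
  expect_equal(res@pooled_cv, 0.10, tolerance = 1e-10)

  same <- cvEqualityTest(list(a, a))
  expect_equal(same@statistic, 0)
  expect_equal(same@p_value, 1)

  # statistic invariant to rescaling a single group
  scaled <- cvEqualityTest(list(wt = 3.7 * a, mut = b))
  expect_equal(scaled@statistic, res@statistic, tolerance = 1e-12)

  expect_error(cvEqualityTest(list(a)), "2 groups")
  expect_error(cvEqualityTest(list(rep(2, 10), rep(3, 8))), "pooled CV")
})

test_that("grouped-vector interface matches the list interface", {
  set.seed(3)
  v <- stats::rnorm(80, 14, 1.5)
  g <- rep(c("a", "b"), each = 40)
  expect_equal(cvEqualityTest(v, g)@statistic,
               cvEqualityTest(split(v, g))@statistic)
})

test_that("permutation p-values agree with the asymptotic reference", {
  a <- exactCVVector(51, 0.05)
  b <- exactCVVector(51, 0.15)
  perm <- cvEqualityPermutation(list(a, b), n_perm = 999, seed = 1L)
  expect_lt(perm$p_value, 0.01)
  expect_equal(perm$statistic, cvEqualityTest(list(a, b))@statistic)

  set.seed(5)
  x <- stats::rnorm(40, 10, 1)
  ident <- cvEqualityPermutation(list(x, x), n_perm = 199, seed = 2L)
  expect_gte(ident$p_value, 0.9)
})

test_that("SD confidence factors come from the chi-square quantiles", {
  f <- sdCIFactors(50, 0.95)
  expect_equal(unname(f["low"]), 0.8353, tolerance = 1e-3)
  expect_equal(unname(f["high"]), 1.2461, tolerance = 1e-3)
  big <- sdCIFactors(1e6, 0.95)
  expect_equal(unname(big), c(1, 1), tolerance = 1e-2)
  # low increases and high decreases with n
  grid <- sdCIFactors(c(5, 10, 50, 200, 1000), 0.95)
  expect_true(all(diff(grid[, "low"]) > 0))
  expect_true(all(diff(grid[, "high"]) < 0))
  expect_error(sdCIFactors(1), "n must be")
  expect_error(sdCIFactors(10, 1.2), "confidence")
})

test_that("minimum sample size is the minimal n meeting the precision rule", {
  crit <- function(n, r, conf = 0.95) {
    f <- sdCIFactors(n, conf)
    max(1 - f["low"], f["high"] - 1) <= r
  }
  for (r in c(0.5, 0.25, 0.1)) {
    n <- minSampleSizeSD(r, 0.95)
    expect_true(crit(n, r))
    expect_false(crit(n - 1, r))
  }
  # frozen values from iterating the criterion directly
  oracle <- function(r) { n <- 2; while (!crit(n, r)) n <- n + 1; n }
  expect_identical(minSampleSizeSD(0.5), 18L)
  expect_identical(minSampleSizeSD(0.25), 49L)
  expect_equal(minSampleSizeSD(0.5), oracle(0.5))
  expect_equal(minSampleSizeSD(0.25), oracle(0.25))
  expect_error(minSampleSizeSD(1e-5, max_n = 1000), "no n <=")
})
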