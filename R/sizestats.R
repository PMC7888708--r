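#' Coefficient of variation (percent)
#'
#' `CV = 100 * sd / mean`, with the sample SD (n - 1 denominator). The
#' standard scale-free dispersion measure for cell length at division.
#'
#' @param x numeric vector, `n >= 2`, positive mean.
#' @return CV in percent.
#' @examples
#' cvPct(c(10, 12, 14))  # 16.67
#' @export
cvPct <- function(x) {
  x <- as.numeric(x)
  stopIfNot(sum(is.finite(x)) == length(x), "x must be finite numeric")
  stopIfNot(length(x) >= 2, "CV requires n >= 2")
  m <- mean(x)
  stopIfNot(m > 0, "CV requires a positive mean")
  100 * stats::sd(x) / m
}

#' Coefficient of quartile variation (percent)
#'
#' `CQV = 100 * (Q3 - Q1) / (Q3 + Q1)`, an outlier-robust relative
#' dispersion measure. Quartiles use linear interpolation of order
#' statistics, `h = (n - 1) p + 1` (quantile type 7).
#'
#' @param x numeric vector, `n >= 4`, with `Q1 + Q3 > 0`.
#' @return CQV in percent.
#' @examples
#' cqvPct(1:7)  # 37.5
#' @export
cqvPct <- function(x) {
  x <- as.numeric(x)
  stopIfNot(sum(is.finite(x)) == length(x), "x must be finite numeric")
  stopIfNot(length(x) >= 4, "CQV requires n >= 4")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  stopIfNot(q[1] + q[2] > 0, "CQV requires Q1 + Q3 > 0")
  100 * (q[2] - q[1]) / (q[2] + q[1])
}

#' Sample skewness (moment coefficient g1)
#'
#' `g1 = m3 / m2^(3/2)` with central moments using the `1/n` convention.
#' Used to gate out strains whose length distribution is skewed towards
#' larger cells (e.g. checkpoint-arrested elongated cells).
#'
#' @param x numeric vector, `n >= 3`, non-zero variance.
#' @return dimensionless skewness.
#' @examples
#' sampleSkewness(c(0, 0, 1))  # 0.7071
#' @export
sampleSkewness <- function(x) {
  x <- as.numeric(x)
  stopIfNot(sum(is.finite(x)) == length(x), "x must be finite numeric")
  n <- length(x)
  stopIfNot(n >= 3, "skewness requires n >= 3")
  d <- x - mean(x)
  m2 <- mean(d^2)
  stopIfNot(m2 > 0, "skewness requires non-zero variance")
  mean(d^3) / m2^1.5
}

# Feltz-Miller asymptotic statistic from per-group means, SDs and sizes.
feltzMillerStat <- function(means, sds, ns) {
  ci <- sds / means
  mi <- ns - 1
  cbar <- sum(mi * ci) / sum(mi)
  stopIfNot(cbar > 0, "pooled CV is zero; test undefined")
  stat <- sum(mi * (ci - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
  list(cv = ci, weights = mi, pooled = cbar, statistic = stat)
}

.asGroupList <- function(x, g) {
  if (is.null(g)) {
    stopIfNot(is.list(x), "supply a list of groups, or values plus labels")
    groups <- x
  } else {
    groups <- split(as.numeric(x), g)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  stopIfNot(length(groups) >= 2, "at least 2 groups are required",
            class = "cellsizer_usage_error")
  for (gr in groups) {
    stopIfNot(length(gr) >= 2, "each group needs n >= 2")
    stopIfNot(mean(gr) > 0, "each group needs a positive mean")
  }
  groups
}

#' Asymptotic chi-square test for equality of coefficients of variation
#'
#' The Feltz-Miller asymptotic test. With per-group CVs
#' `c_i = s_i / mean_i` and weights `m_i = n_i - 1`, the pooled CV is
#' `cbar = sum(m_i c_i) / sum(m_i)` and the statistic
#' `D_AD = sum(m_i (c_i - cbar)^2) / (cbar^2 (0.5 + cbar^2))` is referred to
#' a chi-square distribution with `k - 1` degrees of freedom (upper tail).
#' The statistic is invariant to rescaling any single group by a positive
#' constant.
#'
#' @param x a list of numeric vectors (one per group), or a numeric vector
#'   of values accompanied by `g`.
#' @param g optional group labels, same length as `x`.
#' @return a [CVTestResult-class] object.
#' @examples
#' set.seed(1)
#' a <- rnorm(60, 14, 1.1)   # CV ~ 8%
#' b <- rnorm(60, 14, 2.2)   # CV ~ 16%
#' cvEqualityTest(list(wt = a, mutant = b))
#' @references Feltz, C.J. and Miller, G.E. (1996) An asymptotic test for
#'   the equality of coefficients of variation from k populations.
#'   Statistics in Medicine 15, 647-658.
#' @seealso [cvEqualityPermutation()] for a permutation counterpart.
#' @export
cvEqualityTest <- function(x, g = NULL) {
  groups <- .asGroupList(x, g)
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  ns <- vapply(groups, length, integer(1))
  fm <- feltzMillerStat(means, sds, ns)
  df <- length(groups) - 1L
  p <- stats::pchisq(fm$statistic, df = df, lower.tail = FALSE)
  new("CVTestResult", groups = names(groups), cv = unname(fm$cv),
      n = unname(ns), weights = unname(as.numeric(fm$weights)),
      pooled_cv = fm$pooled, statistic = fm$statistic, df = df,
      p_value = p,
      method = "Feltz-Miller asymptotic test for equality of CVs")
}

#' Permutation test for equality of coefficients of variation
#'
#' Permutation counterpart of [cvEqualityTest()], used as an independent
#' check of the asymptotic chi-square reference. Each group is scaled to
#' mean 1 (the CV is scale invariant), the scaled values are pooled, group
#' labels are permuted, and the Feltz-Miller statistic is recomputed for
#' each permutation. The p-value uses the add-one rule
#' `(b + 1) / (n_perm + 1)`, so it is never zero.
#'
#' @inheritParams cvEqualityTest
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed for the permutations.
#' @return a list with `statistic` (observed D_AD), `p_value` and `n_perm`.
#' @export
cvEqualityPermutation <- function(x, g = NULL, n_perm = 999, seed = NULL) {
  stopIfNot(n_perm >= 100, "n_perm must be >= 100")
  groups <- .asGroupList(x, g)
  ns <- vapply(groups, length, integer(1))
  obs <- feltzMillerStat(vapply(groups, mean, numeric(1)),
                         vapply(groups, stats::sd, numeric(1)),
                         ns)$statistic
  scaled <- unlist(lapply(groups, function(v) v / mean(v)),
                   use.names = FALSE)
  idx <- rep(seq_along(groups), times = ns)
  doPerm <- function() {
    lab <- sample(idx)
    means <- vapply(split(scaled, lab), mean, numeric(1))
    sds <- vapply(split(scaled, lab), stats::sd, numeric(1))
    feltzMillerStat(means, sds, ns)$statistic
  }
  run <- function() {
    perm <- vapply(seq_len(n_perm), function(i) doPerm(), numeric(1))
    (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else withSeed(seed, run())
  list(statistic = obs, p_value = p, n_perm = n_perm)
}

#' Chi-square confidence-interval factors for a standard deviation
#'
#' Multiplicative bounds for the population SD given a sample SD `s` from a
#' normal sample of size `n`: the CI is `(low * s, high * s)` with
#' `low = sqrt((n-1) / qchisq((1+conf)/2, n-1))` and
#' `high = sqrt((n-1) / qchisq((1-conf)/2, n-1))`. Both factors approach 1
#' as `n` grows; this is the basis of the minimum-sample-size rule for
#' SD (and hence CV) precision.
#'
#' @param n sample size (>= 2). Vectorised.
#' @param confidence confidence level in (0, 1).
#' @return named numeric vector(s) `low` and `high` (a two-column matrix for
#'   vector `n`).
#' @examples
#' sdCIFactors(50)  # about (0.835, 1.246)
#' @export
sdCIFactors <- function(n, confidence = 0.95) {
  stopIfNot(all(n >= 2), "n must be >= 2")
  stopIfNot(confidence > 0 && confidence < 1, "confidence must be in (0, 1)")
  low <- sqrt((n - 1) / stats::qchisq((1 + confidence) / 2, df = n - 1))
  high <- sqrt((n - 1) / stats::qchisq((1 - confidence) / 2, df = n - 1))
  if (length(n) == 1L) c(low = low, high = high)
  else cbind(low = low, high = high)
}

#' Minimum sample size for a given SD precision
#'
#' Smallest `n` whose chi-square confidence interval for the SD stays within
#' a relative half-width `r` of the point estimate, i.e.
#' `max(1 - low(n), high(n) - 1) <= r` with the factors from
#' [sdCIFactors()]. At `r = 0.5`, `confidence = 0.95` this gives `n = 18`;
#' the upper factor dominates, so the rule is driven by the chi-square
#' lower-tail quantile. Note that common lab rules of thumb (such as a
#' minimum of 50 cells) are more conservative than this criterion.
#'
#' @param r relative half-width in (0, 1).
#' @param confidence confidence level in (0, 1).
#' @param max_n search bound; exceeding it raises an error.
#' @return the minimal sample size (integer).
#' @export
minSampleSizeSD <- function(r, confidence = 0.95, max_n = 1e6) {
  stopIfNot(r > 0 && r < 1, "r must be in (0, 1)")
  stopIfNot(confidence > 0 && confidence < 1, "confidence must be in (0, 1)")
  # the criterion is monotone in n, so scan blocks then pinpoint
  n <- 2
  block <- 1000
  crit <- function(n) {
    f <- sdCIFactors(n, confidence)
    if (is.matrix(f)) pmax(1 - f[, "low"], f[, "high"] - 1)
    else max(1 - f["low"], f["high"] - 1)
  }
  while (n <= max_n) {
    hi <- min(n + block - 1, max_n)
    v <- crit(n:hi)
    ok <- which(v <= r)
    if (length(ok)) return(as.integer(n + ok[1] - 1))
    n <- hi + 1
  }
  stop(errorCondition(
    sprintf("no n <= %g satisfies relative half-width %g", max_n, r),
    class = c("cellsizer_resource_error", "error", "condition")))
}
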