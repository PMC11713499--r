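#' @importFrom stats shapiro.test t.test wilcox.test cor.test p.adjust median
NULL

.testResult <- function(name, statistic, p, n, alpha = 0.05, familySize = 1L,
                        applicable = TRUE) {
  if (!applicable) {
    return(new("TestResult", testName = name, statistic = NA_real_,
               pValue = NA_real_, pAdjusted = NA_real_, n = as.integer(n),
               significant = NA, applicable = FALSE))
  }
  pAdj <- min(1, p * familySize)
  new("TestResult", testName = name, statistic = unname(statistic),
      pValue = p, pAdjusted = pAdj, n = as.integer(n),
      significant = pAdj < alpha, applicable = TRUE)
}

#' Shapiro-Wilk normality test
#'
#' Normality screening applied to each metric before choosing parametric
#' group comparisons.
#'
#' @param sample numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha significance level.
#' @return A [TestResult-class] with the W statistic.
#' @export
shapiroWilk <- function(sample, alpha = 0.05) {
  n <- length(sample)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(sample)) == 0) stop("zero variance: constant sample")
  ht <- shapiro.test(sample)
  .testResult("Shapiro-Wilk", ht$statistic, ht$p.value, n, alpha)
}

#' Independent-sample t-test
#'
#' Two-sided comparison of two independent groups (e.g. IMRT/VMAT vs SRS
#' cohorts), with optional Bonferroni family-size adjustment.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param alpha significance level applied to the adjusted p-value.
#' @param familySize Bonferroni family size (1 = no correction).
#' @param varEqual passed to [stats::t.test()]; defaults to the classic
#'   pooled-variance test.
#' @return A [TestResult-class].
#' @export
independentTTest <- function(a, b, alpha = 0.05, familySize = 1L,
                             varEqual = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2")
  if (sd(c(a - mean(a), b - mean(b))) == 0)
    stop("degenerate variance: both groups constant")
  ht <- t.test(a, b, var.equal = varEqual)
  .testResult("independent t-test", ht$statistic, ht$p.value,
              length(a) + length(b), alpha, familySize)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired comparison (planning-CT vs synthetic-CT metric values).
#' Zero differences are dropped before ranking; when every difference is
#' zero the result is flagged not-applicable instead of fabricating a
#' p-value. Exact enumeration is used for n <= 25 without ties, the
#' tie-corrected normal approximation otherwise.
#'
#' @param pairedA,pairedB numeric vectors of equal length.
#' @inheritParams independentTTest
#' @return A [TestResult-class]; check `@applicable`.
#' @export
wilcoxonSignedRank <- function(pairedA, pairedB, alpha = 0.05,
                               familySize = 1L) {
  if (length(pairedA) != length(pairedB))
    stop("paired samples must have equal length")
  d <- pairedB - pairedA
  d <- d[d != 0]
  if (length(d) == 0L)
    return(.testResult("Wilcoxon signed-rank", NA, NA, length(pairedA),
                       alpha, familySize, applicable = FALSE))
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = !exact))
  .testResult("Wilcoxon signed-rank", ht$statistic, ht$p.value, length(d),
              alpha, familySize)
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling, used to relate
#' image-quality metrics to gamma pass rates across cases.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @param labels character(2) naming the two variables.
#' @return A [CorrelationResult-class].
#' @export
spearmanCorrelation <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("constant input: rank correlation undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  new("CorrelationResult", coefficient = unname(ht$estimate),
      pValue = ht$p.value, pair = labels)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per p-value; `m` defaults to the number of p-values
#' (one family per comparison table).
#'
#' @param pValues numeric vector in [0, 1].
#' @param familySize family size `m`; `NULL` uses `length(pValues)`.
#' @return Adjusted p-values, capped at 1.
#' @examples
#' bonferroni(c(0.01, 0.5), familySize = 5)  # 0.05, 1
#' @export
bonferroni <- function(pValues, familySize = NULL) {
  stopifnot(all(pValues >= 0 & pValues <= 1, na.rm = TRUE))
  m <- if (is.null(familySize)) length(pValues) else familySize
  pmin(1, pValues * m)
}
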