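# Self-contained Mann-Whitney U and paired Student's t tests.
# Built in-package so that the exact small-sample branch can be verified
# against brute-force enumeration; base R's wilcox.test / t.test are used
# only as independent cross-checks in the test suite.

.testResult <- function(statistic, p, method, n, degenerate = FALSE) {
  new("TestResult", statistic = statistic, p = p, method = method,
      n = as.integer(n), degenerate = degenerate)
}

# U statistic of sample a (vs b) from midranks.
.uStatistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test of two independent samples. U is computed from midranks.
#' When the combined sample size is at most 12 and there are no ties, the
#' two-sided p value is exact, computed by enumerating all
#' \eqn{\binom{n_a+n_b}{n_a}} group assignments of the pooled values:
#' \eqn{p = 2\min(P(U \le u), P(U \ge u))}, capped at 1. Otherwise, the
#' normal approximation with tie correction and continuity correction is
#' used (the regime of the plate-level comparisons, n = 12-136 wells per
#' group).
#'
#' @param a,b numeric samples (non-empty).
#' @return a [TestResult-class] with the U statistic of `a`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))
#' @export
mannWhitneyU <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  u <- .uStatistic(a, b)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  if (na + nb <= 12L && !ties) {
    splits <- utils::combn(na + nb, na)
    r <- rank(pooled)
    uAll <- colSums(matrix(r[splits], nrow = na)) - na * (na + 1) / 2
    pLe <- mean(uAll <= u + 1e-9)
    pGe <- mean(uAll >= u - 1e-9)
    p <- min(1, 2 * min(pLe, pGe))
    return(.testResult(u, p, "mann_whitney_exact", c(na, nb)))
  }
  mU <- na * nb / 2
  r <- rank(pooled)
  tieTab <- table(r)
  nTot <- na + nb
  tieCorr <- sum(tieTab^3 - tieTab) / (nTot * (nTot - 1))
  sigma2 <- na * nb / 12 * (nTot + 1 - tieCorr)
  if (sigma2 <= 0)  # all pooled values identical
    return(.testResult(u, 1, "mann_whitney_normal", c(na, nb),
                       degenerate = TRUE))
  z <- (u - mU - sign(u - mU) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  .testResult(u, p, "mann_whitney_normal", c(na, nb))
}

#' Paired Student's t test (two-sided)
#'
#' Classical paired t on differences d = x - y:
#' \eqn{t = \bar d / (s_d / \sqrt n)} with n - 1 degrees of freedom.
#' Zero-variance differences are reported with the `degenerate` flag set
#' (t = 0, p = 1 when all differences are zero; |t| = Inf, p = 0 when they
#' are a nonzero constant).
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @return a [TestResult-class].
#' @examples
#' pairedT(c(3, 4, 5), c(1, 1, 1))
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between paired samples")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0)
      return(.testResult(0, 1, "paired_t", n, degenerate = TRUE))
    return(.testResult(sign(mean(d)) * Inf, 0, "paired_t", n,
                       degenerate = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  .testResult(t, p, "paired_t", n)
}

#' Significance stars
#'
#' Maps a p value to the star convention used in the assay figures:
#' `****` p < 0.0001, `***` p < 0.0005, `**` p < 0.005, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p p value(s).
#' @return character vector of star labels.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 5e-4) "***" else
      if (pi < 5e-3) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}
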