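# Vectorised two-sided Fisher exact test for 2x2 tables.
#
# The per-site contingency tests dominate DMR-calling runtime, so the
# test is computed directly from the hypergeometric distribution with
# caching over shared margins: all tables with the same (row1, row2,
# col1) totals share one pmf, and their two-sided p-values fall out of a
# single sorted cumulative sum.  The two-sided rule is the standard
# "sum of all outcome probabilities not exceeding the observed one"
# (with the customary 1 + 1e-7 relative tolerance, as in
# stats::fisher.test, which this routine matches to ~1e-15).

#' Two-sided Fisher exact test for 2x2 contingency tables (vectorised)
#'
#' Tables are `[[a, b], [c, d]]`; in the DMR setting `a`/`b` are the
#' methylated/unmethylated counts of sample A at a site and `c`/`d` those
#' of sample B.
#'
#' @param a,b,c,d non-negative integer count vectors of equal length.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_test_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  m <- a + b          # row 1 total (sample A depth)
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total (methylated reads)
  p <- numeric(length(a))
  key <- paste(m, n, k)
  groups <- split(seq_along(a), key)
  relerr <- 1 + 1e-7
  for (idx in groups) {
    mi <- m[idx[1L]]; ni <- n[idx[1L]]; ki <- k[idx[1L]]
    lo <- max(0L, ki - ni); hi <- min(ki, mi)
    dd <- dhyper(lo:hi, mi, ni, ki)
    ord <- order(dd)
    dsort <- dd[ord]
    cum <- cumsum(dsort)
    xs <- a[idx] - lo + 1L
    npos <- findInterval(dd[xs] * relerr, dsort)
    p[idx] <- pmin(1, cum[npos])
  }
  p
}

#' Chi-square test for 2x2 tables (no continuity correction)
#'
#' Offered as the faster alternative where all expected cell counts are
#' at least `min_expected`; tables below that threshold fall back to the
#' exact test.
#'
#' @inheritParams fisher_test_2x2
#' @param min_expected smallest expected cell count admitting the
#'   chi-square approximation.
#' @return numeric vector of two-sided p-values.
#' @export
chisq_test_2x2 <- function(a, b, c, d, min_expected = 5) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  e11 <- r1 * c1 / N; e12 <- r1 * c2 / N
  e21 <- r2 * c1 / N; e22 <- r2 * c2 / N
  ok <- N > 0 & pmin(e11, e12, e21, e22) >= min_expected
  stat <- (a - e11)^2 / e11 + (b - e12)^2 / e12 +
          (c - e21)^2 / e21 + (d - e22)^2 / e22
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (any(!ok))
    p[!ok] <- fisher_test_2x2(a[!ok], b[!ok], c[!ok], d[!ok])
  p
}
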