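#' Pearson chi-square statistic of a contingency table
#'
#' `X2 = sum (n_iv - E_iv)^2 / E_iv` with expected counts
#' `E_iv = t_i * n_:v / n` under independence.  Columns with a zero total
#' contribute nothing; their number and the resulting effective degrees of
#' freedom are attached as attributes (`zero_cols`, `effective_df`), since
#' p-values from the nominal-df reference distribution deserve caution when
#' cells are empty.
#'
#' @param table a [contingency_table].
#' @return Numeric `X2 >= 0` with attributes `zero_cols` and `effective_df`.
#' @examples
#' chi2_statistic(contingency_table(rbind(c(10, 0), c(0, 10))))  # 20
#' @export
chi2_statistic <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cnt <- table$counts
  n <- table$t0 + table$t1
  colsum <- colSums(cnt)
  nz <- colsum > 0
  e0 <- table$t0 * colsum[nz] / n
  e1 <- table$t1 * colsum[nz] / n
  x2 <- sum((cnt[1L, nz] - e0)^2 / e0) + sum((cnt[2L, nz] - e1)^2 / e1)
  structure(x2, zero_cols = sum(!nz),
            effective_df = max(1L, sum(nz) - 1L))
}

#' Upper-tail chi-square p-value as -log10 p
#'
#' Survival probability of the chi-square reference distribution, computed
#' in log space so values remain finite far into the tail (no underflow for
#' statistics up to 1e4 and beyond).  Pair tables use 8 degrees of freedom,
#' single-SNP tables 2.
#'
#' @param x2 chi-square statistic (vectorized).
#' @param df degrees of freedom (8 for 2x9 pair tables, 2 for 2x3 single).
#' @return `-log10 p`, `>= 0`, vectorized over `x2`.
#' @examples
#' chi2_pvalue(2 * log(10) * 3, df = 2)  # exactly 3
#' @export
chi2_pvalue <- function(x2, df) {
  if (any(x2 < 0)) stop("x2 must be >= 0")
  if (any(df < 1)) stop("df must be >= 1")
  -pchisq(x2, df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' One-sided Fisher exact p-value of a cumulated count pair
#'
#' Hypergeometric tail probability of observing at least `x1` Cases among
#' the `x0 + x1` covered samples in the 2x2 table
#' `[[x0, t0 - x0], [x1, t1 - x1]]` with fixed margins -- the direction of
#' enrichment in Cases.  These values track the SS point p-values closely;
#' the test is provided as a vertex-level comparator, not as a scan filter.
#'
#' @inheritParams ss_point_pvalue
#' @return P-value in `(0, 1]`.
#' @examples
#' fisher_exact_1sided(0, 5, 5, 5)  # 1 / choose(10, 5) = 1/252
#' @export
fisher_exact_1sided <- function(x0, x1, t0, t1) {
  if (any(x0 < 0) || any(x0 > t0) || any(x1 < 0) || any(x1 > t1)) {
    stop("counts out of range")
  }
  phyper(x1 - 1, m = x0 + x1, n = t0 + t1 - x0 - x1, k = t1,
         lower.tail = FALSE)
}
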