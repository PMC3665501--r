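#' Phenotype-by-genotype contingency table
#'
#' A 2-by-V table of counts `n[i, v]`: row 1 holds Controls, row 2 Cases;
#' columns are genotype calls (V = 3 for a single SNP) or genotype-call
#' pairs (V = 9 for a SNP pair).  Empty cells are retained as zero columns.
#'
#' @param counts 2-by-V matrix of non-negative integer counts.
#' @param cell_labels optional character vector of column labels.
#' @return An object of class `contingency_table` with elements `counts`,
#'   `t0` (control total), `t1` (case total), `cell_labels`.
#' @examples
#' contingency_table(rbind(c(10, 20, 30), c(5, 10, 15)))
#' @export
contingency_table <- function(counts, cell_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must have 2 rows (controls, cases)")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  t0 <- sum(counts[1L, ])
  t1 <- sum(counts[2L, ])
  if (t0 < 1L || t1 < 1L) stop("degenerate table: need t0 >= 1 and t1 >= 1")
  if (is.null(cell_labels)) cell_labels <- as.character(seq_len(ncol(counts)) - 1L)
  if (length(cell_labels) != ncol(counts)) stop("cell_labels length mismatch")
  structure(list(counts = counts, t0 = t0, t1 = t1,
                 cell_labels = as.character(cell_labels)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> 2 x ", ncol(x$counts),
      " (t0 = ", x$t0, ", t1 = ", x$t1, ")\n", sep = "")
  mat <- x$counts
  dimnames(mat) <- list(c("controls", "cases"), x$cell_labels)
  print(mat)
  invisible(x)
}

#' @describeIn contingency_table long-format counts, one row per
#'   (phenotype, cell).
#' @param x a `contingency_table`.
#' @param ... unused.
#' @export
tidy.contingency_table <- function(x, ...) {
  tibble::tibble(
    phenotype = rep(c("control", "case"), ncol(x$counts)),
    cell = rep(x$cell_labels, each = 2L),
    count = as.integer(x$counts))
}

#' Build a 2x3 single-SNP contingency table
#'
#' Samples with a missing genotype are excluded, so `t0`/`t1` reflect the
#' per-SNP complete cases.
#'
#' @param genotypes integer vector of codes 0/1/2/`NA` for one SNP.
#' @param phenotype integer vector of 0 (control) / 1 (case), same length.
#' @return A [contingency_table] with V = 3 and cell labels `"0" "1" "2"`.
#' @export
build_single_table <- function(genotypes, phenotype) {
  if (length(genotypes) != length(phenotype)) stop("length mismatch")
  keep <- !is.na(genotypes)
  if (!any(keep)) stop("degenerate table: all genotypes missing")
  g <- genotypes[keep]
  ph <- phenotype[keep]
  cnt <- rbind(tabulate(g[ph == 0L] + 1L, nbins = 3L),
               tabulate(g[ph == 1L] + 1L, nbins = 3L))
  contingency_table(cnt, cell_labels = c("0", "1", "2"))
}

#' Build a 2x9 SNP-pair contingency table
#'
#' Cells are ordered `(g1, g2)` over `{0,1,2} x {0,1,2}` row-major, labelled
#' `"g1/g2"`.  A sample missing at either SNP is excluded (per-pair complete
#' case), so marginalizing the nine cells over `g2` reproduces the single-SNP
#' table of `g1` on the shared sample subset.
#'
#' @param g1,g2 integer vectors of codes 0/1/2/`NA`, one per SNP.
#' @inheritParams build_single_table
#' @return A [contingency_table] with V = 9.
#' @export
build_pair_table <- function(g1, g2, phenotype) {
  if (length(g1) != length(g2) || length(g1) != length(phenotype)) {
    stop("length mismatch")
  }
  keep <- !is.na(g1) & !is.na(g2)
  if (!any(keep)) stop("degenerate table: all genotypes missing")
  cell <- g1[keep] * 3L + g2[keep]
  ph <- phenotype[keep]
  cnt <- rbind(tabulate(cell[ph == 0L] + 1L, nbins = 9L),
               tabulate(cell[ph == 1L] + 1L, nbins = 9L))
  labs <- paste(rep(0:2, each = 3L), rep(0:2, 3L), sep = "/")
  contingency_table(cnt, cell_labels = labs)
}

#' Odds ratio and coverage of a cumulated genotype-call subset
#'
#' For a subset of genotype calls covering `x0` of `t0` Controls and `x1` of
#' `t1` Cases, computes the odds ratio
#' `OR = (x1 / (t1 - x1)) / (x0 / (t0 - x0))`, the coverage fractions
#' `xi0 = x0/t0` and `xi1 = x1/t1`, the direction (contributing when
#' OR > 1, protective otherwise), and the *critical sens/spec*: sensitivity
#' `xi1` for contributing subsets, control-side coverage `xi0` for
#' protective ones.  Zero denominators yield an infinite or zero OR with
#' `degenerate = TRUE` (no pseudo-counts are added).
#'
#' @param x0,x1 cumulated Control and Case counts of the subset.
#' @param t0,t1 Control and Case totals.
#' @return A one-row tibble with columns `or`, `xi0`, `xi1`, `direction`,
#'   `critical`, `degenerate`.
#' @examples
#' effect_summary(x0 = 7, x1 = 113, t0 = 2938, t1 = 1952)  # OR ~ 25.7
#' @export
effect_summary <- function(x0, x1, t0, t1) {
  if (x0 < 0 || x0 > t0 || x1 < 0 || x1 > t1) {
    stop("counts out of range: need 0 <= x0 <= t0 and 0 <= x1 <= t1")
  }
  degenerate <- x0 == 0 || x0 == t0 || x1 == 0 || x1 == t1
  odds1 <- x1 / (t1 - x1)     # Inf when x1 == t1
  odds0 <- x0 / (t0 - x0)
  or <- if (odds0 == 0 && odds1 == 0) NaN else odds1 / odds0
  xi0 <- x0 / t0
  xi1 <- x1 / t1
  direction <- if (isTRUE(or > 1)) "contributing" else "protective"
  critical <- if (direction == "contributing") xi1 else xi0
  tibble::tibble(or = or, xi0 = xi0, xi1 = xi1, direction = direction,
                 critical = critical, degenerate = degenerate)
}
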