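#' Prevalence-mapping ROC curve of a contingency table
#'
#' Orders the genotype cells by decreasing case prevalence
#' `n1v / (n0v + n1v)`, merging cells with exactly equal prevalence into one
#' segment and skipping empty cells, then cumulates (control, case) counts.
#' The resulting polyline from `(0, 0)` to `(t0, t1)` is concave in
#' `(x0/t0, x1/t1)` coordinates: it is the ROC curve of the sample
#' prevalence mapping, with up to V linear segments (9 for a fully
#' populated pair table, 3 for a single SNP).
#'
#' @param table a [contingency_table].
#' @return An object of class `roc_curve`: list with `vertices` (integer
#'   matrix of cumulative `(x0, x1)` counts, first row `(0, 0)`, last
#'   `(t0, t1)`), `t0`, `t1`, and `cell_order` (list of cell-label groups,
#'   one per segment; tied cells share a group).
#' @examples
#' tab <- contingency_table(rbind(c(4, 3, 1), c(1, 3, 4)))
#' build_roc(tab)
#' @export
build_roc <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  n0 <- as.numeric(table$counts[1L, ])
  n1 <- as.numeric(table$counts[2L, ])
  tot <- n0 + n1
  keep <- which(tot > 0)
  # order by decreasing prevalence; exact rational comparison via
  # cross-products (counts are integers, products stay well below 2^53)
  ord <- keep[order(-(n1[keep] / tot[keep]), keep)]
  groups <- list()
  verts <- matrix(0, nrow = 1L, ncol = 2L)
  x0 <- 0; x1 <- 0
  i <- 1L
  while (i <= length(ord)) {
    j <- i
    while (j + 1L <= length(ord) &&
           n1[ord[i]] * tot[ord[j + 1L]] == n1[ord[j + 1L]] * tot[ord[i]]) {
      j <- j + 1L
    }
    grp <- ord[i:j]
    x0 <- x0 + sum(n0[grp])
    x1 <- x1 + sum(n1[grp])
    verts <- rbind(verts, c(x0, x1))
    groups[[length(groups) + 1L]] <- table$cell_labels[grp]
    i <- j + 1L
  }
  storage.mode(verts) <- "integer"
  colnames(verts) <- c("x0", "x1")
  structure(list(vertices = verts, t0 = table$t0, t1 = table$t1,
                 cell_order = groups),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$vertices) - 1L, " segment(s), t0 = ", x$t0,
      ", t1 = ", x$t1, "\n", sep = "")
  invisible(x)
}

n_segments <- function(roc) nrow(roc$vertices) - 1L

roc_fractions <- function(roc) {
  cbind(roc$vertices[, 1L] / roc$t0, roc$vertices[, 2L] / roc$t1)
}

# piecewise-linear value of the curve at abscissa fractions xs (in [0, 1])
roc_interpolate <- function(roc, xs) {
  fr <- roc_fractions(roc)
  # concave curves may have a vertical first segment; approx() needs unique x
  ux <- unique(fr[, 1L])
  uy <- vapply(ux, function(x) max(fr[fr[, 1L] == x, 2L]), numeric(1))
  if (length(ux) == 1L) return(rep(uy, length(xs)))
  stats::approx(ux, uy, xout = xs, rule = 2)$y
}

#' Does one ROC curve dominate another?
#'
#' `TRUE` when curve `a` lies on or above curve `b` at every abscissa
#' (tolerance `1e-12` on fractions).  The pair-table curve always dominates
#' both marginal single-SNP curves built on the same samples, because the
#' nine pair cells refine the three single-SNP cells.
#'
#' @param a,b [build_roc()] curves sharing the same totals.
#' @param tol numeric tolerance on fraction coordinates.
#' @return Logical scalar.
#' @export
dominates <- function(a, b, tol = 1e-12) {
  stopifnot(inherits(a, "roc_curve"), inherits(b, "roc_curve"))
  if (a$t0 != b$t0 || a$t1 != b$t1) stop("curves have mismatched totals")
  xs <- sort(unique(c(roc_fractions(a)[, 1L], roc_fractions(b)[, 1L])))
  all(roc_interpolate(a, xs) >= roc_interpolate(b, xs) - tol)
}

#' Split ROC vertices into contributing and protective subsets
#'
#' Interior vertex `i` is *contributing* when the slope of its incoming
#' segment, `((x1_i - x1_{i-1}) / t1) / ((x0_i - x0_{i-1}) / t0)`, is at
#' least 1 (vertical segments count as infinite slope), and *protective*
#' when the outgoing segment slope is at most 1 (horizontal counts as 0).
#' A vertex can belong to both sets.
#'
#' @param roc a [build_roc()] curve.
#' @return List with integer elements `cntr` and `prtv`: row indices into
#'   `roc$vertices` of the interior vertices in each subset.
#' @export
demarcate <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  v <- roc$vertices
  k <- nrow(v)
  cntr <- integer(0)
  prtv <- integer(0)
  for (i in seq_len(k - 2L) + 1L) {   # interior rows 2 .. k-1
    dx_in <- (v[i, 1L] - v[i - 1L, 1L]) / roc$t0
    dy_in <- (v[i, 2L] - v[i - 1L, 2L]) / roc$t1
    dx_out <- (v[i + 1L, 1L] - v[i, 1L]) / roc$t0
    dy_out <- (v[i + 1L, 2L] - v[i, 2L]) / roc$t1
    if (dy_in >= dx_in) cntr <- c(cntr, i)    # slope >= 1, vertical included
    if (dy_out <= dx_out) prtv <- c(prtv, i)  # slope <= 1, horizontal included
  }
  list(cntr = cntr, prtv = prtv)
}

new_null_region <- function(chain, kind, t0 = NULL, t1 = NULL) {
  colnames(chain) <- c("pi0", "pi1")
  structure(list(upper_boundary = chain, kind = kind, t0 = t0, t1 = t1),
            class = "null_region")
}

#' @export
print.null_region <- function(x, ...) {
  cat("<null_region> ", x$kind, ", ", nrow(x$upper_boundary),
      " boundary points\n", sep = "")
  invisible(x)
}

#' Pair-specific convex null region spanned by two single-SNP ROC curves
#'
#' The null hypothesis of the gain (GSS) test is that the population
#' proportions `(pi0, pi1)` lie in the smallest convex region of the unit
#' square containing both single-SNP ROC curves.  Its upper boundary is the
#' concave upper chain of the convex hull of both curves' vertices (in
#' fraction coordinates) together with the corners `(0, 0)` and `(1, 1)`;
#' the region is everything on or below that chain with `pi1 >= 0`.
#'
#' @param roc1,roc2 marginal single-SNP [build_roc()] curves (same totals).
#' @return An object of class `null_region` with elements `upper_boundary`
#'   (matrix of `(pi0, pi1)` chain points from `(0, 0)` to `(1, 1)`) and
#'   `kind = "pair_specific"`.
#' @seealso [diagonal_region()], [p_gss()]
#' @export
build_null_region <- function(roc1, roc2) {
  stopifnot(inherits(roc1, "roc_curve"), inherits(roc2, "roc_curve"))
  if (roc1$t0 != roc2$t0 || roc1$t1 != roc2$t1) {
    stop("curves have mismatched totals")
  }
  pts <- rbind(roc_fractions(roc1), roc_fractions(roc2), c(0, 0), c(1, 1))
  chain <- upper_concave_chain(pts)
  new_null_region(chain, "pair_specific", roc1$t0, roc1$t1)
}

# Upper concave chain of the convex hull of pts (rows = (x, y) in [0,1]^2),
# from (0, 0) to (1, 1).  Keeps only the max-y point per abscissa, then an
# Andrew-style scan keeping strictly right turns.
upper_concave_chain <- function(pts) {
  xs <- sort(unique(pts[, 1L]))
  ys <- vapply(xs, function(x) max(pts[pts[, 1L] == x, 2L]), numeric(1))
  stack <- matrix(c(0, 0), ncol = 2L)
  for (i in seq_along(xs)) {
    p <- c(xs[i], ys[i])
    if (p[1L] == 0 && p[2L] == 0) next
    while (nrow(stack) >= 2L) {
      a <- stack[nrow(stack) - 1L, ]
      b <- stack[nrow(stack), ]
      cr <- (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
      if (cr >= 0) stack <- stack[-nrow(stack), , drop = FALSE] else break
    }
    stack <- rbind(stack, p)
  }
  unname(stack)
}

#' Diagonal null region of the SS test
#'
#' The simple null hypothesis that the probes have no segregation power:
#' `pi0 = pi1`.  The gain test against this region reduces exactly to the
#' SS test.
#'
#' @return A `null_region` with `kind = "diagonal"` and boundary
#'   `{(0,0), (1,1)}`.
#' @export
diagonal_region <- function() {
  new_null_region(rbind(c(0, 0), c(1, 1)), "diagonal")
}

#' Is a point inside (or on the boundary of) a null region?
#'
#' @param region a `null_region`.
#' @param pi0,pi1 population proportions in `[0, 1]`.
#' @param tol boundary tolerance.
#' @return Logical scalar.
#' @export
region_contains <- function(region, pi0, pi1, tol = 1e-12) {
  stopifnot(inherits(region, "null_region"))
  if (pi0 < -tol || pi0 > 1 + tol || pi1 < -tol) return(FALSE)
  ch <- region$upper_boundary
  ux <- unique(ch[, 1L])
  uy <- vapply(ux, function(x) max(ch[ch[, 1L] == x, 2L]), numeric(1))
  top <- if (length(ux) == 1L) max(uy)
  else stats::approx(ux, uy, xout = pi0, rule = 2)$y
  pi1 <= top + tol
}
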