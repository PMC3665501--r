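#' Log-space binomial tail probabilities
#'
#' `log_binom_lower()` returns the natural log of
#' `P[Bin(t, pi) <= x] = sum_{i=0}^{x} C(t, i) pi^i (1 - pi)^(t - i)`;
#' `log_binom_upper()` the natural log of `P[Bin(t, pi) >= x]`.  Both are
#' evaluated in log space through the regularized incomplete beta function
#' (via [stats::pbinom()]), so there is no underflow for totals up to 1e5
#' and beyond.  They satisfy `exp(lower(x)) + exp(upper(x + 1)) = 1`.
#'
#' @param x count, `0 <= x <= t` (vectorized).
#' @param t total number of trials.
#' @param pi success probability in `[0, 1]`.
#' @return Log probability (`<= 0`), vectorized over the inputs.
#' @examples
#' log_binom_lower(0, 4, 0.5)  # log(1/16)
#' log_binom_upper(4, 4, 0.5)  # log(1/16)
#' @export
log_binom_lower <- function(x, t, pi) {
  check_binom_args(x, t, pi)
  pbinom(x, t, pi, log.p = TRUE)
}

#' @rdname log_binom_lower
#' @export
log_binom_upper <- function(x, t, pi) {
  check_binom_args(x, t, pi)
  ifelse(x <= 0, 0, pbinom(x - 1, t, pi, lower.tail = FALSE, log.p = TRUE))
}

check_binom_args <- function(x, t, pi) {
  if (any(x < 0) || any(x > t)) stop("need 0 <= x <= t")
  if (any(t < 0) || any(t != round(t))) stop("t must be a non-negative integer")
  if (any(pi < 0) || any(pi > 1)) stop("pi must lie in [0, 1]")
  invisible(NULL)
}

new_epiroc_test <- function(log10_p, best_vertex, arg_pi, direction, method) {
  log10_p <- max(0, log10_p)
  structure(
    list(log10_p = log10_p, p_value = 10^(-log10_p),
         best_vertex = best_vertex, arg_pi = arg_pi,
         direction = direction, method = method),
    class = "epiroc_test")
}

#' @export
print.epiroc_test <- function(x, ...) {
  cat("<epiroc_test:", x$method, "> flt = ", format(x$log10_p, digits = 6),
      " (p = ", format(x$p_value, digits = 4), ")\n", sep = "")
  if (!anyNA(x$best_vertex)) {
    cat("  best vertex (x0, x1) = (", x$best_vertex[1L], ", ",
        x$best_vertex[2L], "); arg (pi0, pi1) = (",
        format(x$arg_pi[1L], digits = 4), ", ",
        format(x$arg_pi[2L], digits = 4), ")\n", sep = "")
  }
  invisible(x)
}

#' @describeIn ss_point_pvalue one-row tibble of the test result.
#' @param x an `epiroc_test` object.
#' @param ... unused.
#' @export
tidy.epiroc_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, direction = x$direction,
    log10_p = x$log10_p, p_value = x$p_value,
    x0 = x$best_vertex[1L], x1 = x$best_vertex[2L],
    pi0 = x$arg_pi[1L], pi1 = x$arg_pi[2L])
}

#' @describeIn ss_point_pvalue same as `tidy()` (the result is scalar).
#' @export
glance.epiroc_test <- function(x, ...) tidy(x, ...)

#' Exact SS p-value of a single cumulated count pair
#'
#' The sensitivity-and-specificity (SS) test asks how likely it is to
#' observe, by biased sampling alone, at most `x0` of `t0` Controls *and*
#' at least `x1` of `t1` Cases in some genotype-call subset, when the
#' population proportions are equal (`pi0 = pi1`, no segregation power).
#' The p-value is the worst case over the common proportion:
#' `max over pi in [0,1] of P[Bin(t0, pi) <= x0] * P[Bin(t1, pi) >= x1]`.
#' The maximization uses golden-section search on each boundary segment
#' (the objective has no local maxima), to about 1e-12 in `pi`.
#'
#' @param x0,x1 cumulated Control and Case counts (a ROC vertex).
#' @param t0,t1 Control and Case totals.
#' @return An object of class `epiroc_test`: list with `log10_p`
#'   (the flt score, `-log10 p >= 0`), `p_value`, `best_vertex`, `arg_pi`,
#'   `direction`, `method`.
#' @examples
#' ss_point_pvalue(0, 1, 1, 1)  # p = 1/4 at pi = 1/2
#' @export
ss_point_pvalue <- function(x0, x1, t0, t1) {
  check_counts(x0, x1, t0, t1)
  r <- chain_max_cpp(x0, x1, t0, t1, rbind(c(0, 0), c(1, 1)))
  new_epiroc_test(-r[1L], c(x0 = x0, x1 = x1), c(pi0 = r[2L], pi1 = r[3L]),
                  "any", "ss_point")
}

#' Exact GSS p-value of a single cumulated count pair
#'
#' Like [ss_point_pvalue()], but the null hypothesis is that the population
#' proportions `(pi0, pi1)` lie anywhere in a convex `null_region` (for the
#' gain test: the region spanned by the two single-SNP ROC curves).  The
#' objective `P[Bin(t0, pi0) <= x0] * P[Bin(t1, pi1) >= x1]` increases in
#' `pi1` and decreases in `pi0`, so its maximum over the region is attained
#' on the upper boundary chain; the search runs along that chain.  With the
#' diagonal region this reduces exactly to the SS test.
#'
#' @inheritParams ss_point_pvalue
#' @param region a [build_null_region()] or [diagonal_region()] object.
#' @return An `epiroc_test` object.
#' @export
gss_point_pvalue <- function(x0, x1, t0, t1, region) {
  check_counts(x0, x1, t0, t1)
  stopifnot(inherits(region, "null_region"))
  check_region_totals(region, t0, t1)
  r <- chain_max_cpp(x0, x1, t0, t1, region$upper_boundary)
  new_epiroc_test(-r[1L], c(x0 = x0, x1 = x1), c(pi0 = r[2L], pi1 = r[3L]),
                  "any", "gss_point")
}

check_counts <- function(x0, x1, t0, t1) {
  if (t0 < 1 || t1 < 1) stop("totals must be >= 1")
  if (t0 >= 65536 || t1 >= 65536) stop("totals above 65535 are not supported")
  if (x0 < 0 || x0 > t0 || x1 < 0 || x1 > t1) stop("counts out of range")
  invisible(NULL)
}

check_region_totals <- function(region, t0, t1) {
  if (!is.null(region$t0) && (region$t0 != t0 || region$t1 != t1)) {
    stop("region was built for totals (", region$t0, ", ", region$t1,
         "), not (", t0, ", ", t1, ")")
  }
  invisible(NULL)
}

qualifying_vertices <- function(roc, min_ss) {
  v <- roc$vertices
  spe <- 1 - v[, 1L] / roc$t0
  sen <- v[, 2L] / roc$t1
  which(pmin(spe, sen) >= min_ss)
}

#' SS test of a ROC curve
#'
#' The flt_SS score of a probe or probe pair: the outer minimum of
#' [ss_point_pvalue()] over the vertices of its prevalence-mapping ROC
#' curve, i.e. the most significant separation achieved by any
#' prevalence-ordered genotype-call subset.  Vertices with
#' `min(1 - x0/t0, x1/t1) < min_ss` are disregarded (small subsets carry no
#' practical interest and are numerically fragile); when no vertex
#' qualifies the result is `p = 1`, `flt_SS = 0`.  Ties in the outer
#' minimum resolve to the first vertex in curve order.
#'
#' @param roc a [build_roc()] curve (single SNP or pair).
#' @param min_ss minimal sensitivity/specificity fraction (default 0.02).
#' @return An `epiroc_test` with `method = "ss"`; `log10_p` is flt_SS.
#' @export
p_ss <- function(roc, min_ss = 0.02) {
  stopifnot(inherits(roc, "roc_curve"))
  best <- NULL
  for (i in qualifying_vertices(roc, min_ss)) {
    r <- ss_point_pvalue(roc$vertices[i, 1L], roc$vertices[i, 2L],
                         roc$t0, roc$t1)
    if (is.null(best) || r$log10_p > best$log10_p) best <- r
  }
  if (is.null(best)) {
    return(new_epiroc_test(0, c(x0 = NA_integer_, x1 = NA_integer_),
                           c(pi0 = NA_real_, pi1 = NA_real_), "any", "ss"))
  }
  best$method <- "ss"
  best
}

#' GSS test of a SNP pair against its pair-specific null region
#'
#' The gain in sensitivity and specificity: the outer minimum of
#' [gss_point_pvalue()] over the pair's ROC vertices, with the null region
#' built from the two marginal single-SNP curves.  flt_GSS = -log10 of the
#' resulting p-value; when the pair's curve tracks a single-SNP curve every
#' vertex lies in the region and the p-value is close to 1.  With
#' `direction = "contributing"` or `"protective"` the outer minimum is
#' further restricted to the [demarcate()]d vertex subset.
#'
#' @param pair_roc [build_roc()] curve of the 2x9 pair table.
#' @param region [build_null_region()] from the pair's two marginal curves
#'   (or [diagonal_region()], which reduces the test to [p_ss()]).
#' @param direction `"any"`, `"contributing"` or `"protective"`.
#' @inheritParams p_ss
#' @return An `epiroc_test` with `method = "gss"`; `log10_p` is flt_GSS.
#' @export
p_gss <- function(pair_roc, region,
                  direction = c("any", "contributing", "protective"),
                  min_ss = 0.02) {
  stopifnot(inherits(pair_roc, "roc_curve"))
  stopifnot(inherits(region, "null_region"))
  direction <- match.arg(direction)
  check_region_totals(region, pair_roc$t0, pair_roc$t1)
  idx <- qualifying_vertices(pair_roc, min_ss)
  if (direction != "any") {
    dem <- demarcate(pair_roc)
    idx <- intersect(idx, if (direction == "contributing") dem$cntr else dem$prtv)
  }
  best <- NULL
  for (i in idx) {
    r <- gss_point_pvalue(pair_roc$vertices[i, 1L], pair_roc$vertices[i, 2L],
                          pair_roc$t0, pair_roc$t1, region)
    if (is.null(best) || r$log10_p > best$log10_p) best <- r
  }
  if (is.null(best)) {
    best <- new_epiroc_test(0, c(x0 = NA_integer_, x1 = NA_integer_),
                            c(pi0 = NA_real_, pi1 = NA_real_), direction, "gss")
    return(best)
  }
  best$method <- "gss"
  best$direction <- direction
  best
}

#' DSS score: the fast proxy for the gain test
#'
#' `flt_DSS = flt_SS(pair) - max(flt_SS(g1), flt_SS(g2))`: the log-p-value
#' improvement of the pair over its strongest constituent SNP, all three
#' terms computed by [p_ss()] with the same `min_ss` on the same sample
#' subset.  Cheap enough for exhaustive scans and well correlated with
#' flt_GSS.  May be slightly negative in edge cases (vertex exclusion);
#' the value is reported as-is, not clamped.
#'
#' @param pair_roc ROC curve of the pair table.
#' @param roc1,roc2 marginal single-SNP curves on the same sample subset.
#' @inheritParams p_ss
#' @return Numeric flt_DSS score.
#' @export
flt_dss <- function(pair_roc, roc1, roc2, min_ss = 0.02) {
  p_ss(pair_roc, min_ss)$log10_p -
    max(p_ss(roc1, min_ss)$log10_p, p_ss(roc2, min_ss)$log10_p)
}

#' Memoized SS point p-value kernel for fixed totals
#'
#' During a scan the totals `(t0, t1)` are fixed for every pair sharing a
#' complete-case sample subset, so [ss_point_pvalue()] depends only on the
#' cumulated counts `(x0, x1)` and can be tabulated.  Returns a function
#' `(x0, x1) -> epiroc_test` backed by a lazily-filled cache; cached values
#' are the very objects a direct call produces.  `attr(k, "stats")()`
#' reports hit/miss counters.
#'
#' @inheritParams ss_point_pvalue
#' @return A memoizing function of `(x0, x1)`.
#' @examples
#' k <- memoized_ss_kernel(100, 100)
#' k(10, 40)$log10_p
#' @export
memoized_ss_kernel <- function(t0, t1) {
  check_counts(0, 0, t0, t1)
  cache <- new.env(parent = emptyenv())
  hits <- 0L
  misses <- 0L
  f <- function(x0, x1) {
    key <- paste0(x0, ",", x1)
    if (!is.null(got <- cache[[key]])) {
      hits <<- hits + 1L
      return(got)
    }
    misses <<- misses + 1L
    cache[[key]] <- ss_point_pvalue(x0, x1, t0, t1)
  }
  attr(f, "stats") <- function() c(hits = hits, misses = misses)
  f
}
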