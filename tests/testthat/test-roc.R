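test_that("segment counts: 9 for a full pair table, 3 for a single SNP", {
  # distinct prevalences v/(v+10) for case counts 1..9
  pair_tab <- contingency_table(rbind(rep(10L, 9L), 1:9))
  expect_equal(nrow(build_roc(pair_tab)$vertices) - 1L, 9L)

  single_tab <- contingency_table(rbind(c(10L, 10L, 10L), c(1L, 5L, 9L)))
  expect_equal(nrow(build_roc(single_tab)$vertices) - 1L, 3L)
})

test_that("equal-prevalence cells merge; all-equal collapses to the diagonal", {
  tab <- contingency_table(rbind(c(10L, 20L, 30L), c(5L, 10L, 15L)))
  roc <- build_roc(tab)
  expect_equal(nrow(roc$vertices), 2L)     # single segment (0,0) -> (t0,t1)
  expect_equal(unname(roc$vertices[2L, ]), c(60L, 30L))
  expect_length(roc$cell_order, 1L)
  expect_setequal(roc$cell_order[[1L]], c("0", "1", "2"))
})

test_that("built curves are concave with cumulative, conserved counts", {
  set.seed(3)
  for (i in 1:200) {
    roc <- build_roc(random_table(sample(c(3L, 9L), 1L)))
    expect_true(slopes_nonincreasing(roc))
    v <- roc$vertices
    expect_equal(unname(v[1L, ]), c(0L, 0L))
    expect_equal(unname(v[nrow(v), ]), c(roc$t0, roc$t1))
    expect_true(all(diff(v[, 1L]) >= 0) && all(diff(v[, 2L]) >= 0))
  }
})

test_that("pair curves dominate both marginal curves", {
  set.seed(5)
  for (i in 1:200) {
    g1 <- sample(0:2, 40, replace = TRUE)
    g2 <- sample(0:2, 40, replace = TRUE)
    ph <- c(0L, 1L, sample(0:1, 38, replace = TRUE))
    pair <- build_roc(build_pair_table(g1, g2, ph))
    r1 <- build_roc(build_single_table(g1, ph))
    r2 <- build_roc(build_single_table(g2, ph))
    expect_true(dominates(pair, r1))
    expect_true(dominates(pair, r2))
    expect_true(dominates(pair, pair))
  }
})

test_that("crossing curves do not dominate each other", {
  a <- build_roc(contingency_table(rbind(c(1L, 9L), c(6L, 4L))))
  b <- build_roc(contingency_table(rbind(c(5L, 5L), c(9L, 1L))))
  # a rises fast early, b catches up late: verify crossing on a grid
  xs <- seq(0, 1, 0.01)
  da <- epiroc:::roc_interpolate(a, xs) - epiroc:::roc_interpolate(b, xs)
  expect_true(any(da > 1e-9) && any(da < -1e-9))
  expect_false(dominates(a, b))
  expect_false(dominates(b, a))
  expect_error(dominates(a, build_roc(contingency_table(rbind(c(2L, 2L), c(1L, 1L))))),
               "mismatched totals")
})

test_that("demarcation follows the segment-slope rule", {
  # perfect separation: vertical then horizontal -> middle vertex in both
  perf <- build_roc(contingency_table(rbind(c(0L, 4L), c(4L, 0L))))
  dem <- demarcate(perf)
  expect_equal(dem$cntr, 2L)
  expect_equal(dem$prtv, 2L)

  # interior vertices with slope exactly 1 on both sides -> in both sets
  diag3 <- build_roc(contingency_table(rbind(c(2L, 3L, 4L), c(2L, 3L, 4L))))
  # equal prevalences merge; build unmergeable slope-1 curve by hand
  flat <- structure(list(
    vertices = matrix(c(0L, 0L, 3L, 3L, 9L, 9L), ncol = 2L, byrow = TRUE),
    t0 = 9L, t1 = 9L, cell_order = list("a", "b")), class = "roc_curve")
  dem2 <- demarcate(flat)
  expect_equal(dem2$cntr, 2L)
  expect_equal(dem2$prtv, 2L)
  expect_length(demarcate(diag3)$cntr, 0L)  # merged: no interior vertices

  # slopes (3, 1.2, 0.2): vertices after the first two segments are
  # contributing, the vertex before the last segment is protective
  tab <- contingency_table(rbind(c(10L, 25L, 65L), c(30L, 30L, 13L)))
  roc <- build_roc(tab)
  expect_equal(nrow(roc$vertices), 4L)
  dem3 <- demarcate(roc)
  expect_equal(dem3$cntr, c(2L, 3L))
  expect_equal(dem3$prtv, 3L)
})

test_that("null-region chains match a brute-force convex hull", {
  set.seed(9)
  for (i in 1:50) {
    g1 <- sample(0:2, 30, replace = TRUE)
    g2 <- sample(0:2, 30, replace = TRUE)
    ph <- c(0L, 1L, sample(0:1, 28, replace = TRUE))
    r1 <- build_roc(build_single_table(g1, ph))
    r2 <- build_roc(build_single_table(g2, ph))
    reg <- build_null_region(r1, r2)
    ch <- reg$upper_boundary
    expect_equal(unname(ch[1, ]), c(0, 0))
    expect_equal(unname(ch[nrow(ch), ]), c(1, 1))
    # oracle: grDevices::chull over all candidate points
    pts <- unique(rbind(epiroc:::roc_fractions(r1),
                        epiroc:::roc_fractions(r2), c(0, 0), c(1, 1)))
    hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
    # every chain point lies on the hull boundary, every point under the chain
    seg_dist <- function(p, a, b) {
      ab <- b - a
      tt <- if (sum(ab^2) == 0) 0 else
        max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((a + tt * ab - p)^2))
    }
    nh <- nrow(hull)
    for (k in seq_len(nrow(ch))) {
      dmin <- min(vapply(seq_len(nh), function(e)
        seg_dist(ch[k, ], hull[e, ], hull[e %% nh + 1L, ]), numeric(1)))
      expect_lt(dmin, 1e-9)
    }
    for (k in seq_len(nrow(pts))) {
      expect_true(region_contains(reg, pts[k, 1], pts[k, 2], tol = 1e-9))
    }
    # chain is concave
    if (nrow(ch) >= 3) {
      sl <- diff(ch[, 2]) / diff(ch[, 1])
      expect_true(all(diff(sl[is.finite(sl)]) < 1e-9))
    }
  }
})

test_that("degenerate and diagonal regions behave", {
  ph <- rep(0:1, each = 5L)
  flat <- build_roc(build_single_table(rep(1L, 10L), ph))
  reg <- build_null_region(flat, flat)
  expect_equal(unname(reg$upper_boundary), rbind(c(0, 0), c(1, 1)))

  dia <- diagonal_region()
  expect_equal(dia$kind, "diagonal")
  expect_true(region_contains(dia, 0.3, 0.3))
  expect_true(region_contains(dia, 0.5, 0.2))
  expect_false(region_contains(dia, 0.2, 0.5))

  # a dominated curve is absorbed by the dominating curve's hull
  strong <- build_roc(contingency_table(rbind(c(1L, 9L), c(8L, 2L))))
  weak <- build_roc(contingency_table(rbind(c(4L, 6L), c(5L, 5L))))
  stopifnot(dominates(strong, weak))
  reg2 <- build_null_region(strong, weak)
  reg3 <- build_null_region(strong, strong)
  expect_equal(reg2$upper_boundary, reg3$upper_boundary)
})
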