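test_that("log-space binomial tails match direct summation and partition", {
  expect_equal(log_binom_lower(4, 4, 0.3), 0)
  expect_equal(log_binom_lower(0, 4, 0.5), log(1 / 16))
  expect_equal(log_binom_upper(0, 7, 0.9), 0)
  expect_equal(log_binom_upper(4, 4, 0.5), log(1 / 16))
  # complement identity over random cases
  set.seed(2)
  for (i in 1:30) {
    t <- sample(1:200, 1); x <- sample(0:(t - 1), 1); p <- runif(1)
    expect_equal(exp(log_binom_lower(x, t, p)) + exp(log_binom_upper(x + 1, t, p)),
                 1, tolerance = 1e-12)
  }
  # monotone in pi; no underflow at large totals
  ps <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(log_binom_lower(20, 100, ps)) <= 0))
  expect_true(all(diff(log_binom_upper(20, 100, ps)) >= 0))
  expect_true(is.finite(log_binom_lower(10, 1e5, 0.9)))
  expect_error(log_binom_lower(5, 4, 0.5), "x <= t")
})

test_that("SS point p-values match closed forms and the dense-grid oracle", {
  expect_equal(ss_point_pvalue(5, 0, 5, 9)$p_value, 1)   # x1 = 0
  expect_equal(ss_point_pvalue(0, 1, 1, 1)$p_value, 0.25, tolerance = 1e-10)
  expect_equal(ss_point_pvalue(0, 1, 1, 1)$arg_pi[["pi0"]], 0.5, tolerance = 1e-6)
  expect_equal(ss_point_pvalue(0, 2, 2, 2)$p_value, 1 / 16, tolerance = 1e-10)
  set.seed(4)
  for (i in 1:50) {
    t0 <- sample(1:60, 1); t1 <- sample(1:60, 1)
    x0 <- sample(0:t0, 1); x1 <- sample(0:t1, 1)
    r <- ss_point_pvalue(x0, x1, t0, t1)
    expect_lt(abs(r$log10_p - oracle_ss_log10p(x0, x1, t0, t1)), 1e-6)
    # flt / p-value consistency
    expect_equal(r$p_value, 10^(-r$log10_p), tolerance = 1e-9)
  }
})

test_that("SS point p-values are monotone in the cumulated counts", {
  for (x1 in 1:9) {
    expect_gte(ss_point_pvalue(4, x1, 12, 10)$p_value,
               ss_point_pvalue(4, x1 + 1, 12, 10)$p_value - 1e-12)
  }
  for (x0 in 0:10) {
    expect_lte(ss_point_pvalue(x0, 6, 12, 10)$p_value,
               ss_point_pvalue(x0 + 1, 6, 12, 10)$p_value + 1e-12)
  }
})

test_that("GSS point p-value: square region, diagonal reduction, 2-D oracle", {
  # region whose chain passes through (0, 1): both tails reach 1
  perf <- build_roc(contingency_table(rbind(c(0L, 8L), c(8L, 0L))))
  square <- build_null_region(perf, perf)
  expect_equal(gss_point_pvalue(3, 6, 8, 8, square)$p_value, 1)

  # diagonal region reduces exactly to the SS test
  set.seed(6)
  for (i in 1:50) {
    t0 <- sample(1:60, 1); t1 <- sample(1:60, 1)
    x0 <- sample(0:t0, 1); x1 <- sample(0:t1, 1)
    expect_identical(gss_point_pvalue(x0, x1, t0, t1, diagonal_region())$log10_p,
                     ss_point_pvalue(x0, x1, t0, t1)$log10_p)
  }

  # sub-diagonal triangle: max sits on the diagonal
  expect_equal(gss_point_pvalue(0, 1, 1, 1, diagonal_region())$p_value, 0.25,
               tolerance = 1e-9)
  tri_oracle <- oracle_region_log10p(0, 1, 1, 1,
                                     chain = rbind(c(0, 0), c(1, 1)),
                                     step = 1e-4)
  expect_lt(abs(gss_point_pvalue(0, 1, 1, 1, diagonal_region())$log10_p -
                tri_oracle), 1e-4)
})

test_that("GSS point p-values match chain-grid and region-grid oracles", {
  set.seed(8)
  for (i in 1:40) {
    g1 <- sample(0:2, 30, replace = TRUE)
    g2 <- sample(0:2, 30, replace = TRUE)
    ph <- c(0L, 1L, sample(0:1, 28, replace = TRUE))
    r1 <- build_roc(build_single_table(g1, ph))
    r2 <- build_roc(build_single_table(g2, ph))
    reg <- build_null_region(r1, r2)
    t0 <- r1$t0; t1 <- r1$t1
    x0 <- sample(0:t0, 1); x1 <- sample(0:t1, 1)
    got <- gss_point_pvalue(x0, x1, t0, t1, reg)$log10_p
    expect_lt(abs(got - oracle_chain_log10p(x0, x1, t0, t1,
                                            reg$upper_boundary)), 1e-6)
    if (i <= 20) {
      # the full-region maximum lies on the upper chain
      reg_oracle <- oracle_region_log10p(x0, x1, t0, t1,
                                         chain = reg$upper_boundary)
      expect_lt(abs(got - reg_oracle), 1e-2)
    }
  }
})

test_that("p_ss: exclusion rule, perfect separation, vertex-min structure", {
  ph <- rep(0:1, each = 4L)
  # diagonal curve: only endpoints, neither passes min_ss -> p = 1, flt = 0
  dia <- build_roc(build_single_table(rep(1L, 8L), ph))
  r <- p_ss(dia)
  expect_equal(r$p_value, 1)
  expect_equal(r$log10_p, 0)

  # perfect separation with t0 = t1 = 4: p = (1/2)^8 at the corner vertex
  perf <- build_roc(contingency_table(rbind(c(0L, 4L), c(4L, 0L))))
  r2 <- p_ss(perf)
  expect_equal(r2$p_value, 1 / 256, tolerance = 1e-9)
  expect_equal(r2$log10_p, -log10(1 / 256), tolerance = 1e-9)
  expect_equal(unname(r2$best_vertex), c(0, 4))

  # adding a dominated vertex (min over a superset) never lowers the flt
  set.seed(10)
  for (i in 1:20) {
    roc9 <- build_roc(random_table(9L))
    v <- roc9$vertices
    k <- sample(nrow(v) - 1L, 1)
    extra <- floor((v[k, ] + v[k + 1L, ]) / 2)
    aug <- roc9
    aug$vertices <- rbind(v[1:k, , drop = FALSE], extra,
                          v[(k + 1L):nrow(v), , drop = FALSE])
    expect_gte(p_ss(aug)$log10_p + 1e-9, p_ss(roc9)$log10_p)
  }
})

test_that("p_gss: in-region pairs score ~0, diagonal marginals recover SS", {
  ph <- rep(0:1, each = 10L)
  set.seed(12)
  g <- sample(0:2, 20, replace = TRUE)
  # pair of a SNP with itself: pair ROC equals the single ROC
  tabp <- build_pair_table(g, g, ph)
  rocp <- build_roc(tabp)
  r1 <- build_roc(build_single_table(g, ph))
  reg <- build_null_region(r1, r1)
  r <- p_gss(rocp, reg)
  expect_lte(r$log10_p, -log10(0.25) + 1e-9)   # p within [0.25, 1]

  # XOR toy: both marginals are diagonal, GSS = SS of the pair
  toy <- xor_toy()
  rocp2 <- build_roc(build_pair_table(toy$g1, toy$g2, toy$phenotype))
  m1 <- build_roc(build_single_table(toy$g1, toy$phenotype))
  m2 <- build_roc(build_single_table(toy$g2, toy$phenotype))
  reg2 <- build_null_region(m1, m2)
  expect_equal(unname(reg2$upper_boundary), rbind(c(0, 0), c(1, 1)))
  flt_gss <- p_gss(rocp2, reg2)$log10_p
  flt_ss <- p_ss(rocp2)$log10_p
  expect_equal(flt_gss, flt_ss, tolerance = 1e-12)
  expect_equal(flt_ss, -log10(1 / 256), tolerance = 1e-9)

  # direction restriction: the perfect-separation vertex has a vertical
  # incoming and horizontal outgoing segment, so it is demarcated as both
  # contributing and protective and both directional gains equal the full one
  expect_equal(p_gss(rocp2, reg2, "contributing")$log10_p, flt_ss,
               tolerance = 1e-12)
  expect_equal(p_gss(rocp2, reg2, "protective")$log10_p, flt_ss,
               tolerance = 1e-12)
  expect_error(p_gss(rocp2, build_null_region(r1, r1)), "totals")
})

test_that("flt_dss: self-pairs and constant partners gain nothing, XOR gains", {
  ph <- rep(0:1, each = 10L)
  set.seed(14)
  g <- sample(0:2, 20, replace = TRUE)
  rocs <- build_roc(build_single_table(g, ph))
  rocp <- build_roc(build_pair_table(g, g, ph))
  expect_equal(flt_dss(rocp, rocs, rocs), 0, tolerance = 1e-9)

  const <- rep(2L, 20)
  rocc <- build_roc(build_single_table(const, ph))
  rocpc <- build_roc(build_pair_table(g, const, ph))
  expect_equal(flt_dss(rocpc, rocs, rocc), 0, tolerance = 1e-9)

  toy <- xor_toy()
  rocp2 <- build_roc(build_pair_table(toy$g1, toy$g2, toy$phenotype))
  m1 <- build_roc(build_single_table(toy$g1, toy$phenotype))
  m2 <- build_roc(build_single_table(toy$g2, toy$phenotype))
  expect_equal(flt_dss(rocp2, m1, m2), -log10(1 / 256), tolerance = 1e-9)
})

test_that("memoized kernel returns identical values and computes once", {
  k <- memoized_ss_kernel(40, 35)
  set.seed(16)
  keys <- cbind(sample(0:40, 100, replace = TRUE),
                sample(0:35, 100, replace = TRUE))
  for (i in seq_len(nrow(keys))) {
    expect_identical(k(keys[i, 1], keys[i, 2])$log10_p,
                     ss_point_pvalue(keys[i, 1], keys[i, 2], 40, 35)$log10_p)
  }
  before <- attr(k, "stats")()
  for (i in 1:50) k(7, 21)
  after <- attr(k, "stats")()
  expect_equal(after[["misses"]] - before[["misses"]],
               if (any(keys[, 1] == 7 & keys[, 2] == 21)) 0 else 1)
  expect_gte(after[["hits"]] - before[["hits"]], 49)
  # kernels with different totals are distinct caches
  k2 <- memoized_ss_kernel(41, 35)
  expect_false(identical(k(0, 35)$log10_p, k2(0, 35)$log10_p))
})

test_that("SS vertex p-values track one-sided Fisher closely", {
  set.seed(18)
  n <- 1000
  ss <- numeric(n); fi <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- sample(5:80, 1); t1 <- sample(5:80, 1)
    x0 <- sample(0:t0, 1); x1 <- sample(0:t1, 1)
    ss[i] <- ss_point_pvalue(x0, x1, t0, t1)$p_value
    fi[i] <- fisher_exact_1sided(x0, x1, t0, t1)
  }
  expect_gt(cor(log(ss), log(fi), method = "spearman"), 0.99)
})
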