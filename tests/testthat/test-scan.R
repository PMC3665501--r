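test_that("Bonferroni thresholds reproduce the genome-scale constants", {
  expect_equal(bonferroni_threshold(2)$p_threshold, 1)
  expect_equal(bonferroni_threshold(2, alpha = 0.05)$p_threshold, 0.05)
  expect_equal(bonferroni_threshold(500000)$n_pairs, 1.25e11,
               tolerance = 1e-5)
  expect_equal(round(bonferroni_threshold(459012)$log10_threshold), 11)
  expect_equal(bonferroni_threshold(1000)$p_threshold, 1 / 499500)
  expect_equal(bonferroni_threshold(1000)$p_threshold, 2e-6, tolerance = 0.01)
  expect_error(bonferroni_threshold(1), "m >= 2")
})

test_that("univariate scan: conservation, null and separating SNPs", {
  set.seed(31)
  d <- random_geno_data(20, 50, 50)
  # make SNP 1 identically distributed in cases and controls
  d$genotypes[1, ] <- rep(c(0L, 1L, 2L, 1L, 0L), 20)
  # make SNP 2 a perfect separator
  d$genotypes[2, ] <- c(rep(0L, 50), rep(2L, 50))
  res <- scan_univariate(d)
  expect_equal(nrow(res), 20L)            # no SNP silently dropped
  expect_equal(res$snp_idx, 1:20)
  expect_equal(res$flt_ss[1], 0)
  # a perfect separator at 50/50 passes any desk-scale Bonferroni level
  expect_gt(res$flt_ss[2], bonferroni_threshold(1000)$log10_threshold)
  expect_gt(res$chi2_neg_log10p[2], 20)
  # flt_ss agrees with the R-level p_ss path
  for (j in c(1L, 2L, 5L, 9L)) {
    roc <- build_roc(build_single_table(d$genotypes[j, ], d$phenotype))
    expect_equal(res$flt_ss[j], p_ss(roc)$log10_p, tolerance = 1e-9)
  }
})

test_that("pair scan is exhaustive, deterministic and filter-independent", {
  set.seed(32)
  d <- random_geno_data(40, 30, 30)
  sc <- scan_pairs(d, filters = c("dss", "ss", "chi2"), top_k = 1000)
  expect_equal(attr(sc, "n_evaluated"), choose(40, 2))
  # determinism: a second run is identical
  sc2 <- scan_pairs(d, filters = c("dss", "ss", "chi2"), top_k = 1000)
  expect_identical(sc$dss, sc2$dss)
  expect_identical(sc$chi2, sc2$chi2)
  # filter independence: scanning with a subset leaves results unchanged
  only_dss <- scan_pairs(d, filters = "dss", top_k = 1000)
  expect_equal(only_dss$dss[c("snp1_idx", "snp2_idx", "flt_dss")],
               sc$dss[c("snp1_idx", "snp2_idx", "flt_dss")])
  # each pair appears once, ordered indices
  key <- paste(sc$ss$snp1_idx, sc$ss$snp2_idx)
  expect_false(any(duplicated(key)))
  expect_true(all(sc$ss$snp1_idx < sc$ss$snp2_idx))
  # scores sorted descending with deterministic tie-break
  expect_true(all(diff(sc$dss$score) <= 1e-12))
})

test_that("pair counter matches C(m,2) and min_distance excludes pairs", {
  set.seed(33)
  d <- random_geno_data(200, 20, 20)
  sc <- scan_pairs(d, filters = "chi2", top_k = 5)
  expect_equal(attr(sc, "n_evaluated"), 19900)

  # all SNPs on one chromosome at 10kb spacing: radius 25kb excludes
  # lag-1 and lag-2 neighbours
  d2 <- random_geno_data(50, 20, 20)
  sc2 <- scan_pairs(d2, filters = "chi2", top_k = 5, min_distance = 25000)
  expect_equal(attr(sc2, "n_excluded"), 49 + 48)
  expect_equal(attr(sc2, "n_evaluated"), choose(50, 2) - 97)
})

test_that("scan agrees with the R reference path pair by pair", {
  set.seed(34)
  d <- random_geno_data(12, 25, 25)
  d$genotypes[sample(length(d$genotypes), 30)] <- NA
  sc <- scan_pairs(d, filters = c("dss", "ss", "chi2"), top_k = 10000)
  tab <- sc$ss
  for (k in sample(nrow(tab), 20)) {
    g1 <- d$genotypes[tab$snp1_idx[k], ]
    g2 <- d$genotypes[tab$snp2_idx[k], ]
    keep <- !is.na(g1) & !is.na(g2)
    pt <- build_pair_table(g1, g2, d$phenotype)
    roc <- build_roc(pt)
    r1 <- build_roc(build_single_table(g1[keep], d$phenotype[keep]))
    r2 <- build_roc(build_single_table(g2[keep], d$phenotype[keep]))
    expect_equal(tab$flt_ss[k], p_ss(roc)$log10_p, tolerance = 1e-9)
    expect_equal(tab$flt_dss[k], flt_dss(roc, r1, r2), tolerance = 1e-9)
    expect_equal(tab$chi2[k], as.numeric(chi2_statistic(pt)), tolerance = 1e-9)
  }
})

test_that("gss_stage retains planted signal and discards main-effect pairs", {
  set.seed(35)
  model <- make_pure_epistasis_model("xor", maf = 0.4, effect_scale = 0.15)
  sim <- simulate_epistatic(model, 400, 400, 48, seed = 351)
  sc <- scan_pairs(sim$data, filters = "dss", top_k = 20)
  expect_equal(sort(unlist(sc$dss[1, c("snp1_idx", "snp2_idx")])),
               sim$planted, ignore_attr = TRUE)
  kept <- gss_stage(sc$dss[1, ], sim$data)
  expect_equal(nrow(kept), 1L)
  expect_gte(kept$flt_gss, bonferroni_threshold(50)$log10_threshold)
  expect_true(kept$flt_gss <= sc$dss$flt_ss[1] + 1e-9)  # GSS <= SS
  expect_true(nzchar(kept$best_calls))

  # a pair of one SNP with a recoded copy of itself gains nothing
  d <- sim$data
  d$genotypes[3, ] <- 2L - d$genotypes[5, ]   # perfect rank-reversal copy
  cand <- tibble::tibble(snp1_idx = 3L, snp2_idx = 5L)
  expect_equal(nrow(gss_stage(cand, d)), 0L)

  # univariately-driven pair: strong main effect x null SNP has large chi2
  # but no gain
  d2 <- sim$data
  d2$genotypes[7, ] <- simulate_main_effect(0.3, c(1, 2.5, 6), 400, 400,
                                            seed = 352)
  pt <- build_pair_table(d2$genotypes[7, ], d2$genotypes[9, ], d2$phenotype)
  expect_gt(chi2_pvalue(as.numeric(chi2_statistic(pt)), 8),
            bonferroni_threshold(50)$log10_threshold)
  expect_equal(nrow(gss_stage(tibble::tibble(snp1_idx = 7L, snp2_idx = 9L),
                              d2)), 0L)
})

test_that("frequency report counts memberships and conserves totals", {
  rec <- tibble::tibble(snp1_id = c("a", "b", "c"), snp2_id = c("d", "e", "f"))
  fr <- snp_frequency_report(rec)
  expect_equal(sort(fr$snp_id), letters[1:6])
  expect_true(all(fr$n_pairs == 1L))

  hub <- tibble::tibble(snp1_id = rep("hub", 5), snp2_id = letters[1:5])
  fr2 <- snp_frequency_report(hub)
  expect_equal(fr2$n_pairs[fr2$snp_id == "hub"], 5L)
  expect_equal(sum(fr2$n_pairs), 2L * nrow(hub))
  expect_equal(nrow(snp_frequency_report(rec[0, ])), 0L)
})

test_that("OR/critical report: exact log2 values and threshold flags", {
  rec <- tibble::tibble(
    odds_ratio = c(2, 1, 25.728, 0.5),
    critical_sens_spec = c(0.05, 0.3, 0.0579, 0.01),
    direction = c("contributing", "contributing", "contributing", "protective"))
  rep <- or_sensspec_report(rec)
  expect_equal(rep$log2_or[1], 1)
  expect_equal(rep$log2_or[2], 0)
  expect_equal(rep$log2_or[3], log2(25.728))
  expect_equal(rep$log2_or[3], 4.69, tolerance = 2e-3)
  expect_equal(rep$log2_or[4], -1)
  expect_equal(rep$below_min_coverage, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(rep$weak_or, c(FALSE, TRUE, FALSE, FALSE))
})
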