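#' Bonferroni threshold for an exhaustive pairwise scan
#'
#' With `m` SNPs there are `C(m, 2)` unordered pairs; the family-wise
#' threshold is `alpha / C(m, 2)` (default `alpha = 1`, i.e. one expected
#' false positive under the global null -- the convention used throughout
#' the scan engine).  For 459,012 SNPs the -log10 threshold is about 11;
#' for 1,000 SNPs the p threshold is about 2e-6.
#'
#' @param m number of SNPs (`>= 2`).
#' @param alpha family-wise level in `(0, 1]`.
#' @return One-row tibble with `n_pairs`, `p_threshold`,
#'   `log10_threshold = log10(C(m,2) / alpha)`.
#' @examples
#' bonferroni_threshold(1000)
#' @export
bonferroni_threshold <- function(m, alpha = 1) {
  if (m < 2) stop("need m >= 2")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  n_pairs <- m * (m - 1) / 2
  tibble::tibble(n_pairs = n_pairs, p_threshold = alpha / n_pairs,
                 log10_threshold = log10(n_pairs / alpha))
}

geno_int_matrix <- function(data) {
  g <- t(data$genotypes)          # samples x SNPs for column-major access
  storage.mode(g) <- "integer"
  g
}

#' Univariate scan: per-SNP SS and chi-square scores
#'
#' Builds each SNP's 2x3 table (per-SNP complete cases), scores it with the
#' SS test and the 2-df chi-square, and returns one record per SNP in input
#' order.  SNPs whose table is degenerate (no cases or no controls left)
#' get `NA` scores with a warning.
#'
#' @param data a [genotype_data] object.
#' @param min_ss minimal sensitivity/specificity fraction for [p_ss()].
#' @return Tibble with columns `snp_idx`, `snp_id`, `chr`, `pos`, `flt_ss`,
#'   `chi2`, `chi2_neg_log10p`, `t0`, `t1`.
#' @export
scan_univariate <- function(data, min_ss = 0.02) {
  stopifnot(inherits(data, "genotype_data"))
  g <- geno_int_matrix(data)
  ph <- data$phenotype
  flt <- single_scan_cpp(g, ph, min_ss)
  m <- n_snps(data)
  chi2 <- numeric(m); t0 <- integer(m); t1 <- integer(m)
  for (j in seq_len(m)) {
    keep <- !is.na(g[, j])
    t0[j] <- sum(ph[keep] == 0L); t1[j] <- sum(ph[keep] == 1L)
    if (t0[j] == 0L || t1[j] == 0L) { chi2[j] <- NA_real_; next }
    tab <- build_single_table(g[, j], ph)
    chi2[j] <- as.numeric(chi2_statistic(tab))
  }
  if (anyNA(chi2)) warning(sum(is.na(chi2)), " SNP(s) skipped: degenerate table")
  tibble::tibble(
    snp_idx = seq_len(m), snp_id = data$snp_meta$snp_id,
    chr = data$snp_meta$chr, pos = data$snp_meta$pos,
    flt_ss = flt, chi2 = chi2,
    chi2_neg_log10p = ifelse(is.na(chi2), NA_real_, chi2_pvalue(ifelse(is.na(chi2), 0, chi2), 2)),
    t0 = t0, t1 = t1)
}

# Raw exhaustive scan: all evaluated pairs, no truncation.  Backs both
# scan_pairs() and the power harness.
pair_scan_raw <- function(data, filters, min_ss, min_distance) {
  g <- geno_int_matrix(data)
  do_ss <- any(c("ss", "dss") %in% filters)
  do_chi2 <- "chi2" %in% filters
  chr_i <- as.integer(factor(data$snp_meta$chr))
  pos_i <- as.integer(data$snp_meta$pos)
  pos_i[is.na(pos_i)] <- 0L
  raw <- pair_scan_cpp(g, data$phenotype, min_ss, do_ss, do_chi2,
                       chr_i, pos_i, min_distance)
  out <- tibble::tibble(snp1_idx = raw$snp1_idx, snp2_idx = raw$snp2_idx,
                        t0 = raw$t0, t1 = raw$t1)
  if (do_ss) {
    out$flt_ss <- raw$flt_ss
    out$flt_ss1 <- raw$flt_ss1
    out$flt_ss2 <- raw$flt_ss2
    out$flt_dss <- raw$flt_dss
  }
  if (do_chi2) {
    out$chi2 <- raw$chi2
    out$chi2_neg_log10p <- ifelse(is.na(raw$chi2), NA_real_,
                                  chi2_pvalue(ifelse(is.na(raw$chi2), 0, raw$chi2), 8))
  }
  attr(out, "n_evaluated") <- raw$n_evaluated
  attr(out, "n_excluded") <- raw$n_excluded
  out
}

filter_score_col <- c(ss = "flt_ss", dss = "flt_dss", chi2 = "chi2_neg_log10p")

#' Exhaustive pairwise scan with simultaneous filters
#'
#' Iterates every unordered SNP pair exactly once (optionally excluding
#' same-chromosome pairs closer than `min_distance` base pairs), builds the
#' 2x9 pair table once per pair, and feeds it to every enabled filter:
#' `"ss"` (pair flt_SS), `"dss"` (flt_SS gain over the best constituent
#' SNP, the primary epistasis filter) and `"chi2"` (8-df chi-square).  Each
#' filter keeps its own result set -- enabling one filter never changes
#' another's results -- truncated to `top_k` rows after optional Bonferroni
#' thresholding.  Output is fully deterministic: rows sort by descending
#' score, ties by `(snp1_idx, snp2_idx)`.
#'
#' @param data a [genotype_data] object with `m >= 2` SNPs.
#' @param filters subset of `c("dss", "ss", "chi2")`.
#' @param top_k per-filter result-set capacity.
#' @param threshold_mode `"top_k"` keeps the best `top_k` pairs per filter;
#'   `"bonferroni"` additionally requires score `>= log10(C(m,2)/alpha)`.
#' @param alpha family-wise level for `"bonferroni"` mode.
#' @param min_ss minimal sensitivity/specificity fraction for SS/DSS.
#' @param min_distance base-pair exclusion radius, 0 = none (exhaustive
#'   search removes the need for distance constraints; the knob exists for
#'   replicating distance-filtered studies).
#' @return Object of class `pair_scan`: named list of per-filter tibbles
#'   (each with pair indices, ids, positions, all computed scores and a
#'   `score` column), with attributes `n_evaluated`, `n_excluded`, `m`,
#'   `log10_threshold`.
#' @seealso [gss_stage()] for the exact confirmatory stage.
#' @export
scan_pairs <- function(data, filters = c("dss", "chi2"), top_k = 500000L,
                       threshold_mode = c("top_k", "bonferroni"), alpha = 1,
                       min_ss = 0.02, min_distance = 0) {
  stopifnot(inherits(data, "genotype_data"))
  filters <- match.arg(filters, c("dss", "ss", "chi2"), several.ok = TRUE)
  threshold_mode <- match.arg(threshold_mode)
  if (top_k < 1) stop("top_k must be >= 1")
  m <- n_snps(data)
  if (m < 2) stop("need at least 2 SNPs")
  raw <- pair_scan_raw(data, filters, min_ss, min_distance)
  thr <- bonferroni_threshold(m, alpha)
  meta <- data$snp_meta
  decorate <- function(d) {
    d$snp1_id <- meta$snp_id[d$snp1_idx]
    d$snp2_id <- meta$snp_id[d$snp2_idx]
    d$snp1_chr <- meta$chr[d$snp1_idx]
    d$snp1_pos <- meta$pos[d$snp1_idx]
    d$snp2_chr <- meta$chr[d$snp2_idx]
    d$snp2_pos <- meta$pos[d$snp2_idx]
    d
  }
  out <- lapply(filters, function(f) {
    col <- filter_score_col[[f]]
    d <- raw
    d$score <- d[[col]]
    d <- d[!is.na(d$score), , drop = FALSE]
    if (threshold_mode == "bonferroni") {
      d <- d[d$score >= thr$log10_threshold, , drop = FALSE]
    }
    d <- d[order(-d$score, d$snp1_idx, d$snp2_idx), , drop = FALSE]
    decorate(head(d, top_k))
  })
  names(out) <- filters
  structure(out, class = "pair_scan",
            n_evaluated = attr(raw, "n_evaluated"),
            n_excluded = attr(raw, "n_excluded"),
            m = m, log10_threshold = thr$log10_threshold,
            threshold_mode = threshold_mode)
}

#' @export
print.pair_scan <- function(x, ...) {
  cat("<pair_scan> ", format(attr(x, "n_evaluated"), big.mark = ","),
      " pairs evaluated over ", attr(x, "m"), " SNPs (",
      format(attr(x, "n_excluded"), big.mark = ","), " excluded)\n", sep = "")
  for (f in names(x)) {
    cat("  ", f, ": ", nrow(x[[f]]), " record(s)", sep = "")
    if (nrow(x[[f]]) > 0) {
      cat(", top score ", format(x[[f]]$score[1L], digits = 6), sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' @describeIn scan_pairs scan summary as a one-row-per-filter tibble.
#' @param x a `pair_scan` object.
#' @param ... unused.
#' @export
glance.pair_scan <- function(x, ...) {
  tibble::tibble(
    filter = names(x),
    n_records = vapply(x, nrow, integer(1)),
    top_score = vapply(x, function(d)
      if (nrow(d)) d$score[1L] else NA_real_, numeric(1)),
    n_evaluated = attr(x, "n_evaluated"),
    n_excluded = attr(x, "n_excluded"),
    m = attr(x, "m"),
    log10_threshold = attr(x, "log10_threshold"))
}

#' Exact GSS confirmatory stage over candidate pairs
#'
#' Second stage of the two-stage pipeline: a fast, lenient primary filter
#' (usually DSS from [scan_pairs()]) proposes candidate pairs; this stage
#' recomputes each candidate exactly, testing the pair's ROC curve against
#' the convex null region of its two marginal single-SNP curves, separately
#' for contributing and protective gains.  A candidate is retained when its
#' headline gain `flt_gss = max(flt_gss_cntr, flt_gss_prtv)` reaches the
#' Bonferroni level `log10(C(m,2)/alpha)`.  The winning direction's
#' genotype-call subset is reported with its odds ratio, coverage and
#' critical sens/spec (prefix of the prevalence order for contributing
#' subsets, suffix for protective ones).
#'
#' @param candidates tibble with `snp1_idx`, `snp2_idx` columns (any
#'   element of a [scan_pairs()] result works).
#' @param data the [genotype_data] the candidates refer to.
#' @param alpha family-wise level for the retention threshold.
#' @param min_ss minimal sensitivity/specificity fraction.
#' @param log10_threshold retention threshold override; defaults to the
#'   Bonferroni level for `n_snps(data)` pairs at `alpha`.
#' @return Tibble of retained candidates with columns `snp1_idx`,
#'   `snp2_idx`, `snp1_id`, `snp2_id`, `flt_gss_cntr`, `flt_gss_prtv`,
#'   `flt_gss`, `direction`, `odds_ratio`, `xi0`, `xi1`,
#'   `critical_sens_spec`, `best_calls`, plus any score columns carried
#'   over from `candidates`.
#' @export
gss_stage <- function(candidates, data, alpha = 1, min_ss = 0.02,
                      log10_threshold = NULL) {
  stopifnot(inherits(data, "genotype_data"))
  candidates <- tibble::as_tibble(candidates)
  if (is.null(log10_threshold)) {
    log10_threshold <- bonferroni_threshold(n_snps(data), alpha)$log10_threshold
  }
  n <- nrow(candidates)
  res <- vector("list", n)
  for (k in seq_len(n)) {
    i <- candidates$snp1_idx[k]
    j <- candidates$snp2_idx[k]
    gg <- pair_gss_detail(data$genotypes[i, ], data$genotypes[j, ],
                          data$phenotype, min_ss)
    res[[k]] <- gg
  }
  det <- dplyr::bind_rows(res)
  out <- dplyr::bind_cols(candidates, det)
  out$snp1_id <- data$snp_meta$snp_id[out$snp1_idx]
  out$snp2_id <- data$snp_meta$snp_id[out$snp2_idx]
  out <- out[!is.na(out$flt_gss) & out$flt_gss >= log10_threshold, ,
             drop = FALSE]
  out[order(-out$flt_gss, out$snp1_idx, out$snp2_idx), , drop = FALSE]
}

# Full exact GSS work-up of one pair: both directions, best-call subset,
# effect summary.
pair_gss_detail <- function(g1, g2, phenotype, min_ss = 0.02) {
  na_row <- tibble::tibble(
    flt_gss_cntr = NA_real_, flt_gss_prtv = NA_real_, flt_gss = NA_real_,
    direction = NA_character_, odds_ratio = NA_real_, xi0 = NA_real_,
    xi1 = NA_real_, critical_sens_spec = NA_real_, best_calls = NA_character_)
  keep <- !is.na(g1) & !is.na(g2)
  if (!any(keep)) return(na_row)
  ph <- phenotype[keep]
  if (!any(ph == 0L) || !any(ph == 1L)) return(na_row)
  pair_tab <- build_pair_table(g1, g2, phenotype)
  roc_pair <- build_roc(pair_tab)
  roc1 <- build_roc(build_single_table(g1[keep], ph))
  roc2 <- build_roc(build_single_table(g2[keep], ph))
  region <- build_null_region(roc1, roc2)
  cntr <- p_gss(roc_pair, region, "contributing", min_ss)
  prtv <- p_gss(roc_pair, region, "protective", min_ss)
  win <- if (cntr$log10_p >= prtv$log10_p) cntr else prtv
  dir <- if (cntr$log10_p >= prtv$log10_p) "contributing" else "protective"
  if (anyNA(win$best_vertex)) {
    out <- na_row
    out$flt_gss_cntr <- cntr$log10_p
    out$flt_gss_prtv <- prtv$log10_p
    out$flt_gss <- max(cntr$log10_p, prtv$log10_p)
    return(out)
  }
  x0 <- win$best_vertex[[1L]]
  x1 <- win$best_vertex[[2L]]
  vrow <- which(roc_pair$vertices[, 1L] == x0 & roc_pair$vertices[, 2L] == x1)[1L]
  if (dir == "contributing") {
    eff <- effect_summary(x0, x1, roc_pair$t0, roc_pair$t1)
    calls <- unlist(roc_pair$cell_order[seq_len(vrow - 1L)])
  } else {
    eff <- effect_summary(roc_pair$t0 - x0, roc_pair$t1 - x1,
                          roc_pair$t0, roc_pair$t1)
    calls <- unlist(roc_pair$cell_order[seq(vrow, length(roc_pair$cell_order))])
  }
  tibble::tibble(
    flt_gss_cntr = cntr$log10_p, flt_gss_prtv = prtv$log10_p,
    flt_gss = max(cntr$log10_p, prtv$log10_p), direction = dir,
    odds_ratio = eff$or, xi0 = eff$xi0, xi1 = eff$xi1,
    critical_sens_spec = eff$critical,
    best_calls = paste(calls, collapse = ","))
}

#' Per-SNP pair-membership counts
#'
#' How many reported pairs each SNP appears in.  A SNP with strong
#' univariate association typically hubs the top chi-square list (it drags
#' every partner over the threshold) but not the DSS list -- counting
#' memberships makes that confounding pattern visible.
#'
#' @param records tibble of pair records with `snp1_id`, `snp2_id`.
#' @return Tibble with `snp_id`, `n_pairs`, sorted by decreasing count;
#'   the counts sum to twice the number of records.
#' @export
snp_frequency_report <- function(records) {
  records <- tibble::as_tibble(records)
  ids <- c(records$snp1_id, records$snp2_id)
  if (length(ids) == 0L) {
    return(tibble::tibble(snp_id = character(0), n_pairs = integer(0)))
  }
  tb <- table(ids)
  out <- tibble::tibble(snp_id = names(tb), n_pairs = as.integer(tb))
  out[order(-out$n_pairs, out$snp_id), , drop = FALSE]
}

#' Odds-ratio versus critical sens/spec report
#'
#' Per-record effect-size summary: `log2` odds ratio and critical sens/spec
#' (sensitivity for contributing subsets, control-side coverage for
#' protective ones), with flags against the reference lines `critical >=
#' 2%` and `|log2 OR| >= 1`.
#'
#' @param records tibble with `odds_ratio`, `critical_sens_spec`,
#'   `direction` columns (e.g. [gss_stage()] output).
#' @return Tibble with `snp1_id`, `snp2_id` (when present), `log2_or`,
#'   `critical_sens_spec`, `direction`, `below_min_coverage`, `weak_or`.
#' @export
or_sensspec_report <- function(records) {
  records <- tibble::as_tibble(records)
  out <- tibble::tibble(
    log2_or = log2(records$odds_ratio),
    critical_sens_spec = records$critical_sens_spec,
    direction = records$direction,
    below_min_coverage = records$critical_sens_spec < 0.02,
    weak_or = abs(log2(records$odds_ratio)) < 1)
  idcols <- intersect(c("snp1_id", "snp2_id"), names(records))
  if (length(idcols)) out <- dplyr::bind_cols(records[idcols], out)
  out
}
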