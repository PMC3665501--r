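#' Hardy-Weinberg genotype frequencies
#'
#' @param q minor allele frequency in `(0, 0.5]`.
#' @return Numeric vector `((1-q)^2, 2q(1-q), q^2)` of genotype
#'   frequencies for codes 0, 1, 2.
#' @export
hwe_freqs <- function(q) {
  check_maf(q)
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

check_maf <- function(q) {
  if (any(q <= 0) || any(q > 0.5)) stop("maf must lie in (0, 0.5]")
  invisible(NULL)
}

#' Simulate null SNPs under Hardy-Weinberg equilibrium
#'
#' Background SNPs with no association: genotypes are drawn independently
#' of phenotype as Binomial(2, q) minor-allele counts, with per-SNP `q`
#' taken from `maf` (a single value, one value per SNP, or a sampler
#' function of the SNP count; the default draws uniformly from
#' `[0.05, 0.5]`).  Samples are ordered controls first, then cases.
#'
#' @param m number of SNPs.
#' @param n0,n1 number of controls and cases.
#' @param maf minor allele frequency specification.
#' @param seed optional RNG seed for reproducibility.
#' @return A [genotype_data] object.
#' @export
simulate_null <- function(m, n0, n1, maf = NULL, seed = NULL) {
  if (m < 1 || n0 < 1 || n1 < 1) stop("need m >= 1, n0 >= 1, n1 >= 1")
  if (!is.null(seed)) set.seed(seed)
  q <- resolve_maf(maf, m)
  n <- n0 + n1
  # column-major fill recycles q along the SNP dimension -> per-row maf
  geno <- matrix(rbinom(m * n, 2L, q), nrow = m, ncol = n)
  genotype_data(geno, c(rep(0L, n0), rep(1L, n1)))
}

resolve_maf <- function(maf, m) {
  q <- if (is.null(maf)) runif(m, 0.05, 0.5)
  else if (is.function(maf)) maf(m)
  else if (length(maf) == 1L) rep(maf, m)
  else maf
  if (length(q) != m) stop("maf must yield one frequency per SNP")
  check_maf(q)
  q
}

#' Two-locus pure-epistasis penetrance model
#'
#' Builds a 3x3 penetrance table `P(case | g1, g2)` with *no univariate
#' association*: the HWE-weighted marginal penetrance is constant across
#' genotypes at both loci (to 1e-10), so each SNP alone is a null SNP and
#' any detectable signal is purely pairwise.  The construction takes a
#' named interaction pattern, double-centers it under the HWE genotype
#' weights at `maf` (removing both weighted marginals), scales it by
#' `effect_scale` and adds the `baseline` penetrance; the population
#' prevalence equals `baseline` exactly.  `effect_scale = 0` gives a
#' constant table with no association at any level.
#'
#' @param family interaction pattern: `"xor"` (parity of `g1 + g2`),
#'   `"threshold"` (both loci carry the minor allele), or `"rr"` (both
#'   homozygous minor).
#' @param maf shared minor allele frequency of the two loci.
#' @param effect_scale non-negative interaction strength (penetrance
#'   units); values outside the feasible range (penetrance leaving
#'   `[0, 1]`) raise an error naming the range.
#' @param baseline baseline penetrance (= population prevalence).
#' @return Object of class `penetrance_model`: list with `table` (3x3),
#'   `maf1`, `maf2`, `label`, `baseline`, `effect_scale`.
#' @examples
#' make_pure_epistasis_model("xor", maf = 0.5, effect_scale = 0.1)
#' @export
make_pure_epistasis_model <- function(family = c("xor", "threshold", "rr"),
                                      maf, effect_scale, baseline = 0.1) {
  family <- match.arg(family)
  check_maf(maf)
  if (effect_scale < 0) stop("effect_scale must be >= 0")
  if (baseline <= 0 || baseline >= 1) stop("baseline must be in (0, 1)")
  g <- 0:2
  M <- switch(family,
    xor = outer(g, g, function(a, b) as.numeric((a + b) %% 2L)),
    threshold = outer(g, g, function(a, b) as.numeric(a >= 1L & b >= 1L)),
    rr = outer(g, g, function(a, b) as.numeric(a == 2L & b == 2L)))
  w <- hwe_freqs(maf)
  r <- as.numeric(M %*% w)            # weighted row means
  cc <- as.numeric(w %*% M)           # weighted column means
  mm <- sum(w * r)
  E <- M - outer(r, rep(1, 3)) - outer(rep(1, 3), cc) + mm
  if (max(abs(E)) < 1e-14) {
    f <- matrix(baseline, 3, 3)
    if (effect_scale > 0) stop("pattern '", family,
                               "' is degenerate at maf = ", maf)
  } else {
    smax <- min(ifelse(E > 0, (1 - baseline) / E, Inf),
                ifelse(E < 0, -baseline / E, Inf))
    if (effect_scale > smax + 1e-12) {
      stop("infeasible effect_scale: penetrance leaves [0, 1]; ",
           "feasible range is [0, ", format(smax, digits = 6),
           "] at baseline ", baseline)
    }
    f <- baseline + effect_scale * E
    f <- pmin(pmax(f, 0), 1)          # clip 1e-16-level overshoot only
  }
  dimnames(f) <- list(g1 = 0:2, g2 = 0:2)
  structure(list(table = f, maf1 = maf, maf2 = maf,
                 label = family, baseline = baseline,
                 effect_scale = effect_scale),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat("<penetrance_model> ", x$label, " (maf = ", x$maf1,
      ", effect_scale = ", x$effect_scale, ", baseline = ", x$baseline,
      ")\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' Analytic cell probabilities of a penetrance model
#'
#' Joint genotype-cell probabilities under HWE for cases and controls in
#' the infinite-sample limit: `P(g1, g2 | case)` is proportional to
#' `P(g1) P(g2) f(g1, g2)` and `P(g1, g2 | control)` to
#' `P(g1) P(g2) (1 - f(g1, g2))`.  Used for retrospective sampling and for
#' certifying the zero-marginal property.
#'
#' @param model a [make_pure_epistasis_model()] object.
#' @return Tibble with `g1`, `g2`, `prior`, `penetrance`, `p_case`,
#'   `p_control` (the last two each summing to 1).
#' @export
penetrance_cell_probs <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  v <- hwe_freqs(model$maf1)
  w <- hwe_freqs(model$maf2)
  prior <- outer(v, w)
  f <- model$table
  pc <- prior * f
  pk <- prior * (1 - f)
  if (sum(pc) <= 0) stop("penetrance is identically zero")
  tibble::tibble(
    g1 = rep(0:2, 3L), g2 = rep(0:2, each = 3L),
    prior = as.numeric(prior), penetrance = as.numeric(f),
    p_case = as.numeric(pc) / sum(pc),
    p_control = as.numeric(pk) / sum(pk))
}

#' Simulate a dataset with one planted epistatic pair
#'
#' Retrospective case-control sampling to fixed quotas: the planted pair's
#' joint genotypes are drawn from the exact case and control conditional
#' cell distributions of the penetrance model (HWE prior times penetrance,
#' renormalized), which is distributionally identical to rejection sampling
#' individuals until `n0` controls and `n1` cases accumulate.  Background
#' SNPs come from [simulate_null()].  The planted pair is placed at two
#' seeded-random positions.
#'
#' @param model a [make_pure_epistasis_model()] object.
#' @param n0,n1 number of controls and cases.
#' @param m_background number of additional null SNPs.
#' @param maf background MAF specification, as in [simulate_null()].
#' @param seed optional RNG seed.
#' @return List with `data` (a [genotype_data] of `m_background + 2` SNPs),
#'   `planted` (the two planted SNP row indices, increasing), `model`.
#' @export
simulate_epistatic <- function(model, n0, n1, m_background, maf = NULL,
                               seed = NULL) {
  stopifnot(inherits(model, "penetrance_model"))
  if (!is.null(seed)) set.seed(seed)
  cp <- penetrance_cell_probs(model)
  if (n1 > 0 && sum(cp$p_case) <= 0) stop("penetrance is identically zero")
  cells0 <- sample.int(9L, n0, replace = TRUE, prob = cp$p_control)
  cells1 <- sample.int(9L, n1, replace = TRUE, prob = cp$p_case)
  g1 <- c(cp$g1[cells0], cp$g1[cells1])
  g2 <- c(cp$g2[cells0], cp$g2[cells1])
  m <- m_background + 2L
  planted <- sort(sample.int(m, 2L))
  bg <- simulate_null(m_background, n0, n1, maf = maf)
  geno <- matrix(NA_integer_, nrow = m, ncol = n0 + n1)
  geno[-planted, ] <- bg$genotypes
  geno[planted[1L], ] <- g1
  geno[planted[2L], ] <- g2
  data <- genotype_data(geno, c(rep(0L, n0), rep(1L, n1)))
  list(data = data, planted = planted, model = model)
}

#' Simulate a single SNP with genotype relative risks
#'
#' A main-effect SNP under retrospective sampling: penetrance
#' `f(g) = baseline * rr[g + 1]`, genotype prior HWE at `maf`; controls are
#' drawn from `P(g) (1 - f(g))` and cases from `P(g) f(g)`, renormalized.
#' Equal relative risks give a null SNP.  Pairing a strong main-effect SNP
#' with null SNPs reproduces the chi-square confounding phenomenon: the
#' pair inherits the single SNP's association while its DSS gain stays
#' near zero.
#'
#' @param maf minor allele frequency.
#' @param genotype_relative_risks length-3 non-negative vector of risks for
#'   genotypes 0, 1, 2 (relative to `baseline`).
#' @param n0,n1 number of controls and cases.
#' @param baseline baseline penetrance.
#' @param seed optional RNG seed.
#' @return Integer genotype vector of length `n0 + n1`, controls first --
#'   the sample order produced by [simulate_null()] and
#'   [simulate_epistatic()].
#' @export
simulate_main_effect <- function(maf, genotype_relative_risks, n0, n1,
                                 baseline = 0.1, seed = NULL) {
  check_maf(maf)
  rr <- genotype_relative_risks
  if (length(rr) != 3L || any(rr < 0)) {
    stop("genotype_relative_risks must be 3 non-negative values")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- baseline * rr
  if (any(f > 1)) stop("baseline * relative risk exceeds 1")
  v <- hwe_freqs(maf)
  p1 <- v * f
  p0 <- v * (1 - f)
  if (n1 > 0 && sum(p1) <= 0) stop("no case probability mass")
  g0 <- sample(0:2, n0, replace = TRUE, prob = p0)
  g1 <- sample(0:2, n1, replace = TRUE, prob = p1)
  as.integer(c(g0, g1))
}

#' Power and false-positive-rate experiment
#'
#' The simulation benchmark: for each configuration (interaction family,
#' MAF, total sample size, effect scale) and each replicate, embed one pure
#' epistatic pair among null SNPs, scan all pairs with the enabled filters,
#' and call the planted pair *detected* when its score passes the
#' Bonferroni level `log10(C(m,2)/alpha)`.  Power is the detected fraction
#' of replicates; the false positive rate is the mean fraction of
#' non-planted pairs passing the same threshold.  Per-replicate seeds are
#' `seed + replicate index`, so the same background randomness is shared
#' across configurations (paired comparisons).
#'
#' @param configs data frame with columns `family`, `maf`, `n` (total
#'   samples, split equally into cases and controls), `effect_scale`.
#' @param replicates replicates per configuration.
#' @param m total SNP count per dataset (planted pair included).
#' @param filters subset of `c("dss", "chi2")`.
#' @param seed base RNG seed.
#' @param alpha family-wise level.
#' @param min_ss minimal sensitivity/specificity fraction for DSS.
#' @return Object of class `power_report`: tibble with one row per
#'   (configuration, filter): `family`, `maf`, `n`, `effect_scale`,
#'   `filter`, `power`, `fpr`, `replicates`, `seed`.
#' @export
power_fpr_experiment <- function(configs, replicates = 100L, m = 1000L,
                                 filters = c("dss", "chi2"), seed = 1L,
                                 alpha = 1, min_ss = 0.02) {
  configs <- tibble::as_tibble(configs)
  stopifnot(all(c("family", "maf", "n", "effect_scale") %in% names(configs)))
  filters <- match.arg(filters, c("dss", "chi2"), several.ok = TRUE)
  if (replicates < 1) stop("need replicates >= 1")
  thr <- bonferroni_threshold(m, alpha)$log10_threshold
  score_col <- filter_score_col[filters]
  rows <- list()
  for (ci in seq_len(nrow(configs))) {
    cfg <- configs[ci, ]
    model <- make_pure_epistasis_model(cfg$family, cfg$maf, cfg$effect_scale)
    n0 <- floor(cfg$n / 2)
    n1 <- cfg$n - n0
    det <- matrix(0, nrow = replicates, ncol = length(filters),
                  dimnames = list(NULL, filters))
    fpr <- det
    for (r in seq_len(replicates)) {
      sim <- simulate_epistatic(model, n0, n1, m - 2L, seed = seed + r)
      raw <- pair_scan_raw(sim$data, filters, min_ss, 0)
      is_planted <- raw$snp1_idx == sim$planted[1L] &
        raw$snp2_idx == sim$planted[2L]
      for (fi in seq_along(filters)) {
        sc <- raw[[score_col[[fi]]]]
        pass <- !is.na(sc) & sc >= thr
        det[r, fi] <- as.numeric(any(pass & is_planted))
        fpr[r, fi] <- sum(pass & !is_planted) / (nrow(raw) - 1L)
      }
    }
    for (fi in seq_along(filters)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = cfg$family, maf = cfg$maf, n = cfg$n,
        effect_scale = cfg$effect_scale, filter = filters[fi],
        power = mean(det[, fi]), fpr = mean(fpr[, fi]),
        replicates = replicates, seed = seed)
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("power_report", "tbl_df", "tbl", "data.frame"),
            m = m, log10_threshold = thr)
}
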