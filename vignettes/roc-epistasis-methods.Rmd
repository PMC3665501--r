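---
title: "Exact ROC-based tests for epistatic SNP pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact ROC-based tests for epistatic SNP pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiroc)
```

## The problem

Case-control GWAS routinely test every SNP for marginal association, but
many plausible disease architectures involve *epistasis*: a pair of loci
whose joint genotype separates Cases from Controls far better than either
locus alone.  Scanning all pairs is combinatorially heavy (500,000 SNPs
give 1.25 x 10^11 pairs) and statistically treacherous: a single SNP with a
strong marginal effect drags every one of its ~500,000 pairings over a
naive association threshold, burying genuine interactions.

`epiroc` implements a model-free answer built on three exact tests over
*prevalence-mapping ROC curves*, plus an exhaustive two-stage scan engine
and a synthetic-data harness for power evaluation.

## The prevalence mapping and its ROC curve

Write `t0`, `t1` for the numbers of Controls and Cases.  For a SNP pair,
each sample falls in one of nine joint genotype cells; each cell `v` has a
*sample prevalence* `n1v / (n0v + n1v)`.  Thresholding this prevalence at
every possible level sweeps out a piecewise-linear ROC curve: sort cells by
decreasing prevalence and cumulate the (control, case) counts `(x0, x1)`.
`build_roc()` constructs this curve; it has up to 9 segments for a pair,
up to 3 for a single SNP, and is concave by construction.  Cells with
exactly equal prevalence are merged into one segment (the ordering among
tied cells is then irrelevant, and the curve is unique); empty cells are
skipped.

Because the nine pair cells refine the three cells of either constituent
SNP, the pair curve always dominates both single-SNP curves
(`dominates()`); the scientific question is whether the dominance gap is
larger than biased sampling can explain.

## The SS test

A vertex `(x0, x1)` of the curve asserts: some genotype-call subset covers
only `x0` of `t0` Controls while capturing `x1` of `t1` Cases.  Under the
null hypothesis that the underlying population proportions are equal
(`pi0 = pi1`, no segregation power), the worst-case probability of doing at
least this well by biased sampling is

    P_SS(x0, x1) = max over pi in [0,1] of
                   P[Bin(t0, pi) <= x0] * P[Bin(t1, pi) >= x1]

and the test statistic for a whole curve is the minimum of `P_SS` over its
vertices (`p_ss()`), reported as `flt_SS = -log10 p`.  The minimum ranges
over vertices only: vertices are exactly the realizable cumulative count
pairs of the prevalence ordering.

A word on calibration.  For a *fixed* genotype-call subset the worst case
over the null parameter upper-bounds the true sampling probability of
doing at least that well, so each vertex value is a valid conservative
bound for its own pre-specified threshold.  The reported curve statistic,
though, plugs the observed counts into that bound and minimizes over
vertices chosen by the (data-dependent) prevalence ordering; like other
plug-in unconditional statistics it is a ranking score, not a calibrated
p-value, and at moderate levels it rejects more often than its nominal
value under the null -- the null-calibration suite measures exactly this.
The intended use is therefore ranking plus stringent genome-wide
(Bonferroni) cutoffs, mirroring how the two-stage pipeline applies it.

### Minimal sensitivity and specificity

Vertices with `min(1 - x0/t0, x1/t1) < min_ss` are excluded from the outer
minimum.  Tiny subsets can reach extreme significance from a handful of
samples and are numerically fragile; the default `min_ss = 0.02` (2% of
the relevant arm) follows standard practice for this family of filters and
is exposed as a parameter everywhere.  When every vertex is excluded the
result is defined as `p = 1`, `flt = 0`.

## The GSS test

The gain test replaces the diagonal null with the *pair-specific* null: the
population `(pi0, pi1)` lies in the smallest convex region of the unit
square containing both single-SNP ROC curves (`build_null_region()`), i.e.
the pair is no better than biased sampling from a population in which one
of the single SNPs already achieves that operating point.  The inner
maximization runs over this region; since the objective increases in `pi1`
and decreases in `pi0`, the maximum sits on the region's concave upper
boundary chain, and the search is one-dimensional along that chain.
Significant `flt_GSS = -log10 P_GSS` therefore means the pair improves on
*both* constituents beyond sampling bias -- the operational definition of
an epistatic pair used throughout.

Two refinements from practice:

* **Directionality.** Contributing (risk) and protective vertex subsets are
  demarcated by segment slope (incoming slope >= 1 in fraction coordinates
  -> contributing; outgoing slope <= 1 -> protective; `demarcate()`), and
  `p_gss()` can restrict the outer minimum to either subset.  The headline
  pair score is the larger of the two directional gains.  When the outer
  minimum is empty after restriction the convention `p = 1` applies.
* **Diagonal reduction.** With the sub-diagonal region the whole
  optimisation reduces to the SS test; the implementation realizes both
  tests through one chain maximizer, so the reduction is an exact identity
  rather than a numerical coincidence.

## DSS: the scanning proxy

GSS requires a pair-specific convex hull and a chain optimisation per
vertex -- too heavy for 10^11 pairs.  The scan therefore uses

    flt_DSS = flt_SS(pair) - max(flt_SS(g1), flt_SS(g2)),

the log-p improvement of the pair over its stronger constituent, as a fast
primary filter, followed by exact GSS on the survivors (`scan_pairs()`
then `gss_stage()`).  With the vertex-exclusion rule flt_DSS can be
slightly negative; it is reported as-is.  All three flt_SS terms are
computed on the pair's complete-case sample subset so the difference is
internally consistent.

## Numerical choices

* Binomial tails are evaluated in log space through the regularized
  incomplete beta function (`stats::pbinom(log.p = TRUE)`, `R::pbinom` in
  the C++ kernel); no underflow occurs for totals well beyond 10^5.
* The inner maximization is golden-section search per boundary segment
  (the objective has no local maxima along the chain; searching each
  segment separately and taking the best keeps the result correct even if
  per-segment unimodality ever failed), iterated to 1e-12 in the segment
  parameter.  Tests verify agreement with dense-grid oracles to 1e-6 in
  log10 p for totals up to 60.
* Prevalence ordering and tie detection use exact integer cross-product
  comparisons, never floating-point division; dominance and hull
  comparisons in fraction space use a 1e-12 tolerance.
* The exhaustive scan packs genotypes into per-class bitsets and tallies
  the 2x9 table with AND + popcount, and memoizes SS point p-values per
  `(t0, t1, x0, x1)` (a flat array for the dominant totals, a hash map for
  pairs with missing data).  Scan output is deterministic: descending
  score, ties by index pair.
* Degenerate cases: `x1 = 0` or `x0 = t0` give `p = 1` exactly; odds
  ratios with empty margins report 0 or infinity with a degeneracy flag
  rather than pseudo-counts.

## Thresholds

The scan's default significance policy is Bonferroni at family-wise level
`alpha = 1` over `C(m, 2)` pairs -- i.e. one expected false positive under
the global null.  For 459,012 SNPs this gives `flt >= ~11`; for the
1,000-SNP simulation harness, `p <= ~2e-6`.  `alpha` is configurable but
1 is the default used by the reporting examples.

## What the simulator emulates (and what it does not)

`simulate_null()` draws genotypes as Binomial(2, q) minor-allele counts --
Hardy-Weinberg equilibrium with per-SNP MAF from a uniform [0.05, 0.5]
sampler by default -- independent of phenotype.
`make_pure_epistasis_model()` builds 3x3 penetrance tables whose
HWE-weighted marginal penetrances are constant (to 1e-10) at both loci:
the interaction pattern (XOR parity, joint-carrier threshold, or double
recessive) is double-centered under the HWE weights, scaled, and added to
a baseline penetrance of 0.1, which then equals the population prevalence
exactly.  Retrospective sampling to fixed case/control quotas draws the
planted pair's genotypes from the exact conditional cell distributions --
distributionally identical to rejection-sampling individuals until the
quotas fill, just faster.  `simulate_main_effect()` produces the
univariate confounders that reproduce the chi-square banding/hub
phenomenon.

The generator deliberately omits linkage disequilibrium, population
stratification and genotyping error.  Passing the power and recovery
suites therefore demonstrates correctness of the statistics and engine on
clean signals, not robustness to the noise sources that dominate real
GWAS; on real data the confirmatory GSS stage and downstream quality
control carry that burden.

## Study conditions used by the evaluation suites

The test suite and harness run at desk scale, with sizes chosen to keep
the full run in the tens of minutes while preserving the qualitative
regime of the original benchmark design:

* Null calibration: 10,000 single null SNPs at `t0 = t1 = 500`.
* Pipeline recovery: XOR model, MAF 0.4, effect scale 0.15 (a strong
  planted interaction), 800/800 samples, 100 background null SNPs, 100
  replicates.
* Power comparison: XOR and threshold families crossed with MAF
  {0.2, 0.4}, 800 samples, effect scale 0.1, 1,000 SNPs, 100 replicates
  per configuration, detection at the `2e-6` Bonferroni level; per-replicate
  seed = base seed + replicate index.

## Known limitations

* Totals are capped at 65,535 per arm (cache keying); far beyond any
  case-control arm in practice.
* The GSS stage is intended for thousands of candidates, not for
  exhaustive use; that asymmetry is the reason DSS exists.
* Three-way interactions, covariates, dosage data and PLINK 2 formats are
  out of scope.
* The chi-square pair filter keeps the conventional 8 degrees of freedom
  even when genotype cells are empty (an `effective_df` diagnostic is
  attached); p-values for sparse tables deserve the usual caution.
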