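// Exact SS point p-values and the exhaustive pairwise scan kernel.
//
// The SS/GSS inner maximization is a 1-D search along a piecewise-linear
// chain of (pi0, pi1) null-region boundary points; the objective
//   f(pi0, pi1) = log P[Bin(t0, pi0) <= x0] + log P[Bin(t1, pi1) >= x1]
// is unimodal along the chain, so golden-section per segment plus a global
// max over segments is robust.  Binomial tails go through R's pbinom in log
// space (no underflow for totals in the 10^5 range).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const double LN10 = 2.302585092994045684;

// log P[Bin(t, p) <= x]
static inline double lb_lower(double x, double t, double p) {
  return R::pbinom(x, t, p, 1, 1);
}

// log P[Bin(t, p) >= x]
static inline double lb_upper(double x, double t, double p) {
  if (x <= 0.0) return 0.0;
  return R::pbinom(x - 1.0, t, p, 0, 1);
}

struct ChainMaxResult {
  double log10p;   // <= 0
  double pi0, pi1; // argmax
};

static inline double obj(double x0, double x1, double t0, double t1,
                         double p0, double p1) {
  return lb_lower(x0, t0, p0) + lb_upper(x1, t1, p1);
}

// Maximize obj along the polyline given by chain (rows = (pi0, pi1) points,
// ordered from (0,0) to (1,1)).  Golden-section within each segment.
static ChainMaxResult chain_max(double x0, double x1, double t0, double t1,
                                const double* c0, const double* c1, int npts) {
  ChainMaxResult res;
  // Degenerate tails: one factor is identically 1, the other attains 1 at an
  // endpoint of the chain.
  if (x1 <= 0.0) { res.log10p = 0.0; res.pi0 = c0[0]; res.pi1 = c1[0]; return res; }
  if (x0 >= t0) { res.log10p = 0.0; res.pi0 = c0[npts - 1]; res.pi1 = c1[npts - 1]; return res; }

  const double invphi = 0.6180339887498948482;
  double best = R_NegInf, bp0 = c0[0], bp1 = c1[0];

  for (int k = 0; k < npts; ++k) {  // chain vertices
    double f = obj(x0, x1, t0, t1, c0[k], c1[k]);
    if (f > best) { best = f; bp0 = c0[k]; bp1 = c1[k]; }
  }
  for (int k = 0; k + 1 < npts; ++k) {  // segment interiors
    double a0 = c0[k], a1 = c1[k], b0 = c0[k + 1], b1 = c1[k + 1];
    if (a0 == b0 && a1 == b1) continue;
    double lo = 0.0, hi = 1.0;
    double s1 = hi - invphi * (hi - lo), s2 = lo + invphi * (hi - lo);
    double f1 = obj(x0, x1, t0, t1, a0 + s1 * (b0 - a0), a1 + s1 * (b1 - a1));
    double f2 = obj(x0, x1, t0, t1, a0 + s2 * (b0 - a0), a1 + s2 * (b1 - a1));
    while (hi - lo > 1e-12) {
      if (f1 < f2) {
        lo = s1; s1 = s2; f1 = f2;
        s2 = lo + invphi * (hi - lo);
        f2 = obj(x0, x1, t0, t1, a0 + s2 * (b0 - a0), a1 + s2 * (b1 - a1));
      } else {
        hi = s2; s2 = s1; f2 = f1;
        s1 = hi - invphi * (hi - lo);
        f1 = obj(x0, x1, t0, t1, a0 + s1 * (b0 - a0), a1 + s1 * (b1 - a1));
      }
    }
    double sm = 0.5 * (lo + hi);
    double p0 = a0 + sm * (b0 - a0), p1 = a1 + sm * (b1 - a1);
    double fm = obj(x0, x1, t0, t1, p0, p1);
    if (fm > best) { best = fm; bp0 = p0; bp1 = p1; }
  }
  if (best > 0.0) best = 0.0;
  res.log10p = best / LN10;
  res.pi0 = bp0; res.pi1 = bp1;
  return res;
}

// [[Rcpp::export]]
NumericVector chain_max_cpp(double x0, double x1, double t0, double t1,
                            NumericMatrix chain) {
  int npts = chain.nrow();
  std::vector<double> c0(npts), c1(npts);
  for (int k = 0; k < npts; ++k) { c0[k] = chain(k, 0); c1[k] = chain(k, 1); }
  ChainMaxResult r = chain_max(x0, x1, t0, t1, c0.data(), c1.data(), npts);
  return NumericVector::create(r.log10p, r.pi0, r.pi1);
}

static const double DIAG0[2] = {0.0, 1.0};
static const double DIAG1[2] = {0.0, 1.0};

// SS point p-value on the diagonal chain, memoized by (t0, t1, x0, x1).
// The first totals encountered get a flat-array cache (the common case:
// without missing data every pair shares one (t0, t1)); other totals fall
// back to a hash map.
struct SSCache {
  std::vector<double> flat;
  int ft0 = -1, ft1 = -1;
  std::unordered_map<uint64_t, double> map;
};

static inline double ss_point_cached(int x0, int x1, int t0, int t1,
                                     SSCache& cache) {
  if (cache.ft0 < 0 &&
      (double)(t0 + 1) * (double)(t1 + 1) <= 8e6) {
    cache.ft0 = t0; cache.ft1 = t1;
    cache.flat.assign((size_t)(t0 + 1) * (t1 + 1), NA_REAL);
  }
  if (t0 == cache.ft0 && t1 == cache.ft1) {
    double& slot = cache.flat[(size_t)x0 * (t1 + 1) + x1];
    if (!ISNA(slot)) return slot;
    ChainMaxResult r = chain_max(x0, x1, t0, t1, DIAG0, DIAG1, 2);
    slot = r.log10p;
    return slot;
  }
  uint64_t key = ((uint64_t)t0 << 48) | ((uint64_t)t1 << 32) |
                 ((uint64_t)x0 << 16) | (uint64_t)x1;
  std::unordered_map<uint64_t, double>::iterator it = cache.map.find(key);
  if (it != cache.map.end()) return it->second;
  ChainMaxResult r = chain_max(x0, x1, t0, t1, DIAG0, DIAG1, 2);
  cache.map[key] = r.log10p;
  return r.log10p;
}

// Prevalence-ordered ROC over V cells; returns flt_SS = max over qualifying
// vertices of -log10 p (0 if none qualifies).  Cells with zero total are
// skipped; equal-prevalence cells merge into one segment.
static double flt_ss_cells(const long long* n0, const long long* n1, int V,
                           long long t0, long long t1, double min_ss,
                           SSCache& cache) {
  int idx[9]; int m = 0;
  for (int v = 0; v < V; ++v) if (n0[v] + n1[v] > 0) idx[m++] = v;
  if (m == 0) return NA_REAL;
  // sort by decreasing prevalence n1/(n0+n1); exact rational comparison
  std::sort(idx, idx + m, [&](int a, int b) {
    long long ta = n0[a] + n1[a], tb = n0[b] + n1[b];
    long long lhs = n1[a] * tb, rhs = n1[b] * ta;
    if (lhs != rhs) return lhs > rhs;
    return a < b;
  });
  double flt = 0.0;
  long long x0 = 0, x1 = 0;
  int k = 0;
  while (k < m) {
    // merge tie group
    int k2 = k;
    long long ta = n0[idx[k]] + n1[idx[k]];
    while (k2 + 1 < m) {
      int b = idx[k2 + 1];
      long long tb = n0[b] + n1[b];
      if (n1[idx[k]] * tb == n1[b] * ta) ++k2; else break;
    }
    for (int j = k; j <= k2; ++j) { x0 += n0[idx[j]]; x1 += n1[idx[j]]; }
    k = k2 + 1;
    double spe = 1.0 - (double)x0 / (double)t0;
    double sen = (double)x1 / (double)t1;
    if (std::min(spe, sen) < min_ss) continue;
    double lp = ss_point_cached((int)x0, (int)x1, (int)t0, (int)t1, cache);
    if (-lp > flt) flt = -lp;
  }
  return flt;
}

// Exhaustive scan over all unordered SNP pairs.
// geno: samples x m integer matrix, codes 0/1/2, NA for missing.
// pheno: 0 = control, 1 = case.
//
// Genotypes are packed into per-class sample bitsets (one mask per SNP,
// genotype class and phenotype); the 9-cell pair tally is then a popcount
// over ANDed 64-bit words.  A sample missing at a SNP appears in none of
// that SNP's masks, which implements per-pair complete-case exclusion for
// free.  Returns parallel vectors over evaluated pairs.
// [[Rcpp::export]]
List pair_scan_cpp(IntegerMatrix geno, IntegerVector pheno, double min_ss,
                   bool do_ss, bool do_chi2,
                   IntegerVector chr, IntegerVector pos, double min_distance) {
  int n = geno.nrow(), m = geno.ncol();
  if (pheno.size() != n) stop("phenotype length mismatch");
  size_t npairs = (size_t)m * (m - 1) / 2;
  std::vector<int> vi, vj; vi.reserve(npairs); vj.reserve(npairs);
  std::vector<double> vss, vs1, vs2, vdss, vchi2;
  std::vector<int> vt0, vt1;
  if (do_ss) { vss.reserve(npairs); vs1.reserve(npairs); vs2.reserve(npairs); vdss.reserve(npairs); }
  if (do_chi2) vchi2.reserve(npairs);
  vt0.reserve(npairs); vt1.reserve(npairs);

  SSCache cache; cache.map.reserve(1 << 12);
  bool use_dist = min_distance > 0 && chr.size() == m && pos.size() == m;
  const int* gptr = INTEGER(geno);
  const int* ph = INTEGER(pheno);

  // per-phenotype sample ranks and word counts
  std::vector<int> rank(n);
  int n0 = 0, n1 = 0;
  for (int s = 0; s < n; ++s) rank[s] = (ph[s] == 0) ? n0++ : n1++;
  const int w0 = (n0 + 63) / 64, w1 = (n1 + 63) / 64;
  const size_t stride0 = (size_t)3 * w0, stride1 = (size_t)3 * w1;
  std::vector<uint64_t> mk0(stride0 * m, 0), mk1(stride1 * m, 0);
  for (int a = 0; a < m; ++a) {
    const int* ga = gptr + (size_t)a * n;
    uint64_t* m0 = mk0.data() + stride0 * a;
    uint64_t* m1 = mk1.data() + stride1 * a;
    for (int s = 0; s < n; ++s) {
      int v = ga[s];
      if (v == NA_INTEGER) continue;
      if (ph[s] == 0) m0[(size_t)v * w0 + rank[s] / 64] |= 1ULL << (rank[s] % 64);
      else            m1[(size_t)v * w1 + rank[s] / 64] |= 1ULL << (rank[s] % 64);
    }
  }

  size_t n_eval = 0, n_skip = 0, tick = 0;
  for (int a = 0; a < m - 1; ++a) {
    const uint64_t* a0 = mk0.data() + stride0 * a;
    const uint64_t* a1 = mk1.data() + stride1 * a;
    for (int b = a + 1; b < m; ++b) {
      if (++tick % 8192 == 0) checkUserInterrupt();
      if (use_dist && chr[a] == chr[b] &&
          std::llabs((long long)pos[a] - (long long)pos[b]) < (long long)min_distance) {
        ++n_skip; continue;
      }
      const uint64_t* b0 = mk0.data() + stride0 * b;
      const uint64_t* b1 = mk1.data() + stride1 * b;
      long long cnt[18] = {0};
      for (int g1 = 0; g1 < 3; ++g1) {
        for (int g2 = 0; g2 < 3; ++g2) {
          long long c0 = 0, c1 = 0;
          const uint64_t* pa = a0 + (size_t)g1 * w0;
          const uint64_t* pb = b0 + (size_t)g2 * w0;
          for (int w = 0; w < w0; ++w) c0 += __builtin_popcountll(pa[w] & pb[w]);
          const uint64_t* qa = a1 + (size_t)g1 * w1;
          const uint64_t* qb = b1 + (size_t)g2 * w1;
          for (int w = 0; w < w1; ++w) c1 += __builtin_popcountll(qa[w] & qb[w]);
          cnt[g1 * 3 + g2] = c0;
          cnt[9 + g1 * 3 + g2] = c1;
        }
      }
      long long t0 = 0, t1 = 0;
      for (int v = 0; v < 9; ++v) { t0 += cnt[v]; t1 += cnt[9 + v]; }
      ++n_eval;
      vi.push_back(a + 1); vj.push_back(b + 1);
      vt0.push_back((int)t0); vt1.push_back((int)t1);
      if (t0 == 0 || t1 == 0) {
        if (do_ss) { vss.push_back(NA_REAL); vs1.push_back(NA_REAL);
                     vs2.push_back(NA_REAL); vdss.push_back(NA_REAL); }
        if (do_chi2) vchi2.push_back(NA_REAL);
        continue;
      }
      if (do_ss) {
        double sp = flt_ss_cells(cnt, cnt + 9, 9, t0, t1, min_ss, cache);
        long long m10[3], m11[3], m20[3], m21[3];
        for (int g = 0; g < 3; ++g) {
          m10[g] = cnt[g * 3] + cnt[g * 3 + 1] + cnt[g * 3 + 2];
          m11[g] = cnt[9 + g * 3] + cnt[9 + g * 3 + 1] + cnt[9 + g * 3 + 2];
          m20[g] = cnt[g] + cnt[3 + g] + cnt[6 + g];
          m21[g] = cnt[9 + g] + cnt[12 + g] + cnt[15 + g];
        }
        double s1 = flt_ss_cells(m10, m11, 3, t0, t1, min_ss, cache);
        double s2 = flt_ss_cells(m20, m21, 3, t0, t1, min_ss, cache);
        vss.push_back(sp); vs1.push_back(s1); vs2.push_back(s2);
        vdss.push_back(sp - std::max(s1, s2));
      }
      if (do_chi2) {
        double nn = (double)(t0 + t1), x2 = 0.0;
        for (int v = 0; v < 9; ++v) {
          double colsum = (double)(cnt[v] + cnt[9 + v]);
          if (colsum == 0.0) continue;
          double e0 = (double)t0 * colsum / nn, e1 = (double)t1 * colsum / nn;
          double d0 = (double)cnt[v] - e0, d1 = (double)cnt[9 + v] - e1;
          x2 += d0 * d0 / e0 + d1 * d1 / e1;
        }
        vchi2.push_back(x2);
      }
    }
  }

  List out = List::create(
    _["snp1_idx"] = wrap(vi), _["snp2_idx"] = wrap(vj),
    _["t0"] = wrap(vt0), _["t1"] = wrap(vt1),
    _["n_evaluated"] = (double)n_eval, _["n_excluded"] = (double)n_skip);
  if (do_ss) {
    out["flt_ss"] = wrap(vss); out["flt_ss1"] = wrap(vs1);
    out["flt_ss2"] = wrap(vs2); out["flt_dss"] = wrap(vdss);
  }
  if (do_chi2) out["chi2"] = wrap(vchi2);
  return out;
}

// Single-SNP flt_SS values for a whole matrix (used by scan_univariate and
// the null-calibration suite).
// [[Rcpp::export]]
NumericVector single_scan_cpp(IntegerMatrix geno, IntegerVector pheno,
                              double min_ss) {
  int n = geno.nrow(), m = geno.ncol();
  if (pheno.size() != n) stop("phenotype length mismatch");
  NumericVector out(m);
  SSCache cache; cache.map.reserve(1 << 10);
  const int* gptr = INTEGER(geno);
  const int* ph = INTEGER(pheno);
  for (int a = 0; a < m; ++a) {
    const int* ga = gptr + (size_t)a * n;
    long long cnt[6] = {0};
    for (int s = 0; s < n; ++s) {
      int v = ga[s];
      if (v == NA_INTEGER) continue;
      cnt[ph[s] * 3 + v]++;
    }
    long long t0 = cnt[0] + cnt[1] + cnt[2], t1 = cnt[3] + cnt[4] + cnt[5];
    if (t0 == 0 || t1 == 0) { out[a] = NA_REAL; continue; }
    out[a] = flt_ss_cells(cnt, cnt + 3, 3, t0, t1, min_ss, cache);
  }
  return out;
}
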