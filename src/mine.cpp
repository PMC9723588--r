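// MINE core: equipartition, clump construction, and the column-placement
// dynamic program behind the characteristic matrix, MIC and MAS.
//
// The DP exploits that, with the row partition fixed, mutual information
// I(col; row) = H(row) - sum_c (M_c/n) H(row | col = c), so maximising I over
// clump-respecting column partitions is a classic 1-D partition DP minimising
// the additive column cost M_c * H(row | c). Splitting a column never
// increases the cost (concavity of entropy), so the optimum over <= l columns
// equals the exact-l optimum and is nondecreasing in l.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double xlog2(double m) {
  return m > 0.0 ? m * std::log2(m) : 0.0;
}

// Partition pre-sorted values into at most k bins, as equal as possible,
// never splitting tied values. Returns 0-based bin index per position.
static std::vector<int> equipartition_sorted(const std::vector<double>& v, int k) {
  const int n = (int)v.size();
  std::vector<int> bin(n);
  int i = 0, b = 0, cursize = 0;
  double desired = (double)n / k;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) ++j;
    const int s = j - i;
    if (cursize > 0 && b < k - 1 &&
        std::fabs(cursize + s - desired) >= std::fabs(cursize - desired)) {
      ++b;
      cursize = 0;
      desired = (double)(n - i) / (k - b);
    }
    for (int t = i; t < j; ++t) bin[t] = b;
    cursize += s;
    i = j;
  }
  return bin;
}

// Clump ids for points sorted by x: runs of identical x are fused into one
// clump; otherwise consecutive points falling in the same row are fused
// (separating them can never improve a column partition).
static std::vector<int> clump_ids_sorted(const std::vector<double>& xs,
                                         const std::vector<int>& row) {
  const int n = (int)xs.size();
  std::vector<int> lab(n);
  int neg = -1;
  for (int i = 0; i < n;) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    if (j - i > 1) {
      for (int t = i; t < j; ++t) lab[t] = neg;
      --neg;
    } else {
      lab[i] = row[i];
    }
    i = j;
  }
  std::vector<int> cid(n);
  int c = 0;
  cid[0] = 0;
  for (int i = 1; i < n; ++i) {
    if (lab[i] != lab[i - 1]) ++c;
    cid[i] = c;
  }
  return cid;
}

// Cap the number of clumps at khat by equipartitioning points over clump ids
// (ties-together keeps each original clump intact).
static std::vector<int> superclumps(const std::vector<int>& cid, int khat) {
  const int n = (int)cid.size();
  if (cid[n - 1] + 1 <= khat) return cid;
  std::vector<double> cv(n);
  for (int i = 0; i < n; ++i) cv[i] = (double)cid[i];
  std::vector<int> b = equipartition_sorted(cv, khat);
  // bins are already nondecreasing along sorted order
  std::vector<int> out(n);
  int c = 0;
  out[0] = 0;
  for (int i = 1; i < n; ++i) {
    if (b[i] != b[i - 1]) ++c;
    out[i] = c;
  }
  return out;
}

// Best mutual information (bits) for l = 2..lmax columns, given per-point row
// assignment (points sorted by x, clump ids precomputed).
static std::vector<double> optimize_axis_core(const std::vector<int>& cid,
                                              const std::vector<int>& row,
                                              int nrows, int lmax) {
  const int n = (int)row.size();
  const int k = cid[n - 1] + 1;
  std::vector<double> cum((size_t)(k + 1) * nrows, 0.0);
  for (int i = 0; i < n; ++i) cum[(size_t)(cid[i] + 1) * nrows + row[i]] += 1.0;
  for (int c = 1; c <= k; ++c)
    for (int r = 0; r < nrows; ++r)
      cum[(size_t)c * nrows + r] += cum[(size_t)(c - 1) * nrows + r];
  std::vector<double> tot(k + 1, 0.0);
  for (int c = 0; c <= k; ++c) {
    double s = 0;
    for (int r = 0; r < nrows; ++r) s += cum[(size_t)c * nrows + r];
    tot[c] = s;
  }
  double Hrow = 0.0;
  for (int r = 0; r < nrows; ++r) {
    const double m = cum[(size_t)k * nrows + r];
    if (m > 0) Hrow -= (m / n) * std::log2(m / n);
  }

  std::vector<double> out(lmax + 1, 0.0);
  if (k < 2) return out;  // single clump: no split possible, I = 0

  // counts are integers, so m*log2(m) comes from a lookup table
  std::vector<double> xl2(n + 1);
  for (int m = 0; m <= n; ++m) xl2[m] = xlog2((double)m);

  // cost(s, t) for all 0 <= s < t <= k
  std::vector<double> costTab((size_t)(k + 1) * (k + 1), 0.0);
  for (int s = 0; s < k; ++s) {
    for (int t = s + 1; t <= k; ++t) {
      const double M = tot[t] - tot[s];
      double c = xl2[(int)(M + 0.5)];
      for (int r = 0; r < nrows; ++r)
        c -= xl2[(int)(cum[(size_t)t * nrows + r] -
                       cum[(size_t)s * nrows + r] + 0.5)];
      costTab[(size_t)s * (k + 1) + t] = c;
    }
  }

  std::vector<double> prev(k + 1, 0.0), curr(k + 1, 0.0);
  for (int t = 1; t <= k; ++t) prev[t] = costTab[t];  // s = 0
  const int L = std::min(lmax, k);
  for (int l = 2; l <= L; ++l) {
    for (int t = l; t <= k; ++t) {
      double best = R_PosInf;
      for (int s = l - 1; s < t; ++s) {
        const double v = prev[s] + costTab[(size_t)s * (k + 1) + t];
        if (v < best) best = v;
      }
      curr[t] = best;
    }
    prev.swap(curr);
    double mi = Hrow - prev[k] / n;
    if (mi < 0) mi = 0;
    out[l] = mi;
  }
  for (int l = L + 1; l <= lmax; ++l) out[l] = out[L];
  return out;
}

// Sorting permutation of v (stable).
static std::vector<int> order_of(const NumericVector& v) {
  const int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// Full optimize pass: sort x, build row vector in sorted order, clumps,
// superclumps, DP.
static std::vector<double> optimize_pass(const NumericVector& x,
                                         const std::vector<int>& row_orig,
                                         int nrows, int lmax, double cfac) {
  const int n = x.size();
  std::vector<int> ord = order_of(x);
  std::vector<double> xs(n);
  std::vector<int> row(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    row[i] = row_orig[ord[i]];
  }
  std::vector<int> cid = clump_ids_sorted(xs, row);
  const int khat = std::max(2, (int)(cfac * lmax));
  cid = superclumps(cid, khat);
  return optimize_axis_core(cid, row, nrows, lmax);
}

// Equipartition a variable into <= k bins; returns 0-based bin per point in
// original order (and the number of bins actually realised via max + 1).
static std::vector<int> equipartition_var(const NumericVector& y, int k) {
  const int n = y.size();
  std::vector<int> ord = order_of(y);
  std::vector<double> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = y[ord[i]];
  std::vector<int> bin = equipartition_sorted(ys, k);
  std::vector<int> out(n);
  for (int i = 0; i < n; ++i) out[ord[i]] = bin[i];
  return out;
}

// Characteristic matrix for all (a, b) with a*b <= B, a, b >= 2.
// Entry (a, b) = max over the two orientations of the best grid MI with a
// x-bins and b y-bins, normalised by log2(min(a, b)).
static NumericMatrix char_matrix_core(const NumericVector& x,
                                      const NumericVector& y, int B,
                                      double cfac) {
  const int dmax = B / 2;  // with both >= 2, neither axis exceeds B/2
  NumericMatrix M(dmax - 1, dmax - 1);  // index (a-2, b-2)
  std::fill(M.begin(), M.end(), NA_REAL);

  // pass 1: equipartition y into b rows, optimise x into <= a columns
  for (int b = 2; b <= dmax; ++b) {
    const int lmax = B / b;
    if (lmax < 2) continue;
    std::vector<int> row = equipartition_var(y, b);
    int nrows = 1 + *std::max_element(row.begin(), row.end());
    std::vector<double> mi = optimize_pass(x, row, nrows, lmax, cfac);
    for (int a = 2; a <= lmax; ++a) {
      const double v = mi[a] / std::log2((double)std::min(a, b));
      double& cell = M(a - 2, b - 2);
      if (ISNA(cell) || v > cell) cell = v;
    }
  }
  // pass 2: equipartition x into a bins, optimise y into <= b rows
  for (int a = 2; a <= dmax; ++a) {
    const int lmax = B / a;
    if (lmax < 2) continue;
    std::vector<int> row = equipartition_var(x, a);
    int nrows = 1 + *std::max_element(row.begin(), row.end());
    std::vector<double> mi = optimize_pass(y, row, nrows, lmax, cfac);
    for (int b = 2; b <= lmax; ++b) {
      const double v = mi[b] / std::log2((double)std::min(a, b));
      double& cell = M(a - 2, b - 2);
      if (ISNA(cell) || v > cell) cell = v;
    }
  }
  return M;
}

static void mic_mas_from_matrix(const NumericMatrix& M, double& mic,
                                double& mas) {
  mic = 0.0;
  mas = 0.0;
  const int d = M.nrow();
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j < d; ++j) {
      const double v = M(i, j);
      if (ISNA(v)) continue;
      if (v > mic) mic = v;
      const double w = M(j, i);
      if (!ISNA(w)) {
        const double a = std::fabs(v - w);
        if (a > mas) mas = a;
      }
    }
  }
}

// [[Rcpp::export(name = ".char_matrix_cpp")]]
NumericMatrix char_matrix_cpp(NumericVector x, NumericVector y, int B,
                              double cfac) {
  return char_matrix_core(x, y, B, cfac);
}

// [[Rcpp::export(name = ".mic_mas_cpp")]]
NumericVector mic_mas_cpp(NumericVector x, NumericVector y, int B,
                          double cfac) {
  NumericMatrix M = char_matrix_core(x, y, B, cfac);
  double mic, mas;
  mic_mas_from_matrix(M, mic, mas);
  return NumericVector::create(mic, mas);
}

// Permutation test: shuffles y with R's RNG, returns (observed MIC,
// #permutations with MIC >= observed - 1e-12).
// [[Rcpp::export(name = ".mic_perm_cpp")]]
NumericVector mic_perm_cpp(NumericVector x, NumericVector y, int B,
                           double cfac, int nperm) {
  double mic, mas;
  NumericMatrix M = char_matrix_core(x, y, B, cfac);
  mic_mas_from_matrix(M, mic, mas);
  const int n = y.size();
  NumericVector yp = clone(y);
  int count = 0;
  RNGScope scope;
  for (int p = 0; p < nperm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    NumericMatrix Mp = char_matrix_core(x, yp, B, cfac);
    double micp, masp;
    mic_mas_from_matrix(Mp, micp, masp);
    if (micp >= mic - 1e-12) ++count;
  }
  return NumericVector::create(mic, (double)count);
}

// Exposed DP for the optimize_x_axis operation: per-point row assignment
// (1-based from R), best MI for l = 2..lmax.
// [[Rcpp::export(name = ".optimize_x_axis_cpp")]]
NumericVector optimize_x_axis_cpp(NumericVector x, IntegerVector row,
                                  int lmax, double cfac) {
  const int n = x.size();
  std::vector<int> r0(n);
  for (int i = 0; i < n; ++i) r0[i] = row[i] - 1;
  int nrows = 1 + *std::max_element(r0.begin(), r0.end());
  std::vector<double> mi = optimize_pass(x, r0, nrows, lmax, cfac);
  NumericVector out(lmax - 1);
  for (int l = 2; l <= lmax; ++l) out[l - 2] = mi[l];
  return out;
}

// Clump ids (1-based, original point order) for the brute-force oracle.
// [[Rcpp::export(name = ".clump_ids_cpp")]]
IntegerVector clump_ids_rcpp(NumericVector x, IntegerVector row, int khat) {
  const int n = x.size();
  std::vector<int> ord = order_of(x);
  std::vector<double> xs(n);
  std::vector<int> r(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = x[ord[i]];
    r[i] = row[ord[i]] - 1;
  }
  std::vector<int> cid = clump_ids_sorted(xs, r);
  if (khat >= 2) cid = superclumps(cid, khat);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[ord[i]] = cid[i] + 1;
  return out;
}

// Equipartition exposed for tests / the equipartition contract.
// [[Rcpp::export(name = ".equipartition_cpp")]]
IntegerVector equipartition_rcpp(NumericVector y, int k) {
  std::vector<int> b = equipartition_var(y, k);
  IntegerVector out(y.size());
  for (int i = 0; i < (int)b.size(); ++i) out[i] = b[i] + 1;
  return out;
}
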