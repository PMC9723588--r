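// Depth-limited regression trees with Newton (ridge-regularised) leaf
// weights, shared by the gradient-boosting and random-forest surface models.
// For squared loss the Hessian per point is 1, so a leaf weight is
// sum(residuals) / (count + lambda); with lambda = 0 this is the plain mean
// and the split gain reduces to the SSE-reduction criterion.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feat, left, right;
  std::vector<double> thr, val;
};

static void build_node(const NumericMatrix& X, const NumericVector& y,
                       std::vector<int>& idx, int lo, int hi, int depth,
                       int max_depth, int min_split, double lambda, int mtry,
                       TreeBuf& T, int node) {
  const int n = hi - lo;
  double G = 0.0;
  for (int i = lo; i < hi; ++i) G += y[idx[i]];
  T.val[node] = G / (n + lambda);

  if ((max_depth >= 0 && depth >= max_depth) || n < min_split || n < 2) return;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  if (mtry < p) {
    // partial Fisher-Yates with R's RNG: first mtry entries are the subset
    for (int i = 0; i < mtry; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(feats[i], feats[j]);
    }
    feats.resize(mtry);
  }

  const double parent = G * G / (n + lambda);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<int> srt(n);
  for (int f : feats) {
    for (int i = 0; i < n; ++i) srt[i] = idx[lo + i];
    std::stable_sort(srt.begin(), srt.end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
    double GL = 0.0;
    for (int i = 1; i < n; ++i) {
      GL += y[srt[i - 1]];
      if (X(srt[i - 1], f) == X(srt[i], f)) continue;
      const double GR = G - GL;
      const double gain =
          GL * GL / (i + lambda) + GR * GR / ((n - i) + lambda) - parent;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (X(srt[i - 1], f) + X(srt[i], f));
      }
    }
  }
  if (best_f < 0) return;

  // stable partition: <= thr left, > thr right
  std::vector<int> L, R;
  L.reserve(n);
  R.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr)
      L.push_back(idx[i]);
    else
      R.push_back(idx[i]);
  }
  for (size_t i = 0; i < L.size(); ++i) idx[lo + i] = L[i];
  for (size_t i = 0; i < R.size(); ++i) idx[lo + L.size() + i] = R[i];

  const int nl = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0); T.left.push_back(-1);
  T.right.push_back(-1); T.val.push_back(0);
  const int nr = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0); T.left.push_back(-1);
  T.right.push_back(-1); T.val.push_back(0);
  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  T.left[node] = nl;
  T.right[node] = nr;

  build_node(X, y, idx, lo, lo + (int)L.size(), depth + 1, max_depth,
             min_split, lambda, mtry, T, nl);
  build_node(X, y, idx, lo + (int)L.size(), hi, depth + 1, max_depth,
             min_split, lambda, mtry, T, nr);
}

// rows: 1-based training-row subset (bootstrap sample or all rows).
// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int max_depth, int min_split, double lambda, int mtry) {
  RNGScope scope;
  std::vector<int> idx(rows.size());
  for (int i = 0; i < rows.size(); ++i) idx[i] = rows[i] - 1;
  TreeBuf T;
  T.feat.push_back(-1); T.thr.push_back(0); T.left.push_back(-1);
  T.right.push_back(-1); T.val.push_back(0);
  if (mtry < 1) mtry = X.ncol();
  build_node(X, y, idx, 0, (int)idx.size(), 0, max_depth, min_split, lambda,
             mtry, T, 0);
  return List::create(_["feature"] = wrap(T.feat), _["threshold"] = wrap(T.thr),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["value"] = wrap(T.val));
}

static inline double tree_pred_one(const IntegerVector& feat,
                                   const NumericVector& thr,
                                   const IntegerVector& left,
                                   const IntegerVector& right,
                                   const NumericVector& val,
                                   const NumericMatrix& X, int i) {
  int node = 0;
  while (feat[node] >= 0)
    node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
  return val[node];
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector thr = tree["threshold"], val = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = tree_pred_one(feat, thr, left, right, val, X, i);
  return out;
}

// Weighted ensemble prediction: intercept + sum_t w[t] * tree_t(x).
// [[Rcpp::export(name = ".predict_ensemble_cpp")]]
NumericVector predict_ensemble_cpp(List trees, NumericMatrix X,
                                   NumericVector w, double intercept) {
  const int n = X.nrow();
  NumericVector out(n, intercept);
  for (int t = 0; t < trees.size(); ++t) {
    List tree = trees[t];
    IntegerVector feat = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector thr = tree["threshold"], val = tree["value"];
    const double wt = w[t];
    for (int i = 0; i < n; ++i)
      out[i] += wt * tree_pred_one(feat, thr, left, right, val, X, i);
  }
  return out;
}
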