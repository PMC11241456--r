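#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy CART with weighted squared-error impurity. For a 0/1 response the
// variance criterion is equivalent (up to a factor of 2) to Gini, so one
// learner serves classification (RF, AdaBoost stumps) and the regression
// trees that gradient boosting fits to pseudo-residuals.
//
// Trees are stored flat: feature[k] < 0 marks a leaf; value[k] is the
// weighted mean response in the node. mtry features are drawn per node via
// R's RNG so forests are reproducible under set.seed().

struct FlatTree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value, weight;
};

struct Split {
  int feature = -1;
  double threshold = 0.0, gain = 0.0;
};

static Split best_split(const NumericMatrix& X, const NumericVector& y,
                        const NumericVector& w, const std::vector<int>& idx,
                        int mtry, int min_leaf) {
  const int p = X.ncol();
  const int n = (int)idx.size();

  double sw = 0.0, swy = 0.0, swyy = 0.0;
  for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; swyy += w[i] * y[i] * y[i]; }
  const double total_sse = swyy - swy * swy / sw;
  if (total_sse <= 1e-12) return Split();

  // sample mtry candidate features without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  if (mtry < p) {
    for (int j = 0; j < mtry; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
    feats.resize(mtry);
  }

  Split best;
  std::vector<std::pair<double, int> > vals(n);
  for (int j : feats) {
    for (int a = 0; a < n; ++a) vals[a] = std::make_pair(X(idx[a], j), idx[a]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;

    double lw = 0.0, lwy = 0.0, lwyy = 0.0;
    int nl = 0;
    for (int a = 0; a < n - 1; ++a) {
      const int i = vals[a].second;
      lw += w[i]; lwy += w[i] * y[i]; lwyy += w[i] * y[i] * y[i];
      ++nl;
      if (vals[a + 1].first == vals[a].first) continue;
      if (nl < min_leaf || n - nl < min_leaf) continue;
      const double rw = sw - lw, rwy = swy - lwy, rwyy = swyy - lwyy;
      if (lw <= 0.0 || rw <= 0.0) continue;
      const double sse = (lwyy - lwy * lwy / lw) + (rwyy - rwy * rwy / rw);
      const double gain = total_sse - sse;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = j;
        best.threshold = 0.5 * (vals[a].first + vals[a + 1].first);
      }
    }
  }
  return best;
}

static int grow(FlatTree& t, const NumericMatrix& X, const NumericVector& y,
                const NumericVector& w, std::vector<int>& idx, int depth,
                int max_depth, int min_split, int min_leaf, int mtry) {
  double sw = 0.0, swy = 0.0;
  for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; }

  const int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(sw > 0.0 ? swy / sw : 0.0);
  t.weight.push_back(sw);

  if ((max_depth >= 0 && depth >= max_depth) || (int)idx.size() < min_split)
    return node;

  Split s = best_split(X, y, w, idx, mtry, min_leaf);
  if (s.feature < 0) return node;

  std::vector<int> li, ri;
  li.reserve(idx.size());
  ri.reserve(idx.size());
  for (int i : idx)
    (X(i, s.feature) <= s.threshold ? li : ri).push_back(i);
  if (li.empty() || ri.empty()) return node;

  t.feature[node] = s.feature;
  t.threshold[node] = s.threshold;
  idx.clear(); idx.shrink_to_fit();
  t.left[node] = grow(t, X, y, w, li, depth + 1, max_depth, min_split, min_leaf, mtry);
  t.right[node] = grow(t, X, y, w, ri, depth + 1, max_depth, min_split, min_leaf, mtry);
  return node;
}

// [[Rcpp::export(name = ".cart_fit")]]
List cart_fit(NumericMatrix X, NumericVector y, NumericVector w,
              int max_depth, int min_samples_split, int min_samples_leaf,
              int mtry) {
  if (X.nrow() != y.size() || y.size() != w.size())
    stop("X, y and w must have matching lengths");
  RNGScope scope;
  FlatTree t;
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  grow(t, X, y, w, idx, 0, max_depth, min_samples_split, min_samples_leaf,
       mtry > 0 ? std::min<int>(mtry, X.ncol()) : X.ncol());
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value),
                      _["weight"] = wrap(t.weight));
}

// [[Rcpp::export(name = ".cart_predict")]]
List cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  IntegerVector leaf(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (feature[k] >= 0)
      k = (X(i, feature[k]) <= threshold[k]) ? left[k] : right[k];
    out[i] = value[k];
    leaf[i] = k + 1;  // 1-based node id for R-side leaf maps
  }
  return List::create(_["value"] = out, _["leaf"] = leaf);
}
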