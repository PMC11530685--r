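// Decision-tree grower for the weighted random forest.
//
// Splits are chosen by information gain (base-2 entropy) over a random
// feature subset per node, with midpoint thresholds between sorted unique
// values. Every internal node records the class counts of itself and its
// children so the R side can aggregate per-node Gini importance deltas in
// either the unweighted (Gini_m - Gini_l - Gini_r) or child-count-weighted
// form. Uses R's RNG (via R::unif_rand) so forests are reproducible from
// set.seed() alone.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // 0-based column, -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // 0-based node ids, -1 for none
  int depth;
  std::vector<int> counts; // class counts of in-node samples
};

struct GrowState {
  const NumericMatrix& X;
  const IntegerVector& y; // 0-based class codes
  int K;
  int mtry;
  int max_depth;
  int min_leaf;
  std::vector<Node> nodes;
  std::vector<int> feat_buf;    // scratch for feature subsampling
  std::vector<double> xlog2x;   // i * log2(i), i = 0..n; speeds the scan
  GrowState(const NumericMatrix& X_, const IntegerVector& y_, int K_,
            int mtry_, int max_depth_, int min_leaf_, int n_total)
      : X(X_), y(y_), K(K_), mtry(mtry_), max_depth(max_depth_),
        min_leaf(min_leaf_) {
    xlog2x.resize(n_total + 1);
    xlog2x[0] = 0.0;
    for (int i = 1; i <= n_total; ++i) xlog2x[i] = i * std::log2((double)i);
  }
};

inline double entropy_from_counts(const std::vector<int>& c, int n) {
  if (n == 0) return 0.0;
  double h = 0.0;
  for (int k = 0; k < (int)c.size(); ++k) {
    if (c[k] > 0) {
      double p = (double)c[k] / n;
      h -= p * std::log2(p);
    }
  }
  return h;
}

// Sample `mtry` distinct features out of p, ascending order (partial
// Fisher-Yates followed by sort; ascending order makes the lowest-column-
// index tie-break automatic).
void sample_features(GrowState& st, int p, std::vector<int>& out) {
  st.feat_buf.resize(p);
  for (int j = 0; j < p; ++j) st.feat_buf[j] = j;
  int m = std::min(st.mtry, p);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(R::unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(st.feat_buf[i], st.feat_buf[j]);
  }
  out.assign(st.feat_buf.begin(), st.feat_buf.begin() + m);
  std::sort(out.begin(), out.end());
}

// Grow one node on sample rows idx; returns node id.
int grow(GrowState& st, std::vector<int>& idx, int depth) {
  int n = (int)idx.size();
  int id = (int)st.nodes.size();
  st.nodes.push_back(Node());
  Node& self = st.nodes[id]; // note: reference invalidated by recursion below
  self.feature = -1;
  self.threshold = NA_REAL;
  self.left = self.right = -1;
  self.depth = depth;
  std::vector<int> counts(st.K, 0);
  for (int i = 0; i < n; ++i) counts[st.y[idx[i]]]++;
  st.nodes[id].counts = counts;

  int n_classes_present = 0;
  for (int k = 0; k < st.K; ++k) if (counts[k] > 0) ++n_classes_present;
  if (n_classes_present <= 1 || depth >= st.max_depth || n < 2 * st.min_leaf)
    return id;

  double parent_H = entropy_from_counts(counts, n);

  std::vector<int> cand;
  sample_features(st, st.X.ncol(), cand);

  double best_gain = 1e-12; // require strictly positive gain
  int best_feat = -1;
  double best_thr = 0.0;

  // Weighted conditional entropy of a split, times n, via the identity
  // n_l H_l = n_l log2(n_l) - sum_k c_lk log2(c_lk); all table lookups.
  const std::vector<double>& L = st.xlog2x;
  std::vector<std::pair<double, int>> vals(n); // (value, class)
  std::vector<int> left_counts(st.K);
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int j = cand[ci];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(st.X(idx[i], j), (int)st.y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue; // constant column
    std::fill(left_counts.begin(), left_counts.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      left_counts[vals[i].second]++;
      int nl = i + 1, nr = n - nl;
      if (nl < st.min_leaf || nr < st.min_leaf) continue;
      if (vals[i].first == vals[i + 1].first) continue; // not a boundary
      double cond_n = L[nl] + L[nr];
      for (int k = 0; k < st.K; ++k) {
        int cl = left_counts[k];
        int cr = counts[k] - cl;
        cond_n -= L[cl] + L[cr];
      }
      double gain = parent_H - cond_n / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }

  if (best_feat < 0) return id; // no informative split among candidates

  std::vector<int> lidx, ridx;
  lidx.reserve(n);
  ridx.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (st.X(idx[i], best_feat) <= best_thr) lidx.push_back(idx[i]);
    else ridx.push_back(idx[i]);
  }
  st.nodes[id].feature = best_feat;
  st.nodes[id].threshold = best_thr;
  int l = grow(st, lidx, depth + 1);
  int r = grow(st, ridx, depth + 1);
  st.nodes[id].left = l;
  st.nodes[id].right = r;
  return id;
}

} // namespace

// [[Rcpp::export]]
List cpp_build_tree(NumericMatrix X, IntegerVector y, int n_classes,
                    IntegerVector rows, int mtry, int max_depth,
                    int min_samples_leaf) {
  GrowState st(X, y, n_classes, mtry, max_depth, min_samples_leaf,
               rows.size());
  std::vector<int> idx(rows.size());
  for (int i = 0; i < rows.size(); ++i) idx[i] = rows[i] - 1; // 1- -> 0-based
  grow(st, idx, 0);

  int m = (int)st.nodes.size();
  IntegerVector feature(m), left(m), right(m), depth(m), n_node(m),
      leaf_class(m);
  NumericVector threshold(m), gini(m), delta_unw(m), delta_w(m);
  IntegerMatrix counts(m, n_classes);
  for (int i = 0; i < m; ++i) {
    const Node& nd = st.nodes[i];
    feature[i] = nd.feature >= 0 ? nd.feature + 1 : NA_INTEGER;
    threshold[i] = nd.threshold;
    left[i] = nd.left >= 0 ? nd.left + 1 : NA_INTEGER;
    right[i] = nd.right >= 0 ? nd.right + 1 : NA_INTEGER;
    depth[i] = nd.depth;
    int n = 0;
    for (int k = 0; k < n_classes; ++k) {
      counts(i, k) = nd.counts[k];
      n += nd.counts[k];
    }
    n_node[i] = n;
    double g = 1.0;
    for (int k = 0; k < n_classes; ++k) {
      double p = n > 0 ? (double)nd.counts[k] / n : 0.0;
      g -= p * p;
    }
    gini[i] = g;
    // majority class, ties to lowest class index
    int best_k = 0;
    for (int k = 1; k < n_classes; ++k)
      if (nd.counts[k] > nd.counts[best_k]) best_k = k;
    leaf_class[i] = best_k + 1;
    delta_unw[i] = NA_REAL;
    delta_w[i] = NA_REAL;
  }
  // importance deltas for internal nodes
  for (int i = 0; i < m; ++i) {
    const Node& nd = st.nodes[i];
    if (nd.feature < 0) continue;
    double gl = gini[nd.left], gr = gini[nd.right];
    double nl = n_node[nd.left], nr = n_node[nd.right], n = n_node[i];
    delta_unw[i] = gini[i] - gl - gr;
    delta_w[i] = gini[i] - (nl / n) * gl - (nr / n) * gr;
  }
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold, _["left"] = left,
      _["right"] = right, _["depth"] = depth, _["n_node"] = n_node,
      _["counts"] = counts, _["gini"] = gini, _["delta_unweighted"] = delta_unw,
      _["delta_weighted"] = delta_w, _["leaf_class"] = leaf_class);
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  IntegerVector leaf_class = tree["leaf_class"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int j = feature[node] - 1;
      node = (X(i, j) <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = leaf_class[node];
  }
  return out;
}

// Leaf node id (1-based) each row of X falls into; used by tests that
// inspect node membership.
// [[Rcpp::export]]
IntegerVector cpp_tree_leaf_id(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int j = feature[node] - 1;
      node = (X(i, j) <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = node + 1;
  }
  return out;
}
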