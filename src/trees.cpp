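// CART-style regression trees with two growth modes, shared by the random
// forest (bagged, feature-subsampled, fully grown) and the gradient
// boosting (shallow, all features, presorted scan) classifier families.
// Splits maximize the sum-of-squares reduction; ties are broken towards
// the lower feature index and lower threshold, deterministically.
// Randomness (bootstrap, mtry draws) comes from R's RNG so that a single
// set.seed() on the R side makes fits reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Tree {
  std::vector<int> feature;      // -1 = leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;     // node mean of the response
};

static NumericMatrix tree_to_matrix(const Tree& tr) {
  int n = tr.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = tr.feature[i];
    m(i, 1) = tr.threshold[i];
    m(i, 2) = tr.left[i];
    m(i, 3) = tr.right[i];
    m(i, 4) = tr.value[i];
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left", "right", "value");
  return m;
}

struct GrowCtx {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry;
  int max_depth;                 // 0 = unlimited
  int min_node;                  // minimum rows per leaf
  const std::vector<int>* order; // presorted row order per feature (GBM mode)
  std::vector<char> member;      // scratch for presorted scans
  std::vector<double>* importance;
  GrowCtx(const NumericMatrix& X_, const NumericVector& y_)
    : X(X_), y(y_), mtry(0), max_depth(0), min_node(1), order(nullptr),
      importance(nullptr) {}
};

static int grow(GrowCtx& c, std::vector<int>& idx, int lo, int hi,
                int depth, Tree& tree) {
  const int node = (int)tree.feature.size();
  const int n = hi - lo;
  double sum = 0.0;
  for (int t = lo; t < hi; ++t) sum += c.y[idx[t]];
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(sum / n);

  if (n < 2 * c.min_node) return node;
  if (c.max_depth > 0 && depth >= c.max_depth) return node;
  bool const_y = true;
  for (int t = lo + 1; t < hi; ++t)
    if (c.y[idx[t]] != c.y[idx[lo]]) { const_y = false; break; }
  if (const_y) return node;

  const int p = c.X.ncol();
  std::vector<int> feats;
  if (c.mtry >= p) {
    feats.resize(p);
    for (int f = 0; f < p; ++f) feats[f] = f;
  } else {
    // partial Fisher-Yates without replacement, then sorted for
    // deterministic tie-breaking by feature index
    std::vector<int> all(p);
    for (int f = 0; f < p; ++f) all[f] = f;
    for (int t = 0; t < c.mtry; ++t) {
      int j = t + (int)(unif_rand() * (p - t));
      if (j >= p) j = p - 1;
      std::swap(all[t], all[j]);
    }
    feats.assign(all.begin(), all.begin() + c.mtry);
    std::sort(feats.begin(), feats.end());
  }

  const double parent_term = sum * sum / n;
  double best_gain = 1e-10;
  int best_f = -1;
  double best_thr = 0.0;

  if (c.order) {
    // presorted scan over all rows (shallow trees, all features)
    for (int t = lo; t < hi; ++t) c.member[idx[t]] = 1;
    const int ntot = c.X.nrow();
    std::vector<double> xv(n), yv(n);
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      const int f = feats[fi];
      const int* ord = c.order->data() + (size_t)f * ntot;
      int k = 0;
      for (int t = 0; t < ntot; ++t) {
        const int row = ord[t];
        if (c.member[row]) { xv[k] = c.X(row, f); yv[k] = c.y[row]; ++k; }
      }
      if (xv[0] == xv[n - 1]) continue;
      double sl = 0.0;
      for (int t = 0; t < n - 1; ++t) {
        sl += yv[t];
        if (xv[t] == xv[t + 1]) continue;
        const int nl = t + 1, nr = n - nl;
        if (nl < c.min_node || nr < c.min_node) continue;
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr - parent_term;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xv[t] + xv[t + 1]);
        }
      }
    }
    for (int t = lo; t < hi; ++t) c.member[idx[t]] = 0;
  } else {
    // per-node sort (deep trees, few features per split)
    std::vector<std::pair<double, double> > xy(n);
    for (size_t fi = 0; fi < feats.size(); ++fi) {
      const int f = feats[fi];
      for (int t = 0; t < n; ++t) {
        const int row = idx[lo + t];
        xy[t] = std::make_pair(c.X(row, f), c.y[row]);
      }
      std::sort(xy.begin(), xy.end());
      if (xy[0].first == xy[n - 1].first) continue;
      double sl = 0.0;
      for (int t = 0; t < n - 1; ++t) {
        sl += xy[t].second;
        if (xy[t].first == xy[t + 1].first) continue;
        const int nl = t + 1, nr = n - nl;
        if (nl < c.min_node || nr < c.min_node) continue;
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr - parent_term;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xy[t].first + xy[t + 1].first);
        }
      }
    }
  }

  if (best_f < 0) return node;
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (c.X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric degeneracy guard

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  if (c.importance) (*c.importance)[best_f] += best_gain;
  tree.left[node] = grow(c, idx, lo, mid, depth + 1, tree);
  tree.right[node] = grow(c, idx, mid, hi, depth + 1, tree);
  return node;
}

static int descend(const Tree& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr.feature[node] >= 0)
    node = (X(row, tr.feature[node]) <= tr.threshold[node])
      ? tr.left[node] : tr.right[node];
  return node;
}

static double predict_matrix_tree(const NumericMatrix& nodes,
                                  const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)nodes(node, 0) >= 0)
    node = (X(row, (int)nodes(node, 0)) <= nodes(node, 1))
      ? (int)nodes(node, 2) : (int)nodes(node, 3);
  return nodes(node, 4);
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_node, int max_depth) {
  RNGScope scope;
  const int n = X.nrow(), p = X.ncol();
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  GrowCtx ctx(X, y);
  ctx.mtry = std::max(1, std::min(mtry, p));
  ctx.min_node = std::max(1, min_node);
  ctx.max_depth = max_depth;
  ctx.importance = &importance;
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      idx[i] = (j >= n) ? n - 1 : j;
    }
    Tree tr;
    grow(ctx, idx, 0, n, 0, tr);
    trees[t] = tree_to_matrix(tr);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(), importance.end()));
}

// [[Rcpp::export]]
NumericVector forest_vote_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector votes(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nodes = trees[t];
    for (int i = 0; i < n; ++i)
      if (predict_matrix_tree(nodes, X, i) > 0.5) votes[i] += 1.0;
  }
  for (int i = 0; i < n; ++i) votes[i] /= T;
  return votes;
}

// [[Rcpp::export]]
NumericMatrix forest_leaf_means_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nodes = trees[t];
    for (int i = 0; i < n; ++i) out(i, t) = predict_matrix_tree(nodes, X, i);
  }
  return out;
}

// [[Rcpp::export]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int depth,
                 double shrinkage, int min_node) {
  RNGScope scope;
  const int n = X.nrow(), p = X.ncol();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double f0 = std::log(ybar / (1.0 - ybar));

  // presort rows per feature once
  std::vector<int> order((size_t)p * n);
  {
    std::vector<std::pair<double, int> > tmp(n);
    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n; ++i) tmp[i] = std::make_pair(X(i, f), i);
      std::stable_sort(tmp.begin(), tmp.end());
      for (int i = 0; i < n; ++i) order[(size_t)f * n + i] = tmp[i].second;
    }
  }

  std::vector<double> F(n, f0), importance(p, 0.0);
  NumericVector r(n);
  std::vector<double> w(n);
  GrowCtx ctx(X, r);
  ctx.mtry = p;
  ctx.min_node = std::max(1, min_node);
  ctx.max_depth = depth;
  ctx.order = &order;
  ctx.member.assign(n, 0);
  ctx.importance = &importance;

  List trees(n_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      const double pi = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - pi;
      w[i] = std::max(pi * (1.0 - pi), 1e-6);
    }
    for (int i = 0; i < n; ++i) idx[i] = i;
    Tree tr;
    grow(ctx, idx, 0, n, 0, tr);
    // Newton step per leaf: sum(residual) / sum(p(1-p)), clipped
    const int nn = (int)tr.feature.size();
    std::vector<double> num(nn, 0.0), den(nn, 0.0);
    std::vector<int> leaf_of(n);
    for (int i = 0; i < n; ++i) {
      const int leaf = descend(tr, X, i);
      leaf_of[i] = leaf;
      num[leaf] += r[i];
      den[leaf] += w[i];
    }
    for (int nd = 0; nd < nn; ++nd) {
      if (tr.feature[nd] >= 0) continue;
      double g = (den[nd] > 0) ? num[nd] / den[nd] : 0.0;
      if (g > 4.0) g = 4.0;
      if (g < -4.0) g = -4.0;
      tr.value[nd] = g;
    }
    for (int i = 0; i < n; ++i) F[i] += shrinkage * tr.value[leaf_of[i]];
    trees[t] = tree_to_matrix(tr);
  }
  return List::create(_["trees"] = trees, _["f0"] = f0,
                      _["shrinkage"] = shrinkage,
                      _["importance"] = NumericVector(importance.begin(), importance.end()));
}

// Staged boosted scores: column t holds f0 + shrinkage * sum of the first
// t trees, on the link (log-odds) scale.
// [[Rcpp::export]]
NumericMatrix gbm_staged_link_cpp(List trees, double f0, double shrinkage,
                                  NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  std::vector<double> F(n, f0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nodes = trees[t];
    for (int i = 0; i < n; ++i) {
      F[i] += shrinkage * predict_matrix_tree(nodes, X, i);
      out(i, t) = F[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gbm_link_cpp(List trees, double f0, double shrinkage,
                           NumericMatrix X, int n_use) {
  const int n = X.nrow();
  const int T = std::min((int)trees.size(), n_use);
  NumericVector F(n, f0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nodes = trees[t];
    for (int i = 0; i < n; ++i)
      F[i] += shrinkage * predict_matrix_tree(nodes, X, i);
  }
  return F;
}
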