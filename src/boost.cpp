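// Second-order (Newton) gradient-boosted trees for binary logistic loss.
//
// Exact greedy split finding on dense features, with the regularized gain
//   gain = 1/2 * [ S(GL,HL) + S(GR,HR) - S(G,H) ],  S(G,H) = T(G)^2 / (H + lambda)
// where T is the L1 soft-threshold T(G) = sign(G) * max(|G| - alpha, 0), and
// leaf weights w = -T(G) / (H + lambda), scaled by the learning rate at
// training time. Cover is the hessian sum at the split node. Determinism:
// a private xorshift-free mt19937 stream seeded from R, feature iteration in
// ascending index order, ties broken toward the lower feature index and the
// earlier threshold; no std::*_distribution (their algorithms vary across
// standard libraries).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // midpoint between adjacent distinct values
  double value;     // leaf weight (already scaled by learning rate)
  int left, right;  // child indices, -1 for leaf
};

struct SplitInfo {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  double cover = 0.0; // hessian sum at the node
};

struct Importance {
  std::vector<int> splits;
  std::vector<double> gain;
  std::vector<double> cover;
};

inline double soft_threshold(double g, double alpha) {
  if (g > alpha) return g - alpha;
  if (g < -alpha) return g + alpha;
  return 0.0;
}

inline double leaf_score(double G, double H, double alpha, double lambda) {
  double t = soft_threshold(G, alpha);
  return t * t / (H + lambda);
}

inline double leaf_weight(double G, double H, double alpha, double lambda) {
  return -soft_threshold(G, alpha) / (H + lambda);
}

// bounded draw without std::uniform_int_distribution (portability)
inline std::size_t draw_below(std::mt19937_64 &rng, std::size_t n) {
  return static_cast<std::size_t>(rng() % n);
}

struct TreeBuilder {
  const NumericMatrix &X;
  const std::vector<double> &grad, &hess;
  const std::vector<int> &cols; // candidate features, ascending
  double alpha, lambda, min_child_weight, eta;
  int max_depth;
  std::vector<Node> nodes;
  Importance &imp;

  TreeBuilder(const NumericMatrix &X_, const std::vector<double> &g,
              const std::vector<double> &h, const std::vector<int> &cols_,
              double alpha_, double lambda_, double mcw, double eta_,
              int max_depth_, Importance &imp_)
      : X(X_), grad(g), hess(h), cols(cols_), alpha(alpha_), lambda(lambda_),
        min_child_weight(mcw), eta(eta_), max_depth(max_depth_), imp(imp_) {}

  SplitInfo best_split(const std::vector<int> &idx, double G, double H) {
    SplitInfo best;
    best.cover = H;
    const double parent_score = leaf_score(G, H, alpha, lambda);
    std::vector<std::pair<double, int>> vals(idx.size());
    for (int f : cols) {
      for (std::size_t i = 0; i < idx.size(); ++i)
        vals[i] = {X(idx[i], f), idx[i]};
      std::sort(vals.begin(), vals.end(),
                [](const std::pair<double, int> &a,
                   const std::pair<double, int> &b) { return a.first < b.first; });
      if (vals.front().first == vals.back().first) continue; // constant
      double GL = 0.0, HL = 0.0;
      for (std::size_t i = 0; i + 1 < vals.size(); ++i) {
        GL += grad[vals[i].second];
        HL += hess[vals[i].second];
        if (vals[i].first == vals[i + 1].first) continue; // not a boundary
        const double HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        const double GR = G - GL;
        const double gain =
            0.5 * (leaf_score(GL, HL, alpha, lambda) +
                   leaf_score(GR, HR, alpha, lambda) - parent_score);
        if (gain > best.gain + 1e-12) {
          best.gain = gain;
          best.feature = f;
          best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    return best;
  }

  int build(const std::vector<int> &idx, int depth) {
    double G = 0.0, H = 0.0;
    for (int i : idx) {
      G += grad[i];
      H += hess[i];
    }
    SplitInfo sp;
    if (depth < max_depth && idx.size() >= 2) sp = best_split(idx, G, H);
    const int me = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    if (sp.feature < 0 || sp.gain <= 1e-12) {
      nodes[me].feature = -1;
      nodes[me].threshold = 0.0;
      nodes[me].left = nodes[me].right = -1;
      nodes[me].value = eta * leaf_weight(G, H, alpha, lambda);
      return me;
    }
    imp.splits[sp.feature] += 1;
    imp.gain[sp.feature] += sp.gain;
    imp.cover[sp.feature] += sp.cover;
    std::vector<int> left_idx, right_idx;
    left_idx.reserve(idx.size());
    right_idx.reserve(idx.size());
    for (int i : idx) {
      if (X(i, sp.feature) < sp.threshold)
        left_idx.push_back(i);
      else
        right_idx.push_back(i);
    }
    nodes[me].feature = sp.feature;
    nodes[me].threshold = sp.threshold;
    nodes[me].value = 0.0;
    nodes[me].left = build(left_idx, depth + 1);
    nodes[me].right = build(right_idx, depth + 1);
    return me;
  }
};

double tree_predict_row(const std::vector<Node> &nodes, const NumericMatrix &X,
                        int row) {
  int cur = 0;
  while (nodes[cur].feature >= 0)
    cur = (X(row, nodes[cur].feature) < nodes[cur].threshold) ? nodes[cur].left
                                                              : nodes[cur].right;
  return nodes[cur].value;
}

List tree_to_list(const std::vector<Node> &nodes) {
  const int n = static_cast<int>(nodes.size());
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n), value(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    value[i] = nodes[i].value;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["value"] = value, _["left"] = left, _["right"] = right);
}

std::vector<Node> tree_from_list(const List &tr) {
  IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
  NumericVector threshold = tr["threshold"], value = tr["value"];
  std::vector<Node> nodes(feature.size());
  for (int i = 0; i < feature.size(); ++i) {
    nodes[i].feature = feature[i];
    nodes[i].threshold = threshold[i];
    nodes[i].value = value[i];
    nodes[i].left = left[i];
    nodes[i].right = right[i];
  }
  return nodes;
}

} // namespace

// [[Rcpp::export(name = ".gbt_train")]]
List gbt_train(NumericMatrix X, NumericVector y, List params) {
  const int n = X.nrow(), p = X.ncol();
  const int max_depth = as<int>(params["max_depth"]);
  const double subsample = as<double>(params["subsample"]);
  const double colsample = as<double>(params["colsample_bytree"]);
  const double mcw = as<double>(params["min_child_weight"]);
  const double alpha = as<double>(params["alpha"]);
  const double lambda = as<double>(params["lambda"]);
  const double eta = as<double>(params["learning_rate"]);
  const int iterations = as<int>(params["iterations"]);
  const double base_margin = as<double>(params["base_margin"]);
  const bool bootstrap = as<bool>(params["bootstrap"]);
  const std::uint64_t seed = static_cast<std::uint64_t>(as<double>(params["seed"]));

  std::mt19937_64 rng(seed * 2654435761ULL + 1ULL);

  std::vector<double> margin(n, base_margin), grad(n), hess(n);
  List trees(iterations);
  Importance imp;
  imp.splits.assign(p, 0);
  imp.gain.assign(p, 0.0);
  imp.cover.assign(p, 0.0);
  NumericMatrix train_margins(n, iterations);

  std::vector<int> all_rows(n), all_cols(p);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  for (int j = 0; j < p; ++j) all_cols[j] = j;

  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      const double pr = 1.0 / (1.0 + std::exp(-margin[i]));
      grad[i] = pr - y[i];
      hess[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    // row sampling
    std::vector<int> rows;
    if (bootstrap) {
      rows.resize(n);
      for (int i = 0; i < n; ++i) rows[i] = static_cast<int>(draw_below(rng, n));
      std::sort(rows.begin(), rows.end());
    } else if (subsample < 1.0) {
      std::vector<int> perm = all_rows;
      const int m = std::max(1, static_cast<int>(std::floor(subsample * n)));
      for (int i = 0; i < m; ++i) {
        std::size_t j = i + draw_below(rng, n - i);
        std::swap(perm[i], perm[j]);
      }
      rows.assign(perm.begin(), perm.begin() + m);
      std::sort(rows.begin(), rows.end());
    } else {
      rows = all_rows;
    }
    // column sampling (per tree)
    std::vector<int> cols;
    if (colsample < 1.0) {
      std::vector<int> perm = all_cols;
      const int m = std::max(1, static_cast<int>(std::floor(colsample * p)));
      for (int j = 0; j < m; ++j) {
        std::size_t k = j + draw_below(rng, p - j);
        std::swap(perm[j], perm[k]);
      }
      cols.assign(perm.begin(), perm.begin() + m);
      std::sort(cols.begin(), cols.end());
    } else {
      cols = all_cols;
    }

    TreeBuilder tb(X, grad, hess, cols, alpha, lambda, mcw, eta, max_depth, imp);
    tb.build(rows, 0);
    for (int i = 0; i < n; ++i) {
      margin[i] += tree_predict_row(tb.nodes, X, i);
      train_margins(i, it) = margin[i];
    }
    trees[it] = tree_to_list(tb.nodes);
  }

  return List::create(_["trees"] = trees,
                      _["importance_splits"] = wrap(imp.splits),
                      _["importance_gain"] = wrap(imp.gain),
                      _["importance_cover"] = wrap(imp.cover),
                      _["train_margins"] = train_margins);
}

// Cumulative margins: column j holds predictions using trees 1..j.
// [[Rcpp::export(name = ".gbt_margins")]]
NumericMatrix gbt_margins(List trees, NumericMatrix X, double base_margin) {
  const int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, T);
  std::vector<double> cur(n, base_margin);
  for (int t = 0; t < T; ++t) {
    std::vector<Node> nodes = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) {
      cur[i] += tree_predict_row(nodes, X, i);
      out(i, t) = cur[i];
    }
  }
  return out;
}
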