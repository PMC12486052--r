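// Honest causal forest core: subsampled honest trees with
// heterogeneity-maximizing splits and out-of-bag CATE aggregation.
//
// Each tree: (1) draw a subsample without replacement; (2) split it into a
// structure half and an estimation half; (3) grow the partition on the
// structure half only, scoring every candidate cut by the size-weighted
// squared difference of the child treatment-effect estimates; (4) estimate
// leaf effects on the estimation half only (honesty). The within-node effect
// estimate is cov(W, Y) / var(W), which for a raw binary treatment reduces
// to the treated-minus-control mean difference and for residualized
// (locally centered) W, Y is the usual partialled-out regression slope.
//
// Per-feature sample orderings are sorted once per tree and kept sorted
// through splits by stable partitioning, so node scans are linear.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids
  double estimate;  // honest leaf effect (leaves only)
};

struct Problem {
  const double* X; // column-major n x p
  const double* Y; // possibly centered
  const double* W; // possibly centered
  const int* Wb;   // raw binary treatment, for min_leaf counts
  int n, p;
  int min_leaf;
  int mtry;
  double x(int i, int f) const { return X[(size_t)f * n + i]; }
};

struct NodeStats {
  double n = 0, sw = 0, sy = 0, sww = 0, swy = 0;
  int n1 = 0, n0 = 0;
  void add(const Problem& pb, int i) {
    double w = pb.W[i], y = pb.Y[i];
    n += 1; sw += w; sy += y; sww += w * w; swy += w * y;
    if (pb.Wb[i] == 1) n1++; else n0++;
  }
  bool tau(double& out) const {
    if (n < 2) return false;
    double mw = sw / n;
    double varw = sww / n - mw * mw;
    if (varw < 1e-12) return false;
    out = (swy / n - mw * (sy / n)) / varw;
    return true;
  }
};

// per-feature orderings of the node's structure / estimation samples
struct FeatLists {
  std::vector<std::vector<int>> str, est;
};

int build_node(const Problem& pb, FeatLists& fl, double fallback_estimate,
               std::vector<Node>& nodes, std::mt19937& rng) {
  int n_str = (int)fl.str[0].size();

  NodeStats est_stats;
  for (int i : fl.est[0]) est_stats.add(pb, i);
  double leaf_est = fallback_estimate;
  est_stats.tau(leaf_est); // overwrite when estimable in the honest half

  int best_feature = -1;
  double best_threshold = 0, best_score = 0;

  bool can_split =
      n_str >= 4 &&
      est_stats.n1 >= 2 * pb.min_leaf && est_stats.n0 >= 2 * pb.min_leaf;

  if (can_split) {
    int p = pb.p;
    int mtry = std::min(pb.mtry, p);
    // sample mtry distinct features, then visit in ascending index order so
    // score ties resolve to the first covariate in schema order
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int k = j + (int)(rng() % (p - j));
      std::swap(feats[j], feats[k]);
    }
    feats.resize(mtry);
    std::sort(feats.begin(), feats.end());

    NodeStats str_tot;
    for (int i : fl.str[0]) str_tot.add(pb, i);

    for (int f : feats) {
      const std::vector<int>& s_ord = fl.str[f];
      const std::vector<int>& e_ord = fl.est[f];
      NodeStats left;
      size_t e_ptr = 0;
      int e_left1 = 0, e_left0 = 0;
      for (int k = 0; k + 1 < n_str; ++k) {
        int i = s_ord[k];
        left.add(pb, i);
        double xv = pb.x(i, f), xn = pb.x(s_ord[k + 1], f);
        if (xv == xn) continue;
        double cut = 0.5 * (xv + xn);
        while (e_ptr < e_ord.size() && pb.x(e_ord[e_ptr], f) <= cut) {
          if (pb.Wb[e_ord[e_ptr]] == 1) e_left1++; else e_left0++;
          ++e_ptr;
        }
        // honest-half arm counts on both sides must allow estimation
        int e_right1 = est_stats.n1 - e_left1, e_right0 = est_stats.n0 - e_left0;
        if (e_left1 < pb.min_leaf || e_left0 < pb.min_leaf ||
            e_right1 < pb.min_leaf || e_right0 < pb.min_leaf)
          continue;
        NodeStats right;
        right.n = str_tot.n - left.n; right.sw = str_tot.sw - left.sw;
        right.sy = str_tot.sy - left.sy; right.sww = str_tot.sww - left.sww;
        right.swy = str_tot.swy - left.swy;
        right.n1 = str_tot.n1 - left.n1; right.n0 = str_tot.n0 - left.n0;
        if (left.n1 < pb.min_leaf || left.n0 < pb.min_leaf ||
            right.n1 < pb.min_leaf || right.n0 < pb.min_leaf)
          continue;
        double tl, tr;
        if (!left.tau(tl) || !right.tau(tr)) continue;
        double score =
            (left.n * right.n) / (str_tot.n * str_tot.n) * (tl - tr) * (tl - tr);
        if (score > best_score) {
          best_score = score;
          best_feature = f;
          best_threshold = cut;
        }
      }
    }
  }

  int id = (int)nodes.size();
  nodes.push_back(Node{-1, 0.0, -1, -1, leaf_est});
  if (best_feature < 0) return id;

  // stable partition of every feature's ordering: children stay sorted
  FeatLists fll, flr;
  fll.str.resize(pb.p); fll.est.resize(pb.p);
  flr.str.resize(pb.p); flr.est.resize(pb.p);
  int bf = best_feature;
  double bt = best_threshold;
  for (int f = 0; f < pb.p; ++f) {
    for (int i : fl.str[f])
      (pb.x(i, bf) <= bt ? fll.str[f] : flr.str[f]).push_back(i);
    for (int i : fl.est[f])
      (pb.x(i, bf) <= bt ? fll.est[f] : flr.est[f]).push_back(i);
  }
  { FeatLists tmp; std::swap(tmp.str, fl.str); std::swap(tmp.est, fl.est); }
  int lid = build_node(pb, fll, leaf_est, nodes, rng);
  { FeatLists tmp; std::swap(tmp.str, fll.str); std::swap(tmp.est, fll.est); }
  int rid = build_node(pb, flr, leaf_est, nodes, rng);
  nodes[id].feature = bf;
  nodes[id].threshold = bt;
  nodes[id].left = lid;
  nodes[id].right = rid;
  return id;
}

double predict_tree(const std::vector<Node>& nodes, const Problem& pb,
                    int row) {
  int id = 0;
  while (nodes[id].feature >= 0) {
    id = (pb.x(row, nodes[id].feature) <= nodes[id].threshold)
             ? nodes[id].left
             : nodes[id].right;
  }
  return nodes[id].estimate;
}

} // namespace

// [[Rcpp::export(name = ".cf_fit")]]
List cf_fit(NumericMatrix X, NumericVector Y, NumericVector W,
            IntegerVector Wb, int n_trees, double sample_fraction,
            double honesty_fraction, int min_leaf, int mtry, int seed,
            bool keep_trees) {
  int n = X.nrow(), p = X.ncol();
  Problem pb{REAL(X), REAL(Y), REAL(W), INTEGER(Wb), n, p, min_leaf, mtry};
  std::mt19937 rng((unsigned)seed);

  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_count(n, 0);
  List trees(keep_trees ? n_trees : 0);

  int s = std::max(4, (int)std::floor(sample_fraction * n));
  s = std::min(s, n);
  int est_n = (int)std::floor(honesty_fraction * s);
  est_n = std::max(2, std::min(est_n, s - 2));

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    // subsample without replacement, then carve off the honest half
    std::vector<int> perm = all;
    for (int j = 0; j < s; ++j) {
      int k = j + (int)(rng() % (n - j));
      std::swap(perm[j], perm[k]);
    }
    std::vector<int> est_idx(perm.begin(), perm.begin() + est_n);
    std::vector<int> str_idx(perm.begin() + est_n, perm.begin() + s);
    std::vector<bool> in_sub(n, false);
    for (int j = 0; j < s; ++j) in_sub[perm[j]] = true;

    FeatLists fl;
    fl.str.resize(p); fl.est.resize(p);
    for (int f = 0; f < p; ++f) {
      fl.str[f] = str_idx;
      std::sort(fl.str[f].begin(), fl.str[f].end(), [&](int a, int b) {
        double xa = pb.x(a, f), xb = pb.x(b, f);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      fl.est[f] = est_idx;
      std::sort(fl.est[f].begin(), fl.est[f].end(), [&](int a, int b) {
        return pb.x(a, f) < pb.x(b, f);
      });
    }

    std::vector<Node> nodes;
    nodes.reserve(64);
    NodeStats root_est;
    for (int i : est_idx) root_est.add(pb, i);
    double root_fallback = 0.0;
    root_est.tau(root_fallback);
    build_node(pb, fl, root_fallback, nodes, rng);

    for (int i = 0; i < n; ++i) {
      if (in_sub[i]) continue;
      oob_sum[i] += predict_tree(nodes, pb, i);
      oob_count[i] += 1;
    }

    if (keep_trees) {
      NumericMatrix nm((int)nodes.size(), 5);
      for (size_t k = 0; k < nodes.size(); ++k) {
        nm(k, 0) = nodes[k].feature + 1; // 1-based; 0 marks a leaf
        nm(k, 1) = nodes[k].threshold;
        nm(k, 2) = nodes[k].left + 1;
        nm(k, 3) = nodes[k].right + 1;
        nm(k, 4) = nodes[k].estimate;
      }
      IntegerVector sub(s), est(est_n);
      for (int j = 0; j < s; ++j) sub[j] = perm[j] + 1;
      for (int j = 0; j < est_n; ++j) est[j] = est_idx[j] + 1;
      trees[t] = List::create(_["nodes"] = nm, _["subsample"] = sub,
                              _["est_half"] = est);
    }
  }

  NumericVector tau(n);
  for (int i = 0; i < n; ++i) {
    tau[i] = oob_count[i] > 0 ? oob_sum[i] / oob_count[i] : NA_REAL;
  }
  return List::create(_["tau_oob"] = tau, _["oob_count"] = oob_count,
                      _["trees"] = trees);
}
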