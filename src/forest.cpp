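#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Breiman-style regression random forest with per-tree out-of-bag (OOB)
// permutation importance.
//
// Per tree: bootstrap n rows with replacement (integer weights); grow a
// CART regression tree (variance-reduction splits, mtry features sampled
// per node) until a node is pure or smaller than 2 * min_node bootstrap
// copies. Trees are built level-wise over per-node partitioned sorted row
// lists (the global per-feature sort is done once per fit), so split scans
// are sequential and segments of nodes that did not sample a feature are
// skipped wholesale.
//
// Importance of feature m is the mean over trees of (OOB MSE with column m
// permuted within the tree's OOB rows) minus (untouched OOB MSE): positive
// = informative. A feature the tree never splits on contributes exactly 0
// for that tree, so its permutation pass is skipped; for p <= 64 a per-row
// bitmask of path features avoids re-descending rows whose prediction a
// permutation cannot change.
//
// All randomness flows from one std::mt19937_64 engine seeded from R, so a
// fixed seed reproduces the forest bit-for-bit on any platform.

namespace {

struct FNode {
  int feature = -1;       // -1 leaf
  double threshold = 0.0; // x < threshold goes left
  int left = -1, right = -1;
  double value = 0.0;     // leaf mean
};

inline uint64_t rand_below(std::mt19937_64& eng, uint64_t n) {
  const uint64_t limit = std::numeric_limits<uint64_t>::max() -
                         (std::numeric_limits<uint64_t>::max() % n);
  uint64_t r;
  do { r = eng(); } while (r >= limit);
  return r % n;
}

inline double predict_masked(const std::vector<FNode>& nodes,
                             const NumericMatrix& X, int i,
                             int swap_feat, double swap_val,
                             uint64_t* mask_out) {
  int k = 0;
  uint64_t mask = 0;
  while (nodes[k].feature >= 0) {
    const int j = nodes[k].feature;
    if (j < 64) mask |= (uint64_t{1} << j);
    const double v = (j == swap_feat) ? swap_val : X(i, j);
    k = (v < nodes[k].threshold) ? nodes[k].left : nodes[k].right;
  }
  if (mask_out) *mask_out = mask;
  return nodes[k].value;
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y,
                int n_trees, int mtry, int min_node, double seed64) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least two rows");
  if (mtry > p) mtry = p;
  std::mt19937_64 eng((uint64_t)seed64);

  std::vector<std::vector<int>> order0(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& oj = order0[j];
    for (int i = 0; i < n; ++i) oj[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(oj.begin(), oj.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<double> inv_w(n + 1, 0.0);
  for (int c = 1; c <= n; ++c) inv_w[c] = 1.0 / c;

  std::vector<double> imp_sum(p, 0.0);
  double oob_sse = 0.0;
  long oob_n = 0;
  int trees_used = 0, trees_skipped = 0;
  const bool maskable = (p <= 64);

  std::vector<int> w(n), node_of(n), feat_pool(p), oob_rows, perm;
  std::vector<std::vector<int>> srt(p), srt_next(p);
  std::vector<char> tree_used_feat(p);
  std::vector<double> oob_pred, oob_err2;
  std::vector<uint64_t> oob_mask;
  // level scratch, reused across levels/trees to avoid re-allocation
  std::vector<double> levS, parent_score, bestGain, bestThr;
  std::vector<int> levW, bestFeat, child_size, cursor, cur;
  std::vector<char> cand;

  for (int t = 0; t < n_trees; ++t) {
    std::fill(w.begin(), w.end(), 0);
    for (int d = 0; d < n; ++d) w[(int)rand_below(eng, (uint64_t)n)]++;
    oob_rows.clear();
    for (int i = 0; i < n; ++i) {
      node_of[i] = w[i] > 0 ? 0 : -1;
      if (!w[i]) oob_rows.push_back(i);
    }
    for (int j = 0; j < p; ++j) {
      srt[j].clear();
      for (int s = 0; s < n; ++s)
        if (w[order0[j][s]] > 0) srt[j].push_back(order0[j][s]);
    }

    std::vector<FNode> nodes(1);
    std::fill(tree_used_feat.begin(), tree_used_feat.end(), 0);
    std::vector<int> seg_size(1, (int)srt[0].size());
    int level_begin = 0, level_end = 1;

    while (level_begin < level_end) {
      const int nlev = level_end - level_begin;

      // per-node totals, purity, candidate features
      levS.assign(nlev, 0.0);
      parent_score.assign(nlev, 0.0);
      levW.assign(nlev, 0);
      cand.assign((size_t)nlev * p, 0);
      bool any_candidate = false;
      {
        const int* rows = srt[0].data();
        int off = 0;
        for (int k = 0; k < nlev; ++k) {
          double S = 0.0, ymin = R_PosInf, ymax = R_NegInf;
          int W = 0;
          for (int s = 0; s < seg_size[k]; ++s) {
            const int i = rows[off + s];
            S += w[i] * y[i];
            W += w[i];
            if (y[i] < ymin) ymin = y[i];
            if (y[i] > ymax) ymax = y[i];
          }
          levS[k] = S;
          levW[k] = W;
          parent_score[k] = S * S * inv_w[W];
          if (W >= 2 * min_node && ymax > ymin) {
            any_candidate = true;
            for (int j = 0; j < p; ++j) feat_pool[j] = j;
            for (int u = 0; u < mtry; ++u) {
              const int sw = u + (int)rand_below(eng, (uint64_t)(p - u));
              std::swap(feat_pool[u], feat_pool[sw]);
              cand[(size_t)k * p + feat_pool[u]] = 1;
            }
          }
          off += seg_size[k];
        }
      }

      bestGain.assign(nlev, 0.0);
      bestThr.assign(nlev, 0.0);
      bestFeat.assign(nlev, -1);
      if (any_candidate) {
        for (int j = 0; j < p; ++j) {
          const int* rows = srt[j].data();
          const double* col = &X(0, j);
          int off = 0;
          for (int k = 0; k < nlev; ++k) {
            const int cnt = seg_size[k];
            if (cand[(size_t)k * p + j]) {
              double SLv = 0.0, lastv = col[rows[off]];
              int WLv = 0;
              double bg = bestGain[k], bt = bestThr[k];
              int bf = bestFeat[k];
              for (int s = 0; s < cnt; ++s) {
                const int i = rows[off + s];
                const double v = col[i];
                if (s > 0 && v > lastv) {
                  const int wr = levW[k] - WLv;
                  if (WLv >= min_node && wr >= min_node) {
                    const double sr = levS[k] - SLv;
                    const double gain =
                      SLv * SLv * inv_w[WLv] + sr * sr * inv_w[wr] -
                      parent_score[k];
                    if (gain > bg + 1e-12) {
                      bg = gain; bf = j; bt = 0.5 * (lastv + v);
                    }
                  }
                }
                SLv += w[i] * y[i];
                WLv += w[i];
                lastv = v;
              }
              bestGain[k] = bg; bestThr[k] = bt; bestFeat[k] = bf;
            }
            off += cnt;
          }
        }
      }

      // materialise splits, close leaves, route and partition
      const int old_end = level_end;
      for (int k = 0; k < nlev; ++k) {
        const int knode = level_begin + k;
        if (bestFeat[k] >= 0 && bestGain[k] > 0) {
          nodes[knode].feature = bestFeat[k];
          nodes[knode].threshold = bestThr[k];
          tree_used_feat[bestFeat[k]] = 1;
          nodes[knode].left = (int)nodes.size();
          nodes.push_back(FNode());
          nodes[knode].right = (int)nodes.size();
          nodes.push_back(FNode());
        } else {
          nodes[knode].feature = -1;
          nodes[knode].value = levW[k] > 0 ? levS[k] / levW[k] : 0.0;
        }
      }
      const int n_children = (int)nodes.size() - old_end;
      if (n_children > 0) {
        child_size.assign(n_children, 0);
        {
          const int* rows = srt[0].data();
          int off = 0;
          for (int k = 0; k < nlev; ++k) {
            const int knode = level_begin + k;
            if (nodes[knode].feature >= 0) {
              const double* col = &X(0, nodes[knode].feature);
              const double thr = nodes[knode].threshold;
              for (int s = 0; s < seg_size[k]; ++s) {
                const int i = rows[off + s];
                const int ch = (col[i] < thr) ? nodes[knode].left
                                              : nodes[knode].right;
                node_of[i] = ch;
                child_size[ch - old_end]++;
              }
            }
            off += seg_size[k];
          }
        }
        cursor.assign(n_children, 0);
        int acc = 0;
        for (int c = 0; c < n_children; ++c) { cursor[c] = acc; acc += child_size[c]; }
        for (int j = 0; j < p; ++j) {
          std::vector<int>& src = srt[j];
          std::vector<int>& dst = srt_next[j];
          dst.resize(acc);
          cur = cursor;
          int off = 0;
          for (int k = 0; k < nlev; ++k) {
            if (nodes[level_begin + k].feature >= 0) {
              for (int s = 0; s < seg_size[k]; ++s) {
                const int i = src[off + s];
                dst[cur[node_of[i] - old_end]++] = i;
              }
            }
            off += seg_size[k];
          }
          std::swap(srt[j], srt_next[j]);
        }
        seg_size = child_size;
      }
      level_begin = old_end;
      level_end = (int)nodes.size();
    }

    if (oob_rows.empty()) { ++trees_skipped; continue; }
    ++trees_used;

    const int no = (int)oob_rows.size();
    oob_pred.resize(no);
    oob_err2.resize(no);
    oob_mask.resize(no);
    double mse_base = 0.0;
    for (int s = 0; s < no; ++s) {
      uint64_t mask = 0;
      oob_pred[s] = predict_masked(nodes, X, oob_rows[s], -1, 0.0, &mask);
      oob_mask[s] = mask;
      const double e = oob_pred[s] - y[oob_rows[s]];
      oob_err2[s] = e * e;
      mse_base += e * e;
      oob_sse += e * e;
    }
    oob_n += no;
    mse_base /= no;

    perm.resize(no);
    for (int j = 0; j < p; ++j) {
      if (!tree_used_feat[j]) continue; // unused feature: exact zero increase
      for (int s = 0; s < no; ++s) perm[s] = s;
      for (int s = no - 1; s > 0; --s)
        std::swap(perm[s], perm[(int)rand_below(eng, (uint64_t)(s + 1))]);
      double sse_perm = 0.0;
      const uint64_t bit = (j < 64) ? (uint64_t{1} << j) : 0;
      for (int s = 0; s < no; ++s) {
        if (maskable && !(oob_mask[s] & bit)) {
          sse_perm += oob_err2[s]; // feature not on this row's path
          continue;
        }
        const double xv = X(oob_rows[perm[s]], j);
        const double e =
          predict_masked(nodes, X, oob_rows[s], j, xv, nullptr) - y[oob_rows[s]];
        sse_perm += e * e;
      }
      imp_sum[j] += (sse_perm / no - mse_base);
    }
  }

  NumericVector importance(p);
  for (int j = 0; j < p; ++j)
    importance[j] = trees_used > 0 ? imp_sum[j] / trees_used : NA_REAL;

  return List::create(
    _["importance"] = importance,
    _["oob_mse"] = oob_n > 0 ? oob_sse / oob_n : NA_REAL,
    _["trees_used"] = trees_used,
    _["trees_skipped"] = trees_skipped);
}
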