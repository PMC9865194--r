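#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Second-order gradient-boosted regression trees with squared-error loss.
// Exact greedy split search, level-wise growth over per-node sorted row
// lists: each feature's globally pre-sorted row order is maintained
// partitioned by tree node (stable partition per level), so split scans are
// strictly sequential. For squared error the hessian is 1 per row, so H is
// a row count and 1/(H+lambda) comes from a precomputed table; the scan is
// free of divisions and of random node lookups.
//
// Split gain (regularised, with L2 leaf penalty lambda and per-split
// penalty gamma):
//   gain = 0.5 * ( GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ) - gamma
// Leaf weight: w = -G/(H+lambda); prediction update: pred += eta * w.
// Feature importance: total gain summed over all splits using the feature.
//
// The fit is fully deterministic: no row or column subsampling, stable
// tie-breaks (lowest feature index, then lowest threshold, wins equal gains).

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // x < threshold goes left
  int left, right;  // child node ids, -1 for leaf
  double weight;    // leaf value (unscaled by eta)
};

} // namespace

// [[Rcpp::export(name = ".gbt_fit_cpp")]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y,
                 double eta, int nrounds, int max_depth,
                 double gamma, double lambda, double min_child_weight,
                 double base_score) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1 || p < 1) stop("empty design matrix");

  // pre-sort each column once; reused as the starting partition of every tree
  std::vector<std::vector<int>> order0(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& oj = order0[j];
    for (int i = 0; i < n; ++i) oj[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(oj.begin(), oj.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<double> inv_h(n + 1);
  for (int c = 0; c <= n; ++c) inv_h[c] = 1.0 / (c + lambda);
  const int mcw = (int)std::ceil(min_child_weight);

  std::vector<double> pred(n, base_score), g(n), importance(p, 0.0);
  List trees(nrounds);

  // per-node partitioned sorted lists (double-buffered), one per feature
  std::vector<std::vector<int>> srt(p), srt_next(p);
  std::vector<int> node_of(n);
  // level scratch, reused across levels/trees
  std::vector<double> levG, parent_score, bestGain, bestThr;
  std::vector<int> bestFeat, child_of, child_size, cursor, cur;

  for (int m = 0; m < nrounds; ++m) {
    for (int i = 0; i < n; ++i) g[i] = pred[i] - y[i]; // hess = 1

    std::vector<Node> nodes;
    nodes.push_back({-1, 0.0, -1, -1, 0.0});
    std::fill(node_of.begin(), node_of.end(), 0);
    for (int j = 0; j < p; ++j) srt[j] = order0[j];
    std::vector<int> seg_size(1, n); // node sizes at the current level
    int level_begin = 0, level_end = 1;

    for (int depth = 0; ; ++depth) {
      const int nlev = level_end - level_begin;
      int n_active = 0;
      for (int k = 0; k < nlev; ++k) n_active += seg_size[k];
      if (n_active == 0) break;

      // node gradient totals from the first feature's segments
      levG.assign(nlev, 0.0);
      {
        const int* rows = srt[0].data();
        int off = 0;
        for (int k = 0; k < nlev; ++k) {
          double acc = 0.0;
          for (int s = 0; s < seg_size[k]; ++s) acc += g[rows[off + s]];
          levG[k] = acc;
          off += seg_size[k];
        }
      }

      bestGain.assign(nlev, 0.0);
      bestThr.assign(nlev, 0.0);
      bestFeat.assign(nlev, -1);

      if (depth < max_depth) {
        parent_score.assign(nlev, 0.0);
        for (int k = 0; k < nlev; ++k)
          parent_score[k] = 0.5 * levG[k] * levG[k] * inv_h[seg_size[k]] + gamma;
        for (int j = 0; j < p; ++j) {
          const int* rows = srt[j].data();
          const double* col = &X(0, j);
          int off = 0;
          for (int k = 0; k < nlev; ++k) {
            const int cnt = seg_size[k];
            if (cnt >= 2 * mcw) {
              double GL = 0.0, lastv = col[rows[off]];
              const double G = levG[k];
              double bg = bestGain[k], bt = bestThr[k];
              int bf = bestFeat[k];
              for (int s = 0; s < cnt; ++s) {
                const int i = rows[off + s];
                const double v = col[i];
                if (s > 0 && v > lastv) {
                  const int cr = cnt - s;
                  if (s >= mcw && cr >= mcw) {
                    const double gr = G - GL;
                    const double gain =
                      0.5 * (GL * GL * inv_h[s] + gr * gr * inv_h[cr]) -
                      parent_score[k];
                    if (gain > bg + 1e-12) {
                      bg = gain; bf = j; bt = 0.5 * (lastv + v);
                    }
                  }
                }
                GL += g[i];
                lastv = v;
              }
              bestGain[k] = bg; bestThr[k] = bt; bestFeat[k] = bf;
            }
            off += cnt;
          }
        }
      }

      // materialise splits / close leaves; route rows
      const int old_end = level_end;
      child_of.assign(nlev, -1);
      bool any_split = false;
      for (int k = 0; k < nlev; ++k) {
        const int knode = level_begin + k;
        if (bestFeat[k] >= 0 && bestGain[k] > 0) {
          any_split = true;
          nodes[knode].feature = bestFeat[k];
          nodes[knode].threshold = bestThr[k];
          importance[bestFeat[k]] += bestGain[k];
          child_of[k] = (int)nodes.size();
          nodes[knode].left = (int)nodes.size();
          nodes.push_back({-1, 0.0, -1, -1, 0.0});
          nodes[knode].right = (int)nodes.size();
          nodes.push_back({-1, 0.0, -1, -1, 0.0});
        } else {
          // leaf: assign weight and update predictions for its rows
          const double wgt = -levG[k] * inv_h[seg_size[k]];
          nodes[knode].feature = -1;
          nodes[knode].weight = wgt;
          const int* rows = srt[0].data();
          int off = 0;
          for (int kk = 0; kk < k; ++kk) off += seg_size[kk];
          for (int s = 0; s < seg_size[k]; ++s)
            pred[rows[off + s]] += eta * wgt;
        }
      }
      if (!any_split) break;

      // new node ids for surviving rows; count child sizes
      const int n_children = (int)nodes.size() - old_end;
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
      // stable partition of every feature's sorted list into child segments
      cursor.assign(n_children, 0);
      {
        int acc = 0;
        for (int c = 0; c < n_children; ++c) { cursor[c] = acc; acc += child_size[c]; }
        for (int j = 0; j < p; ++j) {
          std::vector<int>& src = srt[j];
          std::vector<int>& dst = srt_next[j];
          dst.resize(acc);
          cur = cursor;
          int off = 0;
          for (int k = 0; k < nlev; ++k) {
            const bool split_k = nodes[level_begin + k].feature >= 0;
            if (split_k) {
              for (int s = 0; s < seg_size[k]; ++s) {
                const int i = src[off + s];
                dst[cur[node_of[i] - old_end]++] = i;
              }
            }
            off += seg_size[k];
          }
          std::swap(srt[j], srt_next[j]);
        }
      }
      seg_size = child_size;
      level_begin = old_end;
      level_end = (int)nodes.size();
    }

    NumericMatrix tr((int)nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tr(k, 0) = nodes[k].feature;
      tr(k, 1) = nodes[k].threshold;
      tr(k, 2) = nodes[k].left;
      tr(k, 3) = nodes[k].right;
      tr(k, 4) = nodes[k].weight;
    }
    trees[m] = tr;
  }

  return List::create(_["trees"] = trees,
                      _["base_score"] = base_score,
                      _["eta"] = eta,
                      _["importance"] = NumericVector(importance.begin(), importance.end()),
                      _["train_pred"] = NumericVector(pred.begin(), pred.end()));
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  const double base = as<double>(model["base_score"]);
  const double eta = as<double>(model["eta"]);
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int m = 0; m < trees.size(); ++m) {
    NumericMatrix tr = trees[m];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (tr(k, 0) >= 0) {
        const int j = (int)tr(k, 0);
        k = (X(i, j) < tr(k, 1)) ? (int)tr(k, 2) : (int)tr(k, 3);
      }
      out[i] += eta * tr(k, 4);
    }
  }
  return out;
}
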