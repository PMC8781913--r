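// Random-forest engine with surrogate splits.
//
// Trees are grown on bootstrap samples drawn with per-sample probabilities
// (case weights), split by Gini decrease over mtry candidate features with
// thresholds at midpoints of consecutive distinct values.  At every internal
// node up to s surrogate splits are recorded together with their adjusted
// agreement; these drive surrogate minimal depth and the mean adjusted
// agreement relation parameter.  Corrected impurity importance (AIR):
// per tree, one row permutation defines a pseudo copy of every feature;
// the candidate pool becomes the 2p actual+pseudo features and pseudo
// features are genuinely split on when they win.  A feature's importance
// is the split gain credited to its actual values minus the gain credited
// to its pseudo copy, which is exactly mean-zero for features unrelated to
// the labels because actual and pseudo copies are process-exchangeable.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline double gini_from_counts(const std::vector<int>& cnt, int m) {
  double g = 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double p = static_cast<double>(cnt[c]) / m;
    g -= p * p;
  }
  return g;
}

// Best threshold for one feature at one node.  xv/yv hold the node's
// values and 0-based classes in arbitrary but matching order.
struct ThresholdEval {
  bool valid;
  double gain;  // parent Gini minus weighted child Gini
  double thr;   // midpoint threshold, ties resolved to the lowest
};

ThresholdEval best_threshold(std::vector<double>& xv, std::vector<int>& yv,
                             int nclass, double parent_gini,
                             std::vector<int>& ord_buf) {
  const int m = static_cast<int>(xv.size());
  ThresholdEval best{false, 0.0, 0.0};
  if (m < 2) return best;
  ord_buf.resize(m);
  for (int i = 0; i < m; ++i) ord_buf[i] = i;
  std::sort(ord_buf.begin(), ord_buf.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });
  std::vector<int> left_cnt(nclass, 0), total_cnt(nclass, 0);
  for (int i = 0; i < m; ++i) total_cnt[yv[i]]++;
  for (int i = 0; i < m - 1; ++i) {
    left_cnt[yv[ord_buf[i]]]++;
    double xlo = xv[ord_buf[i]], xhi = xv[ord_buf[i + 1]];
    if (xhi <= xlo) continue;  // not a boundary between distinct values
    int ml = i + 1, mr = m - ml;
    double gl = 1.0, gr = 1.0;
    for (int c = 0; c < nclass; ++c) {
      double pl = static_cast<double>(left_cnt[c]) / ml;
      double pr = static_cast<double>(total_cnt[c] - left_cnt[c]) / mr;
      gl -= pl * pl;
      gr -= pr * pr;
    }
    double gain = parent_gini -
                  (static_cast<double>(ml) / m) * gl -
                  (static_cast<double>(mr) / m) * gr;
    if (!best.valid || gain > best.gain) {
      best.valid = true;
      best.gain = gain;
      best.thr = xlo + (xhi - xlo) / 2.0;
    }
  }
  return best;
}

// Surrogate search for one candidate feature: threshold and direction
// maximizing agreement with the primary left/right assignment.
struct SurrogateEval {
  bool valid;
  double adj;   // adjusted agreement
  double thr;
  bool flip;    // true: candidate's right side mimics the primary's left
};

SurrogateEval best_surrogate(std::vector<double>& xv, std::vector<int>& is_left,
                             int n_left, std::vector<int>& ord_buf) {
  const int m = static_cast<int>(xv.size());
  SurrogateEval best{false, 0.0, 0.0, false};
  const int n_right = m - n_left;
  const int maj_n = std::max(n_left, n_right);
  if (maj_n == m || m < 2) return best;  // degenerate primary: no surrogates
  ord_buf.resize(m);
  for (int i = 0; i < m; ++i) ord_buf[i] = i;
  std::sort(ord_buf.begin(), ord_buf.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });
  int best_agree = -1;
  int lt = 0;  // primary-left samples among the first t sorted samples
  for (int i = 0; i < m - 1; ++i) {
    lt += is_left[ord_buf[i]];
    double xlo = xv[ord_buf[i]], xhi = xv[ord_buf[i + 1]];
    if (xhi <= xlo) continue;
    int t = i + 1;
    int agree_normal = 2 * lt - t + n_right;
    int agree_flip = m - agree_normal;
    // direction preference at equal agreement: normal before flip;
    // ascending scan keeps the lowest qualifying threshold
    if (agree_normal > best_agree) {
      best_agree = agree_normal;
      best.thr = xlo + (xhi - xlo) / 2.0;
      best.flip = false;
    }
    if (agree_flip > best_agree) {
      best_agree = agree_flip;
      best.thr = xlo + (xhi - xlo) / 2.0;
      best.flip = true;
    }
  }
  if (best_agree < 0) return best;
  double maj = static_cast<double>(maj_n) / m;
  double a = static_cast<double>(best_agree) / m;
  best.adj = (a - maj) / (1.0 - maj);
  best.valid = true;
  return best;
}

struct TreeBuffers {
  std::vector<double> xv;
  std::vector<int> yv, is_left, ord;
};

struct Tree {
  std::vector<int> feat;        // -1 for leaves
  std::vector<double> thr;
  std::vector<int> left, right; // -1 for leaves (0-based node ids)
  std::vector<int> depth, nnode;
  std::vector<int> counts;      // nclass per node, row-major by node
  std::vector<int> surr_node, surr_feat, surr_flip;
  std::vector<double> surr_thr, surr_adj;
  int max_depth = 0;
};

struct NodeTask {
  int id, start, end, depth;
};

void grow_tree(const NumericMatrix& x, const IntegerVector& y, int nclass,
               const std::vector<double>& cumw, int mtry, int min_node_size,
               int n_surr, bool air, const std::vector<int>& perm,
               std::mt19937_64& rng, Tree& tree,
               std::vector<int>& inbag_count, std::vector<double>& imp_actual,
               std::vector<double>& imp_shadow, TreeBuffers& buf) {
  const int n = x.nrow(), p = x.ncol();
  // weighted bootstrap of size n
  std::vector<int> idx(n);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const double wtot = cumw.back();
  for (int i = 0; i < n; ++i) {
    double u = unif(rng) * wtot;
    int j = static_cast<int>(
        std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
    if (j >= n) j = n - 1;
    idx[i] = j;
    inbag_count[j]++;
  }

  // AIR: a forest-level row permutation defines the pseudo copies, so the
  // pseudo features behave like fixed additional noise variables across
  // trees, exactly mirroring the persistence of the actual features'
  // sampling noise
  const int pool_p = air ? 2 * p : p;
  auto value = [&](int sample, int j) -> double {
    return j < p ? x(sample, j) : x(perm[sample], j - p);
  };

  std::vector<int> feat_pool(pool_p);
  std::vector<NodeTask> stack;
  auto new_node = [&](int start, int end, int depth) -> int {
    int id = static_cast<int>(tree.feat.size());
    tree.feat.push_back(-1);
    tree.thr.push_back(NA_REAL);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.depth.push_back(depth);
    tree.nnode.push_back(end - start);
    std::vector<int> cnt(nclass, 0);
    for (int i = start; i < end; ++i) cnt[y[idx[i]]]++;
    tree.counts.insert(tree.counts.end(), cnt.begin(), cnt.end());
    if (depth > tree.max_depth) tree.max_depth = depth;
    return id;
  };

  new_node(0, n, 0);
  stack.push_back({0, 0, n, 0});
  const int min_split = std::max(2, min_node_size);

  while (!stack.empty()) {
    NodeTask task = stack.back();
    stack.pop_back();
    const int m = task.end - task.start;
    std::vector<int> cnt(nclass, 0);
    for (int i = task.start; i < task.end; ++i) cnt[y[idx[i]]]++;
    int n_present = 0;
    for (int c = 0; c < nclass; ++c) n_present += (cnt[c] > 0);
    if (m < min_split || n_present < 2) continue;  // leaf
    double parent_gini = gini_from_counts(cnt, m);

    // draw mtry candidates without replacement from the (augmented) pool
    for (int j = 0; j < pool_p; ++j) feat_pool[j] = j;
    int ndraw = std::min(mtry, pool_p);
    for (int d = 0; d < ndraw; ++d) {
      std::uniform_int_distribution<int> pick(d, pool_p - 1);
      std::swap(feat_pool[d], feat_pool[pick(rng)]);
    }

    buf.yv.resize(m);
    for (int i = 0; i < m; ++i) buf.yv[i] = y[idx[task.start + i]];

    bool found = false;
    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    for (int d = 0; d < ndraw; ++d) {
      int j = feat_pool[d];
      buf.xv.resize(m);
      for (int i = 0; i < m; ++i) buf.xv[i] = value(idx[task.start + i], j);
      ThresholdEval ev = best_threshold(buf.xv, buf.yv, nclass, parent_gini,
                                        buf.ord);
      if (!ev.valid) continue;
      // gain ties are frequent at small nodes; keeping the first candidate
      // in the random draw order makes the winner uniform among tied
      // candidates (still reproducible from the seed).  An index rule here
      // would systematically favor low columns, biasing AIR's pseudo-copy
      // accounting and the SMD null-copy calibration.
      if (!found || ev.gain > best_gain) {
        found = true;
        best_gain = ev.gain;
        best_feat = j;
        best_thr = ev.thr;
      }
    }
    if (!found) continue;  // all candidates constant: leaf

    // importance credit: actual vs pseudo-copy account
    double w = static_cast<double>(m) / n;
    if (best_feat < p)
      imp_actual[best_feat] += w * best_gain;
    else
      imp_shadow[best_feat - p] += w * best_gain;

    int mid = static_cast<int>(
        std::partition(idx.begin() + task.start, idx.begin() + task.end,
                       [&](int s) { return value(s, best_feat) <= best_thr; }) -
        idx.begin());
    if (mid == task.start || mid == task.end) continue;  // numeric guard

    tree.feat[task.id] = best_feat;
    tree.thr[task.id] = best_thr;

    // surrogate splits over all other features
    if (n_surr > 0) {
      buf.is_left.resize(m);
      int n_left = 0;
      for (int i = 0; i < m; ++i) {
        int s = idx[task.start + i];
        buf.is_left[i] = (value(s, best_feat) <= best_thr) ? 1 : 0;
        n_left += buf.is_left[i];
      }
      std::vector<int> sf;
      std::vector<double> sa, st, skey;
      std::vector<int> sflip;
      sf.reserve(p);
      std::uniform_real_distribution<double> ukey(0.0, 1.0);
      for (int j = 0; j < p; ++j) {
        if (j == best_feat) continue;
        buf.xv.resize(m);
        for (int i = 0; i < m; ++i) buf.xv[i] = x(idx[task.start + i], j);
        SurrogateEval sv = best_surrogate(buf.xv, buf.is_left, n_left, buf.ord);
        if (sv.valid && sv.adj > 0) {
          sf.push_back(j);
          sa.push_back(sv.adj);
          st.push_back(sv.thr);
          sflip.push_back(sv.flip ? 1 : 0);
          // ties in adjusted agreement are frequent at small nodes; a
          // random key keeps the stored top-s list unbiased w.r.t. column
          // position (an index rule would systematically favor low columns)
          skey.push_back(ukey(rng));
        }
      }
      std::vector<int> ordr(sf.size());
      for (size_t i = 0; i < ordr.size(); ++i) ordr[i] = static_cast<int>(i);
      std::sort(ordr.begin(), ordr.end(), [&](int a, int b) {
        if (sa[a] != sa[b]) return sa[a] > sa[b];
        return skey[a] < skey[b];
      });
      int keep = std::min<int>(n_surr, static_cast<int>(ordr.size()));
      for (int r = 0; r < keep; ++r) {
        int i = ordr[r];
        tree.surr_node.push_back(task.id);
        tree.surr_feat.push_back(sf[i]);
        tree.surr_thr.push_back(st[i]);
        tree.surr_flip.push_back(sflip[i]);
        tree.surr_adj.push_back(sa[i]);
      }
    }

    int left_id = new_node(task.start, mid, task.depth + 1);
    int right_id = new_node(mid, task.end, task.depth + 1);
    tree.left[task.id] = left_id;
    tree.right[task.id] = right_id;
    stack.push_back({right_id, mid, task.end, task.depth + 1});
    stack.push_back({left_id, task.start, mid, task.depth + 1});
  }
}

List tree_to_list(const Tree& tree, int nclass) {
  int nn = static_cast<int>(tree.feat.size());
  IntegerMatrix counts(nn, nclass);
  for (int i = 0; i < nn; ++i)
    for (int c = 0; c < nclass; ++c) counts(i, c) = tree.counts[i * nclass + c];
  return List::create(
      _["feature"] = IntegerVector(tree.feat.begin(), tree.feat.end()),
      _["threshold"] = NumericVector(tree.thr.begin(), tree.thr.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["depth"] = IntegerVector(tree.depth.begin(), tree.depth.end()),
      _["n_node"] = IntegerVector(tree.nnode.begin(), tree.nnode.end()),
      _["counts"] = counts,
      _["max_depth"] = tree.max_depth,
      _["surr_node"] = IntegerVector(tree.surr_node.begin(), tree.surr_node.end()),
      _["surr_feature"] = IntegerVector(tree.surr_feat.begin(), tree.surr_feat.end()),
      _["surr_threshold"] = NumericVector(tree.surr_thr.begin(), tree.surr_thr.end()),
      _["surr_flip"] = IntegerVector(tree.surr_flip.begin(), tree.surr_flip.end()),
      _["surr_adj"] = NumericVector(tree.surr_adj.begin(), tree.surr_adj.end()));
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix x, IntegerVector y, int nclass,
                    NumericVector case_weights, int ntree, int mtry,
                    int min_node_size, int n_surrogates, bool air,
                    double seed) {
  const int n = x.nrow(), p = x.ncol();
  std::vector<double> cumw(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += case_weights[i];
    cumw[i] = acc;
  }
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  std::vector<double> imp_actual(p, 0.0), imp_shadow(p, 0.0);
  TreeBuffers buf;
  uint64_t base = static_cast<uint64_t>(seed);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  if (air) {
    std::mt19937_64 rng_perm(splitmix64(base ^ 0xA5A5A5A5A5A5A5A5ULL));
    std::shuffle(perm.begin(), perm.end(), rng_perm);
  }
  for (int t = 0; t < ntree; ++t) {
    std::mt19937_64 rng(splitmix64(base ^ splitmix64(static_cast<uint64_t>(t) + 1)));
    Tree tree;
    std::vector<int> ib(n, 0);
    grow_tree(x, y, nclass, cumw, mtry, min_node_size, n_surrogates, air, perm,
              rng, tree, ib, imp_actual, imp_shadow, buf);
    trees[t] = tree_to_list(tree, nclass);
    for (int i = 0; i < n; ++i) inbag(i, t) = ib[i];
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag,
                      _["importance_actual"] =
                          NumericVector(imp_actual.begin(), imp_actual.end()),
                      _["importance_shadow"] =
                          NumericVector(imp_shadow.begin(), imp_shadow.end()));
}

// Best split at a single node; candidates are 1-based feature ids.
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix x, IntegerVector y, int nclass,
                    IntegerVector candidates) {
  const int m = x.nrow();
  std::vector<int> yv(m), ord;
  std::vector<int> cnt(nclass, 0);
  for (int i = 0; i < m; ++i) {
    yv[i] = y[i];
    cnt[y[i]]++;
  }
  double parent_gini = gini_from_counts(cnt, m);
  std::vector<double> xv(m);
  bool found = false;
  double bg = 0.0, bt = 0.0;
  int bf = -1;
  for (int k = 0; k < candidates.size(); ++k) {
    int j = candidates[k] - 1;
    for (int i = 0; i < m; ++i) xv[i] = x(i, j);
    ThresholdEval ev = best_threshold(xv, yv, nclass, parent_gini, ord);
    if (ev.valid &&
        (!found || ev.gain > bg || (ev.gain == bg && j < bf) ||
         (ev.gain == bg && j == bf && ev.thr < bt))) {
      found = true;
      bg = ev.gain;
      bf = j;
      bt = ev.thr;
    }
  }
  return List::create(_["found"] = found, _["feature"] = bf + 1,
                      _["threshold"] = bt, _["decrease"] = bg);
}

// Surrogate search at a single node. is_left gives the primary assignment.
// primary_feature (1-based) is excluded; pass 0 to consider all features.
// [[Rcpp::export]]
DataFrame cpp_find_surrogates(NumericMatrix x, IntegerVector is_left,
                              int primary_feature, int s) {
  const int m = x.nrow(), p = x.ncol();
  int n_left = 0;
  std::vector<int> il(m);
  for (int i = 0; i < m; ++i) {
    il[i] = is_left[i];
    n_left += il[i];
  }
  std::vector<double> xv(m);
  std::vector<int> ord;
  std::vector<int> sf, sflip;
  std::vector<double> sa, st;
  for (int j = 0; j < p; ++j) {
    if (j == primary_feature - 1) continue;
    for (int i = 0; i < m; ++i) xv[i] = x(i, j);
    SurrogateEval sv = best_surrogate(xv, il, n_left, ord);
    if (sv.valid && sv.adj > 0) {
      sf.push_back(j + 1);
      sa.push_back(sv.adj);
      st.push_back(sv.thr);
      sflip.push_back(sv.flip ? 1 : 0);
    }
  }
  std::vector<int> ordr(sf.size());
  for (size_t i = 0; i < ordr.size(); ++i) ordr[i] = static_cast<int>(i);
  std::sort(ordr.begin(), ordr.end(), [&](int a, int b) {
    if (sa[a] != sa[b]) return sa[a] > sa[b];
    return sf[a] < sf[b];
  });
  int keep = std::min<int>(s, static_cast<int>(ordr.size()));
  IntegerVector of(keep), ofl(keep);
  NumericVector ot(keep), oa(keep);
  for (int r = 0; r < keep; ++r) {
    of[r] = sf[ordr[r]];
    ot[r] = st[ordr[r]];
    ofl[r] = sflip[ordr[r]];
    oa[r] = sa[ordr[r]];
  }
  return DataFrame::create(_["feature"] = of, _["threshold"] = ot,
                           _["flip"] = ofl, _["adjusted_agreement"] = oa);
}

// Leaf node id (1-based) for every sample in every tree.
// [[Rcpp::export]]
IntegerMatrix cpp_leaf_ids(List trees, NumericMatrix x) {
  const int n = x.nrow();
  const int ntree = trees.size();
  IntegerMatrix out(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (x(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      }
      out(i, t) = node + 1;
    }
  }
  return out;
}

// Surrogate minimal depth: per tree, a feature's depth is the minimum over
// nodes where it splits or appears as a surrogate; absent features take the
// tree's maximal node depth.  Returns the mean over trees.
// [[Rcpp::export]]
NumericVector cpp_smd(List trees, int p) {
  const int ntree = trees.size();
  std::vector<double> total(p, 0.0);
  std::vector<int> md(p);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"], depth = tr["depth"];
    IntegerVector snode = tr["surr_node"], sfeat = tr["surr_feature"];
    int maxd = as<int>(tr["max_depth"]);
    std::fill(md.begin(), md.end(), maxd);
    for (int i = 0; i < feat.size(); ++i)
      if (feat[i] >= 0 && depth[i] < md[feat[i]]) md[feat[i]] = depth[i];
    for (int i = 0; i < sfeat.size(); ++i) {
      int d = depth[snode[i]];
      if (d < md[sfeat[i]]) md[sfeat[i]] = d;
    }
    for (int j = 0; j < p; ++j) total[j] += md[j];
  }
  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = total[j] / ntree;
  return out;
}

// Mean adjusted agreement: M[i, j] = mean over all nodes (forest-wide)
// where j is the primary splitter of i's recorded adjusted agreement
// (0 when i is not among the node's stored surrogates).
// [[Rcpp::export]]
List cpp_maa(List trees, int p) {
  NumericMatrix M(p, p);
  std::vector<double> cnt(p, 0.0);
  const int ntree = trees.size();
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"];
    IntegerVector snode = tr["surr_node"], sfeat = tr["surr_feature"];
    NumericVector sadj = tr["surr_adj"];
    for (int i = 0; i < feat.size(); ++i)
      if (feat[i] >= 0) cnt[feat[i]] += 1.0;
    for (int i = 0; i < sfeat.size(); ++i) {
      int primary = feat[snode[i]];
      M(sfeat[i], primary) += sadj[i];
    }
  }
  for (int j = 0; j < p; ++j) {
    if (cnt[j] > 0) {
      for (int i = 0; i < p; ++i) M(i, j) /= cnt[j];
    }
  }
  return List::create(_["relation"] = M,
                      _["primary_node_count"] =
                          NumericVector(cnt.begin(), cnt.end()));
}
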