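#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Order-preserving one-to-one alignment of two sorted energy lists,
// maximizing the number of matched pairs (|dE| <= gate) and, among those,
// minimizing the summed |dE|. The two objective components are tracked
// separately (lexicographic comparison) to keep the distances exact.
struct AlignCell { int k; double s; };

static inline bool cell_better(const AlignCell& x, const AlignCell& y) {
  return x.k > y.k || (x.k == y.k && x.s < y.s);
}

static AlignCell align_dp(const double* a, int ma, const double* b, int mb,
                          double gate, std::vector<AlignCell>& dp) {
  // dp is (ma+1) x (mb+1) row-major scratch
  const int W = mb + 1;
  for (int j = 0; j <= mb; ++j) dp[j] = {0, 0.0};
  for (int i = 1; i <= ma; ++i) {
    dp[i * W] = {0, 0.0};
    for (int j = 1; j <= mb; ++j) {
      AlignCell best = dp[(i - 1) * W + j];
      if (cell_better(dp[i * W + j - 1], best)) best = dp[i * W + j - 1];
      double d = std::fabs(a[i - 1] - b[j - 1]);
      if (d <= gate) {
        AlignCell v = dp[(i - 1) * W + j - 1];
        v.k += 1; v.s += d;
        if (cell_better(v, best)) best = v;
      }
      dp[i * W + j] = best;
    }
  }
  return dp[ma * W + mb];
}

// Single-pair alignment with traceback; returns matched index pairs (1-based).
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(NumericVector a, NumericVector b, double gate) {
  const int ma = a.size(), mb = b.size();
  std::vector<AlignCell> dp((ma + 1) * (mb + 1));
  AlignCell v = align_dp(a.begin(), ma, b.begin(), mb, gate, dp);
  const int W = mb + 1;
  // traceback
  std::vector<int> ia, ib;
  int i = ma, j = mb;
  while (i > 0 && j > 0) {
    AlignCell cur = dp[i * W + j];
    double d = std::fabs(a[i - 1] - b[j - 1]);
    AlignCell diag = dp[(i - 1) * W + j - 1];
    if (d <= gate && diag.k + 1 == cur.k && diag.s + d == cur.s) {
      ia.push_back(i); ib.push_back(j); --i; --j;
    } else if (dp[(i - 1) * W + j].k == cur.k &&
               dp[(i - 1) * W + j].s == cur.s) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["k"] = v.k, _["sum_abs_de"] = v.s,
                      _["i"] = wrap(ia), _["j"] = wrap(ib));
}

// Batch scoring of candidate barcode pairs between two pools.
// Pools are concatenated per-cell-sorted energies (en) with 0-based offsets
// (off, length n_cells + 1). Candidates are pairs sharing at least one line
// within the gate, found through a globally sorted line index of pool 2.
// If self = true the pools are the same object and only pairs i < j are
// scored. All candidate scores (k >= min_k) are returned; pairs with score
// >= detail_min additionally get (i, j, k, mean|dE|) rows.
// [[Rcpp::export(name = ".score_pools_cpp")]]
List score_pools_cpp(IntegerVector off1, NumericVector en1,
                     IntegerVector off2, NumericVector en2,
                     double gate, double gap_penalty, int min_k,
                     bool self, double detail_min) {
  const int n1 = off1.size() - 1, n2 = off2.size() - 1;
  // global line index of pool 2
  const int L2 = en2.size();
  std::vector<double> le(L2);
  std::vector<int> lc(L2);
  {
    std::vector<int> ord(L2);
    for (int c = 0; c < n2; ++c)
      for (int t = off2[c]; t < off2[c + 1]; ++t) lc[t] = c;
    for (int t = 0; t < L2; ++t) { ord[t] = t; }
    std::sort(ord.begin(), ord.end(), [&](int x, int y) {
      return en2[x] < en2[y];
    });
    std::vector<int> lc2(L2);
    for (int t = 0; t < L2; ++t) { le[t] = en2[ord[t]]; lc2[t] = lc[ord[t]]; }
    lc = lc2;
  }
  std::vector<int> stamp(n2, -1);
  std::vector<int> cand;
  int max_m = 0;
  for (int c = 0; c < n1; ++c) max_m = std::max(max_m, off1[c + 1] - off1[c]);
  for (int c = 0; c < n2; ++c) max_m = std::max(max_m, off2[c + 1] - off2[c]);
  std::vector<AlignCell> dp((max_m + 1) * (max_m + 1));

  std::vector<double> scores;
  std::vector<int> di, dj, dk;
  std::vector<double> dmean;

  for (int i = 0; i < n1; ++i) {
    const int a0 = off1[i], ma = off1[i + 1] - a0;
    if (ma == 0) continue;
    cand.clear();
    for (int t = a0; t < a0 + ma; ++t) {
      double e = en1[t];
      int lo = (int)(std::lower_bound(le.begin(), le.end(), e - gate) -
                     le.begin());
      int hi = (int)(std::upper_bound(le.begin(), le.end(), e + gate) -
                     le.begin());
      for (int u = lo; u < hi; ++u) {
        int j = lc[u];
        if (self && j <= i) continue;
        if (stamp[j] != i) { stamp[j] = i; cand.push_back(j); }
      }
    }
    for (size_t q = 0; q < cand.size(); ++q) {
      int j = cand[q];
      const int b0 = off2[j], mb = off2[j + 1] - b0;
      if (mb == 0) continue;
      AlignCell v = align_dp(&en1[a0], ma, &en2[b0], mb, gate, dp);
      int k = v.k;
      if (k < min_k) continue;
      double sumde = v.s;
      double s = k - sumde / gate - gap_penalty * (ma + mb - 2 * k);
      scores.push_back(s);
      if (s >= detail_min) {
        di.push_back(i + 1); dj.push_back(j + 1); dk.push_back(k);
        dmean.push_back(k > 0 ? sumde / k : 0.0);
      }
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["scores"] = wrap(scores), _["i"] = wrap(di),
                      _["j"] = wrap(dj), _["k"] = wrap(dk),
                      _["mean_abs_de"] = wrap(dmean));
}
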