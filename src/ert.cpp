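#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// Extremely randomized trees for regression on a sparse count matrix.
//
// Split semantics are canonical: no bootstrap, exactly `mtry` candidate
// features drawn without replacement per node, one uniform random threshold
// in the node's [min, max) value range per usable (non-constant) candidate,
// the candidate with the largest variance reduction wins, and nodes below
// min_split samples (or with zero target variance) become leaves predicting
// the node mean. Feature importance is mean decrease in impurity
// (variance) weighted by the fraction of samples reaching the node,
// normalized per tree and averaged over trees.
//
// The engine is built for very wide sparse count data (~175k k-mer columns,
// ~15 nonzeros each). Candidate evaluation works on per-column value
// histograms (distinct value, member count, member target sum): thresholds
// and split gains only need those aggregates, never the member rows. Trees
// grown on such data are chain-shaped (each split chips a small group off a
// large node), so the surviving large node's histogram is maintained by
// decrementing the chipped members' entries in place; the node is re-rooted
// (histogram rebuilt) once it has shrunk to half the size the histogram was
// built for, and split-off small children are queued and processed with
// their own freshly built histograms. This bounds total build work by
// O(nnz * log n) plus one aggregate scan per node. A candidate whose node
// slice holds one distinct positive value (the common case) splits
// zeros-vs-nonzeros under every admissible threshold, so its gain is
// computed without consuming a threshold draw; the winning split's
// threshold is drawn when it is recorded.

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    threshold.push_back(0.0); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct HEntry { double val; double sumy; long long cnt; };

static inline int rng_below(std::mt19937 &g, uint32_t range) {
  return (int)(((uint64_t)g() * range) >> 32);
}
static inline double rng_real(std::mt19937 &g) {
  return g() * (1.0 / 4294967296.0);
}

struct WorkItem {
  std::vector<int> members;
  int node_id;
  double sum, sumsq;
};

// [[Rcpp::export]]
List ert_fit_cpp(IntegerVector Rp, IntegerVector Ri, NumericVector Rx,
                 IntegerVector Cp, IntegerVector Ci, NumericVector Cx,
                 int n, int pfeat, NumericVector y,
                 int ntrees, double max_features, int min_split,
                 int seed) {
  int mtry = std::max(1, (int)std::ceil(max_features * pfeat));
  int total_nnz = Rx.size();
  NumericVector importance(pfeat);
  std::vector<double> tree_imp(pfeat);
  List trees(ntrees);

  // --- root histogram template (rebuilt by copy for every tree) ----------
  std::vector<int> h0_cols, h0_start(pfeat, 0), h0_len(pfeat, 0);
  std::vector<HEntry> h0;
  h0.reserve(total_nnz / 4);
  for (int j = 0; j < pfeat; ++j) {
    int a = Cp[j], b = Cp[j + 1];
    if (a == b) continue;
    h0_cols.push_back(j);
    int s = h0.size();
    h0_start[j] = s;
    for (int k = a; k < b; ++k) {
      double v = Cx[k], yy = y[Ci[k]];
      int e = s, end = h0.size();
      while (e < end && h0[e].val != v) ++e;
      if (e == end) h0.push_back({v, yy, 1});
      else { h0[e].cnt += 1; h0[e].sumy += yy; }
    }
    h0_len[j] = h0.size() - s;
  }

  // --- per-activation scratch --------------------------------------------
  // Candidate sets are exact uniform mtry-subsets drawn as a bitmask:
  // start from iid fair bits (or the empty/full mask when mtry is far from
  // p/2) and add/remove uniformly random bits until the count is exact.
  // Conditioned on its size a fair-bit mask is uniform, and uniform
  // correction preserves uniformity, so the result matches feature
  // subsampling without replacement while staying cache-resident.
  int mwords = (pfeat + 63) / 64;
  std::vector<uint64_t> cmask(mwords);
  auto draw_candidates = [&](std::mt19937 &rng) {
    if (mtry >= pfeat) {
      std::fill(cmask.begin(), cmask.end(), ~uint64_t(0));
      return;
    }
    int count;
    if (4 * mtry <= pfeat) {
      std::fill(cmask.begin(), cmask.end(), uint64_t(0));
      count = 0;
    } else if (4 * (pfeat - mtry) <= pfeat) {
      std::fill(cmask.begin(), cmask.end(), ~uint64_t(0));
      if (pfeat & 63) cmask[mwords - 1] = (~uint64_t(0)) >> (64 - (pfeat & 63));
      count = pfeat;
    } else {
      count = 0;
      for (int w = 0; w < mwords; ++w) {
        uint64_t bits = ((uint64_t)rng() << 32) | rng();
        if (w == mwords - 1 && (pfeat & 63))
          bits &= (~uint64_t(0)) >> (64 - (pfeat & 63));
        cmask[w] = bits;
        count += __builtin_popcountll(bits);
      }
    }
    while (count > mtry) {
      int j = rng_below(rng, pfeat);
      uint64_t bit = uint64_t(1) << (j & 63);
      if (cmask[j >> 6] & bit) { cmask[j >> 6] &= ~bit; --count; }
    }
    while (count < mtry) {
      int j = rng_below(rng, pfeat);
      uint64_t bit = uint64_t(1) << (j & 63);
      if (!(cmask[j >> 6] & bit)) { cmask[j >> 6] |= bit; ++count; }
    }
  };
  std::vector<int> s_cols, s_start(pfeat, 0), s_len(pfeat, 0),
                   s_epoch(pfeat, 0), s_cap(pfeat, 0);
  std::vector<HEntry> hbuf(std::max((size_t)total_nnz, h0.size()));
  std::vector<int> in_node(n, 0);
  std::vector<double> colval(n, 0.0);
  std::vector<int> left_buf, right_buf;
  int hist_stamp = 0, node_stamp = 0;

  for (int t = 0; t < ntrees; ++t) {
    std::mt19937 rng((unsigned)seed + 0x9E3779B9u * (unsigned)(t + 1));
    std::fill(tree_imp.begin(), tree_imp.end(), 0.0);
    TreeBuf tb;

    std::vector<WorkItem> work;
    {
      WorkItem root;
      root.members.resize(n);
      double s = 0, ss = 0;
      for (int i = 0; i < n; ++i) { root.members[i] = i; s += y[i]; ss += y[i] * y[i]; }
      root.node_id = tb.add_node();
      root.sum = s; root.sumsq = ss;
      work.push_back(std::move(root));
    }
    bool first_item = true;

    while (!work.empty()) {
      WorkItem it = std::move(work.back()); work.pop_back();
      bool use_root = first_item && (int)it.members.size() == n;
      first_item = false;

      // activate: copy (root) or build the members' histogram into hbuf
      const int *cols; int ncols;
      const int *hstart, *hlen;
      HEntry *H = hbuf.data();
      if (use_root) {
        std::memcpy(H, h0.data(), h0.size() * sizeof(HEntry));
        cols = h0_cols.data(); ncols = h0_cols.size();
        hstart = h0_start.data(); hlen = h0_len.data();
      } else {
        ++hist_stamp;
        s_cols.clear();
        for (int r : it.members)
          for (int k = Rp[r]; k < Rp[r + 1]; ++k) {
            int j = Ri[k];
            if (s_epoch[j] != hist_stamp) {
              s_epoch[j] = hist_stamp; s_cap[j] = 0; s_cols.push_back(j);
            }
            ++s_cap[j];
          }
        int pos = 0;
        for (int j : s_cols) { s_start[j] = pos; s_len[j] = 0; pos += s_cap[j]; }
        for (int r : it.members) {
          double yy = y[r];
          for (int k = Rp[r]; k < Rp[r + 1]; ++k) {
            int j = Ri[k];
            double v = Rx[k];
            int s0 = s_start[j], e = s0, end = s0 + s_len[j];
            while (e < end && H[e].val != v) ++e;
            if (e == end) { H[e] = {v, yy, 1}; ++s_len[j]; }
            else { H[e].cnt += 1; H[e].sumy += yy; }
          }
        }
        cols = s_cols.data(); ncols = s_cols.size();
        hstart = s_start.data(); hlen = s_len.data();
      }
      ++node_stamp;
      for (int r : it.members) in_node[r] = node_stamp;
      int hist_nn = it.members.size();

      // grow the chain: keep splitting the larger side in place
      while (true) {
        int nn = it.members.size();
        double mean = it.sum / nn;
        double ssdev = it.sumsq - it.sum * mean;
        tb.value[it.node_id] = mean;
        if (nn < min_split || ssdev <= 1e-12) break;

        draw_candidates(rng);

        int best_j = -1; double best_u = 0, best_gain = -1;
        double best_vmin = 0, best_vmax = 0; bool best_drawn = false;
        for (int ci = 0; ci < ncols; ++ci) {
          int j = cols[ci];
          if (!((cmask[j >> 6] >> (j & 63)) & 1)) continue;
          int s0 = hstart[j], e1 = s0 + hlen[j];
          double sum_r; long long n_r; double u = 0; bool drawn;
          double vmin, vmax;
          if (e1 - s0 == 1) {
            long long c = H[s0].cnt;
            if (c <= 0 || c == nn) continue;   // constant in node
            n_r = c; sum_r = H[s0].sumy;
            vmin = 0; vmax = H[s0].val; drawn = false;
          } else {
            vmin = R_PosInf; vmax = R_NegInf;
            long long nonzero = 0;
            for (int e = s0; e < e1; ++e) {
              if (H[e].cnt <= 0) continue;
              nonzero += H[e].cnt;
              if (H[e].val < vmin) vmin = H[e].val;
              if (H[e].val > vmax) vmax = H[e].val;
            }
            if (nonzero == 0) continue;        // constant zero in node
            long long zeros = nn - nonzero;
            if (zeros > 0) { if (vmin > 0) vmin = 0; if (vmax < 0) vmax = 0; }
            if (vmax <= vmin) continue;        // constant in node
            u = vmin + (vmax - vmin) * rng_real(rng);
            drawn = true;
            sum_r = 0; n_r = 0;
            for (int e = s0; e < e1; ++e)
              if (H[e].cnt > 0 && H[e].val > u) { sum_r += H[e].sumy; n_r += H[e].cnt; }
          }
          long long n_l = nn - n_r;
          if (n_l == 0 || n_r == 0) continue;
          double sum_l = it.sum - sum_r;
          double gain = sum_l * sum_l / n_l + sum_r * sum_r / n_r;
          if (gain > best_gain) {
            best_gain = gain; best_j = j; best_u = u;
            best_vmin = vmin; best_vmax = vmax; best_drawn = drawn;
          }
        }
        if (best_j < 0) break;  // leaf
        if (!best_drawn)
          best_u = best_vmin + (best_vmax - best_vmin) * rng_real(rng);

        // partition members on the winning feature via its global column
        for (int k = Cp[best_j]; k < Cp[best_j + 1]; ++k)
          if (in_node[Ci[k]] == node_stamp) colval[Ci[k]] = Cx[k];
        left_buf.clear(); right_buf.clear();
        double sum_l = 0, ss_l = 0;
        for (int r : it.members) {
          if (colval[r] <= best_u) {
            left_buf.push_back(r); sum_l += y[r]; ss_l += y[r] * y[r];
          } else right_buf.push_back(r);
        }
        for (int k = Cp[best_j]; k < Cp[best_j + 1]; ++k)
          colval[Ci[k]] = 0.0;
        int n_l = left_buf.size(), n_r = right_buf.size();
        if (n_l == 0 || n_r == 0) break;       // numeric guard
        double sum_r = it.sum - sum_l, ss_r = it.sumsq - ss_l;
        double ssdev_l = ss_l - sum_l * sum_l / n_l;
        double ssdev_r = ss_r - sum_r * sum_r / n_r;
        double decrease = (ssdev - ssdev_l - ssdev_r) / n;
        if (decrease > 0) tree_imp[best_j] += decrease;

        int lid = tb.add_node(), rid = tb.add_node();
        tb.feature[it.node_id] = best_j;
        tb.threshold[it.node_id] = best_u;
        tb.left[it.node_id] = lid; tb.right[it.node_id] = rid;

        bool left_small = n_l <= n_r;
        std::vector<int> &small = left_small ? left_buf : right_buf;
        std::vector<int> &large = left_small ? right_buf : left_buf;

        WorkItem sub;
        sub.members.assign(small.begin(), small.end());
        sub.node_id = left_small ? lid : rid;
        sub.sum = left_small ? sum_l : sum_r;
        sub.sumsq = left_small ? ss_l : ss_r;
        tb.value[sub.node_id] = sub.sum / sub.members.size();
        work.push_back(std::move(sub));

        // decrement the chipped members out of the histogram
        for (int r : small) {
          in_node[r] = 0;
          double yy = y[r];
          for (int k = Rp[r]; k < Rp[r + 1]; ++k) {
            int j = Ri[k];
            double v = Rx[k];
            int e = hstart[j];
            while (H[e].val != v) ++e;
            H[e].cnt -= 1; H[e].sumy -= yy;
          }
        }
        it.members.assign(large.begin(), large.end());
        it.node_id = left_small ? rid : lid;
        it.sum = left_small ? sum_r : sum_l;
        it.sumsq = left_small ? ss_r : ss_l;

        if (2 * (int)it.members.size() <= hist_nn) {
          // node has halved: requeue it for a fresh histogram
          tb.value[it.node_id] = it.sum / it.members.size();
          work.push_back(std::move(it));
          break;
        }
      }
    }

    double tot = 0;
    for (int j = 0; j < pfeat; ++j) tot += tree_imp[j];
    if (tot > 0)
      for (int j = 0; j < pfeat; ++j) importance[j] += tree_imp[j] / tot;

    trees[t] = List::create(
      _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["value"] = NumericVector(tb.value.begin(), tb.value.end()));
  }
  for (int j = 0; j < pfeat; ++j) importance[j] /= ntrees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// Predict from a fitted forest. Rows are supplied in the CSR layout used in
// training, so each sample's nonzero features are a sorted slice we can
// binary-search during tree descent.
// [[Rcpp::export]]
NumericVector ert_predict_cpp(List trees,
                              IntegerVector Tp, IntegerVector Ti,
                              NumericVector Tx, int nsamples) {
  int ntrees = trees.size();
  NumericVector out(nsamples);
  for (int t = 0; t < ntrees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int s = 0; s < nsamples; ++s) {
      int lo = Tp[s], hi = Tp[s + 1];
      int node = 0;
      while (feature[node] >= 0) {
        int j = feature[node];
        double v = 0.0;
        int a = lo, b = hi - 1;
        while (a <= b) {
          int m = (a + b) / 2;
          if (Ti[m] < j) a = m + 1;
          else if (Ti[m] > j) b = m - 1;
          else { v = Tx[m]; break; }
        }
        node = (v <= threshold[node]) ? left[node] : right[node];
      }
      out[s] += value[node];
    }
  }
  for (int s = 0; s < nsamples; ++s) out[s] /= ntrees;
  return out;
}
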