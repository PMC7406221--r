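#include <Rcpp.h>
using namespace Rcpp;

// Base-pair type codes shared with the R energy model:
// 0 AT, 1 TA, 2 CG, 3 GC, 4 GT, 5 TG, -1 not a pair (mismatch).
static inline int pair_code(char a, char b) {
  switch (a) {
  case 'A': return b == 'T' ? 0 : -1;
  case 'T': return b == 'A' ? 1 : (b == 'G' ? 5 : -1);
  case 'C': return b == 'G' ? 2 : -1;
  case 'G': return b == 'C' ? 3 : (b == 'T' ? 4 : -1);
  }
  return -1;
}

// Exhaustive stem/loop enumeration over a coding-strand 3' flank.
// start is the 1-based offset of the left arm's first base; it must lie
// within max_dist of the stop codon. Energy = sum of stacking terms over
// consecutive paired positions + loop initiation + mismatch_penalty per
// non-pairing stem position. Hairpins at or below dg_cutoff are reported.
// [[Rcpp::export]]
DataFrame scan_hairpins_cpp(std::string seq,
                            int stem_min, int stem_max,
                            int loop_min, int loop_max,
                            int max_mismatch, int max_dist,
                            double dg_cutoff,
                            NumericMatrix stack6,
                            NumericVector loop_pen,  // index loop_len - loop_min
                            double mismatch_penalty) {
  int n = seq.size();
  std::vector<int> v_start, v_stem, v_loop, v_mm;
  std::vector<double> v_dg;
  std::vector<int> pc(stem_max);
  for (int i0 = 0; i0 < n && i0 < max_dist; ++i0) {
    for (int s = stem_min; s <= stem_max; ++s) {
      for (int l = loop_min; l <= loop_max; ++l) {
        int last = i0 + 2 * s + l;  // one past right arm end (0-based)
        if (last > n) continue;
        int mm = 0;
        bool over = false;
        for (int j = 0; j < s; ++j) {
          pc[j] = pair_code(seq[i0 + j], seq[last - 1 - j]);
          if (pc[j] < 0 && ++mm > max_mismatch) { over = true; break; }
        }
        if (over) continue;
        double dg = loop_pen[l - loop_min] + mismatch_penalty * mm;
        for (int j = 0; j + 1 < s; ++j)
          if (pc[j] >= 0 && pc[j + 1] >= 0)
            dg += stack6(pc[j], pc[j + 1]);
        if (dg <= dg_cutoff) {
          v_start.push_back(i0 + 1);
          v_stem.push_back(s);
          v_loop.push_back(l);
          v_mm.push_back(mm);
          v_dg.push_back(dg);
        }
      }
    }
  }
  return DataFrame::create(
    _["start"] = v_start, _["stem_len"] = v_stem, _["loop_len"] = v_loop,
    _["mismatches"] = v_mm, _["dg"] = v_dg,
    _["stringsAsFactors"] = false);
}
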