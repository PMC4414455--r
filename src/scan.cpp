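// Complementarity scan of a miRNA against transcript windows.
//
// psRNATarget-style expectation scoring: per aligned miRNA position a
// penalty of 0 (Watson-Crick), `wobble` (G:U) or `mismatch`, doubled by
// `seed_mult` within the seed span (miRNA positions seed_start..seed_end,
// 1-based from the 5' end); at most one single-nucleotide bulge on either
// strand, costed `gap` (seed-doubled at its position).
//
// The miRNA binds the transcript antiparallel, so miRNA position k pairs
// with the k-th window base counted from the window's 3' end.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int ptype2(int a, int b) {
  if ((a == 1 && b == 4) || (a == 2 && b == 3) ||
      (a == 3 && b == 2) || (a == 4 && b == 1)) return 1;  // WC
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return 2;  // G:U
  return 0;
}

struct ScanW {
  double mismatch, wobble, gap, seed_mult;
  int seed_start, seed_end;
};

static ScanW read_w(const List &w) {
  ScanW s;
  s.mismatch = as<double>(w["mismatch"]);
  s.wobble = as<double>(w["wobble"]);
  s.gap = as<double>(w["gap"]);
  s.seed_mult = as<double>(w["seed_mult"]);
  s.seed_start = as<int>(w["seed_start"]);
  s.seed_end = as<int>(w["seed_end"]);
  return s;
}

static inline double mult_at(const ScanW &w, int k1based) {
  return (k1based >= w.seed_start && k1based <= w.seed_end) ? w.seed_mult
                                                            : 1.0;
}

static inline double pair_pen(const ScanW &w, int m, int t) {
  int pt = ptype2(m, t);
  if (pt == 1) return 0.0;
  if (pt == 2) return w.wobble;
  return w.mismatch;
}

// best score for miRNA vs a window of length L-1, L or L+1.
// gaptype: 0 none, 1 extra (bulged) target base, 2 bulged miRNA base.
static double score_window(const int *mir, int L, const int *win, int Lp,
                           const ScanW &w, int &gaptype, int &gappos) {
  gaptype = 0; gappos = 0;
  if (Lp == L) {
    double s = 0.0;
    for (int k = 1; k <= L; ++k)
      s += pair_pen(w, mir[k - 1], win[Lp - k]) * mult_at(w, k);
    return s;
  }
  double best = R_PosInf;
  if (Lp == L + 1) {
    for (int g = 1; g <= L - 1; ++g) {
      double s = w.gap * mult_at(w, g + 1);
      for (int k = 1; k <= L; ++k) {
        int idx = (k <= g) ? k : k + 1;  // from the window 3' end
        s += pair_pen(w, mir[k - 1], win[Lp - idx]) * mult_at(w, k);
        if (s >= best) break;
      }
      if (s < best) { best = s; gaptype = 1; gappos = g; }
    }
    return best;
  }
  if (Lp == L - 1) {
    for (int g = 2; g <= L - 1; ++g) {
      double s = w.gap * mult_at(w, g);
      for (int k = 1; k <= L; ++k) {
        if (k == g) continue;
        int idx = (k < g) ? k : k - 1;
        s += pair_pen(w, mir[k - 1], win[Lp - idx]) * mult_at(w, k);
        if (s >= best) break;
      }
      if (s < best) { best = s; gaptype = 2; gappos = g; }
    }
    return best;
  }
  return R_PosInf;
}

// [[Rcpp::export]]
List score_window_cpp(IntegerVector mir, IntegerVector win, List weights) {
  ScanW w = read_w(weights);
  int gt, gp;
  std::vector<int> m(mir.begin(), mir.end()), t(win.begin(), win.end());
  double s = score_window(m.data(), m.size(), t.data(), t.size(), w, gt, gp);
  return List::create(_["score"] = s, _["gaptype"] = gt, _["gappos"] = gp);
}

// All windows of a transcript whose best expectation is <= cutoff.
// Returns 0-based window starts.
// [[Rcpp::export]]
DataFrame scan_transcript_cpp(IntegerVector mir, IntegerVector target,
                              List weights, double cutoff) {
  ScanW w = read_w(weights);
  int L = mir.size(), n = target.size();
  std::vector<int> m(mir.begin(), mir.end()), t(target.begin(), target.end());
  std::vector<int> starts, wlens, gts, gps;
  std::vector<double> scores;
  for (int s0 = 0; s0 < n; ++s0) {
    double best = R_PosInf;
    int bl = 0, bgt = 0, bgp = 0;
    for (int Lp = L - 1; Lp <= L + 1; ++Lp) {
      if (Lp < 2 || s0 + Lp > n) continue;
      int gt, gp;
      double sc = score_window(m.data(), L, t.data() + s0, Lp, w, gt, gp);
      if (sc < best - 1e-9) { best = sc; bl = Lp; bgt = gt; bgp = gp; }
    }
    if (best <= cutoff + 1e-9) {
      starts.push_back(s0); wlens.push_back(bl); scores.push_back(best);
      gts.push_back(bgt); gps.push_back(bgp);
    }
  }
  return DataFrame::create(_["start"] = starts, _["wlen"] = wlens,
                           _["score"] = scores, _["gaptype"] = gts,
                           _["gappos"] = gps);
}
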