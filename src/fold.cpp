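// Minimum-free-energy RNA secondary structure prediction.
//
// Zuker-style dynamic program over the nearest-neighbor model supplied by
// energy_params(): V (closed by a pair), WM/WM2 (multiloop segments) and W
// (exterior). Interior/bulge loop size is capped at params$max_loop.
// Ties in energy are broken in favour of the structure with more pairs,
// then the 5'-most pairing, so output is deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;

// pair codes: 1=AU 2=CG 3=GC 4=UA 5=GU 6=UG (bases A=1 C=2 G=3 U=4)
static inline int ptype(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 4 && b == 1) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

struct EP {
  NumericMatrix stack;
  NumericVector hairpin, bulge, interior;
  double ml_close, ml_unpaired, ml_branch;
  int min_hairpin, max_loop;
};

// true when (e1,p1) is strictly better than (e2,p2)
static inline bool better(double e1, int p1, double e2, int p2) {
  if (e1 < e2 - EPS) return true;
  if (std::fabs(e1 - e2) <= EPS && p1 > p2) return true;
  return false;
}

class Folder {
public:
  int n;
  std::vector<int> c;  // base codes, 0-based
  EP ep;
  std::vector<double> V, WM, WM2;
  std::vector<int> Vp, WMp, WM2p;
  std::vector<double> W;
  std::vector<int> Wp;
  std::vector<int> pairtab;  // result: partner index or -1

  Folder(const IntegerVector &codes, const EP &ep_) : ep(ep_) {
    n = codes.size();
    c.resize(n);
    for (int i = 0; i < n; ++i) c[i] = codes[i];
    V.assign((size_t)n * n, INF); Vp.assign((size_t)n * n, 0);
    WM.assign((size_t)n * n, INF); WMp.assign((size_t)n * n, 0);
    WM2.assign((size_t)n * n, INF); WM2p.assign((size_t)n * n, 0);
    W.assign(n + 1, 0.0); Wp.assign(n + 1, 0);
    pairtab.assign(n, -1);
  }

  inline size_t ix(int i, int j) const { return (size_t)i * n + j; }

  inline double loop_cost(int i, int j, int k, int l) const {
    int l1 = k - i - 1, l2 = j - l - 1;
    if (l1 + l2 > ep.max_loop) return INF;
    if (l1 == 0 && l2 == 0)
      return ep.stack(ptype(c[i], c[j]) - 1, ptype(c[k], c[l]) - 1);
    if (l1 == 0 || l2 == 0) return ep.bulge[l1 + l2 - 1];
    return ep.interior[l1 + l2 - 1];
  }

  void fill() {
    for (int span = ep.min_hairpin + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // ---- V(i,j)
        if (ptype(c[i], c[j]) != 0 && j - i - 1 >= ep.min_hairpin) {
          double be = ep.hairpin[j - i - 2];  // loop size j-i-1, 1-based table
          int bp = 1;
          int kmax = std::min(j - 1, i + ep.max_loop + 1);
          for (int k = i + 1; k <= kmax; ++k) {
            int lmin = std::max(k + ep.min_hairpin + 1,
                                j - 1 - (ep.max_loop - (k - i - 1)));
            for (int l = j - 1; l >= lmin; --l) {
              if (V[ix(k, l)] >= INF / 2) continue;
              double cost = loop_cost(i, j, k, l);
              if (cost >= INF / 2) continue;
              double e = V[ix(k, l)] + cost;
              int p = Vp[ix(k, l)] + 1;
              if (better(e, p, be, bp)) { be = e; bp = p; }
            }
          }
          if (j - i - 1 >= 2) {  // multiloop closing
            double w2 = WM2[ix(i + 1, j - 1)];
            if (w2 < INF / 2) {
              double e = ep.ml_close + ep.ml_branch + w2;
              int p = WM2p[ix(i + 1, j - 1)] + 1;
              if (better(e, p, be, bp)) { be = e; bp = p; }
            }
          }
          V[ix(i, j)] = be; Vp[ix(i, j)] = bp;
        }
        // ---- WM(i,j): >=1 branch inside a multiloop
        {
          double be = INF; int bp = 0;
          if (V[ix(i, j)] < INF / 2) {
            be = V[ix(i, j)] + ep.ml_branch; bp = Vp[ix(i, j)];
          }
          if (WM[ix(i + 1, j)] < INF / 2) {
            double e = WM[ix(i + 1, j)] + ep.ml_unpaired;
            if (better(e, WMp[ix(i + 1, j)], be, bp)) {
              be = e; bp = WMp[ix(i + 1, j)];
            }
          }
          if (WM[ix(i, j - 1)] < INF / 2) {
            double e = WM[ix(i, j - 1)] + ep.ml_unpaired;
            if (better(e, WMp[ix(i, j - 1)], be, bp)) {
              be = e; bp = WMp[ix(i, j - 1)];
            }
          }
          for (int k = i; k < j; ++k) {
            if (WM[ix(i, k)] >= INF / 2 || WM[ix(k + 1, j)] >= INF / 2)
              continue;
            double e = WM[ix(i, k)] + WM[ix(k + 1, j)];
            int p = WMp[ix(i, k)] + WMp[ix(k + 1, j)];
            if (better(e, p, be, bp)) { be = e; bp = p; }
          }
          WM[ix(i, j)] = be; WMp[ix(i, j)] = bp;
          // ---- WM2(i,j): >=2 branches
          double b2 = INF; int p2 = 0;
          for (int k = i; k < j; ++k) {
            if (WM[ix(i, k)] >= INF / 2 || WM[ix(k + 1, j)] >= INF / 2)
              continue;
            double e = WM[ix(i, k)] + WM[ix(k + 1, j)];
            int p = WMp[ix(i, k)] + WMp[ix(k + 1, j)];
            if (better(e, p, b2, p2)) { b2 = e; p2 = p; }
          }
          WM2[ix(i, j)] = b2; WM2p[ix(i, j)] = p2;
        }
      }
    }
    // ---- exterior W
    for (int j = 0; j < n; ++j) {
      double be = W[j]; int bp = Wp[j];  // j unpaired
      for (int i = 0; i <= j; ++i) {
        if (V[ix(i, j)] >= INF / 2) continue;
        double e = (i > 0 ? W[i] : 0.0) + V[ix(i, j)];
        int p = (i > 0 ? Wp[i] : 0) + Vp[ix(i, j)];
        if (better(e, p, be, bp)) { be = e; bp = p; }
      }
      W[j + 1] = be; Wp[j + 1] = bp;
    }
  }

  void traceback() {
    // exterior
    std::vector<std::pair<int, std::pair<int, int> > > st;  // type,i,j
    int j = n - 1;
    while (j >= 0) {
      double tgt = W[j + 1]; int tp = Wp[j + 1];
      if (std::fabs(W[j] - tgt) <= EPS && Wp[j] == tp) { --j; continue; }
      bool found = false;
      for (int i = 0; i <= j && !found; ++i) {
        if (V[ix(i, j)] >= INF / 2) continue;
        double e = (i > 0 ? W[i] : 0.0) + V[ix(i, j)];
        int p = (i > 0 ? Wp[i] : 0) + Vp[ix(i, j)];
        if (std::fabs(e - tgt) <= EPS && p == tp) {
          st.push_back(std::make_pair(0, std::make_pair(i, j)));
          j = i - 1;
          found = true;
        }
      }
      if (!found) --j;  // numerical safety; should not happen
    }
    while (!st.empty()) {
      int type = st.back().first;
      int i = st.back().second.first, jj = st.back().second.second;
      st.pop_back();
      if (type == 0) trace_V(i, jj, st);
      else if (type == 1) trace_WM(i, jj, st);
      else trace_WM2(i, jj, st);
    }
  }

  void trace_V(int i, int j,
               std::vector<std::pair<int, std::pair<int, int> > > &st) {
    pairtab[i] = j; pairtab[j] = i;
    double tgt = V[ix(i, j)]; int tp = Vp[ix(i, j)];
    if (std::fabs(ep.hairpin[j - i - 2] - tgt) <= EPS && tp == 1) return;
    int kmax = std::min(j - 1, i + ep.max_loop + 1);
    for (int k = i + 1; k <= kmax; ++k) {
      int lmin = std::max(k + ep.min_hairpin + 1,
                          j - 1 - (ep.max_loop - (k - i - 1)));
      for (int l = j - 1; l >= lmin; --l) {
        if (V[ix(k, l)] >= INF / 2) continue;
        double cost = loop_cost(i, j, k, l);
        if (cost >= INF / 2) continue;
        if (std::fabs(V[ix(k, l)] + cost - tgt) <= EPS &&
            Vp[ix(k, l)] + 1 == tp) {
          st.push_back(std::make_pair(0, std::make_pair(k, l)));
          return;
        }
      }
    }
    if (j - i - 1 >= 2 && WM2[ix(i + 1, j - 1)] < INF / 2) {
      double e = ep.ml_close + ep.ml_branch + WM2[ix(i + 1, j - 1)];
      if (std::fabs(e - tgt) <= EPS && WM2p[ix(i + 1, j - 1)] + 1 == tp) {
        st.push_back(std::make_pair(2, std::make_pair(i + 1, j - 1)));
        return;
      }
    }
    Rcpp::stop("fold traceback failed in V");
  }

  void trace_WM(int i, int j,
                std::vector<std::pair<int, std::pair<int, int> > > &st) {
    double tgt = WM[ix(i, j)]; int tp = WMp[ix(i, j)];
    if (V[ix(i, j)] < INF / 2 &&
        std::fabs(V[ix(i, j)] + ep.ml_branch - tgt) <= EPS &&
        Vp[ix(i, j)] == tp) {
      st.push_back(std::make_pair(0, std::make_pair(i, j)));
      return;
    }
    if (i + 1 <= j && WM[ix(i + 1, j)] < INF / 2 &&
        std::fabs(WM[ix(i + 1, j)] + ep.ml_unpaired - tgt) <= EPS &&
        WMp[ix(i + 1, j)] == tp) {
      st.push_back(std::make_pair(1, std::make_pair(i + 1, j)));
      return;
    }
    if (j - 1 >= i && WM[ix(i, j - 1)] < INF / 2 &&
        std::fabs(WM[ix(i, j - 1)] + ep.ml_unpaired - tgt) <= EPS &&
        WMp[ix(i, j - 1)] == tp) {
      st.push_back(std::make_pair(1, std::make_pair(i, j - 1)));
      return;
    }
    for (int k = i; k < j; ++k) {
      if (WM[ix(i, k)] >= INF / 2 || WM[ix(k + 1, j)] >= INF / 2) continue;
      if (std::fabs(WM[ix(i, k)] + WM[ix(k + 1, j)] - tgt) <= EPS &&
          WMp[ix(i, k)] + WMp[ix(k + 1, j)] == tp) {
        st.push_back(std::make_pair(1, std::make_pair(i, k)));
        st.push_back(std::make_pair(1, std::make_pair(k + 1, j)));
        return;
      }
    }
    Rcpp::stop("fold traceback failed in WM");
  }

  void trace_WM2(int i, int j,
                 std::vector<std::pair<int, std::pair<int, int> > > &st) {
    double tgt = WM2[ix(i, j)]; int tp = WM2p[ix(i, j)];
    for (int k = i; k < j; ++k) {
      if (WM[ix(i, k)] >= INF / 2 || WM[ix(k + 1, j)] >= INF / 2) continue;
      if (std::fabs(WM[ix(i, k)] + WM[ix(k + 1, j)] - tgt) <= EPS &&
          WMp[ix(i, k)] + WMp[ix(k + 1, j)] == tp) {
        st.push_back(std::make_pair(1, std::make_pair(i, k)));
        st.push_back(std::make_pair(1, std::make_pair(k + 1, j)));
        return;
      }
    }
    Rcpp::stop("fold traceback failed in WM2");
  }
};

static EP read_params(const List &params) {
  EP ep;
  ep.stack = as<NumericMatrix>(params["stack"]);
  ep.hairpin = as<NumericVector>(params["hairpin"]);
  ep.bulge = as<NumericVector>(params["bulge"]);
  ep.interior = as<NumericVector>(params["interior"]);
  ep.ml_close = as<double>(params["ml_close"]);
  ep.ml_unpaired = as<double>(params["ml_unpaired"]);
  ep.ml_branch = as<double>(params["ml_branch"]);
  ep.min_hairpin = as<int>(params["min_hairpin"]);
  ep.max_loop = as<int>(params["max_loop"]);
  return ep;
}

// [[Rcpp::export]]
List fold_rna_cpp(IntegerVector codes, List params) {
  EP ep = read_params(params);
  Folder f(codes, ep);
  f.fill();
  double mfe = f.W[f.n];
  int npairs = f.Wp[f.n];
  std::string db(f.n, '.');
  if (mfe < -EPS || npairs > 0) {
    f.traceback();
    for (int i = 0; i < f.n; ++i) {
      if (f.pairtab[i] > i) { db[i] = '('; db[f.pairtab[i]] = ')'; }
    }
  } else {
    mfe = 0.0; npairs = 0;
  }
  return List::create(_["dotbracket"] = db, _["mfe"] = mfe,
                      _["npairs"] = npairs);
}

// Intermolecular duplex MFE: pairs only between strand a (5'->3') and
// strand b (5'->3', read antiparallel); same stack/loop tables, plus a
// helix initiation term. No intramolecular structure.
// [[Rcpp::export]]
double duplex_mfe_cpp(IntegerVector a, IntegerVector b, List params,
                      double init) {
  EP ep = read_params(params);
  int n = a.size(), m = b.size();
  std::vector<double> D((size_t)n * m, INF);
  double best = 0.0;  // empty duplex
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = ptype(a[i], b[j]);
      if (pt == 0) continue;
      double e = init;  // open a new duplex at this pair
      for (int ip = std::max(0, i - ep.max_loop - 1); ip < i; ++ip) {
        for (int jp = std::min(m - 1, j + ep.max_loop + 1); jp > j; --jp) {
          if (D[(size_t)ip * m + jp] >= INF / 2) continue;
          int l1 = i - ip - 1, l2 = jp - j - 1;
          if (l1 + l2 > ep.max_loop) continue;
          double cost;
          if (l1 == 0 && l2 == 0)
            cost = ep.stack(ptype(a[ip], b[jp]) - 1, pt - 1);
          else if (l1 == 0 || l2 == 0)
            cost = ep.bulge[l1 + l2 - 1];
          else
            cost = ep.interior[l1 + l2 - 1];
          double cand = D[(size_t)ip * m + jp] + cost;
          if (cand < e) e = cand;
        }
      }
      D[(size_t)i * m + j] = e;
      if (e < best) best = e;
    }
  }
  return best;
}
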