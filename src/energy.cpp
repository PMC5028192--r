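// Simplified nearest-neighbour RNA energy engine.
//
// Model (37C, kcal/mol): Watson-Crick + GU pairs; helix stacking energies;
// hairpin / bulge / interior loop penalties indexed by total unpaired length;
// linear multibranch penalty (a + b per branch + c per unpaired); duplex
// initiation and AU/GU duplex-end penalties. No dangles, no coaxial stacking,
// no special hairpins, no loop-asymmetry term. Interior loops are capped at
// `max_loop` unpaired nucleotides for intramolecular folds and at
// `duplex_max_loop` for intermolecular duplexes; both caps are model
// parameters shared with the brute-force oracles used in the tests.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-9;

// base encoding A=0 C=1 G=2 U=3; pair index AU=0 UA=1 CG=2 GC=3 GU=4 UG=5
static inline int pidx(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

struct Params {
  double stack[6][6];
  std::vector<double> hairpin, bulge, interior;
  double init, au_end;
  double ml_a, ml_b, ml_c;
  int max_loop, duplex_max_loop, min_hairpin;

  double hp(int size) const {
    if (size < 1 || size > (int)hairpin.size()) return INF;
    return hairpin[size - 1];
  }
  // interior/bulge loop between two pairs; d1,d2 unpaired on each side
  double loop(int p, int q, int d1, int d2, int cap) const {
    if (d1 + d2 > cap) return INF;
    if (d1 == 0 && d2 == 0) return stack[p][q];
    int sz = d1 + d2;
    const std::vector<double> &tab = (d1 == 0 || d2 == 0) ? bulge : interior;
    if (sz < 1 || sz > (int)tab.size()) return INF;
    return tab[sz - 1];
  }
  double auend(int p) const {
    return (p == 2 || p == 3) ? 0.0 : au_end; // CG/GC free, AU/UA/GU/UG pay
  }
};

static Params parse_params(const List &par) {
  Params P;
  NumericMatrix st = par["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) {
      double v = st(i, j);
      P.stack[i][j] = R_finite(v) ? v : INF;
    }
  NumericVector hp = par["hairpin"], bu = par["bulge"], in = par["internal"];
  P.hairpin.assign(hp.begin(), hp.end());
  P.bulge.assign(bu.begin(), bu.end());
  P.interior.assign(in.begin(), in.end());
  for (auto *v : {&P.hairpin, &P.bulge, &P.interior})
    for (double &x : *v) if (!R_finite(x)) x = INF;
  P.init = as<double>(par["init"]);
  P.au_end = as<double>(par["au_end"]);
  NumericVector ml = par["multi"];
  P.ml_a = R_finite(ml[0]) ? ml[0] : INF;
  P.ml_b = R_finite(ml[1]) ? ml[1] : INF;
  P.ml_c = R_finite(ml[2]) ? ml[2] : INF;
  P.max_loop = as<int>(par["max_loop"]);
  P.duplex_max_loop = as<int>(par["duplex_max_loop"]);
  P.min_hairpin = as<int>(par["min_hairpin"]);
  return P;
}

static inline bool feq(double a, double b) { return std::fabs(a - b) < EPS; }

// ---------------------------------------------------------------- folding --

struct FoldDP {
  int n;
  std::vector<double> V, M, M1;
  std::vector<double> W;
  const Params *P;
  const int *s;
  const int *open; // forced-unpaired mask (0/1), may be null

  double &v(int i, int j) { return V[(size_t)i * n + j]; }
  double &m(int i, int j) { return M[(size_t)i * n + j]; }
  double &m1(int i, int j) { return M1[(size_t)i * n + j]; }

  bool pairable(int i, int j) const {
    if (open && (open[i] || open[j])) return false;
    return j - i - 1 >= P->min_hairpin && pidx(s[i], s[j]) >= 0;
  }

  void run(const int *seq, int len, const Params &par, const int *mask) {
    s = seq; n = len; P = &par; open = mask;
    V.assign((size_t)n * n, INF);
    M.assign((size_t)n * n, INF);
    M1.assign((size_t)n * n, INF);
    for (int d = 0; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        if (pairable(i, j)) {
          int p = pidx(s[i], s[j]);
          double best = P->hp(j - i - 1);
          int kmax = std::min(j - 1, i + 1 + P->max_loop);
          for (int k = i + 1; k <= kmax; ++k) {
            int d1 = k - i - 1;
            int lmin = std::max(k + P->min_hairpin + 1, j - 1 - (P->max_loop - d1));
            for (int l = j - 1; l >= lmin; --l) {
              if (!pairable(k, l)) continue;
              double e = P->loop(p, pidx(s[k], s[l]), d1, j - l - 1, P->max_loop);
              if (e >= INF) continue;
              double c = e + v(k, l);
              if (c < best) best = c;
            }
          }
          if (P->ml_a < INF) {
            for (int u = i + 1; u <= j - 2; ++u) {
              double c = P->ml_a + P->ml_b + m(i + 1, u) + m1(u + 1, j - 1);
              if (c < best) best = c;
            }
          }
          v(i, j) = best;
        }
        // M1: exactly one branch whose 5' end is i
        double b1 = INF;
        if (d > 0) b1 = m1(i, j - 1) + P->ml_c;
        if (v(i, j) < INF) b1 = std::min(b1, v(i, j) + P->ml_b);
        m1(i, j) = b1;
        // M: >= 1 branch anywhere in [i, j]
        double bm = m1(i, j);
        if (d > 0) bm = std::min(bm, m(i + 1, j) + P->ml_c);
        for (int u = i; u < j; ++u) {
          double c = m(i, u) + m1(u + 1, j);
          if (c < bm) bm = c;
        }
        m(i, j) = bm;
      }
    }
    W.assign(n + 1, 0.0);
    for (int j = 0; j < n; ++j) {
      double best = W[j];
      for (int i = 0; i <= j; ++i) {
        double wi = (i > 0 ? W[i] : 0.0);
        if (v(i, j) < INF && wi + v(i, j) < best) best = wi + v(i, j);
      }
      W[j + 1] = best;
    }
  }

  std::string traceback() {
    std::string db(n, '.');
    // frames: kind 0 = external [0..j], 1 = V(i,j), 2 = M(i,j), 3 = M1(i,j)
    struct Fr { int kind, i, j; };
    std::vector<Fr> st;
    st.push_back({0, 0, n - 1});
    while (!st.empty()) {
      Fr f = st.back(); st.pop_back();
      if (f.kind == 0) {
        int j = f.j;
        if (j < 0) continue;
        if (feq(W[j + 1], W[j])) { st.push_back({0, 0, j - 1}); continue; }
        bool done = false;
        for (int i = 0; i <= j && !done; ++i) {
          double wi = (i > 0 ? W[i] : 0.0);
          if (v(i, j) < INF && feq(W[j + 1], wi + v(i, j))) {
            st.push_back({1, i, j});
            st.push_back({0, 0, i - 1});
            done = true;
          }
        }
        continue;
      }
      int i = f.i, j = f.j;
      if (f.kind == 1) {
        db[i] = '('; db[j] = ')';
        double val = v(i, j);
        if (feq(val, P->hp(j - i - 1))) continue;
        int p = pidx(s[i], s[j]);
        bool done = false;
        int kmax = std::min(j - 1, i + 1 + P->max_loop);
        for (int k = i + 1; k <= kmax && !done; ++k) {
          int d1 = k - i - 1;
          int lmin = std::max(k + P->min_hairpin + 1, j - 1 - (P->max_loop - d1));
          for (int l = j - 1; l >= lmin && !done; --l) {
            if (!pairable(k, l)) continue;
            double e = P->loop(p, pidx(s[k], s[l]), d1, j - l - 1, P->max_loop);
            if (e < INF && feq(val, e + v(k, l))) {
              st.push_back({1, k, l});
              done = true;
            }
          }
        }
        if (done) continue;
        for (int u = i + 1; u <= j - 2 && !done; ++u) {
          if (feq(val, P->ml_a + P->ml_b + m(i + 1, u) + m1(u + 1, j - 1))) {
            st.push_back({2, i + 1, u});
            st.push_back({3, u + 1, j - 1});
            done = true;
          }
        }
      } else if (f.kind == 2) {
        double val = m(i, j);
        if (feq(val, m1(i, j))) { st.push_back({3, i, j}); continue; }
        if (i < j && feq(val, m(i + 1, j) + P->ml_c)) { st.push_back({2, i + 1, j}); continue; }
        for (int u = i; u < j; ++u)
          if (feq(val, m(i, u) + m1(u + 1, j))) {
            st.push_back({2, i, u});
            st.push_back({3, u + 1, j});
            break;
          }
      } else {
        double val = m1(i, j);
        if (v(i, j) < INF && feq(val, v(i, j) + P->ml_b)) { st.push_back({1, i, j}); continue; }
        if (i < j) st.push_back({3, i, j - 1});
      }
    }
    return db;
  }
};

// [[Rcpp::export]]
List c_fold(IntegerVector s, List par, LogicalVector open_mask, bool structure = true) {
  Params P = parse_params(par);
  int n = s.size();
  std::vector<int> seq(s.begin(), s.end());
  std::vector<int> mask(n, 0);
  bool any = false;
  if (open_mask.size() == n)
    for (int i = 0; i < n; ++i) { mask[i] = open_mask[i] ? 1 : 0; any = any || mask[i]; }
  FoldDP dp;
  dp.run(seq.data(), n, P, any ? mask.data() : nullptr);
  double e = dp.W[n];
  std::string db;
  if (structure) db = dp.traceback();
  return List::create(_["energy"] = e, _["structure"] = db);
}

// all contiguous intervals up to max_site: opening cost matrix (n x max_site)
// [[Rcpp::export]]
NumericMatrix c_opening_profile(IntegerVector s, List par, int max_site) {
  Params P = parse_params(par);
  int n = s.size();
  std::vector<int> seq(s.begin(), s.end());
  FoldDP dp;
  dp.run(seq.data(), n, P, nullptr);
  double e0 = dp.W[n];
  NumericMatrix out(n, max_site);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> mask(n, 0);
  for (int i = 0; i < n; ++i) {
    std::fill(mask.begin(), mask.end(), 0);
    for (int len = 1; len <= max_site && i + len <= n; ++len) {
      mask[i + len - 1] = 1;
      FoldDP dpc;
      dpc.run(seq.data(), n, P, mask.data());
      double d = dpc.W[n] - e0;
      out(i, len - 1) = d > 0 ? d : 0.0;
    }
  }
  return out;
}

// ----------------------------------------------------------------- duplex --

// energy-only duplex MFE (intermolecular pairs only), capped at 0
static double duplex_energy(const int *a, int na, const int *b, int nb, const Params &P) {
  int cap = P.duplex_max_loop;
  std::vector<double> D((size_t)na * nb, INF);
  double best = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = nb - 1; j >= 0; --j) {
      int p = pidx(a[i], b[j]);
      if (p < 0) continue;
      double d = P.init + P.auend(p);
      int kmin = std::max(0, i - 1 - cap);
      for (int k = i - 1; k >= kmin; --k) {
        int d1 = i - k - 1;
        int lmax = std::min(nb - 1, j + 1 + (cap - d1));
        for (int l = j + 1; l <= lmax; ++l) {
          double dkl = D[(size_t)k * nb + l];
          if (dkl >= INF) continue;
          int q = pidx(a[k], b[l]);
          double e = P.loop(q, p, d1, l - j - 1, cap);
          if (e >= INF) continue;
          if (dkl + e < d) d = dkl + e;
        }
      }
      D[(size_t)i * nb + j] = d;
      double tot = d + P.auend(p);
      if (tot < best) best = tot;
    }
  }
  return best;
}

// full duplex with sites and pairing string
// [[Rcpp::export]]
List c_duplex(IntegerVector av, IntegerVector bv, List par) {
  Params P = parse_params(par);
  int na = av.size(), nb = bv.size(), cap = P.duplex_max_loop;
  std::vector<int> a(av.begin(), av.end()), b(bv.begin(), bv.end());
  std::vector<double> D((size_t)na * nb, INF);
  std::vector<int> SA((size_t)na * nb, -1), SB((size_t)na * nb, -1),
      PK((size_t)na * nb, -1), PL((size_t)na * nb, -1);
  for (int i = 0; i < na; ++i) {
    for (int j = nb - 1; j >= 0; --j) {
      int p = pidx(a[i], b[j]);
      if (p < 0) continue;
      size_t ij = (size_t)i * nb + j;
      double d = P.init + P.auend(p);
      int sa = i, sb = j, pk = -1, pl = -1;
      int kmin = std::max(0, i - 1 - cap);
      for (int k = i - 1; k >= kmin; --k) {
        int d1 = i - k - 1;
        int lmax = std::min(nb - 1, j + 1 + (cap - d1));
        for (int l = j + 1; l <= lmax; ++l) {
          size_t kl = (size_t)k * nb + l;
          if (D[kl] >= INF) continue;
          double e = P.loop(pidx(a[k], b[l]), p, d1, l - j - 1, cap);
          if (e >= INF) continue;
          double cnd = D[kl] + e;
          bool better = cnd < d - EPS;
          if (!better && cnd < d + EPS) { // tie: lexicographically smaller site
            if (SA[kl] < sa || (SA[kl] == sa && SB[kl] > sb)) better = true;
          }
          if (better) { d = cnd; sa = SA[kl]; sb = SB[kl]; pk = k; pl = l; }
        }
      }
      D[ij] = d; SA[ij] = sa; SB[ij] = sb; PK[ij] = pk; PL[ij] = pl;
    }
  }
  double best = 0.0;
  int bi = -1, bj = -1;
  long btup[4] = {0, 0, 0, 0};
  for (int i = 0; i < na; ++i)
    for (int j = nb - 1; j >= 0; --j) {
      size_t ij = (size_t)i * nb + j;
      if (D[ij] >= INF) continue;
      double tot = D[ij] + P.auend(pidx(a[i], b[j]));
      if (tot > -EPS) continue;
      long tup[4] = {SA[ij], i, j, SB[ij]};
      bool take = tot < best - EPS;
      if (!take && tot < best + EPS && bi >= 0) {
        for (int t = 0; t < 4; ++t) {
          if (tup[t] < btup[t]) { take = true; break; }
          if (tup[t] > btup[t]) break;
        }
      }
      if (take) { best = tot; bi = i; bj = j; for (int t = 0; t < 4; ++t) btup[t] = tup[t]; }
    }
  if (bi < 0)
    return List::create(_["energy"] = 0.0, _["site_a"] = IntegerVector::create(NA_INTEGER, NA_INTEGER),
                        _["site_b"] = IntegerVector::create(NA_INTEGER, NA_INTEGER), _["pairing"] = "");
  // collect pairs by walking prev pointers
  std::vector<std::pair<int, int>> pairs;
  int i = bi, j = bj;
  while (i >= 0) {
    pairs.push_back({i, j});
    size_t ij = (size_t)i * nb + j;
    int k = PK[ij], l = PL[ij];
    i = k; j = l;
  }
  int a1 = pairs.back().first, a2 = pairs.front().first;
  int b1 = pairs.front().second, b2 = pairs.back().second;
  std::string sa(a2 - a1 + 1, '.'), sb(b2 - b1 + 1, '.');
  for (auto &pr : pairs) { sa[pr.first - a1] = '('; sb[pr.second - b1] = ')'; }
  return List::create(_["energy"] = best,
                      _["site_a"] = IntegerVector::create(a1 + 1, a2 + 1),
                      _["site_b"] = IntegerVector::create(b1 + 1, b2 + 1),
                      _["pairing"] = sa + "&" + sb);
}

// [[Rcpp::export]]
NumericMatrix c_duplex_batch(List A, List B, List par) {
  Params P = parse_params(par);
  int na = A.size(), nb = B.size();
  std::vector<std::vector<int>> as(na), bs(nb);
  for (int i = 0; i < na; ++i) { IntegerVector v = A[i]; as[i].assign(v.begin(), v.end()); }
  for (int j = 0; j < nb; ++j) { IntegerVector v = B[j]; bs[j].assign(v.begin(), v.end()); }
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j)
      out(i, j) = duplex_energy(as[i].data(), as[i].size(), bs[j].data(), bs[j].size(), P);
  return out;
}

// ----------------------------------------------------------------- access --

// opening + hybridisation joint minimum. openA/openB give the cost of holding
// each interval (row = start, col = length-1) unpaired; the optimal site is
// exactly the duplex span, so we minimise over duplex start pair (k,l) and
// extension within a max_site window on both molecules.
struct AccessBest {
  double e = 0.0;
  int k = -1, i = -1, j = -1, l = -1;
};

static AccessBest access_core(const int *a, int na, const int *b, int nb,
                              const Params &P, int max_site,
                              const double *openA, const double *openB) {
  int cap = P.duplex_max_loop;
  AccessBest best;
  std::vector<double> E((size_t)max_site * max_site);
  for (int k = 0; k < na; ++k) {
    for (int l = nb - 1; l >= 0; --l) {
      int p0 = pidx(a[k], b[l]);
      if (p0 < 0) continue;
      int wa = std::min(max_site, na - k);
      int wb = std::min(max_site, l + 1);
      std::fill(E.begin(), E.end(), INF);
      E[0] = 0.0;
      double base = P.init + P.auend(p0);
      for (int oi = 0; oi < wa; ++oi) {
        for (int oj = 0; oj < wb; ++oj) {
          int i = k + oi, j = l - oj;
          if (oi + oj > 0) {
            int p = pidx(a[i], b[j]);
            if (p < 0) continue;
            double d = INF;
            for (int dk = oi - 1; dk >= 0 && (oi - dk - 1) <= cap; --dk) {
              int d1 = oi - dk - 1;
              for (int dl = oj - 1; dl >= 0 && d1 + (oj - dl - 1) <= cap; --dl) {
                double prev = E[(size_t)dk * max_site + dl];
                if (prev >= INF) continue;
                double e = P.loop(pidx(a[k + dk], b[l - dl]), p, d1, oj - dl - 1, cap);
                if (e < INF && prev + e < d) d = prev + e;
              }
            }
            E[(size_t)oi * max_site + oj] = d;
            if (d >= INF) continue;
          }
          int p = pidx(a[i], b[j]);
          double tot = base + E[(size_t)oi * max_site + oj] + P.auend(p) +
                       openA[(size_t)k + (size_t)oi * na] +
                       openB[(size_t)j + (size_t)oj * nb];
          if (tot > -EPS) continue;
          bool take = tot < best.e - EPS;
          if (!take && tot < best.e + EPS && best.k >= 0) {
            long tup[4] = {k, i, j, l}, bt[4] = {best.k, best.i, best.j, best.l};
            for (int t = 0; t < 4; ++t) {
              if (tup[t] < bt[t]) { take = true; break; }
              if (tup[t] > bt[t]) break;
            }
          }
          if (take) { best.e = tot; best.k = k; best.i = i; best.j = j; best.l = l; }
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List c_access(IntegerVector av, IntegerVector bv, List par, int max_site,
              NumericMatrix openA, NumericMatrix openB) {
  Params P = parse_params(par);
  int na = av.size(), nb = bv.size();
  std::vector<int> a(av.begin(), av.end()), b(bv.begin(), bv.end());
  AccessBest bst = access_core(a.data(), na, b.data(), nb, P, max_site,
                               REAL(openA), REAL(openB));
  if (bst.k < 0)
    return List::create(_["energy"] = 0.0,
                        _["site_a"] = IntegerVector::create(NA_INTEGER, NA_INTEGER),
                        _["site_b"] = IntegerVector::create(NA_INTEGER, NA_INTEGER),
                        _["pairing"] = "", _["open_a"] = 0.0, _["open_b"] = 0.0,
                        _["duplex"] = 0.0);
  // rebuild the pair chain for the winning start with prev pointers
  int cap = P.duplex_max_loop, k = bst.k, l = bst.l;
  int wa = std::min(max_site, na - k), wb = std::min(max_site, l + 1);
  std::vector<double> E((size_t)max_site * max_site, INF);
  std::vector<int> PI((size_t)max_site * max_site, -1), PJ((size_t)max_site * max_site, -1);
  E[0] = 0.0;
  for (int oi = 0; oi < wa; ++oi)
    for (int oj = 0; oj < wb; ++oj) {
      if (oi + oj == 0) continue;
      int p = pidx(a[k + oi], b[l - oj]);
      if (p < 0) continue;
      double d = INF; int pi = -1, pj = -1;
      for (int dk = oi - 1; dk >= 0 && (oi - dk - 1) <= cap; --dk) {
        int d1 = oi - dk - 1;
        for (int dl = oj - 1; dl >= 0 && d1 + (oj - dl - 1) <= cap; --dl) {
          double prev = E[(size_t)dk * max_site + dl];
          if (prev >= INF) continue;
          double e = P.loop(pidx(a[k + dk], b[l - dl]), p, d1, oj - dl - 1, cap);
          if (e < INF && prev + e < d) { d = prev + e; pi = dk; pj = dl; }
        }
      }
      E[(size_t)oi * max_site + oj] = d;
      PI[(size_t)oi * max_site + oj] = pi;
      PJ[(size_t)oi * max_site + oj] = pj;
    }
  std::vector<std::pair<int, int>> pairs;
  int oi = bst.i - k, oj = l - bst.j;
  while (oi >= 0) {
    pairs.push_back({k + oi, l - oj});
    int ni = PI[(size_t)oi * max_site + oj], nj = PJ[(size_t)oi * max_site + oj];
    if (oi == 0 && oj == 0) break;
    oi = ni; oj = nj;
  }
  int a1 = bst.k, a2 = bst.i, b1 = bst.j, b2 = bst.l;
  std::string sa(a2 - a1 + 1, '.'), sb(b2 - b1 + 1, '.');
  for (auto &pr : pairs) { sa[pr.first - a1] = '('; sb[pr.second - b1] = ')'; }
  double oa = openA((size_t)a1, a2 - a1), ob = openB((size_t)b1, b2 - b1);
  return List::create(_["energy"] = bst.e,
                      _["site_a"] = IntegerVector::create(a1 + 1, a2 + 1),
                      _["site_b"] = IntegerVector::create(b1 + 1, b2 + 1),
                      _["pairing"] = sa + "&" + sb,
                      _["open_a"] = oa, _["open_b"] = ob,
                      _["duplex"] = bst.e - oa - ob);
}

// [[Rcpp::export]]
NumericMatrix c_access_batch(List A, List B, List par, int max_site,
                             List openAs, List openBs) {
  Params P = parse_params(par);
  int na = A.size(), nb = B.size();
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    IntegerVector av = A[i];
    NumericMatrix oa = openAs[i];
    std::vector<int> a(av.begin(), av.end());
    for (int j = 0; j < nb; ++j) {
      IntegerVector bv = B[j];
      NumericMatrix ob = openBs[j];
      std::vector<int> b(bv.begin(), bv.end());
      out(i, j) = access_core(a.data(), a.size(), b.data(), b.size(), P,
                              max_site, REAL(oa), REAL(ob)).e;
    }
  }
  return out;
}
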