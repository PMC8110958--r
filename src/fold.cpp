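#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Secondary-structure DP engines.
//
// Bases are encoded A=0, C=1, G=2, U=3. Pair types are indexed
// CG=0, GC=1, GU=2, UG=3, AU=4, UA=5 (-1 = not pairable).
// Minimum hairpin loop size is 3 (a pair (i,j) requires j - i - 1 >= 3).

static const double INF_E = 1e9;
static const double EPS = 1e-6;
static const int TURN = 3;

static inline int pair_type(int a, int b) {
  if (a == 1 && b == 2) return 0;  // C-G
  if (a == 2 && b == 1) return 1;  // G-C
  if (a == 2 && b == 3) return 2;  // G-U
  if (a == 3 && b == 2) return 3;  // U-G
  if (a == 0 && b == 3) return 4;  // A-U
  if (a == 3 && b == 0) return 5;  // U-A
  return -1;
}

struct Model {
  const double *stack;        // 6x6, column-major from R
  std::vector<double> hairpin, bulge, internal_;
  double asym, asym_max, ml_a, ml_b, ml_c, lxc;
  int maxloop;

  double stk(int p, int q) const { return stack[p + 6 * q]; }

  double loop_tab(const std::vector<double> &tab, int L) const {
    int m = (int)tab.size();
    if (L <= 0) return INF_E;
    if (L <= m) return tab[L - 1];
    return tab[m - 1] + lxc * std::log((double)L / (double)m);
  }
  double hairpin_e(int L) const {
    if (L < TURN) return INF_E;
    return loop_tab(hairpin, L);
  }
  double bulge_e(int L) const { return loop_tab(bulge, L); }
  double internal_e(int l1, int l2) const {
    double a = asym * std::abs(l1 - l2);
    if (a > asym_max) a = asym_max;
    return loop_tab(internal_, l1 + l2) + a;
  }
};

struct Fold {
  int n;
  std::vector<int> s;
  const Model &em;
  std::vector<double> V, WM;   // n x n, index i*n+j
  std::vector<double> W;       // external, W[j] = MFE of s[0..j]
  std::vector<int> pairv;

  Fold(const std::vector<int> &seq, const Model &m)
    : n((int)seq.size()), s(seq), em(m),
      V(n * n, INF_E), WM(n * n, INF_E), W(n, 0.0), pairv(n, -1) {}

  inline double &v(int i, int j) { return V[i * n + j]; }
  inline double &wm(int i, int j) { return WM[i * n + j]; }

  // energy of the two-pair decomposition (stack / bulge / internal)
  double loop_e(int i, int j, int ip, int jp, int pt, int ptin) const {
    int l1 = ip - i - 1, l2 = j - jp - 1;
    if (l1 == 0 && l2 == 0) return em.stack[pt + 6 * ptin];
    if (l1 == 0 || l2 == 0) return em.bulge_e(l1 + l2);
    return em.internal_e(l1, l2);
  }

  void fill() {
    for (int d = TURN + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        int pt = pair_type(s[i], s[j]);
        double best = INF_E;
        if (pt >= 0) {
          best = em.hairpin_e(j - i - 1);
          // interior loops (stack, bulge, internal) capped at maxloop
          int ipmax = std::min(i + 1 + em.maxloop, j - TURN - 2);
          for (int ip = i + 1; ip <= ipmax; ++ip) {
            int l1 = ip - i - 1;
            for (int jp = j - 1; jp >= ip + TURN + 1; --jp) {
              int l2 = j - jp - 1;
              if (l1 + l2 > em.maxloop) break;
              int ptin = pair_type(s[ip], s[jp]);
              if (ptin < 0) continue;
              double e = loop_e(i, j, ip, jp, pt, ptin) + v(ip, jp);
              if (e < best) best = e;
            }
          }
          // multiloop: closing pair + >= 2 branches inside
          for (int k = i + 1; k + 1 <= j - 1; ++k) {
            double a = wm(i + 1, k), b = wm(k + 1, j - 1);
            if (a >= INF_E / 2 || b >= INF_E / 2) continue;
            double e = em.ml_a + em.ml_b + a + b;
            if (e < best) best = e;
          }
        }
        v(i, j) = best;

        // WM: segment holding >= 1 multiloop branch
        double w = INF_E;
        if (v(i, j) < INF_E / 2) w = v(i, j) + em.ml_b;
        if (wm(i + 1, j) < INF_E / 2) w = std::min(w, wm(i + 1, j) + em.ml_c);
        if (wm(i, j - 1) < INF_E / 2) w = std::min(w, wm(i, j - 1) + em.ml_c);
        for (int k = i; k + 1 <= j; ++k) {
          double a = wm(i, k), b = wm(k + 1, j);
          if (a < INF_E / 2 && b < INF_E / 2) w = std::min(w, a + b);
        }
        wm(i, j) = w;
      }
      // WM for single-base growth of short segments is handled above since
      // wm() of spans < TURN+1 stays INF (no pair fits).
    }
    for (int j = 0; j < n; ++j) {
      double best = (j > 0) ? W[j - 1] : 0.0;
      for (int i = 0; i + TURN + 1 <= j; ++i) {
        if (v(i, j) >= INF_E / 2) continue;
        double e = ((i > 0) ? W[i - 1] : 0.0) + v(i, j);
        if (e < best) best = e;
      }
      W[j] = best;
    }
  }

  void trace_W(int j) {
    while (j >= TURN + 1) {
      bool advanced = false;
      // prefer the 5'-most branch ending at j among co-optimal choices
      for (int i = 0; i + TURN + 1 <= j; ++i) {
        if (v(i, j) >= INF_E / 2) continue;
        double e = ((i > 0) ? W[i - 1] : 0.0) + v(i, j);
        if (std::fabs(e - W[j]) < EPS) {
          trace_V(i, j);
          j = i - 1;
          advanced = true;
          break;
        }
      }
      if (!advanced) --j;
    }
  }

  void trace_V(int i, int j) {
    pairv[i] = j; pairv[j] = i;
    int pt = pair_type(s[i], s[j]);
    double target = v(i, j);
    // interior decompositions, shortest loops first (stack preferred)
    for (int sz = 0; sz <= em.maxloop; ++sz) {
      for (int l1 = 0; l1 <= sz; ++l1) {
        int l2 = sz - l1;
        int ip = i + 1 + l1, jp = j - 1 - l2;
        if (jp < ip + TURN + 1) continue;
        int ptin = pair_type(s[ip], s[jp]);
        if (ptin < 0) continue;
        double e = loop_e(i, j, ip, jp, pt, ptin) + v(ip, jp);
        if (std::fabs(e - target) < EPS) { trace_V(ip, jp); return; }
      }
    }
    if (std::fabs(em.hairpin_e(j - i - 1) - target) < EPS) return;
    for (int k = i + 1; k + 1 <= j - 1; ++k) {
      double a = wm(i + 1, k), b = wm(k + 1, j - 1);
      if (a >= INF_E / 2 || b >= INF_E / 2) continue;
      if (std::fabs(em.ml_a + em.ml_b + a + b - target) < EPS) {
        trace_WM(i + 1, k); trace_WM(k + 1, j - 1); return;
      }
    }
    Rcpp::stop("internal traceback failure in V");
  }

  void trace_WM(int i, int j) {
    double target = wm(i, j);
    if (v(i, j) < INF_E / 2 && std::fabs(v(i, j) + em.ml_b - target) < EPS) {
      trace_V(i, j); return;
    }
    if (wm(i + 1, j) < INF_E / 2 &&
        std::fabs(wm(i + 1, j) + em.ml_c - target) < EPS) {
      trace_WM(i + 1, j); return;
    }
    if (wm(i, j - 1) < INF_E / 2 &&
        std::fabs(wm(i, j - 1) + em.ml_c - target) < EPS) {
      trace_WM(i, j - 1); return;
    }
    for (int k = i; k + 1 <= j; ++k) {
      double a = wm(i, k), b = wm(k + 1, j);
      if (a < INF_E / 2 && b < INF_E / 2 && std::fabs(a + b - target) < EPS) {
        trace_WM(i, k); trace_WM(k + 1, j); return;
      }
    }
    Rcpp::stop("internal traceback failure in WM");
  }

  std::string dotbracket() const {
    std::string db(n, '.');
    for (int i = 0; i < n; ++i) {
      if (pairv[i] > i) { db[i] = '('; db[pairv[i]] = ')'; }
    }
    return db;
  }
};

// [[Rcpp::export]]
List fold_zuker_cpp(IntegerVector seq, NumericMatrix stack,
                    NumericVector hairpin, NumericVector bulge,
                    NumericVector internal, double asym, double asym_max,
                    double ml_a, double ml_b, double ml_c, double lxc,
                    int maxloop) {
  Model em;
  em.stack = stack.begin();
  em.hairpin.assign(hairpin.begin(), hairpin.end());
  em.bulge.assign(bulge.begin(), bulge.end());
  em.internal_.assign(internal.begin(), internal.end());
  em.asym = asym; em.asym_max = asym_max;
  em.ml_a = ml_a; em.ml_b = ml_b; em.ml_c = ml_c;
  em.lxc = lxc; em.maxloop = maxloop;

  std::vector<int> s(seq.begin(), seq.end());
  Fold f(s, em);
  f.fill();
  double mfe = f.W[f.n - 1];
  if (mfe > -EPS) {
    // the open chain is optimal (or tied): report it
    return List::create(_["structure"] = std::string(f.n, '.'),
                        _["mfe"] = 0.0);
  }
  f.trace_W(f.n - 1);
  return List::create(_["structure"] = f.dotbracket(), _["mfe"] = mfe);
}

// Nussinov base-pair maximization; energy reported as -(number of pairs).
// [[Rcpp::export]]
List fold_nussinov_cpp(IntegerVector seq) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> D(n * n, 0);
  auto d = [&](int i, int j) -> int& { return D[i * n + j]; };

  for (int span = TURN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = d(i, j - 1);
      for (int k = i; k <= j - TURN - 1; ++k) {
        if (pair_type(s[k], s[j]) < 0) continue;
        int left = (k > i) ? d(i, k - 1) : 0;
        int inner = (k + 1 <= j - 1) ? d(k + 1, j - 1) : 0;
        int cand = left + 1 + inner;
        if (cand > best) best = cand;
      }
      d(i, j) = best;
    }
  }

  std::vector<int> pairv(n, -1);
  // iterative traceback over a stack of segments; 5'-most pairing preferred
  std::vector<std::pair<int,int>> todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i < TURN + 1) continue;
    bool paired = false;
    for (int k = i; k <= j - TURN - 1; ++k) {
      if (pair_type(s[k], s[j]) < 0) continue;
      int left = (k > i) ? d(i, k - 1) : 0;
      int inner = (k + 1 <= j - 1) ? d(k + 1, j - 1) : 0;
      if (left + 1 + inner == d(i, j)) {
        pairv[k] = j; pairv[j] = k;
        if (k > i) todo.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) todo.push_back(std::make_pair(k + 1, j - 1));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push_back(std::make_pair(i, j - 1));
  }

  std::string db(n, '.');
  int np = 0;
  for (int i = 0; i < n; ++i)
    if (pairv[i] > i) { db[i] = '('; db[pairv[i]] = ')'; ++np; }
  return List::create(_["structure"] = db, _["mfe"] = -(double)np);
}
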