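#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Poincare-section visit detector on the integer lattice.
//
// Section P_j (1-based j) is the triangle with vertices (0,0,0),
// (Omega,Omega,Omega) and Omega*e_j, i.e. the set {N_{j+1} = N_{j+2},
// N_j >= max(N_{j+1}, N_{j+2})} (cyclic indices). A visit occurs at a jump
// where D_j = N_{j+1} - N_{j+2} changes sign in the model's orientation
// (orient = +1, -1, or 0 for either direction), with D_j = 0 attributed to
// the side being left, subject to the triangle condition, and provided the
// section differs from the one currently occupied. Circuits returning to the
// anchor section after visiting both other sections are reduced to cycle
// lengths (the sum of the three leg times).
struct CrossDetector {
  int sgn[3];
  int cur;          // current section 0..2, -1 before the first visit
  int anchor;       // section anchoring circuit completion
  double t_anchor;
  bool seen[3];
  int orient;
  std::vector<int> ev_sec;
  std::vector<double> ev_t;
  std::vector<double> cycles;

  void visit(int j, double t) {
    ev_sec.push_back(j + 1);
    ev_t.push_back(t);
    if (anchor < 0) {
      anchor = j;
      t_anchor = t;
    } else if (j == anchor) {
      if (seen[(j + 1) % 3] && seen[(j + 2) % 3])
        cycles.push_back(t - t_anchor);
      t_anchor = t;
      seen[0] = seen[1] = seen[2] = false;
    }
    seen[j] = true;
    cur = j;
  }

  void init(const int* N, int orient_) {
    orient = orient_;
    cur = -1;
    anchor = -1;
    t_anchor = 0.0;
    seen[0] = seen[1] = seen[2] = false;
    for (int j = 0; j < 3; ++j) {
      int D = N[(j + 1) % 3] - N[(j + 2) % 3];
      sgn[j] = (D > 0) - (D < 0);
    }
    // a start lying on a section counts as the first visit (t = 0)
    for (int j = 0; j < 3; ++j) {
      int a = N[(j + 1) % 3], b = N[(j + 2) % 3];
      if (a == b && N[j] >= a) {
        visit(j, 0.0);
        break;
      }
    }
  }

  void step(const int* N, double t) {
    for (int j = 0; j < 3; ++j) {
      int a = N[(j + 1) % 3], b = N[(j + 2) % 3];
      int D = a - b;
      int s = (D > 0) - (D < 0);
      if (s != 0) {
        if (sgn[j] != 0 && s != sgn[j] && (orient == 0 || s == orient) &&
            N[j] >= a && N[j] >= b && j != cur) {
          visit(j, t);
        }
        sgn[j] = s;
      }
    }
  }
};

// Combinatorial mass-action propensity of reaction j at state N:
// c_j * prod_k choose(N_k, R_jk) * prod_k choose(omega - N_k, C_jk)
// with reactant orders at most 2.
static inline double propensity_one(const double rate, const int* N,
                                    const int* R, const int* C, int ns,
                                    double omega) {
  double a = rate;
  for (int k = 0; k < ns; ++k) {
    int r = R[k];
    if (r == 1) {
      a *= N[k];
    } else if (r == 2) {
      a *= 0.5 * N[k] * (N[k] - 1);
    }
    int c = C[k];
    if (c > 0) {
      double M = omega - N[k];
      if (M < 0) M = 0;
      if (c == 1) {
        a *= M;
      } else {
        a *= 0.5 * M * (M - 1);
      }
    }
  }
  return a > 0 ? a : 0.0;
}

// Exact Gillespie direct-method simulation.
// stop_mode: 0 none, 1 stop when any species first reaches 0,
//            2 stop after max_cycles completed circuits.
// reason codes: 0 t_max, 1 absorbed, 2 stop_predicate, 3 max_steps.
// [[Rcpp::export]]
List ssa_core(IntegerMatrix Snet, IntegerMatrix Rct, IntegerMatrix Cmp,
              NumericVector rate, double omega, IntegerVector init,
              double t_max, bool record, int stop_mode, bool detect,
              int orient, int max_cycles, double max_steps) {
  const int nr = Snet.nrow();
  const int ns = Snet.ncol();
  std::vector<int> N(init.begin(), init.end());
  std::vector<double> a(nr);
  // row-wise copies for cache-friendly access
  std::vector<int> S(nr * ns), R(nr * ns), C(nr * ns);
  for (int j = 0; j < nr; ++j)
    for (int k = 0; k < ns; ++k) {
      S[j * ns + k] = Snet(j, k);
      R[j * ns + k] = Rct(j, k);
      C[j * ns + k] = Cmp(j, k);
    }

  std::vector<double> ts;
  std::vector<int> path;
  if (record) {
    ts.push_back(0.0);
    path.insert(path.end(), N.begin(), N.end());
  }

  std::vector<double> ext(ns, -1.0);
  for (int k = 0; k < ns; ++k)
    if (N[k] == 0) ext[k] = 0.0;

  CrossDetector det;
  if (detect && ns == 3) det.init(N.data(), orient);

  double t = 0.0;
  double steps = 0.0;
  int reason = 0;

  for (;;) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      a[j] = propensity_one(rate[j], N.data(), &R[j * ns], &C[j * ns], ns,
                            omega);
      a0 += a[j];
    }
    if (a0 <= 0.0) {
      reason = 1;
      break;
    }
    double dt = exp_rand() / a0;
    if (t + dt > t_max) {
      t = t_max;
      reason = 0;
      break;
    }
    t += dt;
    double u = unif_rand() * a0;
    int j = 0;
    double csum = a[0];
    while (u > csum && j < nr - 1) csum += a[++j];
    for (int k = 0; k < ns; ++k) N[k] += S[j * ns + k];
    steps += 1.0;

    if (record) {
      ts.push_back(t);
      path.insert(path.end(), N.begin(), N.end());
    }
    bool zero_stop = false;
    for (int k = 0; k < ns; ++k)
      if (N[k] == 0 && ext[k] < 0) {
        ext[k] = t;
        if (stop_mode == 1) zero_stop = true;
      }
    if (detect && ns == 3) det.step(N.data(), t);
    if (zero_stop) {
      reason = 2;
      break;
    }
    if (stop_mode == 2 && detect &&
        (int)det.cycles.size() >= max_cycles) {
      reason = 2;
      break;
    }
    if (steps >= max_steps) {
      reason = 3;
      break;
    }
  }

  NumericVector ext_out(ns);
  for (int k = 0; k < ns; ++k)
    ext_out[k] = ext[k] < 0 ? NA_REAL : ext[k];

  List out = List::create(
      _["t_end"] = t, _["n_jumps"] = steps, _["reason"] = reason,
      _["final"] = IntegerVector(N.begin(), N.end()),
      _["extinction"] = ext_out,
      _["ev_sec"] = IntegerVector(det.ev_sec.begin(), det.ev_sec.end()),
      _["ev_t"] = NumericVector(det.ev_t.begin(), det.ev_t.end()),
      _["cycles"] = NumericVector(det.cycles.begin(), det.cycles.end()));
  if (record) {
    int n = (int)ts.size();
    IntegerMatrix X(n, ns);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < ns; ++k) X(i, k) = path[i * ns + k];
    out["times"] = NumericVector(ts.begin(), ts.end());
    out["states"] = X;
  }
  return out;
}

// Apply the section-visit detector to a recorded jump path (rows of X are
// consecutive states; t gives jump times, first row is the initial state).
// [[Rcpp::export]]
List crossings_path(IntegerMatrix X, NumericVector t, int orient) {
  if (X.ncol() != 3) stop("crossing detection requires 3 species");
  int n = X.nrow();
  if (n != t.size()) stop("times and states disagree in length");
  CrossDetector det;
  int N[3];
  for (int k = 0; k < 3; ++k) N[k] = X(0, k);
  det.init(N, orient);
  for (int i = 1; i < n; ++i) {
    for (int k = 0; k < 3; ++k) N[k] = X(i, k);
    det.step(N, t[i]);
  }
  return List::create(
      _["ev_sec"] = IntegerVector(det.ev_sec.begin(), det.ev_sec.end()),
      _["ev_t"] = NumericVector(det.ev_t.begin(), det.ev_t.end()),
      _["cycles"] = NumericVector(det.cycles.begin(), det.cycles.end()));
}
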