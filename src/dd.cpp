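#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Uniformization kernels for the diversity-dependent master equations.
// Both propagate linear birth-death-type generators as
//   e^{A t} p = e^{-a} sum_j (a^j / j!) P^j p,  P = I + A / Omega
// chunked so each series stays short.

// 1-D missing-species master equation: states m = 0..M, k observed
// lineages, up rate lam(k+m) (2k+m), down rate mu(k+m) m, diagonal
// -(lam+mu)(k+m).
// [[Rcpp::export]]
NumericVector dd_propagate_cpp(NumericVector p0, NumericVector up,
                               NumericVector down, NumericVector diagloss,
                               double dt) {
  int n = p0.size();
  double Omega = 0.0;
  for (int i = 0; i < n; i++) Omega = std::max(Omega, diagloss[i]);
  Omega += 1e-12;
  int nchunk = std::max(1, (int)std::ceil(Omega * dt / 80.0));
  double a = Omega * dt / nchunk;
  int jmax = std::max(10, (int)std::ceil(a + 12.0 * std::sqrt(a) + 20.0));
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> term(n), acc(n), tmp(n);
  for (int c = 0; c < nchunk; c++) {
    double wj = std::exp(-a);
    double total_w = wj;
    for (int i = 0; i < n; i++) {
      term[i] = p[i];
      acc[i] = wj * p[i];
    }
    int j = 0;
    while (j < jmax && (1.0 - total_w) > 1e-14) {
      j++;
      // tmp = P term
      for (int i = 0; i < n; i++) {
        double Av = -diagloss[i] * term[i];
        if (i > 0) Av += up[i - 1] * term[i - 1];
        if (i < n - 1) Av += down[i + 1] * term[i + 1];
        tmp[i] = term[i] + Av / Omega;
      }
      std::swap(term, tmp);
      wj *= a / j;
      total_w += wj;
      for (int i = 0; i < n; i++) acc[i] += wj * term[i];
    }
    p = acc;
  }
  return NumericVector(p.begin(), p.end());
}

// 2-D two-type (crown subtree A / B) physical master equation on counts
// (nA, nB), started from (1, 1); returns P(nA >= 1 and nB >= 1 at
// crown_age). lamn/mun give per-lineage rates at total count n = 1..2S
// (index n-1).
//
// State-space reduction: once both subtrees hold more than `safe`
// lineages, the probability that either subsequently dies out is at most
// E_max^safe (E_max < 1 the single-lineage extinction probability), which
// is negligible for safe ~ 20; such states absorb into a "both survive"
// mass. The tracked region is therefore the L-shaped union
// {nA <= S, nB <= safe} U {nA <= safe, nB <= S}, ~2*safe*S states instead
// of S^2. The big coordinate reflects at S (overflow counted as alive).
class LGrid {
 public:
  int S, c, d, csz, n_states;
  LGrid(int S_, int c_) : S(S_), c(c_), d(S_ + 1), csz(c_ + 1) {
    n_states = d * csz + csz * (S - c); // block1: b<=c; block2: b>c, a<=c
  }
  // -1 if (a,b) is outside the tracked region (i.e. both > c: safe)
  inline int idx(int a, int b) const {
    if (a > S || b > S) return -2; // beyond the cap (handled by caller)
    if (b <= c) return a + d * b;
    if (a <= c) return d * csz + a + csz * (b - c - 1);
    return -1;
  }
};

// [[Rcpp::export]]
double dd_crown_survival_cpp(NumericVector lamn, NumericVector mun, int S,
                             double crown_age, double boundary_tol,
                             int safe = 20) {
  int c = std::min(safe, S - 1);
  LGrid g(S, c);
  int N = g.n_states;
  std::vector<double> birthA(N), birthB(N), deathA(N), deathB(N),
      diagloss(N), toSafe(N);
  std::vector<int> upA(N, -1), upB(N, -1), dnA(N, -1), dnB(N, -1);
  std::vector<int> stA(N), stB(N);
  double Omega = 0.0;
  for (int aI = 0; aI <= S; aI++) {
    for (int b = 0; b <= S; b++) {
      int idx = g.idx(aI, b);
      if (idx < 0) continue;
      stA[idx] = aI;
      stB[idx] = b;
      int n = std::max(aI + b, 1);
      double la = lamn[n - 1], mu = mun[n - 1];
      double bA = (aI < S) ? aI * la : 0.0; // reflecting at the cap
      double bB = (b < S) ? b * la : 0.0;
      double dA = aI * mu, dB = b * mu;
      // a birth that lands in the both-safe corner absorbs
      int iA = g.idx(aI + 1, b);
      int iB = g.idx(aI, b + 1);
      double safe_rate = 0.0;
      if (bA > 0 && iA == -1) {
        safe_rate += bA;
        bA = 0.0;
      }
      if (bB > 0 && iB == -1) {
        safe_rate += bB;
        bB = 0.0;
      }
      birthA[idx] = bA;
      birthB[idx] = bB;
      deathA[idx] = dA;
      deathB[idx] = dB;
      toSafe[idx] = safe_rate;
      upA[idx] = (bA > 0) ? iA : -1;
      upB[idx] = (bB > 0) ? iB : -1;
      dnA[idx] = (aI > 0) ? g.idx(aI - 1, b) : -1;
      dnB[idx] = (b > 0) ? g.idx(aI, b - 1) : -1;
      diagloss[idx] = bA + bB + dA + dB + safe_rate;
      Omega = std::max(Omega, diagloss[idx]);
    }
  }
  Omega += 1e-12;
  int nchunk = std::max(1, (int)std::ceil(Omega * crown_age / 80.0));
  double a = Omega * crown_age / nchunk;
  int jmax = std::max(10, (int)std::ceil(a + 12.0 * std::sqrt(a) + 20.0));
  std::vector<double> P(N + 1, 0.0), term(N + 1), acc(N + 1), tmp(N + 1);
  // last entry is the absorbed both-safe mass
  P[g.idx(1, 1)] = 1.0;
  for (int ch = 0; ch < nchunk; ch++) {
    double wj = std::exp(-a);
    double total_w = wj;
    for (int i = 0; i <= N; i++) {
      term[i] = P[i];
      acc[i] = wj * P[i];
    }
    int j = 0;
    while (j < jmax && (1.0 - total_w) > 1e-13) {
      j++;
      for (int i = 0; i < N; i++) {
        double Av = -diagloss[i] * term[i];
        tmp[i] = Av; // filled below with inflows
      }
      tmp[N] = 0.0;
      for (int i = 0; i < N; i++) {
        double v = term[i];
        if (v != 0.0) {
          if (upA[i] >= 0) tmp[upA[i]] += birthA[i] * v;
          if (upB[i] >= 0) tmp[upB[i]] += birthB[i] * v;
          if (dnA[i] >= 0) tmp[dnA[i]] += deathA[i] * v;
          if (dnB[i] >= 0) tmp[dnB[i]] += deathB[i] * v;
          if (toSafe[i] > 0) tmp[N] += toSafe[i] * v;
        }
      }
      // deaths from a dead coordinate fall out of the region (extinct): lost
      for (int i = 0; i <= N; i++) tmp[i] = term[i] + tmp[i] / Omega;
      std::swap(term, tmp);
      wj *= a / j;
      total_w += wj;
      for (int i = 0; i <= N; i++) acc[i] += wj * term[i];
    }
    P = acc;
  }
  // boundary mass at the reflecting cap (big coordinate == S)
  double boundary = 0.0;
  for (int b = 0; b <= c; b++) boundary += P[g.idx(S, b)];
  for (int aI = 0; aI <= c; aI++) {
    int i2 = g.idx(aI, S);
    if (i2 >= 0) boundary += P[i2];
  }
  if (boundary > boundary_tol) return -1.0; // caller grows S
  double pboth = P[N];
  for (int i = 0; i < N; i++) {
    if (stA[i] >= 1 && stB[i] >= 1) pboth += P[i];
  }
  if (pboth < 1e-300) pboth = 1e-300;
  if (pboth > 1.0) pboth = 1.0;
  return pboth;
}
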