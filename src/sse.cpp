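#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// State-dependent speciation-extinction pruning on a binary ultrametric
// tree with an arbitrary cladogenetic tensor over k combined states.
//
// Along a branch, with age t increasing toward the root:
//   dE_s/dt = mu_s - (lambda_s + mu_s) E_s + (Q E)_s + sum_ij C[s,i,j] E_i E_j
//   dD_s/dt = -(lambda_s + mu_s) D_s + (Q D)_s + sum_ij C[s,i,j] (E_i D_j + D_i E_j)
// where Q has off-diagonal anagenetic rates and negative row sums on the
// diagonal, and C is the ordered-daughter-pair cladogenesis tensor with
// sum_ij C[s,i,j] = lambda_s. At internal nodes daughters combine through
// C; at the root the lambda factor is omitted (weights C/lambda).
//
// Integration: adaptive Cash-Karp Runge-Kutta 4(5).

struct SseSystem {
  int k;
  const double* lambda;
  const double* mu;
  const double* Q;     // k x k, column-major
  int nclado;
  const int* cs;       // parent state (0-based)
  const int* ci;       // daughter 1 state
  const int* cj;       // daughter 2 state
  const double* crate; // event rate

  // y = (E[0..k-1], D[0..k-1])
  void deriv(const std::vector<double>& y, std::vector<double>& dy) const {
    for (int s = 0; s < k; s++) {
      double qe = 0.0, qd = 0.0;
      for (int j = 0; j < k; j++) {
        qe += Q[s + k * j] * y[j];
        qd += Q[s + k * j] * y[k + j];
      }
      dy[s] = mu[s] - (lambda[s] + mu[s]) * y[s] + qe;
      dy[k + s] = -(lambda[s] + mu[s]) * y[k + s] + qd;
    }
    for (int e = 0; e < nclado; e++) {
      int s = cs[e], i = ci[e], j = cj[e];
      double r = crate[e];
      dy[s] += r * y[i] * y[j];
      dy[k + s] += r * (y[i] * y[k + j] + y[k + i] * y[j]);
    }
  }
};

// Cash-Karp coefficients
static const double ck_b[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592, 253.0 / 4096}};
static const double ck_c5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0, 512.0 / 1771};
static const double ck_c4[6] = {2825.0 / 27648, 0, 18575.0 / 48384, 13525.0 / 55296,
                                277.0 / 14336, 1.0 / 4};

// integrate y over [t0, t1]; returns false on failure
static bool integrate(const SseSystem& sys, std::vector<double>& y,
                      double t0, double t1, double rtol, double atol) {
  int n = 2 * sys.k;
  double span = t1 - t0;
  if (span <= 0) return true;
  double h = span / 10.0;
  double hmin = span * 1e-12 + 1e-14;
  double t = t0;
  std::vector<double> kst[6];
  for (int i = 0; i < 6; i++) kst[i].assign(n, 0.0);
  std::vector<double> ytmp(n), y5(n), y4(n);
  int nstep = 0;
  while (t < t1 - 1e-14 * span) {
    if (++nstep > 1000000) return false;
    if (t + h > t1) h = t1 - t;
    sys.deriv(y, kst[0]);
    for (int stage = 1; stage < 6; stage++) {
      for (int i = 0; i < n; i++) {
        double acc = y[i];
        for (int m = 0; m < stage; m++) acc += h * ck_b[stage][m] * kst[m][i];
        ytmp[i] = acc;
      }
      sys.deriv(ytmp, kst[stage]);
    }
    double errmax = 0.0;
    for (int i = 0; i < n; i++) {
      double d5 = 0.0, d4 = 0.0;
      for (int m = 0; m < 6; m++) {
        d5 += ck_c5[m] * kst[m][i];
        d4 += ck_c4[m] * kst[m][i];
      }
      y5[i] = y[i] + h * d5;
      y4[i] = y[i] + h * d4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      y = y5;
      double grow = (errmax > 1e-10) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (grow > 5.0) grow = 5.0;
      h *= grow;
    } else {
      double shrink = 0.9 * std::pow(errmax, -0.25);
      if (shrink < 0.1) shrink = 0.1;
      h *= shrink;
      if (h < hmin) return false;
    }
    for (int i = 0; i < n; i++) {
      if (!std::isfinite(y[i])) return false;
      if (i < sys.k) { // clamp E into [0, 1]
        if (y[i] < 0) y[i] = 0;
        if (y[i] > 1) y[i] = 1;
      } else if (y[i] < 0 && y[i] > -1e-13) {
        y[i] = 0;
      }
    }
  }
  return true;
}

// [[Rcpp::export]]
List sse_prune_cpp(IntegerMatrix edge, NumericVector t_child, NumericVector t_parent,
                   int n_tip, NumericVector lambda, NumericVector mu,
                   NumericMatrix Qm, IntegerVector cs, IntegerVector ci,
                   IntegerVector cj, NumericVector crate, NumericMatrix tipD,
                   NumericVector E0, NumericMatrix nodeMask,
                   double rtol, double atol) {
  int k = lambda.size();
  int n_edge = edge.nrow();
  int nn = n_tip + n_tip; // tips + internal (binary: n - 1 internal, root id n_tip+1)
  SseSystem sys{k, lambda.begin(), mu.begin(), Qm.begin(),
                (int)cs.size(), cs.begin(), ci.begin(), cj.begin(), crate.begin()};
  std::vector<std::vector<double>> storeE(nn + 1), storeD(nn + 1);
  std::vector<int> arrived(nn + 1, 0);
  double logscale = 0.0;
  int root = n_tip + 1;
  bool ok = true;

  for (int r = 0; r < n_edge && ok; r++) {
    int child = edge(r, 1);
    int parent = edge(r, 0);
    std::vector<double> y(2 * k);
    if (child <= n_tip) {
      for (int s = 0; s < k; s++) {
        y[s] = E0[s];
        y[k + s] = tipD(child - 1, s);
      }
    } else {
      if (arrived[child] != 2) { ok = false; break; }
      for (int s = 0; s < k; s++) {
        y[s] = storeE[child][s];
        y[k + s] = storeD[child][s];
      }
    }
    if (!integrate(sys, y, t_child[r], t_parent[r], rtol, atol)) { ok = false; break; }
    double sum = 0.0;
    for (int s = 0; s < k; s++) sum += y[k + s];
    if (!(sum > 0) || !std::isfinite(sum)) { ok = false; break; }
    for (int s = 0; s < k; s++) y[k + s] /= sum;
    logscale += std::log(sum);
    if (arrived[parent] == 0) {
      storeE[parent].assign(y.begin(), y.begin() + k);
      storeD[parent].assign(y.begin() + k, y.end());
      arrived[parent] = 1;
    } else {
      std::vector<double> Dnew(k, 0.0), Enew(k);
      for (int s = 0; s < k; s++) {
        Enew[s] = 0.5 * (storeE[parent][s] + y[s]);
      }
      for (int e = 0; e < sys.nclado; e++) {
        int s = cs[e], i = ci[e], j = cj[e];
        double r2 = crate[e];
        if (parent == root && lambda[s] > 0) r2 /= lambda[s];
        Dnew[s] += r2 * storeD[parent][i] * y[k + j];
      }
      int mrow = parent - n_tip - 1;
      double sum2 = 0.0;
      for (int s = 0; s < k; s++) {
        Dnew[s] *= nodeMask(mrow, s);
        sum2 += Dnew[s];
      }
      if (!(sum2 > 0) || !std::isfinite(sum2)) { ok = false; break; }
      for (int s = 0; s < k; s++) Dnew[s] /= sum2;
      logscale += std::log(sum2);
      storeE[parent] = Enew;
      storeD[parent] = Dnew;
      arrived[parent] = 2;
    }
  }
  if (!ok || arrived[root] != 2) {
    return List::create(Named("ok") = false);
  }
  return List::create(
    Named("ok") = true,
    Named("D_root") = NumericVector(storeD[root].begin(), storeD[root].end()),
    Named("E_root") = NumericVector(storeE[root].begin(), storeE[root].end()),
    Named("logscale") = logscale);
}
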