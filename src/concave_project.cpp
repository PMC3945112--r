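#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Weighted Euclidean projection of v onto the cone of concave sequences
//   C = { u : u_i - 2 u_{i+1} + u_{i+2} <= 0,  i = 0..m-1 },  m = K - 2.
//
// Solved through the dual: u = v - W^{-1} D' mu with mu >= 0, where D is
// the second-difference operator. The dual is a nonnegative least-squares
// problem with pentadiagonal normal matrix Q = D W^{-1} D'. Strategy:
// block principal pivoting (Portugal-Judice-Vicente), where whole blocks
// of constraints enter and leave the working set per iteration — typically
// a few dozen banded solves — falling back to the classical Lawson-Hanson
// single-pivot iteration (monotone, cycle-free) if pivoting stalls on an
// adversarial input. Working-set systems keep bandwidth 2 under
// compressed indexing, so every solve is a banded Cholesky in O(|P|).

namespace {

struct BandChol {
  int n;
  std::vector<double> d0, d1, d2;
  bool factor(const std::vector<double>& a0, const std::vector<double>& a1,
              const std::vector<double>& a2) {
    n = (int)a0.size();
    d0.assign(n, 0.0); d1.assign(std::max(n - 1, 0), 0.0);
    d2.assign(std::max(n - 2, 0), 0.0);
    for (int i = 0; i < n; ++i) {
      double s = a0[i];
      if (i >= 1) s -= d1[i - 1] * d1[i - 1];
      if (i >= 2) s -= d2[i - 2] * d2[i - 2];
      if (s <= 0.0 || !std::isfinite(s)) return false;
      d0[i] = std::sqrt(s);
      if (i + 1 < n) {
        double s1 = a1[i];
        if (i >= 1) s1 -= d1[i - 1] * d2[i - 1];
        d1[i] = s1 / d0[i];
      }
      if (i + 2 < n) d2[i] = a2[i] / d0[i];
    }
    return true;
  }
  void solve(std::vector<double>& x) const {
    for (int i = 0; i < n; ++i) {
      double s = x[i];
      if (i >= 1) s -= d1[i - 1] * x[i - 1];
      if (i >= 2) s -= d2[i - 2] * x[i - 2];
      x[i] = s / d0[i];
    }
    for (int i = n - 1; i >= 0; --i) {
      double s = x[i];
      if (i + 1 < n) s -= d1[i] * x[i + 1];
      if (i + 2 < n) s -= d2[i] * x[i + 2];
      x[i] = s / d0[i];
    }
  }
};

struct Projector {
  int K, m;
  const double* v;
  std::vector<double> wi;          // 1 / w
  std::vector<double> q0, q1, q2;  // pentadiagonal Q = D W^{-1} D'
  std::vector<double> b;           // D v
  std::vector<double> mu, u, r, z;
  std::vector<char> inP;
  std::vector<int> P;
  BandChol chol;
  double tol;

  Projector(const double* v_, const double* w_, int K_, double tol_)
      : K(K_), m(K_ - 2), v(v_), tol(tol_) {
    wi.resize(K);
    for (int j = 0; j < K; ++j) wi[j] = 1.0 / w_[j];
    q0.resize(m); q1.resize(std::max(m - 1, 0)); q2.resize(std::max(m - 2, 0));
    b.resize(m);
    for (int i = 0; i < m; ++i) {
      q0[i] = wi[i] + 4.0 * wi[i + 1] + wi[i + 2];
      b[i] = v[i] - 2.0 * v[i + 1] + v[i + 2];
      if (i + 1 < m) q1[i] = -2.0 * wi[i + 1] - 2.0 * wi[i + 2];
      if (i + 2 < m) q2[i] = wi[i + 2];
    }
    mu.assign(m, 0.0); u.assign(K, 0.0); r.assign(m, 0.0);
    inP.assign(m, 0);
  }

  double qEntry(int i, int j) const {
    int lo = std::min(i, j), d = std::abs(i - j);
    if (d == 0) return q0[lo];
    if (d == 1) return q1[lo];
    if (d == 2) return q2[lo];
    return 0.0;
  }

  bool solvePassive() {
    P.clear();
    for (int i = 0; i < m; ++i) if (inP[i]) P.push_back(i);
    int n = (int)P.size();
    z.assign(n, 0.0);
    if (n == 0) return true;
    std::vector<double> a0(n), a1(std::max(n - 1, 0)), a2(std::max(n - 2, 0));
    for (int a = 0; a < n; ++a) {
      a0[a] = qEntry(P[a], P[a]);
      if (a + 1 < n) a1[a] = qEntry(P[a], P[a + 1]);
      if (a + 2 < n) a2[a] = qEntry(P[a], P[a + 2]);
    }
    if (!chol.factor(a0, a1, a2)) return false;
    std::vector<double> rhs(n), res(n);
    for (int a = 0; a < n; ++a) rhs[a] = b[P[a]];
    z = rhs;
    chol.solve(z);
    for (int refine = 0; refine < 4; ++refine) {
      for (int a = 0; a < n; ++a) {
        double s = 0.0;
        for (int c = std::max(0, a - 2); c <= std::min(n - 1, a + 2); ++c)
          s += qEntry(P[a], P[c]) * z[c];
        res[a] = rhs[a] - s;
      }
      chol.solve(res);
      for (int a = 0; a < n; ++a) z[a] += res[a];
    }
    return true;
  }

  void computeU() {
    for (int j = 0; j < K; ++j) {
      double t = 0.0;
      if (j - 2 >= 0 && j - 2 < m) t += mu[j - 2];
      if (j - 1 >= 0 && j - 1 < m) t -= 2.0 * mu[j - 1];
      if (j < m) t += mu[j];
      u[j] = v[j] - wi[j] * t;
    }
    for (int i = 0; i < m; ++i) r[i] = u[i] - 2.0 * u[i + 1] + u[i + 2];
  }

  double muScale() const {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s = std::max(s, std::abs(mu[i]));
    return s;
  }
  // cancellation in u = v - W^{-1} D' mu bounds the attainable residual
  double primalTol() const { return std::max(tol, 1e-13 * muScale()); }

  bool blockPivot(int maxOuter, int& iter) {
    int ninfBest = m + 1, backup = 3, stall = 0;
    for (; iter < maxOuter; ++iter) {
      if (!solvePassive()) {
        int worst = -1; double mn = R_PosInf;
        for (int i = 0; i < m; ++i)
          if (inP[i] && mu[i] < mn) { mn = mu[i]; worst = i; }
        if (worst < 0) return false;
        inP[worst] = 0;
        continue;
      }
      std::fill(mu.begin(), mu.end(), 0.0);
      double zmax = 0.0;
      for (size_t a = 0; a < P.size(); ++a) {
        mu[P[a]] = z[a];
        zmax = std::max(zmax, std::abs(z[a]));
      }
      computeU();
      double dTol = std::max(tol, 1e-11 * zmax);
      double pTol = std::max(tol, 1e-13 * zmax);
      std::vector<int> H1, H2;
      for (size_t a = 0; a < P.size(); ++a)
        if (z[a] < -dTol) H1.push_back(P[a]);
      for (int i = 0; i < m; ++i)
        if (!inP[i] && r[i] > pTol) H2.push_back(i);
      int ninf = (int)(H1.size() + H2.size());
      if (ninf == 0) {
        for (int i = 0; i < m; ++i) if (mu[i] < 0.0) mu[i] = 0.0;
        computeU();
        return true;
      }
      if (ninf < ninfBest) { ninfBest = ninf; backup = 3; stall = 0; }
      else if (backup > 0) { --backup; ++stall; }
      else ++stall;
      if (stall > 100) return false;
      if (backup > 0 || ninf == 1) {
        for (int i : H1) inP[i] = 0;
        for (int i : H2) inP[i] = 1;
      } else {
        int last = -1;
        if (!H1.empty()) last = H1.back();
        if (!H2.empty()) last = std::max(last, H2.back());
        inP[last] = !inP[last];
      }
    }
    return false;
  }

  // solve the passive set and restore dual feasibility by line steps
  void restoreFeasible() {
    int guard = 0;
    while (true) {
      if (!solvePassive()) {
        // numerically singular: drop the smallest multiplier and retry
        int worst = -1; double mn = R_PosInf;
        for (int i = 0; i < m; ++i)
          if (inP[i] && mu[i] < mn) { mn = mu[i]; worst = i; }
        if (worst < 0) break;
        inP[worst] = 0;
        if (++guard > m + 10) break;
        continue;
      }
      int n = (int)P.size();
      double alpha = 1.0; int blockA = -1;
      for (int a = 0; a < n; ++a) {
        if (z[a] <= 0.0) {
          double denom = mu[P[a]] - z[a];
          double step = (denom > 0) ? mu[P[a]] / denom : 0.0;
          if (step < alpha) { alpha = step; blockA = a; }
        }
      }
      if (blockA < 0) {
        for (int a = 0; a < n; ++a) mu[P[a]] = z[a];
        break;
      }
      for (int a = 0; a < n; ++a)
        mu[P[a]] = std::max(0.0, mu[P[a]] + alpha * (z[a] - mu[P[a]]));
      mu[P[blockA]] = 0.0;
      for (int a = 0; a < n; ++a) if (mu[P[a]] <= 0.0) inP[P[a]] = 0;
      inP[P[blockA]] = 0;
      if (++guard > m + 10) break;
    }
  }

  // classical Lawson-Hanson: one constraint enters per outer step, dual
  // feasibility restored by line steps; monotone and cycle-free. Starts
  // from the current (clamped) multipliers, so a near-solution left by
  // the block phase costs only the missing pivots.
  bool lawsonHanson(int maxOuter, int& iter) {
    for (int i = 0; i < m; ++i) {
      if (mu[i] < 0.0) mu[i] = 0.0;
      inP[i] = mu[i] > 0.0 ? 1 : 0;
    }
    restoreFeasible();
    computeU();
    for (; iter < maxOuter; ++iter) {
      double pTol = primalTol();
      int worst = -1; double wv = pTol;
      for (int i = 0; i < m; ++i)
        if (!inP[i] && r[i] > wv) { wv = r[i]; worst = i; }
      if (worst < 0) return true;
      inP[worst] = 1;
      restoreFeasible();
      computeU();
    }
    return false;
  }
};

} // namespace

// [[Rcpp::export(name = ".concaveProjectCpp")]]
List concaveProjectCpp(NumericVector v, NumericVector w, double tol,
                       int maxOuter, NumericVector muInit) {
  const int K = v.size();
  if (K <= 2) {
    return List::create(_["u"] = clone(v),
                        _["mu"] = NumericVector(std::max(K - 2, 0)),
                        _["iterations"] = 0, _["converged"] = true,
                        _["maxViolation"] = 0.0);
  }
  Projector prj(v.begin(), w.begin(), K, tol);
  if (muInit.size() == prj.m)
    for (int i = 0; i < prj.m; ++i) if (muInit[i] > 0.0) prj.inP[i] = 1;
  if (maxOuter <= 0) maxOuter = 3 * prj.m + 500;
  int iter = 0;
  bool ok = prj.blockPivot(maxOuter, iter);
  if (!ok) ok = prj.lawsonHanson(maxOuter + 10 * prj.m, iter);
  double maxViol = 0.0;
  for (int i = 0; i < prj.m; ++i) maxViol = std::max(maxViol, prj.r[i]);
  bool converged = ok || maxViol <= prj.primalTol();
  NumericVector uOut(prj.u.begin(), prj.u.end());
  NumericVector muOut(prj.mu.begin(), prj.mu.end());
  return List::create(_["u"] = uOut, _["mu"] = muOut, _["iterations"] = iter,
                      _["converged"] = converged, _["maxViolation"] = maxViol);
}
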