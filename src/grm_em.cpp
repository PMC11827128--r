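// Inner loops of the marginal maximum likelihood (EM) machinery:
//  - a fused E-step that builds the category log-probability tables and
//    accumulates expected category-by-node counts in one pass, and
//  - a safeguarded Newton M-step on the unconstrained item
//    parameterization (log slope, first threshold, log threshold gaps).
// The line search never accepts a step that lowers the expected
// complete-data log-likelihood, so the EM ascent property is preserved.

#include <Rcpp.h>
using namespace Rcpp;

static const double PROB_FLOOR = 1e-12;

static inline double logistic(double z) {
  return 1.0 / (1.0 + std::exp(-z));
}

// Fused E-step for one group.
// resp: n x I (1..K, complete); a: I slopes; b: I x (K-1) thresholds;
// grid: Q nodes; logw: log prior weights.
// [[Rcpp::export(name = ".estep_cpp")]]
List estep_cpp(const IntegerMatrix& resp, const NumericVector& a,
               const NumericMatrix& b, const NumericVector& grid,
               const NumericVector& logw) {
  const int n = resp.nrow(), ni = resp.ncol(), nq = grid.size();
  const int nb = b.ncol(), k = nb + 1;
  // per-item K x Q tables, column-major within item
  std::vector<double> logp((size_t)ni * k * nq), prob((size_t)ni * k * nq);
  for (int i = 0; i < ni; ++i) {
    double* lp = &logp[(size_t)i * k * nq];
    double* pp = &prob[(size_t)i * k * nq];
    for (int q = 0; q < nq; ++q) {
      double prev = 1.0;
      for (int c = 0; c < k; ++c) {
        const double cur = (c == nb) ? 0.0
          : logistic(a[i] * (grid[q] - b(i, c)));
        double p = prev - cur;
        if (p < PROB_FLOOR) p = PROB_FLOOR;
        pp[c + k * q] = p;
        lp[c + k * q] = std::log(p);
        prev = cur;
      }
    }
  }
  std::vector<double> counts((size_t)ni * k * nq, 0.0);
  NumericVector em(n), ev(n);
  double ll = 0.0;
  std::vector<double> row(nq);
  for (int j = 0; j < n; ++j) {
    for (int q = 0; q < nq; ++q) row[q] = logw[q];
    for (int i = 0; i < ni; ++i) {
      const double* lp = &logp[(size_t)i * k * nq];
      const int x = resp(j, i) - 1;
      for (int q = 0; q < nq; ++q) row[q] += lp[x + k * q];
    }
    double m = row[0];
    for (int q = 1; q < nq; ++q) if (row[q] > m) m = row[q];
    double s = 0.0;
    for (int q = 0; q < nq; ++q) { row[q] = std::exp(row[q] - m); s += row[q]; }
    ll += m + std::log(s);
    double e1 = 0.0, e2 = 0.0;
    for (int q = 0; q < nq; ++q) {
      const double p = row[q] / s;
      row[q] = p;
      e1 += p * grid[q];
      e2 += p * grid[q] * grid[q];
    }
    em[j] = e1; ev[j] = e2;
    for (int i = 0; i < ni; ++i) {
      double* ct = &counts[(size_t)i * k * nq];
      const int x = resp(j, i) - 1;
      for (int q = 0; q < nq; ++q) ct[x + k * q] += row[q];
    }
  }
  List clist(ni);
  for (int i = 0; i < ni; ++i) {
    NumericMatrix r(k, nq);
    std::copy(counts.begin() + (size_t)i * k * nq,
              counts.begin() + (size_t)(i + 1) * k * nq, REAL(r));
    clist[i] = r;
  }
  return List::create(_["ll"] = ll, _["counts"] = clist,
                      _["e_theta"] = em, _["e_theta2"] = ev);
}

// Expected complete-data log-likelihood of one item and its analytic
// gradient on the unconstrained scale par = (log a, b_1, log gaps).
static double objgrad(const double* par, int k, const double* r,
                      const double* grid, int nq, double* grad) {
  const int nb = k - 1;
  const double a = std::exp(par[0]);
  std::vector<double> b(nb);
  b[0] = par[1];
  for (int m = 1; m < nb; ++m) b[m] = b[m - 1] + std::exp(par[1 + m]);
  double f = 0.0, dfda = 0.0;
  std::vector<double> dfdb(nb, 0.0), ps(nb), pq(nb), w(k);
  for (int q = 0; q < nq; ++q) {
    const double th = grid[q];
    for (int m = 0; m < nb; ++m) {
      ps[m] = logistic(a * (th - b[m]));
      pq[m] = ps[m] * (1.0 - ps[m]);
    }
    for (int c = 0; c < k; ++c) {
      const double hi = (c == 0) ? 1.0 : ps[c - 1];
      const double lo = (c == nb) ? 0.0 : ps[c];
      double p = hi - lo;
      if (p < PROB_FLOOR) p = PROB_FLOOR;
      const double rc = r[c + k * q];
      if (rc > 0.0) f += rc * std::log(p);
      w[c] = rc / p;
    }
    if (grad) {
      for (int m = 0; m < nb; ++m) {
        const double d = w[m + 1] - w[m]; // df/dP*_m
        dfda += d * pq[m] * (th - b[m]);
        dfdb[m] += d * (-a) * pq[m];
      }
    }
  }
  if (grad) {
    grad[0] = a * dfda;
    double tail = 0.0;
    for (int m = nb - 1; m >= 1; --m) { // chain rule through the log gaps
      tail += dfdb[m];
      grad[1 + m] = std::exp(par[1 + m]) * tail;
    }
    grad[1] = tail + dfdb[0]; // b_1 shifts every threshold
  }
  return f;
}

// [[Rcpp::export(name = ".item_objgrad_cpp")]]
List item_objgrad_cpp(const NumericVector& par, const NumericMatrix& r,
                      const NumericVector& grid) {
  const int k = r.nrow();
  NumericVector grad(par.size());
  const double f = objgrad(REAL(par), k, REAL(r), REAL(grid), r.ncol(),
                           REAL(grad));
  return List::create(_["value"] = f, _["gradient"] = grad);
}

// Solve A x = g for symmetric positive-definite A by Cholesky (tiny dense
// system). Returns false if A is not numerically positive definite --
// i.e. the curvature does not certify a local maximum, in which case the
// caller falls back to a gradient step.
static bool solve_spd(std::vector<double>& A, std::vector<double>& g,
                      int p) {
  for (int c = 0; c < p; ++c) {
    double d = A[c + p * c];
    for (int kk = 0; kk < c; ++kk) d -= A[c + p * kk] * A[c + p * kk];
    if (d <= 1e-12) return false;
    d = std::sqrt(d);
    A[c + p * c] = d;
    for (int rw = c + 1; rw < p; ++rw) {
      double s = A[rw + p * c];
      for (int kk = 0; kk < c; ++kk) s -= A[rw + p * kk] * A[c + p * kk];
      A[rw + p * c] = s / d;
    }
  }
  for (int rw = 0; rw < p; ++rw) { // forward substitution
    double s = g[rw];
    for (int cc = 0; cc < rw; ++cc) s -= A[rw + p * cc] * g[cc];
    g[rw] = s / A[rw + p * rw];
  }
  for (int rw = p - 1; rw >= 0; --rw) { // back substitution
    double s = g[rw];
    for (int cc = rw + 1; cc < p; ++cc) s -= A[cc + p * rw] * g[cc];
    g[rw] = s / A[rw + p * rw];
  }
  return true;
}

// Safeguarded Newton ascent of the expected complete-data log-likelihood:
// Hessian by forward differences of the analytic gradient, step halving
// until the objective does not decrease (generalized-EM guarantee).
// [[Rcpp::export(name = ".mstep_newton_cpp")]]
NumericVector mstep_newton_cpp(const NumericVector& par0,
                               const NumericMatrix& r,
                               const NumericVector& grid,
                               const int max_steps = 6,
                               const double gtol = 1e-7) {
  const int p = par0.size(), k = r.nrow(), nq = r.ncol();
  const double* rp = REAL(r);
  const double* gp = REAL(grid);
  std::vector<double> par(par0.begin(), par0.end());
  std::vector<double> grad(p), gph(p), H(p * p), step(p), trial(p);
  double f = objgrad(par.data(), k, rp, gp, nq, grad.data());
  const double h = 1e-5;
  for (int it = 0; it < max_steps; ++it) {
    double gmax = 0.0;
    for (int d = 0; d < p; ++d) gmax = std::max(gmax, std::fabs(grad[d]));
    if (gmax < gtol) break;
    for (int d = 0; d < p; ++d) {
      trial = par;
      trial[d] += h;
      objgrad(trial.data(), k, rp, gp, nq, gph.data());
      for (int rr = 0; rr < p; ++rr) H[rr + p * d] = (gph[rr] - grad[rr]) / h;
    }
    // symmetrize, negate and ridge: solve (-H + lambda I) step = grad
    std::vector<double> A(p * p);
    double dmax = 0.0;
    for (int d = 0; d < p; ++d) dmax = std::max(dmax, std::fabs(H[d + p * d]));
    const double ridge = 1e-6 * std::max(dmax, 1.0);
    for (int rr = 0; rr < p; ++rr) {
      for (int cc = 0; cc < p; ++cc) {
        A[rr + p * cc] = -0.5 * (H[rr + p * cc] + H[cc + p * rr]);
      }
      A[rr + p * rr] += ridge;
    }
    step.assign(grad.begin(), grad.end());
    bool ok = solve_spd(A, step, p);
    if (!ok) { // gradient fallback, modest scale
      double gn = 0.0;
      for (int d = 0; d < p; ++d) gn += grad[d] * grad[d];
      gn = std::sqrt(gn);
      for (int d = 0; d < p; ++d) step[d] = grad[d] / std::max(gn, 1.0);
    }
    // trust-region-style cap keeps flat directions from running away
    double smax = 0.0;
    for (int d = 0; d < p; ++d) smax = std::max(smax, std::fabs(step[d]));
    if (smax > 1.0) for (int d = 0; d < p; ++d) step[d] /= smax;
    double dot = 0.0;
    for (int d = 0; d < p; ++d) dot += step[d] * grad[d];
    if (dot < gtol * gtol) break; // numerically flat: stay put
    double t = 1.0, fnew = -HUGE_VAL;
    bool accepted = false;
    for (int ls = 0; ls < 25; ++ls) {
      for (int d = 0; d < p; ++d) trial[d] = par[d] + t * step[d];
      fnew = objgrad(trial.data(), k, rp, gp, nq, gph.data());
      if (fnew >= f + 1e-4 * t * dot) { accepted = true; break; } // Armijo
      t *= 0.5;
    }
    if (!accepted) break;
    par = trial;
    grad = gph;
    if (fnew - f < 1e-10 * (std::fabs(f) + 1.0)) { f = fnew; break; }
    f = fnew;
  }
  return NumericVector(par.begin(), par.end());
}
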