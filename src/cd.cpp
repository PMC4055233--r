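#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Penalty kinds: 0 = lasso, 1 = scad, 2 = sica.
// Penalty value p_lambda(theta) = lam * rho(theta), theta >= 0.
// SCAD's rho is the integral of its printed derivative
// rho'(t) = I(t <= lam) + (a*lam - t)_+ / ((a-1)*lam) * I(t > lam),
// so p_lambda is linear, then quadratic, then constant lam^2*(a+1)/2.

static double pen_value(int kind, double lam, double a, double t) {
  if (t < 0.0) t = -t;
  if (lam == 0.0) return 0.0;
  switch (kind) {
  case 0:
    return lam * t;
  case 1: {
    if (t <= lam) return lam * t;
    double al = a * lam;
    if (t >= al) return lam * lam * (a + 1.0) / 2.0;
    return (2.0 * al * t - t * t - lam * lam) / (2.0 * (a - 1.0));
  }
  case 2:
    return lam * (a + 1.0) * t / (a + t);
  }
  return NA_REAL;
}

// objective of the one-dimensional subproblem
static inline double uni_obj(int kind, double lam, double a,
                             double v, double vjj, double b) {
  return 0.5 * vjj * b * b - v * b + pen_value(kind, lam, a, std::fabs(b));
}

// real roots of c3 x^3 + c2 x^2 + c1 x + c0 = 0 (c3 != 0), Cardano /
// trigonometric form; roots written into out[], count returned
static int cubic_roots(double c3, double c2, double c1, double c0,
                       double out[3]) {
  double p2 = c2 / c3, p1 = c1 / c3, p0 = c0 / c3;
  // depressed cubic t^3 + pt + q, x = t - p2/3
  double shift = p2 / 3.0;
  double p = p1 - p2 * p2 / 3.0;
  double q = 2.0 * p2 * p2 * p2 / 27.0 - p2 * p1 / 3.0 + p0;
  double disc = q * q / 4.0 + p * p * p / 27.0;
  int nr = 0;
  if (disc > 0.0) {
    double sq = std::sqrt(disc);
    double u = std::cbrt(-q / 2.0 + sq);
    double w = std::cbrt(-q / 2.0 - sq);
    out[nr++] = u + w - shift;
  } else if (disc == 0.0) {
    double u = std::cbrt(-q / 2.0);
    out[nr++] = 2.0 * u - shift;
    out[nr++] = -u - shift;
  } else {
    double r = std::sqrt(-p * p * p / 27.0);
    double phi = std::acos(std::min(1.0, std::max(-1.0, -q / (2.0 * r))));
    double m = 2.0 * std::sqrt(-p / 3.0);
    for (int k = 0; k < 3; ++k) {
      out[nr++] = m * std::cos((phi + 2.0 * M_PI * k) / 3.0) - shift;
    }
  }
  return nr;
}

// Exact minimizer of 0.5*vjj*b^2 - v*b + p_lambda(|b|).
// Ties between 0 and a nonzero candidate resolve to 0.
// [[Rcpp::export(name = ".cd_uni_min")]]
double cd_uni_min(int kind, double lam, double a, double v, double vjj) {
  if (vjj <= 0.0) stop("vjj must be > 0");
  if (lam == 0.0) return v / vjj;
  double s = (v >= 0.0) ? 1.0 : -1.0;
  double va = std::fabs(v);
  if (kind == 0) {  // lasso: closed-form soft threshold
    double st = va - lam;
    return (st > 0.0) ? s * st / vjj : 0.0;
  }
  // enumerate stationary points of the smooth pieces on b > 0 (for |v|)
  double cand[8];
  int nc = 0;
  if (kind == 1) {  // scad
    double al = a * lam;
    double b1 = (va - lam) / vjj;                       // piece (0, lam]
    if (b1 > 0.0 && b1 <= lam) cand[nc++] = b1;
    double den = vjj * (a - 1.0) - 1.0;                 // piece (lam, a*lam]
    if (den != 0.0) {
      double b2 = (va * (a - 1.0) - al) / den;
      if (b2 > lam && b2 <= al) cand[nc++] = b2;
    }
    double b3 = va / vjj;                               // piece (a*lam, inf)
    if (b3 >= al) cand[nc++] = b3;
    cand[nc++] = lam;                                   // piece boundaries
    cand[nc++] = al;
  } else {          // sica: (vjj*b - v)(a+b)^2 + lam*a*(a+1) = 0, b > 0
    double roots[3];
    double c3 = vjj;
    double c2 = 2.0 * a * vjj - va;
    double c1 = a * a * vjj - 2.0 * a * va;
    double c0 = lam * a * (a + 1.0) - va * a * a;
    int nr = cubic_roots(c3, c2, c1, c0, roots);
    for (int k = 0; k < nr; ++k) {
      if (roots[k] > 0.0 && R_finite(roots[k])) {
        // one Newton polish step on the stationarity equation
        double b = roots[k];
        for (int it = 0; it < 2; ++it) {
          double ab = a + b;
          double f = vjj * b - va + lam * a * (a + 1.0) / (ab * ab);
          double fp = vjj - 2.0 * lam * a * (a + 1.0) / (ab * ab * ab);
          if (fp != 0.0) {
            double bn = b - f / fp;
            if (bn > 0.0 && R_finite(bn)) b = bn;
          }
        }
        cand[nc++] = b;
      }
    }
  }
  double best = 0.0, bestobj = 0.0;  // objective at b = 0 is exactly 0
  for (int k = 0; k < nc; ++k) {
    double obj = uni_obj(kind, lam, a, va, vjj, cand[k]);
    if (obj < bestobj) {
      bestobj = obj;
      best = cand[k];
    }
  }
  return s * best;
}

// [[Rcpp::export(name = ".cd_pen_value")]]
NumericVector cd_pen_value(int kind, double lam, double a,
                           NumericVector theta) {
  int m = theta.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    if (theta[i] < 0) stop("theta must be >= 0");
    out[i] = pen_value(kind, lam, a, theta[i]);
  }
  return out;
}

static double full_objective(int kind, double lam, double a,
                             const std::vector<double>& beta,
                             const NumericVector& b,
                             const std::vector<double>& r) {
  // L(beta) = -0.5*beta'b - 0.5*beta'r  with  r = b - V beta
  int p = (int) beta.size();
  double L = 0.0, P = 0.0;
  for (int j = 0; j < p; ++j) {
    L += beta[j] * (b[j] + r[j]);
    if (beta[j] != 0.0) P += pen_value(kind, lam, a, std::fabs(beta[j]));
  }
  return -0.5 * L + P;
}

// Column access for V: either a precomputed dense matrix, or lazy
// reconstruction from the factorization n*V = Z'diag(w)Z - S'diag(ck)S
// with per-column caching (only columns of coordinates that ever move
// are materialized -- the memory- and time-saver for p >> n).
struct ColSource {
  int p;
  // dense backend
  const double* V = nullptr;
  // lazy backend
  const double* Z = nullptr;   // n x p
  const double* w = nullptr;   // n
  const double* S = nullptr;   // K x p
  const double* ck = nullptr;  // K
  int n = 0, K = 0;
  double nscale = 1.0;
  std::vector<double> diag_;
  std::vector<std::vector<double> > cache;

  double diag(int j) const { return V ? V[(size_t) j * p + j] : diag_[j]; }

  const double* col(int j) {
    if (V) return V + (size_t) j * p;
    std::vector<double>& c = cache[j];
    if (c.empty()) {
      c.assign(p, 0.0);
      // Z' (w .* Z[,j])
      std::vector<double> wz(n), cs(K);
      const double* zj = Z + (size_t) j * n;
      for (int i = 0; i < n; ++i) wz[i] = w[i] * zj[i];
      const double* sj = S + (size_t) j * K;
      for (int k = 0; k < K; ++k) cs[k] = ck[k] * sj[k];
      for (int q = 0; q < p; ++q) {
        const double* zq = Z + (size_t) q * n;
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += zq[i] * wz[i];
        const double* sq = S + (size_t) q * K;
        for (int k = 0; k < K; ++k) acc -= sq[k] * cs[k];
        c[q] = acc / nscale;
      }
    }
    return c.data();
  }
};

struct CdResult {
  double objective = 0.0;
  std::vector<double> trace;
  int sweeps = 0;
  bool converged = false;
};

// One penalized solve, operating in place on (beta, r) with r = b - V beta
// maintained as an invariant (so warm starts across a lambda path reuse
// both the iterate and the residual).
static CdResult cd_run(const NumericVector& b, ColSource& M,
                       std::vector<double>& beta, std::vector<double>& r,
                       int kind, double lam, double a, double tol,
                       int max_sweeps, bool active_set) {
  int p = b.size();
  CdResult out;
  std::vector<double>& trace = out.trace;
  bool& converged = out.converged;
  int& sweeps = out.sweeps;
  auto sweep_set = [&](const std::vector<int>& idx) -> double {
    double maxchg = 0.0;
    for (size_t q = 0; q < idx.size(); ++q) {
      int j = idx[q];
      double vjj = M.diag(j);
      if (vjj <= 0.0) { continue; }  // no information: frozen at 0
      double v = r[j] + vjj * beta[j];
      double bn = cd_uni_min(kind, lam, a, v, vjj);
      double delta = bn - beta[j];
      if (delta != 0.0) {
        beta[j] = bn;
        const double* col = M.col(j);
        for (int k = 0; k < p; ++k) r[k] -= delta * col[k];
        double ad = std::fabs(delta);
        if (ad > maxchg) maxchg = ad;
      }
    }
    return maxchg;
  };
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int full_done = 0;
  while (sweeps < max_sweeps) {
    double maxchg;
    if (active_set && full_done >= 2) {
      // iterate on the current nonzero set over a compact copy of the
      // active submatrix of V (cache-friendly, O(|A|^2) per sweep),
      // then confirm with a full KKT sweep
      std::vector<int> act;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
      int m = (int) act.size();
      if (m > 0) {
        std::vector<double> Vaa((size_t) m * m), ra(m), ba(m), bold(m);
        for (int q = 0; q < m; ++q) {
          int j = act[q];
          ra[q] = r[j];
          bold[q] = beta[j];
          ba[q] = beta[j];
          const double* col = M.col(j);
          for (int s = 0; s < m; ++s) Vaa[(size_t) q * m + s] = col[act[s]];
        }
        while (sweeps < max_sweeps) {
          double chg = 0.0;
          for (int q = 0; q < m; ++q) {
            double vjj = M.diag(act[q]);
            if (vjj <= 0.0) continue;
            double v = ra[q] + vjj * ba[q];
            double bn = cd_uni_min(kind, lam, a, v, vjj);
            double delta = bn - ba[q];
            if (delta != 0.0) {
              ba[q] = bn;
              const double* col = &Vaa[(size_t) q * m];
              for (int s = 0; s < m; ++s) ra[s] -= delta * col[s];
              double ad = std::fabs(delta);
              if (ad > chg) chg = ad;
            }
          }
          ++sweeps;
          if (chg < tol) break;
        }
        // push net changes back into beta and the full residual
        for (int q = 0; q < m; ++q) {
          double delta = ba[q] - bold[q];
          if (delta != 0.0) {
            int j = act[q];
            beta[j] = ba[q];
            const double* col = M.col(j);
            for (int k = 0; k < p; ++k) r[k] -= delta * col[k];
          }
        }
        trace.push_back(full_objective(kind, lam, a, beta, b, r));
      }
      if (sweeps >= max_sweeps) break;
      maxchg = sweep_set(all);
      ++full_done;
    } else {
      maxchg = sweep_set(all);
      ++full_done;
    }
    ++sweeps;
    double obj = full_objective(kind, lam, a, beta, b, r);
    if (!R_finite(obj)) stop("non-finite objective at sweep %d", sweeps);
    trace.push_back(obj);
    if (maxchg < tol) { converged = true; break; }
  }
  for (int j = 0; j < p; ++j) {
    if (!R_finite(beta[j])) stop("non-finite coefficient at sweep %d", sweeps);
  }
  out.objective = trace.empty() ? 0.0 : trace.back();
  return out;
}

static List cd_fit_list(const NumericVector& b, ColSource& M, int kind,
                        double lam, double a, NumericVector beta_init,
                        double tol, int max_sweeps, bool active_set) {
  int p = b.size();
  std::vector<double> beta(REAL(beta_init), REAL(beta_init) + p);
  std::vector<double> r(REAL(b), REAL(b) + p);
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double* col = M.col(j);
      for (int k = 0; k < p; ++k) r[k] -= beta[j] * col[k];
    }
  }
  CdResult res = cd_run(b, M, beta, r, kind, lam, a, tol, max_sweeps,
                        active_set);
  return List::create(
      _["beta"] = NumericVector(beta.begin(), beta.end()),
      _["residual"] = NumericVector(r.begin(), r.end()),
      _["objective"] = res.objective,
      _["objective_trace"] = NumericVector(res.trace.begin(),
                                           res.trace.end()),
      _["sweeps"] = res.sweeps,
      _["converged"] = res.converged);
}

// Cyclic coordinate descent on Q(beta) = 0.5 beta'V beta - b'beta +
// sum_j p_lambda(|beta_j|) with V supplied dense.
// [[Rcpp::export(name = ".cd_solve")]]
List cd_solve(NumericVector b, NumericMatrix V, int kind, double lam,
              double a, NumericVector beta_init, double tol,
              int max_sweeps, bool active_set) {
  int p = b.size();
  if (V.nrow() != p || V.ncol() != p) stop("dimension mismatch between b and V");
  ColSource M;
  M.p = p;
  M.V = REAL(V);
  return cd_fit_list(b, M, kind, lam, a, beta_init, tol, max_sweeps,
                     active_set);
}

static ColSource lazy_source(NumericVector b, NumericVector Vdiag,
                             NumericMatrix Z, NumericVector w,
                             NumericMatrix S, NumericVector ck,
                             double nscale) {
  int p = b.size();
  if (Z.ncol() != p || S.ncol() != p || Vdiag.size() != p) {
    stop("dimension mismatch in lazy coordinate descent inputs");
  }
  ColSource M;
  M.p = p;
  M.Z = REAL(Z);
  M.w = REAL(w);
  M.S = REAL(S);
  M.ck = REAL(ck);
  M.n = Z.nrow();
  M.K = S.nrow();
  M.nscale = nscale;
  M.diag_.assign(REAL(Vdiag), REAL(Vdiag) + p);
  M.cache.resize(p);
  return M;
}

// Same algorithm with V reconstructed column-by-column from its factors
// n*V = Z'diag(w)Z - S'diag(ck)S; only columns of coordinates that ever
// become active are computed (and cached).
// [[Rcpp::export(name = ".cd_solve_lazy")]]
List cd_solve_lazy(NumericVector b, NumericVector Vdiag, NumericMatrix Z,
                   NumericVector w, NumericMatrix S, NumericVector ck,
                   double nscale, int kind, double lam, double a,
                   NumericVector beta_init, double tol, int max_sweeps,
                   bool active_set) {
  ColSource M = lazy_source(b, Vdiag, Z, w, S, ck, nscale);
  return cd_fit_list(b, M, kind, lam, a, beta_init, tol, max_sweeps,
                     active_set);
}

// Whole warm-started lambda path in one call: the column cache is shared
// across all lambdas, which is what makes high-dimensional paths cheap.
// [[Rcpp::export(name = ".cd_path_lazy")]]
List cd_path_lazy(NumericVector b, NumericVector Vdiag, NumericMatrix Z,
                  NumericVector w, NumericMatrix S, NumericVector ck,
                  double nscale, int kind, NumericVector lambdas, double a,
                  double tol, int max_sweeps, bool active_set,
                  bool warm_start) {
  ColSource M = lazy_source(b, Vdiag, Z, w, S, ck, nscale);
  int p = b.size();
  int L = lambdas.size();
  std::vector<double> beta(p, 0.0), r(REAL(b), REAL(b) + p);
  NumericMatrix betas(p, L);
  NumericVector objective(L);
  IntegerVector sweeps(L);
  LogicalVector converged(L);
  List traces(L);
  for (int l = 0; l < L; ++l) {
    if (!warm_start) {
      std::fill(beta.begin(), beta.end(), 0.0);
      std::copy(REAL(b), REAL(b) + p, r.begin());
    }
    CdResult res = cd_run(b, M, beta, r, kind, lambdas[l], a, tol,
                          max_sweeps, active_set);
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    objective[l] = res.objective;
    sweeps[l] = res.sweeps;
    converged[l] = res.converged;
    traces[l] = NumericVector(res.trace.begin(), res.trace.end());
  }
  return List::create(_["beta"] = betas, _["objective"] = objective,
                      _["sweeps"] = sweeps, _["converged"] = converged,
                      _["traces"] = traces);
}
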