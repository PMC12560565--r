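#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pathwise elastic-net penalized logistic regression by IRLS.
//
// Objective, for mixing alpha and penalty strength lambda:
//   (1/n) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ]
//     + lambda * sum_j pen_j * ( alpha*|b_j| + (1-alpha)/2 * b_j^2 )
// with eta = a0 + X b; the intercept a0 is never penalized and pen_j is a
// per-column penalty factor (0 exempts a column, e.g. forced main effects).
//
// The weighted least-squares subproblem of each IRLS step is solved by
// coordinate descent when alpha > 0 (soft thresholding) and by an exact
// Cholesky solve of the (p+1)-dimensional ridge system when alpha == 0.
// Step halving enforces monotone decrease of the true objective.

static inline double splus(double x) {
  if (x > 30.0) return x + std::exp(-x);
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

struct Problem {
  const double* x; // column-major, n rows
  const double* y;
  int n, p;
  double alpha, lam;
  const double* pen;
};

static double objective(const Problem& pb, const std::vector<double>& eta,
                        double /*a0*/, const std::vector<double>& beta) {
  double nll = 0.0;
  for (int i = 0; i < pb.n; ++i) nll += splus(eta[i]) - pb.y[i] * eta[i];
  nll /= pb.n;
  double penval = 0.0;
  for (int j = 0; j < pb.p; ++j)
    penval += pb.pen[j] * (pb.alpha * std::fabs(beta[j]) +
                           0.5 * (1.0 - pb.alpha) * beta[j] * beta[j]);
  return nll + pb.lam * penval;
}

static void update_eta(const Problem& pb, double a0,
                       const std::vector<double>& beta,
                       std::vector<double>& eta) {
  for (int i = 0; i < pb.n; ++i) eta[i] = a0;
  for (int j = 0; j < pb.p; ++j) {
    double bj = beta[j];
    if (bj == 0.0) continue;
    const double* xj = pb.x + (size_t)j * pb.n;
    for (int i = 0; i < pb.n; ++i) eta[i] += xj[i] * bj;
  }
}

// exact Newton step for the ridge objective over [intercept, beta]:
// (Xa' W Xa / n + lam*diag(0, pen)) delta = Xa' W r / n - lam*diag(0, pen)*b
static bool ridge_newton_step(const Problem& pb, const std::vector<double>& w,
                              const std::vector<double>& r,
                              const std::vector<double>& beta, double& da0,
                              std::vector<double>& dbeta) {
  const int m = pb.p + 1;
  std::vector<double> H((size_t)m * m, 0.0), g(m, 0.0);
  // column 0 is the intercept (all ones)
  std::vector<const double*> cols(m);
  static thread_local std::vector<double> ones;
  if ((int)ones.size() < pb.n) ones.assign(pb.n, 1.0);
  cols[0] = ones.data();
  for (int j = 0; j < pb.p; ++j) cols[j + 1] = pb.x + (size_t)j * pb.n;
  for (int a = 0; a < m; ++a) {
    for (int b = a; b < m; ++b) {
      double s = 0.0;
      for (int i = 0; i < pb.n; ++i) s += w[i] * cols[a][i] * cols[b][i];
      H[(size_t)a * m + b] = H[(size_t)b * m + a] = s / pb.n;
    }
    double s = 0.0;
    for (int i = 0; i < pb.n; ++i) s += w[i] * cols[a][i] * r[i];
    g[a] = s / pb.n;
    if (a > 0) {
      double lp = pb.lam * (1.0 - pb.alpha) * pb.pen[a - 1];
      H[(size_t)a * m + a] += lp;
      g[a] -= lp * beta[a - 1];
    }
  }
  // Cholesky H = L L'
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b <= a; ++b) {
      double s = H[(size_t)a * m + b];
      for (int k = 0; k < b; ++k)
        s -= H[(size_t)a * m + k] * H[(size_t)b * m + k];
      if (a == b) {
        if (s <= 0.0) return false;
        H[(size_t)a * m + a] = std::sqrt(s);
      } else {
        H[(size_t)a * m + b] = s / H[(size_t)b * m + b];
      }
    }
  }
  // forward/backward solve
  for (int a = 0; a < m; ++a) {
    double s = g[a];
    for (int k = 0; k < a; ++k) s -= H[(size_t)a * m + k] * g[k];
    g[a] = s / H[(size_t)a * m + a];
  }
  for (int a = m - 1; a >= 0; --a) {
    double s = g[a];
    for (int k = a + 1; k < m; ++k) s -= H[(size_t)k * m + a] * g[k];
    g[a] = s / H[(size_t)a * m + a];
  }
  da0 = g[0];
  for (int j = 0; j < pb.p; ++j) dbeta[j] = g[j + 1];
  return true;
}

// coordinate descent on the penalized WLS subproblem (alpha > 0). The
// intercept together with any penalty-factor-0 (forced) columns forms an
// unpenalized block that plain coordinate iterations traverse slowly when
// correlated, so that block is updated by an exact weighted least-squares
// solve between passes over the penalized coordinates.
static void cd_wls(const Problem& pb, const std::vector<double>& w,
                   std::vector<double>& r, double& a0,
                   std::vector<double>& beta) {
  const double inner_tol = 1e-9;
  const int max_sweeps = 1000;
  const int n = pb.n;
  std::vector<double> v(pb.p);
  std::vector<bool> active(pb.p, true);
  std::vector<int> freecol;
  for (int j = 0; j < pb.p; ++j) {
    const double* xj = pb.x + (size_t)j * n;
    double vj = 0.0;
    for (int i = 0; i < n; ++i) vj += w[i] * xj[i] * xj[i];
    v[j] = vj / n;
    if (pb.pen[j] == 0.0) freecol.push_back(j);
  }
  // Cholesky factor of the free-block normal matrix [1, X_F]' W [1, X_F] / n
  const int m = (int)freecol.size() + 1;
  std::vector<double> L((size_t)m * m, 0.0), g(m), del(m);
  {
    std::vector<const double*> cols(m);
    static thread_local std::vector<double> ones;
    if ((int)ones.size() < n) ones.assign(n, 1.0);
    cols[0] = ones.data();
    for (int a = 1; a < m; ++a) cols[a] = pb.x + (size_t)freecol[a - 1] * n;
    for (int a = 0; a < m; ++a) {
      for (int b = 0; b <= a; ++b) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * cols[a][i] * cols[b][i];
        s /= n;
        for (int k = 0; k < b; ++k)
          s -= L[(size_t)a * m + k] * L[(size_t)b * m + k];
        L[(size_t)a * m + b] = (a == b) ? std::sqrt(std::max(s, 1e-12))
                                        : s / L[(size_t)b * m + b];
      }
    }
  }
  bool full_sweep = true;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxdel = 0.0;
    // exact update of the unpenalized block given the current residual
    {
      double s0 = 0.0;
      for (int i = 0; i < n; ++i) s0 += w[i] * r[i];
      g[0] = s0 / n;
      for (int a = 1; a < m; ++a) {
        const double* xj = pb.x + (size_t)freecol[a - 1] * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * r[i];
        g[a] = s / n;
      }
      for (int a = 0; a < m; ++a) {
        double s = g[a];
        for (int k = 0; k < a; ++k) s -= L[(size_t)a * m + k] * del[k];
        del[a] = s / L[(size_t)a * m + a];
      }
      for (int a = m - 1; a >= 0; --a) {
        double s = del[a];
        for (int k = a + 1; k < m; ++k) s -= L[(size_t)k * m + a] * del[k];
        del[a] = s / L[(size_t)a * m + a];
      }
      a0 += del[0];
      for (int i = 0; i < n; ++i) r[i] -= del[0];
      if (std::fabs(del[0]) > maxdel) maxdel = std::fabs(del[0]);
      for (int a = 1; a < m; ++a) {
        double d = del[a];
        if (d == 0.0) continue;
        int j = freecol[a - 1];
        const double* xj = pb.x + (size_t)j * n;
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
        beta[j] += d;
        if (std::fabs(d) > maxdel) maxdel = std::fabs(d);
      }
    }
    // soft-thresholded coordinate pass over the penalized columns
    for (int j = 0; j < pb.p; ++j) {
      if (pb.pen[j] == 0.0) continue;
      if (!full_sweep && !active[j]) continue;
      const double* xj = pb.x + (size_t)j * n;
      double u = 0.0;
      for (int i = 0; i < n; ++i) u += w[i] * xj[i] * r[i];
      u = u / n + v[j] * beta[j];
      double bj = soft(u, pb.lam * pb.alpha * pb.pen[j]) /
                  (v[j] + pb.lam * (1.0 - pb.alpha) * pb.pen[j]);
      double d = bj - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
        beta[j] = bj;
        if (std::fabs(d) > maxdel) maxdel = std::fabs(d);
      }
      if (full_sweep) active[j] = beta[j] != 0.0;
    }
    if (maxdel < inner_tol) {
      if (full_sweep) break;
      full_sweep = true; // converged on the active set; re-check all
    } else {
      full_sweep = false;
    }
  }
}

// Core path fit. beta/a0 are warm-started across the lambda grid.
// [[Rcpp::export]]
List cd_logistic_path(NumericMatrix X, NumericVector y, double alpha,
                      NumericVector lambda, NumericVector penalty,
                      double tol = 1e-7, int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  NumericMatrix beta_out(p, nlam);
  NumericVector a0_out(nlam), obj_out(nlam);
  IntegerVector niter(nlam);
  LogicalVector conv(nlam);

  std::vector<double> beta(p, 0.0), dbeta(p), beta_new(p);
  double ybar = mean(y);
  double a0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> eta(n), w(n), r(n);
  const double wmin = 1e-6;

  Problem pb{REAL(X), REAL(y), n, p, alpha, 0.0, REAL(penalty)};

  for (int l = 0; l < nlam; ++l) {
    pb.lam = lambda[l];
    update_eta(pb, a0, beta, eta);
    double obj = objective(pb, eta, a0, beta);
    int it = 0;
    bool converged = false;
    while (it < maxit) {
      for (int i = 0; i < n; ++i) {
        double pr = 1.0 / (1.0 + std::exp(-eta[i]));
        double wi = pr * (1.0 - pr);
        if (wi < wmin) wi = wmin;
        w[i] = wi;
        // residual of working response z = eta + (y - pr)/w around current fit
        r[i] = (pb.y[i] - pr) / wi;
      }
      double a0_new = a0;
      if (alpha == 0.0) {
        double da0 = 0.0;
        if (ridge_newton_step(pb, w, r, beta, da0, dbeta)) {
          a0_new = a0 + da0;
          for (int j = 0; j < p; ++j) beta_new[j] = beta[j] + dbeta[j];
        } else {
          for (int j = 0; j < p; ++j) beta_new[j] = beta[j];
        }
      } else {
        beta_new = beta;
        cd_wls(pb, w, r, a0_new, beta_new);
      }
      // step halving onto the true objective (beta_new holds the full step)
      double step = 1.0;
      double obj_new = 0.0;
      double a0_try = a0_new;
      std::vector<double> beta_try = beta_new;
      for (int h = 0; h < 50; ++h) {
        update_eta(pb, a0_try, beta_try, eta);
        obj_new = objective(pb, eta, a0_try, beta_try);
        if (obj_new <= obj + 1e-14) break;
        step *= 0.5;
        a0_try = a0 + step * (a0_new - a0);
        for (int j = 0; j < p; ++j)
          beta_try[j] = beta[j] + step * (beta_new[j] - beta[j]);
      }
      a0 = a0_try;
      beta = beta_try;
      ++it;
      if (std::fabs(obj - obj_new) < tol * (std::fabs(obj) + 1e-10)) {
        obj = obj_new;
        converged = true;
        break;
      }
      obj = obj_new;
    }
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    a0_out[l] = a0;
    obj_out[l] = obj;
    niter[l] = it;
    conv[l] = converged;
  }
  return List::create(_["a0"] = a0_out, _["beta"] = beta_out,
                      _["objective"] = obj_out, _["niter"] = niter,
                      _["converged"] = conv);
}

// Cross-validated held-out binomial deviance per observation and lambda.
// foldid is 1-based; each fold's model is refit from scratch on the
// remaining rows with the same path routine, then the held-out
// observations' deviances (-2 * log-likelihood) are stored.
// [[Rcpp::export]]
NumericMatrix cd_logistic_cv(NumericMatrix X, NumericVector y, double alpha,
                             NumericVector lambda, NumericVector penalty,
                             IntegerVector foldid, double tol = 1e-7,
                             int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
  int nfold = 0;
  for (int i = 0; i < n; ++i) if (foldid[i] > nfold) nfold = foldid[i];
  NumericMatrix dev(n, nlam);
  std::fill(dev.begin(), dev.end(), NA_REAL);

  for (int k = 1; k <= nfold; ++k) {
    int ntr = 0;
    for (int i = 0; i < n; ++i) if (foldid[i] != k) ++ntr;
    if (ntr == n || ntr == 0) continue;
    NumericMatrix Xtr(ntr, p);
    NumericVector ytr(ntr);
    int row = 0;
    double ysum = 0.0;
    for (int i = 0; i < n; ++i) {
      if (foldid[i] == k) continue;
      for (int j = 0; j < p; ++j) Xtr(row, j) = X(i, j);
      ytr[row] = y[i];
      ysum += y[i];
      ++row;
    }
    if (ysum == 0.0 || ysum == ntr) continue; // one-class fold: left NA
    List fit = cd_logistic_path(Xtr, ytr, alpha, lambda, penalty, tol, maxit);
    NumericVector a0 = fit["a0"];
    NumericMatrix beta = fit["beta"];
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != k) continue;
      for (int l = 0; l < nlam; ++l) {
        double e = a0[l];
        for (int j = 0; j < p; ++j) e += X(i, j) * beta(j, l);
        dev(i, l) = 2.0 * (splus(e) - y[i] * e);
      }
    }
  }
  return dev;
}
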