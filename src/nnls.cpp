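// Non-negative least squares kernels for multi-component T2 fitting.
//
// The per-voxel problems are tiny (32-96 rows, 60 columns) but occur in the
// millions across a study, so the active-set solver works on the Gram system
// (Bro & de Jong's fast NNLS variant of Lawson-Hanson): Tikhonov lambdas then
// only shift the Gram diagonal and cost no extra matrix products.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Solve min ||Ax - y||^2 s.t. x >= 0 given G = A'A and b = A'y.
// Active-set iteration on the normal equations; exact KKT at convergence
// up to `tol` on the dual (gradient) components. `warm`, when non-null,
// seeds the passive set from a nearby solution's support (the result is
// still KKT-optimal; only the iteration count changes).
static vec fnnls(const mat& G, const vec& b, double tol,
                 const vec* warm = nullptr) {
  const uword n = G.n_cols;
  std::vector<bool> passive(n, false);
  vec x(n, fill::zeros);
  if (warm != nullptr) {
    uvec idx(n);
    uword np = 0;
    for (uword j = 0; j < n; ++j)
      if ((*warm)(j) > 0) { passive[j] = true; idx(np++) = j; }
    if (np > 0) {
      idx.resize(np);
      vec z;
      bool ok = solve(z, G.submat(idx, idx), b(idx),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok && z.min() > 0) {
        x(idx) = z;
      } else {
        for (uword j = 0; j < n; ++j) passive[j] = false;
      }
    }
  }
  vec w = b - G * x; // gradient of 0.5*objective
  const uword itmax = 30 * n;
  uword it = 0;
  while (it++ < itmax) {
    // most violating active coordinate
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = (int)j; }
    if (t < 0) break;
    passive[t] = true;
    // inner loop: restore feasibility on the passive set
    while (true) {
      uvec idx(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) idx(np++) = j;
      idx.resize(np);
      vec z;
      bool ok = solve(z, G.submat(idx, idx), b(idx),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) z = pinv(G.submat(idx, idx)) * b(idx);
      if (np == 0) break;
      if (z.min() > 0) {
        x.zeros();
        x(idx) = z;
        break;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k)
        if (z(k) <= 0) {
          double denom = x(idx(k)) - z(k);
          double a = denom > 0 ? x(idx(k)) / denom : 0.0;
          if (a < alpha) alpha = a;
        }
      vec xi = x(idx);
      xi += alpha * (z - xi);
      x.zeros();
      x(idx) = xi;
      for (uword k = 0; k < np; ++k)
        if (x(idx(k)) <= tol * 1e-6 || z(k) <= 0) {
          if (x(idx(k)) <= 1e-12) { passive[idx(k)] = false; x(idx(k)) = 0; }
        }
    }
    w = b - G * x;
  }
  return x;
}

static double gram_tol(const mat& G) {
  return 1e-11 * std::max(1.0, G.diag().max());
}

// [[Rcpp::export]]
arma::vec cpp_nnls(const arma::mat& A, const arma::vec& y) {
  mat G = A.t() * A;
  vec b = A.t() * y;
  return fnnls(G, b, gram_tol(G));
}

// [[Rcpp::export]]
arma::vec cpp_reg_nnls(const arma::mat& A, const arma::vec& y, double lam) {
  mat G = A.t() * A;
  G.diag() += lam * lam;
  vec b = A.t() * y;
  return fnnls(G, b, gram_tol(G));
}

// data-term residual ||Ax - y||^2 via the Gram identity
static inline double data_resid(const mat& G0, const vec& b, double yty,
                                const vec& x) {
  double r = yty - 2.0 * dot(x, b) + dot(x, G0 * x);
  return r > 0 ? r : 0.0;
}

// Mean squared error of unregularized NNLS fits, one per column of Y.
// [[Rcpp::export]]
arma::vec cpp_nnls_mse(const arma::mat& A, const arma::mat& Y) {
  mat G = A.t() * A;
  double tol = gram_tol(G);
  vec out(Y.n_cols);
  vec warm; // neighbouring voxels have similar supports
  for (uword v = 0; v < Y.n_cols; ++v) {
    vec y = Y.col(v);
    vec b = A.t() * y;
    vec x = fnnls(G, b, tol, warm.n_elem ? &warm : nullptr);
    warm = x;
    out(v) = data_resid(G, b, dot(y, y), x) / (double)A.n_rows;
  }
  return out;
}

// Tikhonov path: residual^2 (data term) and ||x||^2 at each lambda, per voxel.
// [[Rcpp::export]]
Rcpp::List cpp_reg_path(const arma::mat& A, const arma::mat& Y,
                        const arma::vec& lambdas) {
  mat G0 = A.t() * A;
  double tol = gram_tol(G0);
  const uword nl = lambdas.n_elem, nv = Y.n_cols;
  mat resid(nl, nv), xnorm(nl, nv);
  for (uword v = 0; v < nv; ++v) {
    vec y = Y.col(v);
    vec b = A.t() * y;
    double yty = dot(y, y);
    for (uword l = 0; l < nl; ++l) {
      mat G = G0;
      G.diag() += lambdas(l) * lambdas(l);
      vec x = fnnls(G, b, tol);
      resid(l, v) = data_resid(G0, b, yty, x);
      xnorm(l, v) = dot(x, x);
    }
  }
  return Rcpp::List::create(Rcpp::Named("resid2") = resid,
                            Rcpp::Named("xnorm2") = xnorm);
}

static vec solve_lam(const mat& G0, const vec& b, double tol, double lam,
                     const vec* warm = nullptr) {
  mat G = G0;
  G.diag() += lam * lam;
  return fnnls(G, b, tol, warm);
}

// Chi-square criterion per voxel: largest lambda with data residual
// <= factor * chi2min, monotone bisection on the lambda grid then within the
// bracketing interval (relative tolerance `rtol` on the achieved factor).
// [[Rcpp::export]]
Rcpp::List cpp_chi2_select(const arma::mat& A, const arma::mat& Y,
                           const arma::vec& lambdas, double factor,
                           double rtol) {
  mat G0 = A.t() * A;
  double tol = gram_tol(G0);
  const uword nv = Y.n_cols, nl = lambdas.n_elem, nt = A.n_cols;
  mat X(nt, nv, fill::zeros);
  vec lam_out(nv), res_out(nv);
  ivec degen(nv, fill::zeros);
  // cross-voxel warm starts: neighbouring voxels have similar spectra
  vec w0, whi;
  for (uword v = 0; v < nv; ++v) {
    vec y = Y.col(v);
    vec b = A.t() * y;
    double yty = dot(y, y);
    vec x0 = fnnls(G0, b, tol, v ? &w0 : nullptr);
    w0 = x0;
    double chi2min = data_resid(G0, b, yty, x0);
    if (chi2min <= 1e-14 * std::max(1.0, yty)) {
      // perfect unregularized fit: keep it, smallest grid lambda, flag
      vec x = solve_lam(G0, b, tol, lambdas(0));
      X.col(v) = x;
      lam_out(v) = lambdas(0);
      res_out(v) = data_resid(G0, b, yty, x);
      degen(v) = 1;
      continue;
    }
    double target = factor * chi2min;
    // residual at the largest grid lambda
    vec xhi = solve_lam(G0, b, tol, lambdas(nl - 1),
                        whi.n_elem ? &whi : nullptr);
    whi = xhi;
    double rhi = data_resid(G0, b, yty, xhi);
    if (rhi <= target) {
      X.col(v) = xhi;
      lam_out(v) = lambdas(nl - 1);
      res_out(v) = rhi;
      continue;
    }
    // binary search on grid for boundary: resid(lo) <= target < resid(hi)
    uword lo = 0, hi = nl - 1;
    vec xprev = x0;
    while (hi - lo > 1) {
      uword mid = (lo + hi) / 2;
      vec x = solve_lam(G0, b, tol, lambdas(mid), &xprev);
      xprev = x;
      double r = data_resid(G0, b, yty, x);
      if (r <= target) lo = mid; else hi = mid;
    }
    double llo = lambdas(lo), lhi = lambdas(hi);
    vec xbest = solve_lam(G0, b, tol, llo, &xprev);
    double rbest = data_resid(G0, b, yty, xbest);
    for (int it = 0; it < 60; ++it) {
      if (std::fabs(rbest / chi2min - factor) <= rtol * factor) break;
      double lm = std::sqrt(llo * lhi); // log-scale midpoint
      vec x = solve_lam(G0, b, tol, lm, &xbest);
      double r = data_resid(G0, b, yty, x);
      if (r <= target) { llo = lm; xbest = x; rbest = r; }
      else lhi = lm;
      if (lhi / llo < 1.0 + 1e-4) break; // lambda bracket exhausted
    }
    X.col(v) = xbest;
    lam_out(v) = llo;
    res_out(v) = rbest;
  }
  return Rcpp::List::create(Rcpp::Named("x") = X,
                            Rcpp::Named("lambda") = lam_out,
                            Rcpp::Named("resid2") = res_out,
                            Rcpp::Named("degenerate") = degen);
}

// signed Menger curvature of the triplet (p1, p2, p3) in the (log rho, log eta)
// plane; positive at an L-shaped corner traversed with increasing residual
static double menger(double x1, double y1, double x2, double y2, double x3,
                     double y3) {
  double cross = (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1);
  double d12 = std::hypot(x2 - x1, y2 - y1);
  double d23 = std::hypot(x3 - x2, y3 - y2);
  double d13 = std::hypot(x3 - x1, y3 - y1);
  double denom = d12 * d23 * d13;
  if (denom <= 0) return 0.0;
  return 2.0 * cross / denom;
}

// L-curve criterion per voxel: lambda at maximum discrete (Menger) curvature
// of (log resid^2, log ||x||^2), refined by golden-section over the
// bracketing interval. Degenerate curves fall back to the smallest lambda.
// [[Rcpp::export]]
Rcpp::List cpp_lcurve_select(const arma::mat& A, const arma::mat& Y,
                             const arma::vec& lambdas) {
  mat G0 = A.t() * A;
  double tol = gram_tol(G0);
  const uword nv = Y.n_cols, nl = lambdas.n_elem, nt = A.n_cols;
  mat X(nt, nv, fill::zeros);
  vec lam_out(nv), res_out(nv);
  ivec fallback(nv, fill::zeros);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  for (uword v = 0; v < nv; ++v) {
    vec y = Y.col(v);
    vec b = A.t() * y;
    double yty = dot(y, y);
    vec lr(nl), le(nl);
    std::vector<vec> xs(nl);
    const vec* wprev = nullptr;
    for (uword l = 0; l < nl; ++l) {
      vec x = solve_lam(G0, b, tol, lambdas(l), wprev);
      xs[l] = x;
      wprev = &xs[l];
      double r = data_resid(G0, b, yty, x);
      double e = dot(x, x);
      lr(l) = std::log(std::max(r, 1e-300));
      le(l) = std::log(std::max(e, 1e-300));
    }
    int best = -1;
    double kbest = 0.0;
    for (uword l = 1; l + 1 < nl; ++l) {
      if (!std::isfinite(lr(l - 1)) || !std::isfinite(le(l - 1)) ||
          !std::isfinite(lr(l)) || !std::isfinite(le(l)) ||
          !std::isfinite(lr(l + 1)) || !std::isfinite(le(l + 1)))
        continue;
      double k = menger(lr(l - 1), le(l - 1), lr(l), le(l), lr(l + 1),
                        le(l + 1));
      if (k > kbest + 1e-15) { kbest = k; best = (int)l; }
      // ties keep the earlier (smaller) lambda
    }
    if (best < 0 || kbest <= 1e-12) {
      X.col(v) = xs[0];
      lam_out(v) = lambdas(0);
      res_out(v) = data_resid(G0, b, yty, xs[0]);
      fallback(v) = 1;
      continue;
    }
    // golden-section on the middle lambda of the bracketing triplet
    double x1c = lr(best - 1), y1c = le(best - 1);
    double x3c = lr(best + 1), y3c = le(best + 1);
    double a = std::log(lambdas(best - 1)), bb = std::log(lambdas(best + 1));
    vec xwarm = xs[best];
    auto curv_at = [&](double loglam, vec& xout) {
      double lm = std::exp(loglam);
      vec x = solve_lam(G0, b, tol, lm, &xwarm);
      xout = x;
      double r = data_resid(G0, b, yty, x);
      double e = dot(x, x);
      return menger(x1c, y1c, std::log(std::max(r, 1e-300)),
                    std::log(std::max(e, 1e-300)), x3c, y3c);
    };
    double c = bb - gr * (bb - a), d = a + gr * (bb - a);
    vec xc, xd;
    double fc = curv_at(c, xc), fd = curv_at(d, xd);
    for (int it = 0; it < 25 && (bb - a) > 1e-4; ++it) {
      if (fc > fd) {
        bb = d; d = c; fd = fc; xd = xc;
        c = bb - gr * (bb - a);
        fc = curv_at(c, xc);
      } else {
        a = c; c = d; fc = fd; xc = xd;
        d = a + gr * (bb - a);
        fd = curv_at(d, xd);
      }
    }
    double loglam = fc > fd ? c : d;
    vec xfin = fc > fd ? xc : xd;
    double lam = std::exp(loglam);
    // the plain grid maximum wins if refinement did not improve on it
    double kgrid = menger(x1c, y1c, lr(best), le(best), x3c, y3c);
    if (std::max(fc, fd) < kgrid) {
      lam = lambdas(best);
      xfin = xs[best];
    }
    X.col(v) = xfin;
    lam_out(v) = lam;
    res_out(v) = data_resid(G0, b, yty, xfin);
  }
  return Rcpp::List::create(Rcpp::Named("x") = X,
                            Rcpp::Named("lambda") = lam_out,
                            Rcpp::Named("resid2") = res_out,
                            Rcpp::Named("fallback") = fallback);
}
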