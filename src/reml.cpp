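// Variational ReML estimation of covariance components on the log scale,
// Bayesian model reduction of single components, and the permutation-null
// driver.  Model: voxels i.i.d. N(0, Sigma(h)) with
//   Sigma(h) = sum_k exp(h_k) Q_k,   Q_m = I (noise, last slice),
// Gaussian hyperprior h ~ N(pm, diag(pv)).  Fisher scoring with step
// halving maximises the penalised log-likelihood
//   J(h) = L(h) - 0.5 (h-pm)' diag(1/pv) (h-pm),
// and the free energy at the mode is the Laplace evidence
//   F = J + 0.5 [ log|Cq| - log|Cp| ].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool sigma_of(const cube& Q, const vec& h, mat& Sigma) {
  const uword m = Q.n_slices;
  Sigma.zeros(Q.n_rows, Q.n_cols);
  for (uword k = 0; k < m; ++k) Sigma += std::exp(h(k)) * Q.slice(k);
  return Sigma.is_finite();
}

// penalised objective; returns -inf when Sigma is not PD
static double objective(const mat& S, double n, const cube& Q, const vec& h,
                        const vec& pm, const vec& pv, double& L) {
  mat Sigma;
  if (!sigma_of(Q, h, Sigma)) return -datum::inf;
  mat R;
  if (!chol(R, Sigma)) return -datum::inf;
  const double ld = 2.0 * accu(log(R.diag()));
  mat iS;
  if (!inv_sympd(iS, Sigma)) return -datum::inf;
  const double p = static_cast<double>(S.n_rows);
  const double tr = accu(iS % S);  // trace(iS * S), S symmetric
  L = -0.5 * n * (p * std::log(2.0 * datum::pi) + ld + tr);
  const vec e = h - pm;
  return L - 0.5 * accu(square(e) / pv);
}

struct Fit {
  vec h;
  mat Cq;
  double F, L;
  int iter;
  bool conv;
};

static Fit reml_core(const mat& S, double n, const cube& Q,
                     const vec& pm, const vec& pv, double tol, int maxIter) {
  const uword p = S.n_rows, m = Q.n_slices;
  Fit out;
  vec h = pm;
  double L = 0.0;
  double J = objective(S, n, Q, h, pm, pv, L);
  if (!std::isfinite(J)) {
    // lift the noise floor to the data scale and retry
    h(m - 1) = std::log(std::max(trace(S) / p, 1e-6));
    J = objective(S, n, Q, h, pm, pv, L);
  }
  mat Hess(m, m, fill::eye);
  bool conv = false;
  int it = 0;
  for (it = 1; it <= maxIter; ++it) {
    mat Sigma;
    sigma_of(Q, h, Sigma);
    mat iS = inv_sympd(Sigma);
    mat T = iS * S;
    cube A(p, p, m);
    vec g(m);
    for (uword k = 0; k < m; ++k) {
      A.slice(k) = (std::exp(h(k))) * (iS * Q.slice(k));
      g(k) = 0.5 * n * (accu(A.slice(k) % T.t()) - trace(A.slice(k)));
    }
    mat Info(m, m);
    for (uword k = 0; k < m; ++k)
      for (uword l = k; l < m; ++l)
        Info(k, l) = Info(l, k) = 0.5 * n * accu(A.slice(k) % A.slice(l).t());
    vec e = h - pm;
    vec grad = g - e / pv;
    Hess = Info + diagmat(1.0 / pv);
    vec dh;
    if (!solve(dh, Hess, grad, solve_opts::likely_sympd + solve_opts::no_approx))
      dh = grad / (Hess.diag() + 1e-8);
    const double mx = abs(dh).max();
    if (mx > 8.0) dh *= 8.0 / mx;  // trust region in log units

    double Jn = -datum::inf, Ln = 0.0, step = 1.0;
    vec hn = h;
    for (int halv = 0; halv < 24; ++halv) {
      hn = h + step * dh;
      Jn = objective(S, n, Q, hn, pm, pv, Ln);
      if (std::isfinite(Jn) && Jn >= J - 1e-10) break;
      step *= 0.5;
    }
    if (!std::isfinite(Jn) || Jn < J - 1e-10) { conv = true; break; }
    const double dJ = Jn - J;
    h = hn; J = Jn; L = Ln;
    if (dJ < tol) { conv = true; break; }
  }
  // Laplace posterior at the mode
  {
    mat Sigma;
    sigma_of(Q, h, Sigma);
    mat iS = inv_sympd(Sigma);
    cube A(p, p, m);
    for (uword k = 0; k < m; ++k)
      A.slice(k) = (std::exp(h(k))) * (iS * Q.slice(k));
    mat Info(m, m);
    for (uword k = 0; k < m; ++k)
      for (uword l = k; l < m; ++l)
        Info(k, l) = Info(l, k) = 0.5 * n * accu(A.slice(k) % A.slice(l).t());
    Hess = Info + diagmat(1.0 / pv);
  }
  mat Cq;
  if (!inv_sympd(Cq, Hess)) Cq = pinv(Hess);
  out.h = h;
  out.Cq = Cq;
  out.L = L;
  double ldq, sgn;
  log_det(ldq, sgn, Cq);
  out.F = J + 0.5 * (ldq - accu(log(pv)));
  out.iter = it > maxIter ? maxIter : it;
  out.conv = conv;
  return out;
}

// Gaussian Bayesian model reduction: change in log evidence when the
// prior over component `idx` is replaced by N(rm, rv) (rv small pins the
// component off).  Uses the identity
//   dF = 0.5[ ln|Cp| - ln|Cq| - ln|rCp| - ln|Pi| ]
//      + 0.5[ b' Pi^-1 b - mu'Pq mu - rpm'rPp rpm + pm'Pp pm ]
// with Pi = Pq + rPp - Pp, b = Pq mu + rPp rpm - Pp pm.
static double bmr_delta(const vec& mu, const mat& Cq, const vec& pm,
                        const vec& pv, uword idx, double rm, double rv,
                        bool& ok) {
  mat Pq;
  ok = inv_sympd(Pq, Cq);
  if (!ok) return 0.0;
  vec rpv = pv; rpv(idx) = rv;
  vec rpm = pm; rpm(idx) = rm;
  mat Pi = Pq + diagmat(1.0 / rpv - 1.0 / pv);
  vec b = Pq * mu + rpm / rpv - pm / pv;
  mat Ci;
  if (!inv_sympd(Ci, Pi)) { ok = false; return 0.0; }
  double ldq, ldPi, sgn;
  log_det(ldq, sgn, Cq);
  log_det(ldPi, sgn, Pi);
  const double t1 = 0.5 * (accu(log(pv)) - ldq - accu(log(rpv)) - ldPi);
  const double t2 = 0.5 * (dot(b, Ci * b) - dot(mu, Pq * mu) -
                           accu(square(rpm) / rpv) + accu(square(pm) / pv));
  ok = true;
  return t1 + t2;
}

static cube as_Q(const arma::cube& G) {
  // append the identity noise slice
  cube Q(G.n_rows, G.n_cols, G.n_slices + 1);
  Q.slices(0, G.n_slices - 1) = G;
  Q.slice(G.n_slices) = eye(G.n_rows, G.n_cols);
  return Q;
}

// [[Rcpp::export(name = ".reml_fit_cpp")]]
Rcpp::List reml_fit_cpp(const arma::mat& S, double n, const arma::cube& G,
                        const arma::vec& priorMean, const arma::vec& priorVar,
                        double tol, int maxIter) {
  cube Q = as_Q(G);
  Fit f = reml_core(S, n, Q, priorMean, priorVar, tol, maxIter);
  return Rcpp::List::create(
      Rcpp::Named("mean") = f.h, Rcpp::Named("cov") = f.Cq,
      Rcpp::Named("F") = f.F, Rcpp::Named("logLik") = f.L,
      Rcpp::Named("iterations") = f.iter, Rcpp::Named("converged") = f.conv);
}

// [[Rcpp::export(name = ".bmr_cpp")]]
Rcpp::NumericVector bmr_cpp(const arma::vec& mu, const arma::mat& Cq,
                            const arma::vec& priorMean,
                            const arma::vec& priorVar, int nComp,
                            double redMean, double redVar) {
  Rcpp::NumericVector out(nComp);
  for (int k = 0; k < nComp; ++k) {
    bool ok = true;
    out[k] = bmr_delta(mu, Cq, priorMean, priorVar, k, redMean, redVar, ok);
    if (!ok) out[k] = NA_REAL;
  }
  return out;
}

// Group-level evidence under a stack of relabelled second-moment
// matrices.  `Ss` holds one already-projected matrix per
// (permutation, subject) pair, permutation-major (the caller applies
// the label permutation and the basis projection, so the identity row
// is arithmetically identical to the single-fit path); per matrix the
// model is refitted and each component scored by BMR; group deltaF is
// the fixed-effects sum over subjects.  `G` is already projected.
// [[Rcpp::export(name = ".null_evidence_cpp")]]
Rcpp::List null_evidence_cpp(const arma::cube& Ss, const arma::vec& ns,
                             const arma::cube& G, int nPerm,
                             const arma::vec& priorMean,
                             const arma::vec& priorVar, double redMean,
                             double redVar, double tol, int maxIter) {
  const uword nperm = (uword)nPerm, ncomp = G.n_slices;
  const uword nsub = Ss.n_slices / nperm;
  cube Q = as_Q(G);
  mat out(nperm, ncomp, fill::zeros);
  unsigned nonconv = 0;
  for (uword r = 0; r < nperm; ++r) {
    for (uword s = 0; s < nsub; ++s) {
      const mat& Sp = Ss.slice(r * nsub + s);
      Fit f = reml_core(Sp, ns(s), Q, priorMean, priorVar, tol, maxIter);
      if (!f.conv) ++nonconv;
      for (uword k = 0; k < ncomp; ++k) {
        bool ok = true;
        double d = bmr_delta(f.h, f.Cq, priorMean, priorVar, k, redMean,
                             redVar, ok);
        if (!ok) {
          // fallback: explicit refit with the reduced prior
          vec rpm = priorMean; rpm(k) = redMean;
          vec rpv = priorVar; rpv(k) = redVar;
          Fit fr = reml_core(Sp, ns(s), Q, rpm, rpv, tol, maxIter);
          d = fr.F - f.F;
        }
        out(r, k) += d;
      }
    }
    if (r % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("deltaF") = out,
                            Rcpp::Named("nonConverged") = (int)nonconv);
}
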