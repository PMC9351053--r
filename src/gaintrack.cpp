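// Compiled numerical core: Jansen-Rit drift, stochastic integrators for the
// fast and slow-fast systems, and the continuous-discrete unscented Kalman
// filter.  R-level wrappers own all validation; everything here assumes
// well-formed inputs (fixed-layout parameter vectors, see pack_params() in R).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Parameter vector layout (must match .pack_params in R/parameters.R):
//  0 a_p  1 a_ex  2 a_i  3 r_p  4 r_ex  5 r_i  6 c
//  7 e0   8 rho   9 v_th 10 input_mean 11 input_var
static const int P_AP = 0, P_AEX = 1, P_AI = 2, P_RP = 3, P_REX = 4,
                 P_RI = 5, P_C = 6, P_E0 = 7, P_RHO = 8, P_VTH = 9,
                 P_MU = 10, P_VAR = 11;

inline double sigm(double v, const double* p) {
  return p[P_E0] / (1.0 + std::exp(-p[P_RHO] * (v - p[P_VTH])));
}

// Six-state drift; a_i supplied separately so the augmented filter can
// substitute the tracked gain without copying the parameter vector.
static void drift6(const double* x, const double* p, double omega,
                   double a_i, double* dx) {
  const double s_p  = sigm(x[2] - x[4], p);
  const double s_ex = sigm(p[P_C] * x[0], p);
  const double s_i  = sigm(0.25 * p[P_C] * x[0], p);
  dx[0] = x[1];
  dx[1] = p[P_AP] * p[P_RP] * s_p - 2.0 * p[P_RP] * x[1]
          - p[P_RP] * p[P_RP] * x[0];
  dx[2] = x[3];
  dx[3] = p[P_AEX] * p[P_REX] * (omega + 0.8 * p[P_C] * s_ex)
          - 2.0 * p[P_REX] * x[3] - p[P_REX] * p[P_REX] * x[2];
  dx[4] = x[5];
  dx[5] = a_i * p[P_RI] * (0.25 * p[P_C] * s_i)
          - 2.0 * p[P_RI] * x[5] - p[P_RI] * p[P_RI] * x[4];
}

// [[Rcpp::export]]
arma::vec cpp_nmm_drift(const arma::vec& x, const arma::vec& pars,
                        double omega) {
  vec dx(6);
  drift6(x.memptr(), pars.memptr(), omega, pars[P_AI], dx.memptr());
  return dx;
}

// Deterministic RK4 step of the six fast states with frozen a_i and omega.
static void rk4_6(double* x, const double* p, double omega, double a_i,
                  double dt) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  drift6(x, p, omega, a_i, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  drift6(tmp, p, omega, a_i, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  drift6(tmp, p, omega, a_i, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = x[i] + dt * k3[i];
  drift6(tmp, p, omega, a_i, k4);
  for (int i = 0; i < 6; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static void check_bound(const double* x, int n, double bound, int step) {
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(x[i]) || std::fabs(x[i]) > bound)
      Rcpp::stop("state diverged (|x| > %g) at integration step %d", bound,
                 step + 1);
  }
}

// Integrate the noise-driven NMM.  `noise` holds standard-normal draws, one
// per step; the diffusion enters only the x_ex* equation with amplitude
// a_ex * r_ex * sqrt(input_var * dt) so that output statistics are invariant
// to the step size.  scheme: 0 = RK4 drift + additive increment (stochastic
// RK for additive noise), 1 = Euler-Maruyama.
// [[Rcpp::export]]
Rcpp::List cpp_integrate_nmm(const arma::vec& pars, const arma::vec& x0,
                             double dt, int n_steps, const arma::vec& noise,
                             int scheme, int thin, double bound) {
  const double* p = pars.memptr();
  const double amp = p[P_AEX] * p[P_REX] *
                     std::sqrt(p[P_VAR] * dt);
  double x[6];
  for (int i = 0; i < 6; ++i) x[i] = x0[i];

  const int n_out = n_steps / thin;
  mat states(n_out, 6);
  vec obs(n_out);
  int k = 0;
  for (int s = 0; s < n_steps; ++s) {
    if (scheme == 0) {
      rk4_6(x, p, p[P_MU], p[P_AI], dt);
      x[3] += amp * noise[s];
    } else {
      double dx[6];
      drift6(x, p, p[P_MU], p[P_AI], dx);
      for (int i = 0; i < 6; ++i) x[i] += dt * dx[i];
      x[3] += amp * noise[s];
    }
    check_bound(x, 6, bound, s);
    if ((s + 1) % thin == 0) {
      for (int i = 0; i < 6; ++i) states(k, i) = x[i];
      obs[k] = x[2] - x[4];
      ++k;
    }
  }
  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("obs") = obs);
}

// Slow-fast co-integration: the six fast states plus the inhibitory gain
// a_i with dA/dt = eps * (-alpha A + beta * sigma(V)) + eps * sqrt(svar) dW,
// V = x_ex - x_i.  slow = [eps, alpha, beta, slow_noise_var].
// [[Rcpp::export]]
Rcpp::List cpp_integrate_slow_fast(const arma::vec& pars,
                                   const arma::vec& slow,
                                   const arma::vec& x0, double ai0,
                                   double dt, int n_steps,
                                   const arma::vec& z_fast,
                                   const arma::vec& z_slow,
                                   int scheme, int thin, double bound) {
  const double* p = pars.memptr();
  const double eps = slow[0], alpha = slow[1], beta = slow[2];
  const double amp_fast = p[P_AEX] * p[P_REX] * std::sqrt(p[P_VAR] * dt);
  const double amp_slow = eps * std::sqrt(slow[3] * dt);

  double x[6];
  for (int i = 0; i < 6; ++i) x[i] = x0[i];
  double a_i = ai0;

  const int n_out = n_steps / thin;
  mat states(n_out, 6);
  vec obs(n_out), gain(n_out);
  int k = 0;
  for (int s = 0; s < n_steps; ++s) {
    const double v = x[2] - x[4];
    const double da = eps * (-alpha * a_i + beta * sigm(v, p));
    if (scheme == 0) {
      rk4_6(x, p, p[P_MU], a_i, dt);
      x[3] += amp_fast * z_fast[s];
    } else {
      double dx[6];
      drift6(x, p, p[P_MU], a_i, dx);
      for (int i = 0; i < 6; ++i) x[i] += dt * dx[i];
      x[3] += amp_fast * z_fast[s];
    }
    a_i += dt * da + amp_slow * z_slow[s];
    check_bound(x, 6, bound, s);
    if (!std::isfinite(a_i) || std::fabs(a_i) > bound)
      Rcpp::stop("gain diverged at integration step %d", s + 1);
    if ((s + 1) % thin == 0) {
      for (int i = 0; i < 6; ++i) states(k, i) = x[i];
      obs[k] = x[2] - x[4];
      gain[k] = a_i;
      ++k;
    }
  }
  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("obs") = obs,
                            Rcpp::Named("gain") = gain);
}

// ---------------------------------------------------------------------------
// Continuous-discrete UKF
// ---------------------------------------------------------------------------

// Square root of (n + lambda) * P via Cholesky, with eigenvalue clipping
// (negative ripple set to zero) as the fallback when P has drifted off the
// PSD cone or is degenerate.
static bool psd_sqrt(const mat& P, double scale, mat& L) {
  mat S = scale * P;
  S = 0.5 * (S + S.t());
  if (chol(L, S, "lower")) return true;
  vec eval;
  mat evec;
  if (!eig_sym(eval, evec, S)) return false;
  eval.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  L = evec * diagmat(sqrt(eval));
  return true;
}

struct UTWeights {
  double lambda, wm0, wc0, wi;
  UTWeights(int n, double a, double b, double kappa) {
    lambda = a * a * (n + kappa) - n;
    wm0 = lambda / (n + lambda);
    wc0 = wm0 + 1.0 - a * a + b;
    wi = 0.5 / (n + lambda);
  }
};

// Generate 2n+1 scaled sigma points (columns).
static bool make_sigma(const vec& m, const mat& P, double a, double kappa,
                       mat& X) {
  const int n = m.n_elem;
  const double lambda = a * a * (n + kappa) - n;
  mat L;
  if (!psd_sqrt(P, n + lambda, L)) return false;
  X.set_size(n, 2 * n + 1);
  X.col(0) = m;
  for (int i = 0; i < n; ++i) {
    X.col(1 + i) = m + L.col(i);
    X.col(1 + n + i) = m - L.col(i);
  }
  return true;
}

// [[Rcpp::export]]
Rcpp::List cpp_sigma_points(const arma::vec& m, const arma::mat& P,
                            double alpha, double beta, double kappa) {
  const int n = m.n_elem;
  UTWeights w(n, alpha, beta, kappa);
  mat X;
  if (!make_sigma(m, P, alpha, kappa, X))
    Rcpp::stop("sigma-point factorization failed: covariance not PSD after regularization");
  vec wm(2 * n + 1), wc(2 * n + 1);
  wm.fill(w.wi);
  wc.fill(w.wi);
  wm[0] = w.wm0;
  wc[0] = w.wc0;
  return Rcpp::List::create(Rcpp::Named("points") = X,
                            Rcpp::Named("wm") = wm, Rcpp::Named("wc") = wc);
}

// Propagate a 7-dim augmented point [x(6), a_i] through the deterministic
// drift (omega frozen at input_mean, d a_i/dt = 0) by n_sub RK4 sub-steps.
static void prop_aug(double* pt, const double* p, double dt, int n_sub) {
  const double h = dt / n_sub;
  for (int s = 0; s < n_sub; ++s) rk4_6(pt, p, p[P_MU], pt[6], h);
}

// Linear fixture drift xdot = A x, propagated with the same RK4 sub-stepping
// (used to certify the filter against a closed-form Kalman filter).
static void prop_lin(vec& pt, const mat& A, double dt, int n_sub) {
  const double h = dt / n_sub;
  const int n = pt.n_elem;
  vec k1(n), k2(n), k3(n), k4(n);
  for (int s = 0; s < n_sub; ++s) {
    k1 = A * pt;
    k2 = A * (pt + 0.5 * h * k1);
    k3 = A * (pt + 0.5 * h * k2);
    k4 = A * (pt + h * k3);
    pt += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
}

// One unscented prediction: sigma points -> deterministic propagation ->
// recombination + discretized process noise Q * dt.  model: 0 = augmented
// NMM (pars used), 1 = linear (Alin used).
static void ukf_predict_core(vec& m, mat& P, int model, const vec& pars,
                             const mat& Alin, const vec& Qdiag, double dt,
                             int n_sub, double alpha, double beta,
                             double kappa, double bound, int sample_idx) {
  const int n = m.n_elem;
  UTWeights w(n, alpha, beta, kappa);
  mat X;
  if (!make_sigma(m, P, alpha, kappa, X))
    Rcpp::stop("sigma-point factorization failed at sample %d", sample_idx);
  for (uword j = 0; j < X.n_cols; ++j) {
    if (model == 0) {
      prop_aug(X.colptr(j), pars.memptr(), dt, n_sub);
      check_bound(X.colptr(j), n, bound, sample_idx);
    } else {
      vec col = X.col(j);
      prop_lin(col, Alin, dt, n_sub);
      X.col(j) = col;
    }
  }
  vec mp = w.wm0 * X.col(0);
  for (int j = 1; j < 2 * n + 1; ++j) mp += w.wi * X.col(j);
  mat Pp(n, n, fill::zeros);
  vec d = X.col(0) - mp;
  Pp += w.wc0 * (d * d.t());
  for (int j = 1; j < 2 * n + 1; ++j) {
    d = X.col(j) - mp;
    Pp += w.wi * (d * d.t());
  }
  Pp += diagmat(Qdiag * dt);
  m = mp;
  P = 0.5 * (Pp + Pp.t());
}

// Linear measurement update y = h' x + e, e ~ N(0, R).  Exact because the
// observation operator is linear; no sigma points needed.
static double ukf_update_core(vec& m, mat& P, double y, const vec& h,
                              double R, double& innov_var) {
  vec Ph = P * h;
  innov_var = dot(h, Ph) + R;
  const double innov = y - dot(h, m);
  vec K = Ph / innov_var;
  m += K * innov;
  P -= K * Ph.t();
  P = 0.5 * (P + P.t());
  return innov;
}

// [[Rcpp::export]]
Rcpp::List cpp_ukf_predict(const arma::vec& m, const arma::mat& P, int model,
                           const arma::vec& pars, const arma::mat& Alin,
                           const arma::vec& Qdiag, double dt, int n_sub,
                           double alpha, double beta, double kappa,
                           double bound) {
  vec mm = m;
  mat PP = P;
  ukf_predict_core(mm, PP, model, pars, Alin, Qdiag, dt, n_sub, alpha, beta,
                   kappa, bound, 0);
  return Rcpp::List::create(Rcpp::Named("mean") = mm, Rcpp::Named("cov") = PP);
}

// [[Rcpp::export]]
Rcpp::List cpp_ukf_update(const arma::vec& m, const arma::mat& P, double y,
                          const arma::vec& h, double R) {
  vec mm = m;
  mat PP = P;
  double iv;
  double innov = ukf_update_core(mm, PP, y, h, R, iv);
  return Rcpp::List::create(Rcpp::Named("mean") = mm, Rcpp::Named("cov") = PP,
                            Rcpp::Named("innovation") = innov,
                            Rcpp::Named("innovation_var") = iv);
}

// Full filter pass.  Per sample: predict over the inter-sample interval,
// then linear update.  Returns posterior means/sds, innovations and their
// variances, and the accumulated Gaussian log-likelihood.
// [[Rcpp::export]]
Rcpp::List cpp_ukf_filter(const arma::vec& y, double dt_obs, int model,
                          const arma::vec& pars, const arma::mat& Alin,
                          const arma::vec& Qdiag, double Rvar,
                          const arma::vec& h, const arma::vec& m0,
                          const arma::mat& P0, int n_sub, double alpha,
                          double beta, double kappa, double bound) {
  const int N = y.n_elem, n = m0.n_elem;
  vec m = m0;
  mat P = P0;
  mat means(N, n), sds(N, n);
  vec innov(N), innov_var(N);
  double ll = 0.0;
  for (int t = 0; t < N; ++t) {
    ukf_predict_core(m, P, model, pars, Alin, Qdiag, dt_obs, n_sub, alpha,
                     beta, kappa, bound, t + 1);
    double iv;
    innov[t] = ukf_update_core(m, P, y[t], h, Rvar, iv);
    innov_var[t] = iv;
    ll += -0.5 * (std::log(2.0 * M_PI * iv) + innov[t] * innov[t] / iv);
    means.row(t) = m.t();
    sds.row(t) = sqrt(clamp(P.diag(), 0.0, datum::inf)).t();
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("means") = means, Rcpp::Named("sds") = sds,
      Rcpp::Named("innovation") = innov,
      Rcpp::Named("innovation_var") = innov_var,
      Rcpp::Named("loglik") = ll);
}
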