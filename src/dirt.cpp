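// Gibbs sampler core for the DIR-RT joint model of dichotomous item
// responses and test-level response times.
//
// Layout conventions (all indices 0-based, prepared by the R wrappers):
//   cells  = person-date pairs, grouped contiguously by person, dates in
//            chronological order within person;
//   tests  = grouped contiguously by cell;
//   items  = grouped contiguously by test.
// All randomness goes through R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ------------------------------------------------------------------
// one-sided truncated normal (Robert 1995 exponential rejection in the
// tail, plain rejection otherwise); stable for |mean|/sd up to ~30
// ------------------------------------------------------------------

static double rtnorm_lower_std(double a) {
  if (a < 0.45) {
    double x;
    do { x = R::norm_rand(); } while (x < a);
    return x;
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + R::exp_rand() / alpha;
    double diff = x - alpha;
    if (std::log(R::unif_rand()) <= -0.5 * diff * diff) return x;
  }
}

// draw from N(mean, sd^2) truncated to (0, inf) if positive, else (-inf, 0]
static double rtnorm1(double mean, double sd, bool positive) {
  if (positive) {
    double a = (0.0 - mean) / sd;
    return mean + sd * rtnorm_lower_std(a);
  } else {
    double a = mean / sd;
    return mean - sd * rtnorm_lower_std(a);
  }
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm(int n, double mean, double sd, bool positive) {
  if (sd <= 0.0) stop("sd must be positive");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm1(mean, sd, positive);
  return out;
}

// ------------------------------------------------------------------
// Kolmogorov-Smirnov mixing-scale sampler.
//
// The standard logistic law is a scale mixture of normals: eps = 2*psi*N(0,1)
// with psi ~ K-S.  Writing lambda = (2*psi)^2, the mixing density is
//   f(lambda) = sum_{n>=1} (-1)^{n+1} n^2 exp(-n^2 lambda / 2),
// and the full conditional given a residual r is
//   p(lambda | r) ∝ lambda^{-1/2} exp(-r^2/(2 lambda)) f(lambda).
// Proposal: lambda ~ GIG(1/2, 1, r^2), sampled through 1/lambda ~
// InverseGaussian(1/|r|, 1).  The acceptance function is
//   alpha(lambda) = exp(lambda/2) f(lambda) <= 1,
// evaluated by an alternating-series squeeze for lambda > 4/3 and by the
// Jacobi theta-transformed (all-positive) series otherwise, summed below
// double precision so the left branch is exact.
// ------------------------------------------------------------------

static bool ks_accept(double lam, double u) {
  if (lam > 4.0 / 3.0) {
    double Z = 1.0, X = std::exp(-0.5 * lam);
    int j = 0;
    for (;;) {
      ++j;
      double n = j + 1.0;
      Z -= n * n * std::pow(X, n * n - 1.0);
      if (Z > u) return true;
      ++j;
      n = j + 1.0;
      Z += n * n * std::pow(X, n * n - 1.0);
      if (Z < u) return false;
      if (j > 1000) stop("K-S scale sampler: series squeeze did not converge");
    }
  } else {
    double H = 0.5 * std::log(2.0) + 2.5 * std::log(M_PI)
      - 2.5 * std::log(lam) - M_PI * M_PI / (2.0 * lam) + 0.5 * lam;
    double K = lam / (M_PI * M_PI);
    double X = std::exp(-M_PI * M_PI / (2.0 * lam));
    double S = 0.0;
    for (int m = 1; m <= 41; m += 2) {
      double term = (m * m - K) * std::pow(X, (double)(m * m - 1));
      S += term;
      if (term < 1e-17 * S) break;
    }
    return std::log(u) < H + std::log(S);
  }
}

// returns lambda = (2 psi)^2; counts proposals through *tries
static double draw_lambda_ks(double r, long* tries) {
  double ar = std::fabs(r);
  if (ar < 1e-6) ar = 1e-6;
  double mu = 1.0 / ar;
  for (int k = 0; k < 10000; ++k) {
    if (tries) ++(*tries);
    double v = R::norm_rand();
    v *= v;
    double w = mu + 0.5 * mu * mu * v
      - 0.5 * mu * std::sqrt(4.0 * mu * v + mu * mu * v * v);
    double x = (R::unif_rand() <= mu / (mu + w)) ? w : mu * mu / w;
    double lam = 1.0 / x;
    if (!R_finite(lam) || lam <= 0.0) continue;
    if (ks_accept(lam, R::unif_rand())) return lam;
  }
  stop("K-S scale sampler failed to accept after 10000 proposals");
}

// [[Rcpp::export]]
List cpp_ks_scale(NumericVector residual) {
  int n = residual.size();
  NumericVector psi(n);
  long tries = 0;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(residual[i])) stop("non-finite residual in K-S scale draw");
    psi[i] = 0.5 * std::sqrt(draw_lambda_ks(residual[i], &tries));
  }
  return List::create(_["psi"] = psi, _["proposals"] = (double)tries);
}

// ------------------------------------------------------------------
// scalar-state Kalman forward filter + backward sampler / smoother.
// state:  theta_t = cc[t] * theta_{t-1} + aa[t] + N(0, qq[t]),  t >= 1
// prior:  theta_0 ~ N(mu0, v0)
// obs:    pooled precision P[t] >= 0, precision-weighted sum W[t]
// ------------------------------------------------------------------

static void kalman_filter(int T, const double* cc, const double* aa,
                          const double* qq, const double* P, const double* W,
                          double mu0, double v0, double* m, double* v,
                          double* mpred, double* vpred) {
  for (int t = 0; t < T; ++t) {
    double mp, vp;
    if (t == 0) { mp = mu0; vp = v0; }
    else { mp = cc[t] * m[t - 1] + aa[t]; vp = cc[t] * cc[t] * v[t - 1] + qq[t]; }
    double prec = 1.0 / vp + P[t];
    m[t] = (mp / vp + W[t]) / prec;
    v[t] = 1.0 / prec;
    if (mpred) { mpred[t] = mp; vpred[t] = vp; }
  }
}

static void ffbs_draw(int T, const double* cc, const double* aa,
                      const double* qq, const double* P, const double* W,
                      double mu0, double v0, double* out) {
  std::vector<double> m(T), v(T);
  kalman_filter(T, cc, aa, qq, P, W, mu0, v0, m.data(), v.data(), NULL, NULL);
  out[T - 1] = m[T - 1] + std::sqrt(v[T - 1]) * R::norm_rand();
  for (int t = T - 2; t >= 0; --t) {
    double prec = 1.0 / v[t] + cc[t + 1] * cc[t + 1] / qq[t + 1];
    double mean = (m[t] / v[t]
                   + cc[t + 1] * (out[t + 1] - aa[t + 1]) / qq[t + 1]) / prec;
    out[t] = mean + std::sqrt(1.0 / prec) * R::norm_rand();
  }
}

// smoothed (conditional) mean, variance and lag-1 covariance, for
// validation against a dense joint-Gaussian solve
// [[Rcpp::export]]
List cpp_ffbs_moments(NumericVector cc, NumericVector aa, NumericVector qq,
                      NumericVector P, NumericVector W,
                      double mu0, double v0) {
  int T = P.size();
  std::vector<double> m(T), v(T), mp(T), vp(T);
  kalman_filter(T, cc.begin(), aa.begin(), qq.begin(), P.begin(), W.begin(),
                mu0, v0, m.data(), v.data(), mp.data(), vp.data());
  NumericVector sm(T), sv(T), lag1(std::max(T - 1, 0));
  sm[T - 1] = m[T - 1];
  sv[T - 1] = v[T - 1];
  for (int t = T - 2; t >= 0; --t) {
    double J = v[t] * cc[t + 1] / vp[t + 1];
    sm[t] = m[t] + J * (sm[t + 1] - mp[t + 1]);
    sv[t] = v[t] + J * J * (sv[t + 1] - vp[t + 1]);
    lag1[t] = J * sv[t + 1];
  }
  return List::create(_["mean"] = sm, _["var"] = sv, _["lag1cov"] = lag1);
}

// [[Rcpp::export]]
NumericVector cpp_ffbs_draw(NumericVector cc, NumericVector aa,
                            NumericVector qq, NumericVector P,
                            NumericVector W, double mu0, double v0) {
  int T = P.size();
  NumericVector out(T);
  ffbs_draw(T, cc.begin(), aa.begin(), qq.begin(), P.begin(), W.begin(),
            mu0, v0, out.begin());
  return out;
}

// ------------------------------------------------------------------
// single-site inverted-U ability draw: exact-up-to-grid inverse-cdf
// sampler for the conditional
//   p(theta) ∝ N(theta; m0, v0) *
//              prod_s exp(-lam_eps/2 * (r_s - rho*(theta - d_s)^2)^2)
// The second factor is bounded by 1, so the Gaussian part envelopes the
// density and a grid of +-width sd around m0 captures all but a
// negligible tail.
// ------------------------------------------------------------------

static double theta_invu_draw(double m0, double v0, double rho,
                              double lam_eps, int S, const double* r,
                              const double* d, int grid_n, double width) {
  double s0 = std::sqrt(v0);
  double lo = m0 - width * s0;
  double step = 2.0 * width * s0 / (grid_n - 1);
  std::vector<double> lw(grid_n);
  double mx = -1e300;
  for (int g = 0; g < grid_n; ++g) {
    double th = lo + g * step;
    double z = (th - m0) / s0;
    double lp = -0.5 * z * z;
    for (int s = 0; s < S; ++s) {
      double dev = r[s] - rho * (th - d[s]) * (th - d[s]);
      lp += -0.5 * lam_eps * dev * dev;
    }
    lw[g] = lp;
    if (lp > mx) mx = lp;
  }
  double tot = 0.0;
  for (int g = 0; g < grid_n; ++g) { lw[g] = std::exp(lw[g] - mx); tot += lw[g]; }
  double u = R::unif_rand() * tot, acc = 0.0;
  int pick = grid_n - 1;
  for (int g = 0; g < grid_n; ++g) {
    acc += lw[g];
    if (u <= acc) { pick = g; break; }
  }
  // piecewise-constant cell around the chosen node
  return lo + pick * step + (R::unif_rand() - 0.5) * step;
}

// [[Rcpp::export]]
NumericVector cpp_theta_invu_draws(int n, double m0, double v0, double rho,
                                   double lam_eps, NumericVector r,
                                   NumericVector d, int grid_n, double width) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = theta_invu_draw(m0, v0, rho, lam_eps, r.size(), r.begin(),
                             d.begin(), grid_n, width);
  return out;
}

// ------------------------------------------------------------------
// model workspace
// ------------------------------------------------------------------

struct Model {
  int np, ncell, ntest, nitem;
  IntegerVector cell_person;
  NumericVector cell_lapse;   // capped lapse to previous date; <= 0 on first date
  IntegerVector test_cell;
  NumericVector d;
  bool has_times;
  NumericVector logT;
  IntegerVector item_test;
  IntegerVector y;
  double sigma_b, theta_M;
  NumericVector mu0, s0;
  std::vector<int> pcell0, ctest0, titem0; // group offsets
  std::vector<int> item_cell;

  Model(List dat) {
    np = as<int>(dat["n_persons"]);
    cell_person = dat["cell_person"];
    cell_lapse = dat["cell_lapse"];
    test_cell = dat["test_cell"];
    d = dat["d"];
    has_times = as<bool>(dat["has_times"]);
    if (has_times) logT = dat["logT"]; else logT = NumericVector(0);
    item_test = dat["item_test"];
    y = dat["y"];
    sigma_b = as<double>(dat["sigma_b"]);
    theta_M = as<double>(dat["theta_M"]);
    mu0 = dat["mu0"];
    s0 = dat["s0"];
    ncell = cell_person.size();
    ntest = test_cell.size();
    nitem = item_test.size();
    pcell0 = offsets(cell_person, np, ncell, "cells by person");
    ctest0 = offsets(test_cell, ncell, ntest, "tests by cell");
    titem0 = offsets(item_test, ntest, nitem, "items by test");
    item_cell.resize(nitem);
    for (int k = 0; k < nitem; ++k) item_cell[k] = test_cell[item_test[k]];
  }

  static std::vector<int> offsets(const IntegerVector& g, int ngroup, int n,
                                  const char* what) {
    std::vector<int> off(ngroup + 1, 0);
    int prev = -1;
    for (int k = 0; k < n; ++k) {
      if (g[k] < prev || g[k] < 0 || g[k] >= ngroup)
        stop("index arrays must be grouped and sorted (%s)", what);
      prev = g[k];
      off[g[k] + 1]++;
    }
    for (int j = 0; j < ngroup; ++j) off[j + 1] += off[j];
    return off;
  }
};

struct State {
  NumericVector theta, delta, tau, e, b, z, psi;
  NumericVector beta, gamma, lam_delta, lam_e, lam_tau;
  double rho, lam_theta, lam_eps;
  long ks_proposals, ks_draws;

  State(List st) {
    theta = clone(as<NumericVector>(st["theta"]));
    delta = clone(as<NumericVector>(st["delta"]));
    tau = clone(as<NumericVector>(st["tau"]));
    e = clone(as<NumericVector>(st["e"]));
    b = clone(as<NumericVector>(st["b"]));
    z = clone(as<NumericVector>(st["z"]));
    psi = clone(as<NumericVector>(st["psi"]));
    beta = clone(as<NumericVector>(st["beta"]));
    gamma = clone(as<NumericVector>(st["gamma"]));
    lam_delta = clone(as<NumericVector>(st["lam_delta"]));
    lam_e = clone(as<NumericVector>(st["lam_e"]));
    lam_tau = clone(as<NumericVector>(st["lam_tau"]));
    rho = as<double>(st["rho"]);
    lam_theta = as<double>(st["lam_theta"]);
    lam_eps = as<double>(st["lam_eps"]);
    ks_proposals = ks_draws = 0;
  }

  List as_list() const {
    return List::create(
      _["theta"] = theta, _["delta"] = delta, _["tau"] = tau, _["e"] = e,
      _["b"] = b, _["z"] = z, _["psi"] = psi, _["beta"] = beta,
      _["gamma"] = gamma, _["lam_delta"] = lam_delta, _["lam_e"] = lam_e,
      _["lam_tau"] = lam_tau, _["rho"] = rho, _["lam_theta"] = lam_theta,
      _["lam_eps"] = lam_eps);
  }
};

struct Priors {
  double a_delta, b_delta, a_e, b_e, a_tau, b_tau, a_theta, b_theta,
    a_eps, b_eps, beta_mean, beta_sd, rho_fallback_sd,
    gamma_mean, gamma_prec, rho_mean, rho_prec;
  Priors(List pr) {
    a_delta = as<double>(pr["a_delta"]); b_delta = as<double>(pr["b_delta"]);
    a_e = as<double>(pr["a_e"]); b_e = as<double>(pr["b_e"]);
    a_tau = as<double>(pr["a_tau"]); b_tau = as<double>(pr["b_tau"]);
    a_theta = as<double>(pr["a_theta"]); b_theta = as<double>(pr["b_theta"]);
    a_eps = as<double>(pr["a_eps"]); b_eps = as<double>(pr["b_eps"]);
    beta_mean = as<double>(pr["beta_mean"]); beta_sd = as<double>(pr["beta_sd"]);
    rho_fallback_sd = as<double>(pr["rho_fallback_sd"]);
    // Gaussian priors for gamma and rho; precision 0 means flat
    gamma_mean = pr.containsElementNamed("gamma_mean") ?
      as<double>(pr["gamma_mean"]) : 0.0;
    gamma_prec = pr.containsElementNamed("gamma_prec") ?
      as<double>(pr["gamma_prec"]) : 0.0;
    rho_mean = pr.containsElementNamed("rho_mean") ?
      as<double>(pr["rho_mean"]) : 0.0;
    rho_prec = pr.containsElementNamed("rho_prec") ?
      as<double>(pr["rho_prec"]) : 0.0;
  }
};

// linear predictor of the augmented response for item k
static inline double eta_item(const Model& M, const State& S, int k) {
  int t = M.item_test[k], c = M.item_cell[k];
  return S.theta[c] - S.b[k] + S.delta[c] + S.e[t];
}

// transition coefficients for a cell that has a predecessor
static inline void trans_coef(const Model& M, const State& S, int cell,
                              double* cc, double* aa, double* qq) {
  int p = M.cell_person[cell];
  double h = M.cell_lapse[cell];
  *cc = 1.0 - S.beta[p] * h / M.theta_M;
  *aa = S.beta[p] * h;
  *qq = h / S.lam_theta;
}

// ------------------------------------------------------------------
// Gibbs blocks
// ------------------------------------------------------------------

static void upd_z(const Model& M, State& S) {
  for (int k = 0; k < M.nitem; ++k) {
    double eta = eta_item(M, S, k);
    S.z[k] = rtnorm1(eta, 2.0 * S.psi[k], M.y[k] == 1);
  }
}

static void upd_psi(const Model& M, State& S) {
  for (int k = 0; k < M.nitem; ++k) {
    double r = S.z[k] - eta_item(M, S, k);
    S.psi[k] = 0.5 * std::sqrt(draw_lambda_ks(r, &S.ks_proposals));
    ++S.ks_draws;
  }
}

static void upd_b(const Model& M, State& S) {
  double pb = 1.0 / (M.sigma_b * M.sigma_b);
  for (int k = 0; k < M.nitem; ++k) {
    int t = M.item_test[k], c = M.item_cell[k];
    double pl = 1.0 / (4.0 * S.psi[k] * S.psi[k]);
    double u = S.theta[c] + S.delta[c] + S.e[t] - S.z[k];
    double prec = pb + pl;
    double mean = (M.d[t] * pb + u * pl) / prec;
    S.b[k] = mean + std::sqrt(1.0 / prec) * R::norm_rand();
  }
}

static void upd_delta(const Model& M, State& S) {
  for (int c = 0; c < M.ncell; ++c) {
    int p = M.cell_person[c];
    double prec = S.lam_delta[p], wsum = 0.0;
    for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t) {
      for (int k = M.titem0[t]; k < M.titem0[t + 1]; ++k) {
        double pl = 1.0 / (4.0 * S.psi[k] * S.psi[k]);
        prec += pl;
        wsum += pl * (S.z[k] + S.b[k] - S.theta[c] - S.e[t]);
      }
    }
    S.delta[c] = wsum / prec + std::sqrt(1.0 / prec) * R::norm_rand();
  }
}

// constrained (sum-to-zero) test random effects: draw the unconstrained
// Gaussian conditional, then condition exactly on the linear constraint
static void upd_e(const Model& M, State& S) {
  std::vector<double> mean, var;
  for (int c = 0; c < M.ncell; ++c) {
    int p = M.cell_person[c];
    int s0 = M.ctest0[c], s1 = M.ctest0[c + 1], nS = s1 - s0;
    if (nS == 1) { S.e[s0] = 0.0; continue; }
    mean.assign(nS, 0.0); var.assign(nS, 0.0);
    double esum = 0.0, vsum = 0.0;
    for (int t = s0; t < s1; ++t) {
      double prec = S.lam_e[p], wsum = 0.0;
      for (int k = M.titem0[t]; k < M.titem0[t + 1]; ++k) {
        double pl = 1.0 / (4.0 * S.psi[k] * S.psi[k]);
        prec += pl;
        wsum += pl * (S.z[k] + S.b[k] - S.theta[c] - S.delta[c]);
      }
      double v = 1.0 / prec;
      double draw = wsum * v + std::sqrt(v) * R::norm_rand();
      mean[t - s0] = draw; var[t - s0] = v;
      esum += draw; vsum += v;
    }
    for (int t = s0; t < s1; ++t)
      S.e[t] = mean[t - s0] - var[t - s0] * esum / vsum;
    // wash out residual round-off so the constraint holds exactly
    double resid = 0.0;
    for (int t = s0; t < s1; ++t) resid += S.e[t];
    for (int t = s0; t < s1; ++t) S.e[t] -= resid / nS;
  }
}

// pooled pseudo-observations of theta per cell (item part, plus the time
// part when the monotone linkage makes log-times linear in theta)
static void theta_obs(const Model& M, const State& S, int linkage,
                      bool use_times, std::vector<double>& P,
                      std::vector<double>& W) {
  P.assign(M.ncell, 0.0);
  W.assign(M.ncell, 0.0);
  for (int k = 0; k < M.nitem; ++k) {
    int t = M.item_test[k], c = M.item_cell[k];
    double pl = 1.0 / (4.0 * S.psi[k] * S.psi[k]);
    P[c] += pl;
    W[c] += pl * (S.z[k] + S.b[k] - S.delta[c] - S.e[t]);
  }
  if (use_times && linkage == 0 && S.rho != 0.0) {
    for (int t = 0; t < M.ntest; ++t) {
      int c = M.test_cell[t];
      int p = M.cell_person[c];
      double prec = S.rho * S.rho * S.lam_eps;
      double val = (M.logT[t] - S.gamma[p] + S.tau[c] + S.rho * M.d[t]) / S.rho;
      P[c] += prec;
      W[c] += prec * val;
    }
  }
}

static void upd_theta_ffbs(const Model& M, State& S, int linkage) {
  std::vector<double> P, W;
  theta_obs(M, S, linkage, M.has_times, P, W);
  std::vector<double> cc, aa, qq, Pp, Wp, out;
  for (int p = 0; p < M.np; ++p) {
    int c0 = M.pcell0[p], c1 = M.pcell0[p + 1], T = c1 - c0;
    if (T == 0) continue;
    cc.assign(T, 0.0); aa.assign(T, 0.0); qq.assign(T, 1.0);
    Pp.assign(T, 0.0); Wp.assign(T, 0.0); out.assign(T, 0.0);
    for (int t = 1; t < T; ++t)
      trans_coef(M, S, c0 + t, &cc[t], &aa[t], &qq[t]);
    for (int t = 0; t < T; ++t) { Pp[t] = P[c0 + t]; Wp[t] = W[c0 + t]; }
    ffbs_draw(T, cc.data(), aa.data(), qq.data(), Pp.data(), Wp.data(),
              M.mu0[p], M.s0[p] * M.s0[p], out.data());
    for (int t = 0; t < T; ++t) S.theta[c0 + t] = out[t];
  }
}

static void upd_theta_single_site(const Model& M, State& S, int grid_n,
                                  double grid_width) {
  std::vector<double> r, d;
  for (int p = 0; p < M.np; ++p) {
    int c0 = M.pcell0[p], c1 = M.pcell0[p + 1], T = c1 - c0;
    for (int t = 0; t < T; ++t) {
      int c = c0 + t;
      double prec = 0.0, wsum = 0.0;
      if (t == 0) {
        double v = M.s0[p] * M.s0[p];
        prec += 1.0 / v; wsum += M.mu0[p] / v;
      } else {
        double cc, aa, qq;
        trans_coef(M, S, c, &cc, &aa, &qq);
        prec += 1.0 / qq;
        wsum += (cc * S.theta[c - 1] + aa) / qq;
      }
      if (t < T - 1) {
        double cc, aa, qq;
        trans_coef(M, S, c + 1, &cc, &aa, &qq);
        prec += cc * cc / qq;
        wsum += cc * (S.theta[c + 1] - aa) / qq;
      }
      for (int s = M.ctest0[c]; s < M.ctest0[c + 1]; ++s) {
        for (int k = M.titem0[s]; k < M.titem0[s + 1]; ++k) {
          double pl = 1.0 / (4.0 * S.psi[k] * S.psi[k]);
          prec += pl;
          wsum += pl * (S.z[k] + S.b[k] - S.delta[c] - S.e[s]);
        }
      }
      double m0 = wsum / prec, v0 = 1.0 / prec;
      if (!M.has_times) {
        S.theta[c] = m0 + std::sqrt(v0) * R::norm_rand();
        continue;
      }
      r.clear(); d.clear();
      for (int s = M.ctest0[c]; s < M.ctest0[c + 1]; ++s) {
        r.push_back(M.logT[s] - S.gamma[p] + S.tau[c]);
        d.push_back(M.d[s]);
      }
      S.theta[c] = theta_invu_draw(m0, v0, S.rho, S.lam_eps, (int)r.size(),
                                   r.data(), d.data(), grid_n, grid_width);
    }
  }
}

static void upd_beta(const Model& M, State& S, const Priors& PR) {
  for (int p = 0; p < M.np; ++p) {
    double sxx = 0.0, sxy = 0.0;
    for (int c = M.pcell0[p] + 1; c < M.pcell0[p + 1]; ++c) {
      double h = M.cell_lapse[c];
      double x = h * (1.0 - S.theta[c - 1] / M.theta_M);
      double yv = S.theta[c] - S.theta[c - 1];
      sxx += x * x / h;
      sxy += x * yv / h;
    }
    double prec = 1.0 / (PR.beta_sd * PR.beta_sd) + S.lam_theta * sxx;
    double mean = (PR.beta_mean / (PR.beta_sd * PR.beta_sd)
                   + S.lam_theta * sxy) / prec;
    S.beta[p] = rtnorm1(mean, std::sqrt(1.0 / prec), true);
  }
}

static inline double fval(int linkage, double x) {
  return linkage == 0 ? x : x * x;
}

static void upd_time_block(const Model& M, State& S, const Priors& PR,
                           int linkage) {
  if (!M.has_times) return;
  // gamma_i | . (flat prior by default; optional Gaussian)
  for (int p = 0; p < M.np; ++p) {
    double sum = 0.0; int n = 0;
    for (int c = M.pcell0[p]; c < M.pcell0[p + 1]; ++c) {
      for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t) {
        double f = fval(linkage, S.theta[c] - M.d[t]);
        sum += M.logT[t] + S.tau[c] - S.rho * f;
        ++n;
      }
    }
    double prec = PR.gamma_prec + n * S.lam_eps;
    if (prec > 0.0) {
      double mean = (PR.gamma_prec * PR.gamma_mean + S.lam_eps * sum) / prec;
      S.gamma[p] = mean + std::sqrt(1.0 / prec) * R::norm_rand();
    }
  }
  // tau_it | . (zero-mean Gaussian prior)
  for (int c = 0; c < M.ncell; ++c) {
    int p = M.cell_person[c];
    double wsum = 0.0; int n = 0;
    for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t) {
      double f = fval(linkage, S.theta[c] - M.d[t]);
      wsum += S.gamma[p] + S.rho * f - M.logT[t];
      ++n;
    }
    double prec = S.lam_tau[p] + n * S.lam_eps;
    S.tau[c] = S.lam_eps * wsum / prec + std::sqrt(1.0 / prec) * R::norm_rand();
  }
  // rho | . (flat prior)
  double sff = 0.0, sfy = 0.0;
  for (int c = 0; c < M.ncell; ++c) {
    int p = M.cell_person[c];
    for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t) {
      double f = fval(linkage, S.theta[c] - M.d[t]);
      double yv = M.logT[t] - S.gamma[p] + S.tau[c];
      sff += f * f;
      sfy += f * yv;
    }
  }
  double rprec = PR.rho_prec + S.lam_eps * sff;
  if (S.lam_eps * sff > 1e-12 || PR.rho_prec > 0.0) {
    double mean = (PR.rho_prec * PR.rho_mean + S.lam_eps * sfy) / rprec;
    S.rho = mean + std::sqrt(1.0 / rprec) * R::norm_rand();
  } else {
    S.rho = PR.rho_fallback_sd * R::norm_rand(); // no linkage signal
  }
}

static void upd_precisions(const Model& M, State& S, const Priors& PR,
                           int linkage) {
  for (int p = 0; p < M.np; ++p) {
    double ssd = 0.0, sst = 0.0, sse = 0.0;
    int T = M.pcell0[p + 1] - M.pcell0[p], dfe = 0;
    for (int c = M.pcell0[p]; c < M.pcell0[p + 1]; ++c) {
      ssd += S.delta[c] * S.delta[c];
      sst += S.tau[c] * S.tau[c];
      int nS = M.ctest0[c + 1] - M.ctest0[c];
      dfe += nS - 1;
      for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t)
        sse += S.e[t] * S.e[t];
    }
    S.lam_delta[p] = R::rgamma(PR.a_delta + 0.5 * T,
                               1.0 / (PR.b_delta + 0.5 * ssd));
    S.lam_e[p] = R::rgamma(PR.a_e + 0.5 * dfe, 1.0 / (PR.b_e + 0.5 * sse));
    if (M.has_times)
      S.lam_tau[p] = R::rgamma(PR.a_tau + 0.5 * T,
                               1.0 / (PR.b_tau + 0.5 * sst));
  }
  // lam_theta (shared)
  double sstr = 0.0; int ntr = 0;
  for (int p = 0; p < M.np; ++p) {
    for (int c = M.pcell0[p] + 1; c < M.pcell0[p + 1]; ++c) {
      double cc, aa, qq;
      trans_coef(M, S, c, &cc, &aa, &qq);
      double resid = S.theta[c] - cc * S.theta[c - 1] - aa;
      sstr += resid * resid / M.cell_lapse[c];
      ++ntr;
    }
  }
  S.lam_theta = R::rgamma(PR.a_theta + 0.5 * ntr, 1.0 / (PR.b_theta + 0.5 * sstr));
  // lam_eps (shared, time residuals)
  if (M.has_times) {
    double sse = 0.0;
    for (int c = 0; c < M.ncell; ++c) {
      int p = M.cell_person[c];
      for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t) {
        double f = fval(linkage, S.theta[c] - M.d[t]);
        double resid = M.logT[t] - (S.gamma[p] - S.tau[c] + S.rho * f);
        sse += resid * resid;
      }
    }
    S.lam_eps = R::rgamma(PR.a_eps + 0.5 * M.ntest, 1.0 / (PR.b_eps + 0.5 * sse));
  }
}

static void check_finite(const NumericVector& x, const char* block, int iter) {
  for (int i = 0; i < x.size(); ++i)
    if (!R_finite(x[i]))
      stop("MCMC diverged in block '%s' at iteration %d", block, iter + 1);
}

static void run_block(const Model& M, State& S, const Priors& PR, int linkage,
                      int grid_n, double grid_width, int block, int iter) {
  switch (block) {
  case 1: upd_z(M, S); check_finite(S.z, "z", iter); break;
  case 2: upd_psi(M, S); check_finite(S.psi, "psi", iter); break;
  case 3: upd_b(M, S); check_finite(S.b, "b", iter); break;
  case 4: upd_delta(M, S); check_finite(S.delta, "delta", iter); break;
  case 5: upd_e(M, S); check_finite(S.e, "e", iter); break;
  case 6:
    if (linkage == 0 || !M.has_times) upd_theta_ffbs(M, S, linkage);
    else upd_theta_single_site(M, S, grid_n, grid_width);
    check_finite(S.theta, "theta", iter);
    break;
  case 7: upd_beta(M, S, PR); check_finite(S.beta, "beta", iter); break;
  case 8:
    upd_time_block(M, S, PR, linkage);
    check_finite(S.gamma, "time", iter);
    check_finite(S.tau, "time", iter);
    if (!R_finite(S.rho)) stop("MCMC diverged in block 'time' at iteration %d", iter + 1);
    break;
  case 9:
    upd_precisions(M, S, PR, linkage);
    check_finite(S.lam_delta, "precisions", iter);
    check_finite(S.lam_e, "precisions", iter);
    check_finite(S.lam_tau, "precisions", iter);
    if (!R_finite(S.lam_theta) || !R_finite(S.lam_eps))
      stop("MCMC diverged in block 'precisions' at iteration %d", iter + 1);
    break;
  default: stop("unknown Gibbs block id %d", block);
  }
}

// single sweep (or selected blocks), exported for unit-testing the
// individual full conditionals
// [[Rcpp::export]]
List cpp_sweep(List dat, List state, List priors, int linkage,
               IntegerVector blocks, int grid_n = 301,
               double grid_width = 8.0) {
  Model M(dat);
  State S(state);
  Priors PR(priors);
  for (int j = 0; j < blocks.size(); ++j)
    run_block(M, S, PR, linkage, grid_n, grid_width, blocks[j], 0);
  return S.as_list();
}

// [[Rcpp::export]]
List cpp_run_chain(List dat, List state, List priors, List cfg) {
  Model M(dat);
  State S(state);
  Priors PR(priors);
  int n_iter = as<int>(cfg["n_iter"]);
  int burn_in = as<int>(cfg["burn_in"]);
  int thin = as<int>(cfg["thin"]);
  int linkage = as<int>(cfg["linkage"]);
  int grid_n = as<int>(cfg["grid_n"]);
  double grid_width = as<double>(cfg["grid_width"]);
  bool store_latent = as<bool>(cfg["store_latent"]);

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix dr_theta(n_keep, M.ncell), dr_beta(n_keep, M.np),
    dr_gamma(n_keep, M.np), dr_ld(n_keep, M.np), dr_le(n_keep, M.np),
    dr_lt(n_keep, M.np);
  NumericVector dr_rho(n_keep), dr_lth(n_keep), dr_lep(n_keep),
    e_maxsum(n_keep);
  NumericMatrix dr_delta, dr_e, dr_tau;
  if (store_latent) {
    dr_delta = NumericMatrix(n_keep, M.ncell);
    dr_e = NumericMatrix(n_keep, M.ntest);
    dr_tau = NumericMatrix(n_keep, M.ncell);
  }

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int blk = 1; blk <= 9; ++blk)
      run_block(M, S, PR, linkage, grid_n, grid_width, blk, it);
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int c = 0; c < M.ncell; ++c) dr_theta(kept, c) = S.theta[c];
      for (int p = 0; p < M.np; ++p) {
        dr_beta(kept, p) = S.beta[p];
        dr_gamma(kept, p) = S.gamma[p];
        dr_ld(kept, p) = S.lam_delta[p];
        dr_le(kept, p) = S.lam_e[p];
        dr_lt(kept, p) = S.lam_tau[p];
      }
      dr_rho[kept] = S.rho;
      dr_lth[kept] = S.lam_theta;
      dr_lep[kept] = S.lam_eps;
      double mx = 0.0;
      for (int c = 0; c < M.ncell; ++c) {
        double sm = 0.0;
        for (int t = M.ctest0[c]; t < M.ctest0[c + 1]; ++t) sm += S.e[t];
        if (std::fabs(sm) > mx) mx = std::fabs(sm);
      }
      e_maxsum[kept] = mx;
      if (store_latent) {
        for (int c = 0; c < M.ncell; ++c) {
          dr_delta(kept, c) = S.delta[c];
          dr_tau(kept, c) = S.tau[c];
        }
        for (int t = 0; t < M.ntest; ++t) dr_e(kept, t) = S.e[t];
      }
      ++kept;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["theta"] = dr_theta, _["beta"] = dr_beta, _["gamma"] = dr_gamma,
    _["lam_delta"] = dr_ld, _["lam_e"] = dr_le, _["lam_tau"] = dr_lt,
    _["rho"] = dr_rho, _["lam_theta"] = dr_lth, _["lam_eps"] = dr_lep,
    _["e_maxsum"] = e_maxsum,
    _["ks_accept_rate"] = S.ks_draws > 0 ?
      (double)S.ks_draws / (double)S.ks_proposals : NA_REAL,
    _["final_state"] = S.as_list());
  if (store_latent) {
    out["delta"] = dr_delta;
    out["e"] = dr_e;
    out["tau"] = dr_tau;
  }
  return out;
}
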