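// Compiled core: sleep-network vector field, RK4 path integration, the
// unscented Kalman filter recursion, and the multiple-shooting segment cost.
// Everything here is deterministic; all random number generation (thalamic
// impulses, observation noise) happens on the R side so that seeds are
// controlled by R's RNG alone.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Pars {
  // per-group sigmoid/time-constant/transmitter parameters
  double lc_Fmax, lc_alpha, lc_beta, lc_tauF, lc_gamma, lc_tauC;
  double dr_Fmax, dr_alpha, dr_beta, dr_tauF, dr_gamma, dr_tauC;
  double v_Fmax, v_alpha, v_beta, v_k, v_tauF, v_gamma, v_tauC;
  double r_Fmax, r_alpha, r_beta, r_tauF, r_gamma, r_tauC;
  double wr_Fmax, wr_alpha, wr_beta, wr_tauF, wr_gamma, wr_tauC;
  // coupling constants (sign encodes excitation/inhibition)
  double gA_lc, gG_lc, gD_lc, gA_dr, gG_dr, gD_dr;
  double gN_vlpo, gS_vlpo, gA_r, gN_r, gS_r, gG_r, gA_wr, gG_wr;
  // homeostatic drive
  double h_max, h_theta, h_tau_acc, h_tau_diss;
  // thalamic noise (only the decay constant is used in the deterministic part)
  double n_tau;
  // quasi-static additive drive standing in for unmodeled SCN input
  double a_scn;
  // SCN cell group (FBFD only)
  double scn_Fmax, scn_alpha, scn_beta, scn_tauF, scn_gamma, scn_tauC;
  double circ_amp, circ_offset, g_feedback;
  double gscn_lc, gscn_dr, gscn_vlpo, gscn_r;
  double period_s, light_onset_s;
  bool fbfd;
  int dim;
};

static double getp(const NumericVector& pv, const char* nm) {
  CharacterVector nms = pv.names();
  for (int i = 0; i < pv.size(); ++i)
    if (std::strcmp(nms[i], nm) == 0) return pv[i];
  stop("parameter vector is missing entry '%s'", std::string(nm));
  return NA_REAL;
}

static Pars parse_pars(const NumericVector& pv) {
  Pars p;
  p.lc_Fmax = getp(pv, "lc.F_max"); p.lc_alpha = getp(pv, "lc.alpha");
  p.lc_beta = getp(pv, "lc.beta"); p.lc_tauF = getp(pv, "lc.tau_F");
  p.lc_gamma = getp(pv, "lc.gamma"); p.lc_tauC = getp(pv, "lc.tau_C");
  p.dr_Fmax = getp(pv, "dr.F_max"); p.dr_alpha = getp(pv, "dr.alpha");
  p.dr_beta = getp(pv, "dr.beta"); p.dr_tauF = getp(pv, "dr.tau_F");
  p.dr_gamma = getp(pv, "dr.gamma"); p.dr_tauC = getp(pv, "dr.tau_C");
  p.v_Fmax = getp(pv, "vlpo.F_max"); p.v_alpha = getp(pv, "vlpo.alpha");
  p.v_beta = getp(pv, "vlpo.beta"); p.v_k = getp(pv, "vlpo.k");
  p.v_tauF = getp(pv, "vlpo.tau_F");
  p.v_gamma = getp(pv, "vlpo.gamma"); p.v_tauC = getp(pv, "vlpo.tau_C");
  p.r_Fmax = getp(pv, "r.F_max"); p.r_alpha = getp(pv, "r.alpha");
  p.r_beta = getp(pv, "r.beta"); p.r_tauF = getp(pv, "r.tau_F");
  p.r_gamma = getp(pv, "r.gamma"); p.r_tauC = getp(pv, "r.tau_C");
  p.wr_Fmax = getp(pv, "wr.F_max"); p.wr_alpha = getp(pv, "wr.alpha");
  p.wr_beta = getp(pv, "wr.beta"); p.wr_tauF = getp(pv, "wr.tau_F");
  p.wr_gamma = getp(pv, "wr.gamma"); p.wr_tauC = getp(pv, "wr.tau_C");
  p.gA_lc = getp(pv, "g.A_LC"); p.gG_lc = getp(pv, "g.G_LC");
  p.gD_lc = getp(pv, "g.D_LC"); p.gA_dr = getp(pv, "g.A_DR");
  p.gG_dr = getp(pv, "g.G_DR"); p.gD_dr = getp(pv, "g.D_DR");
  p.gN_vlpo = getp(pv, "g.N_VLPO"); p.gS_vlpo = getp(pv, "g.S_VLPO");
  p.gA_r = getp(pv, "g.A_R"); p.gN_r = getp(pv, "g.N_R");
  p.gS_r = getp(pv, "g.S_R"); p.gG_r = getp(pv, "g.G_R");
  p.gA_wr = getp(pv, "g.A_WR"); p.gG_wr = getp(pv, "g.G_WR");
  p.h_max = getp(pv, "h.h_max"); p.h_theta = getp(pv, "h.theta");
  p.h_tau_acc = getp(pv, "h.tau_acc"); p.h_tau_diss = getp(pv, "h.tau_diss");
  p.n_tau = getp(pv, "noise.tau_delta");
  p.a_scn = getp(pv, "a_scn");
  p.fbfd = getp(pv, "fbfd") > 0.5;
  p.dim = p.fbfd ? 14 : 12;
  if (p.fbfd) {
    p.scn_Fmax = getp(pv, "scn.F_max"); p.scn_alpha = getp(pv, "scn.alpha");
    p.scn_beta = getp(pv, "scn.beta"); p.scn_tauF = getp(pv, "scn.tau_F");
    p.scn_gamma = getp(pv, "scn.gamma"); p.scn_tauC = getp(pv, "scn.tau_C");
    p.circ_amp = getp(pv, "scn.circ_amplitude");
    p.circ_offset = getp(pv, "scn.circ_offset");
    p.g_feedback = getp(pv, "scn.g_feedback");
    p.gscn_lc = getp(pv, "scn.g_scn_LC"); p.gscn_dr = getp(pv, "scn.g_scn_DR");
    p.gscn_vlpo = getp(pv, "scn.g_scn_VLPO"); p.gscn_r = getp(pv, "scn.g_scn_R");
    p.period_s = getp(pv, "scn.period_h") * 3600.0;
    p.light_onset_s = getp(pv, "scn.light_onset_h") * 3600.0;
  }
  return p;
}

static inline double sigf(double c, double Fmax, double alpha, double beta) {
  return 0.5 * Fmax * (1.0 + std::tanh((c - beta) / alpha));
}

// state layout: 0 F_LC, 1 F_DR, 2 F_VLPO, 3 F_R, 4 F_WR,
//               5 C_N, 6 C_S, 7 C_G, 8 C_AR, 9 C_AWR, 10 h, 11 delta,
//               12 F_SCN, 13 C_SCN (FBFD only)
static inline void deriv(const double* x, double t, const Pars& p, double* dx) {
  const double C_A = x[8] + x[9];  // total ACh is the sum of both sources
  double s_lc = 0.0, s_dr = 0.0, s_v = 0.0, s_r = 0.0;
  if (p.fbfd) {
    const double cgs = x[13];
    s_lc = p.gscn_lc * cgs; s_dr = p.gscn_dr * cgs;
    s_v = p.gscn_vlpo * cgs; s_r = p.gscn_r * cgs;
  }
  const double c_lc = p.gA_lc * C_A + p.gG_lc * x[7] + p.gD_lc * x[11] + p.a_scn + s_lc;
  const double c_dr = p.gA_dr * C_A + p.gG_dr * x[7] + p.gD_dr * x[11] + p.a_scn + s_dr;
  const double c_v  = p.gN_vlpo * x[5] + p.gS_vlpo * x[6] + p.a_scn + s_v;
  const double c_r  = p.gA_r * C_A + p.gN_r * x[5] + p.gS_r * x[6] + p.gG_r * x[7] + p.a_scn + s_r;
  const double c_wr = p.gA_wr * C_A + p.gG_wr * x[7];
  const double beta_v = p.v_beta - p.v_k * x[10];  // homeostatic threshold shift
  dx[0] = (sigf(c_lc, p.lc_Fmax, p.lc_alpha, p.lc_beta) - x[0]) / p.lc_tauF;
  dx[1] = (sigf(c_dr, p.dr_Fmax, p.dr_alpha, p.dr_beta) - x[1]) / p.dr_tauF;
  dx[2] = (sigf(c_v, p.v_Fmax, p.v_alpha, beta_v) - x[2]) / p.v_tauF;
  dx[3] = (sigf(c_r, p.r_Fmax, p.r_alpha, p.r_beta) - x[3]) / p.r_tauF;
  dx[4] = (sigf(c_wr, p.wr_Fmax, p.wr_alpha, p.wr_beta) - x[4]) / p.wr_tauF;
  dx[5] = (std::tanh(x[0] / p.lc_gamma) - x[5]) / p.lc_tauC;
  dx[6] = (std::tanh(x[1] / p.dr_gamma) - x[6]) / p.dr_tauC;
  dx[7] = (std::tanh(x[2] / p.v_gamma) - x[7]) / p.v_tauC;
  dx[8] = (std::tanh(x[3] / p.r_gamma) - x[8]) / p.r_tauC;
  dx[9] = (std::tanh(x[4] / p.wr_gamma) - x[9]) / p.wr_tauC;
  dx[10] = (x[0] > p.h_theta) ? (p.h_max - x[10]) / p.h_tau_acc
                              : -x[10] / p.h_tau_diss;
  dx[11] = -x[11] / p.n_tau;  // impulses are injected between RK4 steps
  if (p.fbfd) {
    const double circ = p.circ_offset +
      p.circ_amp * std::sin(2.0 * M_PI * (t - p.light_onset_s) / p.period_s);
    const double c_scn = circ + p.g_feedback * (x[6] + C_A);
    dx[12] = (sigf(c_scn, p.scn_Fmax, p.scn_alpha, p.scn_beta) - x[12]) / p.scn_tauF;
    dx[13] = (std::tanh(x[12] / p.scn_gamma) - x[13]) / p.scn_tauC;
  }
}

static inline void rk4_step(double* x, double t, double dt, const Pars& p,
                            double* k1, double* k2, double* k3, double* k4,
                            double* tmp) {
  const int d = p.dim;
  deriv(x, t, p, k1);
  for (int i = 0; i < d; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  deriv(tmp, t + 0.5 * dt, p, k2);
  for (int i = 0; i < d; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  deriv(tmp, t + 0.5 * dt, p, k3);
  for (int i = 0; i < d; ++i) tmp[i] = x[i] + dt * k3[i];
  deriv(tmp, t + dt, p, k4);
  for (int i = 0; i < d; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
NumericVector cpp_sleep_deriv(NumericVector x, double t, NumericVector pv) {
  Pars p = parse_pars(pv);
  if ((int)x.size() != p.dim)
    stop("state has length %d but the model dimension is %d", (int)x.size(), p.dim);
  NumericVector dx(p.dim);
  deriv(x.begin(), t, p, dx.begin());
  return dx;
}

// Deterministic RK4 path with Poisson impulse counts (precomputed in R)
// applied to the thalamic input between steps.
// [[Rcpp::export]]
NumericMatrix cpp_rk4_path(NumericVector x0, double t0, double dt, int nstep,
                           NumericVector pv, IntegerVector impulses,
                           double impulse_amplitude) {
  Pars p = parse_pars(pv);
  const int d = p.dim;
  if ((int)x0.size() != d) stop("initial state has wrong dimension");
  const bool has_imp = impulses.size() > 0;
  if (has_imp && (int)impulses.size() != nstep)
    stop("impulse series must have one entry per step");
  NumericMatrix out(nstep + 1, d);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
  for (int j = 0; j < d; ++j) out(0, j) = x[j];
  for (int i = 0; i < nstep; ++i) {
    rk4_step(x.data(), t0 + i * dt, dt, p, k1.data(), k2.data(), k3.data(),
             k4.data(), tmp.data());
    for (int j = 0; j < d; ++j) {
      if (!std::isfinite(x[j]))
        stop("non-finite state at integration step %d (component %d)", i + 1, j + 1);
    }
    if (has_imp && impulses[i] > 0) x[11] += impulses[i] * impulse_amplitude;
    for (int j = 0; j < d; ++j) out(i + 1, j) = x[j];
  }
  return out;
}

// Symmetric 2n sigma-point set: columns of x +/- sqrt(n P); Cholesky with
// escalating diagonal jitter when P has drifted off the SPD cone numerically.
static arma::mat sigma_sqrt(const arma::mat& P, int n) {
  arma::mat L;
  arma::mat M = (double)n * P;
  double jit = 1e-12;
  for (int attempt = 0; attempt < 8; ++attempt) {
    arma::mat Mj = M + jit * arma::eye(M.n_rows, M.n_cols);
    if (arma::chol(L, Mj, "lower")) return L;
    jit *= 100.0;
  }
  stop("covariance square root failed even after jitter repair");
  return L;
}

// UKF over a series of observations of a subset of state components.
// Y: m x T observations; Rdiag: m x T per-step observation variances;
// Qdiag: length-d covariance inflation. Missing observations (NaN) trigger a
// predict-only step. Returns the corrected mean and covariance diagonal at
// every step.
// [[Rcpp::export]]
List cpp_ukf_sleep(arma::mat Y, IntegerVector obs_idx, arma::mat Rdiag,
                   arma::vec Qdiag, arma::vec x0, arma::mat P0,
                   double t0, double dt, NumericVector pv) {
  Pars p = parse_pars(pv);
  const int d = p.dim;
  const int m = Y.n_rows;
  const int T = Y.n_cols;
  if ((int)x0.n_elem != d) stop("x0 has wrong dimension");
  if ((int)Qdiag.n_elem != d) stop("Q diagonal has wrong dimension");
  if ((int)Rdiag.n_rows != m || (int)Rdiag.n_cols != T)
    stop("R series must be m x T");
  arma::uvec oi(m);
  for (int j = 0; j < m; ++j) {
    if (obs_idx[j] < 1 || obs_idx[j] > d) stop("observation index out of range");
    oi[j] = obs_idx[j] - 1;
  }
  arma::vec x = x0;
  arma::mat P = P0;
  arma::mat Xs(d, 2 * d);
  arma::mat Xhat(d, T);
  arma::mat Pdiag(d, T);
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
  const double w = 1.0 / (2.0 * d);
  for (int k = 0; k < T; ++k) {
    // predict: spread, propagate, average
    arma::mat L = sigma_sqrt(P, d);
    for (int j = 0; j < d; ++j) {
      Xs.col(j) = x + L.col(j);
      Xs.col(d + j) = x - L.col(j);
    }
    const double tk = t0 + k * dt;
    for (int c = 0; c < 2 * d; ++c) {
      double* xc = Xs.colptr(c);
      rk4_step(xc, tk, dt, p, k1.data(), k2.data(), k3.data(), k4.data(),
               tmp.data());
      for (int j = 0; j < d; ++j)
        if (!std::isfinite(xc[j]))
          stop("non-finite sigma point at filter step %d", k + 1);
    }
    arma::vec xpred = arma::mean(Xs, 1);
    arma::mat D = Xs.each_col() - xpred;
    arma::mat Ppred = w * (D * D.t());
    Ppred.diag() += Qdiag;
    bool have_y = Y.col(k).is_finite();
    if (have_y) {
      // gain built from the inflated forecast covariance, so the diagonal
      // inflation raises the Kalman gain directly
      arma::mat Pyy = Ppred.submat(oi, oi);
      arma::mat Pxy = Ppred.cols(oi);
      arma::mat S = Pyy + arma::diagmat(Rdiag.col(k));
      arma::mat K;
      if (!arma::solve(K, S.t(), Pxy.t()))
        stop("singular innovation covariance at filter step %d", k + 1);
      K = K.t();
      arma::vec ypred = xpred.rows(oi);
      x = xpred + K * (Y.col(k) - ypred);
      P = Ppred - K * Pxy.t();
    } else {
      x = xpred;
      P = Ppred;
    }
    P = 0.5 * (P + P.t());  // keep the covariance symmetric
    Xhat.col(k) = x;
    Pdiag.col(k) = P.diag();
  }
  return List::create(_["xhat"] = Xhat, _["Pdiag"] = Pdiag,
                      _["x_final"] = x, _["P_final"] = P);
}

// Multiple-shooting segment cost: short deterministic forecasts re-anchored on
// the reconstruction every seg_steps, scored on the measured variables with
// inverse-standard-deviation weights; returns the window-averaged squared
// divergence. Infeasible integrations yield +Inf.
// [[Rcpp::export]]
double cpp_shooting_cost(arma::mat recon, double t0, double dt, int seg_steps,
                         IntegerVector obs_idx, arma::vec wts,
                         NumericVector pv) {
  Pars p = parse_pars(pv);
  const int d = p.dim;
  const int T = recon.n_cols;
  if ((int)recon.n_rows != d) stop("reconstruction has wrong dimension");
  if (seg_steps < 1) stop("segment length must be at least one step");
  const int m = obs_idx.size();
  if ((int)wts.n_elem != m) stop("one weight per measured variable required");
  std::vector<double> k1(d), k2(d), k3(d), k4(d), tmp(d);
  std::vector<double> x(d);
  double J = 0.0;
  long npts = 0;
  for (int s = 0; s + 1 < T; s += seg_steps) {
    for (int j = 0; j < d; ++j) x[j] = recon(j, s);
    const int end = std::min(s + seg_steps, T - 1);
    for (int k = s; k < end; ++k) {
      rk4_step(x.data(), t0 + k * dt, dt, p, k1.data(), k2.data(), k3.data(),
               k4.data(), tmp.data());
      for (int j = 0; j < d; ++j)
        if (!std::isfinite(x[j])) return R_PosInf;
      for (int j = 0; j < m; ++j) {
        const double e = x[obs_idx[j] - 1] - recon(obs_idx[j] - 1, k + 1);
        J += wts[j] * wts[j] * e * e;
      }
      ++npts;
    }
  }
  if (npts == 0) stop("window too short for the requested segment length");
  return J / (double)npts;
}
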