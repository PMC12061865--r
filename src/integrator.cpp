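#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integrator for the coupled two-region mean-field model.
//
// Parameter vector layout: 29 values per region (PFC block then SCC block):
//  0 I_thr_E, 1 I_thr_I, 2 g_E, 3 g_I, 4 d_E, 5 d_I, 6 J_NMDA, 7 J,
//  8 w_plus, 9 W_E, 10 W_I, 11 W5HT_E, 12 W5HT_I, 13 R, 14 Io,
//  15 tau_NMDA, 16 tau_GABA, 17 gamma, 18 C_in, 19 sign, 20 X1, 21 X2,
//  22 alpha, 23 C_BR, 24 Vmax, 25 Km, 26 tau_5HT, 27 J_5HT, 28 beta
// State layout: (S_E, S_I, M, conc) for PFC then SCC.
// Noise enters only the gating variables, with sigma*sqrt(dt) scaling; the
// four standard-normal draws per step are ordered
// (S_E pfc, S_I pfc, S_E scc, S_I scc) and come from R's RNG stream.

static const int NPAR = 29;

static inline double transfer(double I, double g, double d, double thr) {
  double x = g * (I - thr);
  double dx = d * x;
  if (std::fabs(dx) < 1e-6) return 1.0 / d;
  return x / (1.0 - std::exp(-dx));
}

static const char *STATE_NAMES[8] = {
  "S_E_pfc", "S_I_pfc", "M_pfc", "conc_pfc",
  "S_E_scc", "S_I_scc", "M_scc", "conc_scc"
};

static inline void drift8(const double *par, const double *s, double *d8,
                          double *rates /* r_E_pfc, r_I_pfc, r_E_scc, r_I_scc */) {
  for (int k = 0; k < 2; ++k) {
    const double *p = par + k * NPAR;
    int i = k * 4, io = (1 - k) * 4;
    double SE = s[i], SI = s[i + 1], M = s[i + 2], C = s[i + 3];
    double Cc = C > 0.0 ? C : 0.0;
    double IE = p[8] * p[6] * SE - p[7] * SI + p[19] * p[11] * p[13] * M +
                p[9] * p[14] + p[6] * p[18] * s[io];
    double II = p[6] * SE - SI + p[19] * p[12] * p[13] * M + p[10] * p[14];
    double rE = transfer(IE, p[2], p[4], p[0]);
    double rI = transfer(II, p[3], p[5], p[1]);
    if (rE < 0.0) rE = 0.0;
    if (rI < 0.0) rI = 0.0;
    d8[i]     = -SE / p[15] + (1.0 - SE) * p[17] * rE;
    d8[i + 1] = -SI / p[16] + rI;
    d8[i + 2] = (-M + p[27] / (1.0 + std::exp(-p[28] * (Cc + 1.0)))) / p[26];
    d8[i + 3] = p[22] * p[23] * rE * p[20] -
                p[24] * Cc / (p[25] + Cc) * p[21];
    rates[k * 2] = rE;
    rates[k * 2 + 1] = rI;
  }
}

// [[Rcpp::export(name = ".em_integrate_cpp")]]
List em_integrate_cpp(NumericVector par, NumericVector state0, double dt,
                      int n_steps, int n_transient, double sigma,
                      bool record = false, int thin = 1) {
  if (par.size() != 2 * NPAR) stop("parameter vector of wrong length");
  if (state0.size() != 8) stop("state vector must have length 8");
  if (dt <= 0.0) stop("dt must be positive");
  if (n_transient < 0 || n_transient >= n_steps)
    stop("need 0 <= n_transient < n_steps");

  double s[8], d8[8], rates[4];
  for (int j = 0; j < 8; ++j) s[j] = state0[j];

  double sqdt = std::sqrt(dt);
  int n_ret = n_steps - n_transient;
  double acc[6] = {0, 0, 0, 0, 0, 0};  // conc, rE, rI per region

  int n_rec = record ? (n_steps / thin + 1) : 0;
  NumericMatrix traj(n_rec, record ? 9 : 0);
  int irec = 0;
  if (record) {
    traj(0, 0) = 0.0;
    for (int j = 0; j < 8; ++j) traj(0, j + 1) = s[j];
    irec = 1;
  }

  for (int step = 1; step <= n_steps; ++step) {
    drift8(&par[0], s, d8, rates);
    double z[4];
    z[0] = norm_rand();
    z[1] = norm_rand();
    z[2] = norm_rand();
    z[3] = norm_rand();
    for (int k = 0; k < 2; ++k) {
      int i = k * 4;
      s[i]     += dt * d8[i]     + sigma * sqdt * z[k * 2];
      s[i + 1] += dt * d8[i + 1] + sigma * sqdt * z[k * 2 + 1];
      s[i + 2] += dt * d8[i + 2];
      s[i + 3] += dt * d8[i + 3];
      // clamps: gating to natural ranges, concentration nonnegative
      if (s[i] < 0.0) s[i] = 0.0;
      if (s[i] > 1.0) s[i] = 1.0;
      if (s[i + 1] < 0.0) s[i + 1] = 0.0;
      if (s[i + 3] < 0.0) s[i + 3] = 0.0;
    }
    for (int j = 0; j < 8; ++j) {
      if (!std::isfinite(s[j]) || std::fabs(s[j]) > 1e6)
        stop("state variable '%s' diverged (non-finite or |x| > 1e6) at step %d",
             STATE_NAMES[j], step);
    }
    if (step > n_transient) {
      drift8(&par[0], s, d8, rates);  // rates at the post-step state
      acc[0] += s[3];
      acc[1] += rates[0];
      acc[2] += rates[1];
      acc[3] += s[7];
      acc[4] += rates[2];
      acc[5] += rates[3];
    }
    if (record && step % thin == 0 && irec < n_rec) {
      traj(irec, 0) = step * dt;
      for (int j = 0; j < 8; ++j) traj(irec, j + 1) = s[j];
      ++irec;
    }
  }

  NumericVector fin(8);
  for (int j = 0; j < 8; ++j) fin[j] = s[j];
  List out = List::create(
    _["mean_conc"] = NumericVector::create(acc[0] / n_ret, acc[3] / n_ret),
    _["mean_r_E"] = NumericVector::create(acc[1] / n_ret, acc[4] / n_ret),
    _["mean_r_I"] = NumericVector::create(acc[2] / n_ret, acc[5] / n_ret),
    _["final_state"] = fin,
    _["n_retained"] = n_ret);
  if (record) out["trajectory"] = traj;
  return out;
}
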