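// Core integrators: Wilson-Cowan network with homeostatic inhibitory
// plasticity, Balloon-Windkessel hemodynamics, and a streaming combined
// path used by parameter sweeps (never materialises the 1 ms state).
//
// All noise comes from R's RNG (norm_rand), so results are reproducible
// via set.seed() on the R side. One standard-normal draw per region per
// Euler step, consumed in region order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigm(double x, double mu, double sigma) {
  return 1.0 / (1.0 + std::exp(-(x - mu) / sigma));
}

struct WcPar {
  double rE, rI, tauE, tauI, aEE, aEI, P, D, rhoE, mu, sigmaI, dt;
  double noise_scale;  // D, or D*sqrt(dt) under the Euler-Maruyama switch
};

static WcPar wc_par_from_list(const List& cfg) {
  WcPar p;
  p.rE = as<double>(cfg["r_E"]);      p.rI = as<double>(cfg["r_I"]);
  p.tauE = as<double>(cfg["tau_E"]);  p.tauI = as<double>(cfg["tau_I"]);
  p.aEE = as<double>(cfg["a_EE"]);    p.aEI = as<double>(cfg["a_EI"]);
  p.P = as<double>(cfg["P"]);         p.D = as<double>(cfg["D"]);
  p.rhoE = as<double>(cfg["rho_E"]);  p.mu = as<double>(cfg["mu"]);
  p.sigmaI = as<double>(cfg["sigma_I"]);
  p.dt = as<double>(cfg["dt"]);
  // "white": D scales delta-correlated white noise, discretized as
  // D * eps / sqrt(dt) (dt-consistent SDE limit). "per_step": literal
  // bounded per-step fluctuation D * eps.
  std::string nc = as<std::string>(cfg["noise_convention"]);
  p.noise_scale = (nc == "white") ? p.D / std::sqrt(p.dt) : p.D;
  return p;
}

// one Euler step, in place; coup buffer avoids reallocation
static inline void wc_step(arma::vec& E, arma::vec& I, arma::vec& a,
                           arma::vec& coup,
                           const arma::mat& C, const arma::vec& G,
                           const arma::vec& sigmaE, const WcPar& p,
                           double tau_ip) {
  const arma::uword N = E.n_elem;
  coup = C.t() * E;  // coup_i = sum_j C_ji E_j
  const double dt = p.dt;
  for (arma::uword i = 0; i < N; ++i) {
    const double eps = norm_rand();
    const double argE = p.aEE * E[i] - a[i] * I[i] + G[i] * coup[i] + p.P +
                        p.noise_scale * eps;
    const double dE = (-E[i] + (1.0 - p.rE * E[i]) * sigm(argE, p.mu, sigmaE[i])) / p.tauE;
    const double dI = (-I[i] + (1.0 - p.rI * I[i]) * sigm(p.aEI * E[i], p.mu, p.sigmaI)) / p.tauI;
    const double da = I[i] * (E[i] - p.rhoE) / tau_ip;
    E[i] += dt * dE;
    I[i] += dt * dI;
    a[i] += dt * da;
    if (a[i] < 0.0) a[i] = 0.0;  // inhibitory weight cannot go negative
  }
}

static void check_finite(const arma::vec& E, double t_now) {
  if (!E.is_finite()) {
    arma::uword bad = 0;
    for (arma::uword i = 0; i < E.n_elem; ++i)
      if (!std::isfinite(E[i])) { bad = i; break; }
    stop("integration diverged at t = %f s (node %d)", t_now, (int)(bad + 1));
  }
}

// [[Rcpp::export]]
List wc_sim_cpp(const arma::mat& C, const arma::vec& G, const arma::vec& sigmaE,
                const List& cfg, bool record_I, bool record_a) {
  const WcPar p = wc_par_from_list(cfg);
  const double t_transient = as<double>(cfg["t_transient"]);
  const double t_main = as<double>(cfg["t_main"]);
  const double tau_tr = as<double>(cfg["tau_ip_transient"]);
  const double tau_main = as<double>(cfg["tau_ip_main"]);
  const int stride = as<int>(cfg["stride"]);
  const arma::uword N = C.n_rows;

  arma::vec E(N), I(N), a(N), coup(N);
  E.fill(as<double>(cfg["init_E"]));
  I.fill(as<double>(cfg["init_I"]));
  a.fill(as<double>(cfg["init_a_IE"]));

  const long n_tr = (long)std::lround(t_transient / p.dt);
  const long n_main = (long)std::lround(t_main / p.dt);
  const long n_rec = n_main / stride;

  for (long t = 1; t <= n_tr; ++t) {
    wc_step(E, I, a, coup, C, G, sigmaE, p, tau_tr);
    if (t % 10000 == 0) check_finite(E, t * p.dt);
  }
  arma::mat Erec(N, n_rec), Irec, arec;
  if (record_I) Irec.set_size(N, n_rec);
  if (record_a) arec.set_size(N, n_rec);
  arma::vec e_sum(N, arma::fill::zeros);
  long k = 0;
  for (long t = 1; t <= n_main; ++t) {
    wc_step(E, I, a, coup, C, G, sigmaE, p, tau_main);
    e_sum += E;
    if (t % stride == 0 && k < n_rec) {
      check_finite(E, t_transient + t * p.dt);
      Erec.col(k) = E;
      if (record_I) Irec.col(k) = I;
      if (record_a) arec.col(k) = a;
      ++k;
    }
  }
  List out = List::create(_["E"] = Erec,
                          _["e_mean"] = e_sum / (double)n_main,
                          _["sample_interval"] = p.dt * stride);
  if (record_I) out["I"] = Irec;
  if (record_a) out["a_IE"] = arec;
  return out;
}

struct BwPar {
  double tau_s, tau_f, tau_v, tau_q, inv_kappa, E0, V0, k1, k2, k3, dt;
};

static BwPar bw_par_from_list(const List& h) {
  BwPar b;
  b.tau_s = as<double>(h["tau_s"]); b.tau_f = as<double>(h["tau_f"]);
  b.tau_v = as<double>(h["tau_v"]); b.tau_q = as<double>(h["tau_q"]);
  b.inv_kappa = 1.0 / as<double>(h["kappa"]);
  b.E0 = as<double>(h["E_0"]); b.V0 = as<double>(h["V_0"]);
  b.k1 = as<double>(h["k_1"]); b.k2 = as<double>(h["k_2"]); b.k3 = as<double>(h["k_3"]);
  b.dt = as<double>(h["dt"]);
  return b;
}

static inline void bw_step(double u, double& s, double& f, double& v, double& q,
                           const BwPar& b) {
  if (v <= 0.0 || q <= 0.0 || f <= 0.0)
    stop("hemodynamic integration diverged (nonpositive f, v or q)");
  const double vk = std::pow(v, b.inv_kappa);
  const double ds = u - s / b.tau_s - (f - 1.0) / b.tau_f;
  const double df = s;
  const double dv = (f - vk) / b.tau_v;
  const double dq = (f * (1.0 - std::pow(1.0 - b.E0, 1.0 / f)) / b.E0 -
                     q * vk / v) / b.tau_q;
  s += b.dt * ds;
  f += b.dt * df;
  v += b.dt * dv;
  q += b.dt * dq;
}

static inline double bw_readout(double v, double q, const BwPar& b) {
  return b.V0 * (b.k1 * (1.0 - q) + b.k2 * (1.0 - q / v) + b.k3 * (1.0 - v));
}

// E_series: N x T drive sampled at the hemodynamic dt; starts from rest.
// [[Rcpp::export]]
arma::mat bw_sim_cpp(const arma::mat& E_series, const List& hcfg) {
  const BwPar b = bw_par_from_list(hcfg);
  const arma::uword N = E_series.n_rows, T = E_series.n_cols;
  arma::mat B(N, T);
  for (arma::uword i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (arma::uword t = 0; t < T; ++t) {
      bw_step(E_series(i, t), s, f, v, q, b);
      B(i, t) = bw_readout(v, q, b);
    }
  }
  return B;
}

// Combined neural + hemodynamic path. The hemodynamic state advances once
// every `hemo_every` neural steps (reconciling the two integration steps),
// runs warm through the neural transient, and BOLD is recorded once every
// `rec_every` hemodynamic steps of the analysis window.
// [[Rcpp::export]]
List wc_bold_cpp(const arma::mat& C, const arma::vec& G, const arma::vec& sigmaE,
                 const List& cfg, const List& hcfg, int rec_every) {
  const WcPar p = wc_par_from_list(cfg);
  const BwPar b = bw_par_from_list(hcfg);
  const double t_transient = as<double>(cfg["t_transient"]);
  const double t_main = as<double>(cfg["t_main"]);
  const double tau_tr = as<double>(cfg["tau_ip_transient"]);
  const double tau_main = as<double>(cfg["tau_ip_main"]);
  const int hemo_every = (int)std::lround(b.dt / p.dt);
  if (hemo_every < 1) stop("hemodynamic dt must be >= neural dt");
  const arma::uword N = C.n_rows;

  arma::vec E(N), I(N), a(N), coup(N);
  E.fill(as<double>(cfg["init_E"]));
  I.fill(as<double>(cfg["init_I"]));
  a.fill(as<double>(cfg["init_a_IE"]));
  arma::vec s(N, arma::fill::zeros), f(N, arma::fill::ones),
            v(N, arma::fill::ones), q(N, arma::fill::ones);

  const long n_tr = (long)std::lround(t_transient / p.dt);
  const long n_main = (long)std::lround(t_main / p.dt);
  const long n_hemo = n_main / hemo_every;
  const long n_bold = n_hemo / rec_every;

  for (long t = 1; t <= n_tr; ++t) {
    wc_step(E, I, a, coup, C, G, sigmaE, p, tau_tr);
    if (t % hemo_every == 0)
      for (arma::uword i = 0; i < N; ++i) bw_step(E[i], s[i], f[i], v[i], q[i], b);
    if (t % 10000 == 0) check_finite(E, t * p.dt);
  }

  arma::mat bold(N, n_bold);
  arma::vec e_sum(N, arma::fill::zeros);
  long kh = 0, kb = 0;
  for (long t = 1; t <= n_main; ++t) {
    wc_step(E, I, a, coup, C, G, sigmaE, p, tau_main);
    e_sum += E;
    if (t % hemo_every == 0) {
      for (arma::uword i = 0; i < N; ++i) bw_step(E[i], s[i], f[i], v[i], q[i], b);
      ++kh;
      if (kh % rec_every == 0 && kb < n_bold) {
        check_finite(E, t_transient + t * p.dt);
        for (arma::uword i = 0; i < N; ++i) bold(i, kb) = bw_readout(v[i], q[i], b);
        ++kb;
      }
    }
  }
  return List::create(_["bold"] = bold,
                      _["e_mean"] = e_sum / (double)n_main,
                      _["sample_interval"] = b.dt * rec_every,
                      _["a_IE_final"] = a);
}
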