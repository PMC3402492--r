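// Trial simulator for the two-layer latching attractor model.
//
// The recurrent covariance matrix J = s * C'C (zero diagonal, C = Xi - p)
// is never formed: the recurrent field J (r ∘ x) is computed through the
// low-rank factor C (n_patterns x N) with an explicit diagonal correction,
// and the inter-network projections through their pattern factors. This is
// algebraically identical to the dense matrices built in R (asserted by the
// test suite) and keeps a full trial in the hundreds of microseconds.
//
// All randomness is drawn from R's RNG (norm_rand), so set.seed() in R makes
// trials bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

struct NetPar {
  double p, T, tau_n, theta, lambda, reg_frac, theta_ext, eta_amp, tau_corr, U, tau_r, xm;
};

static NetPar unpack_par(const List& L) {
  NetPar q;
  q.p = as<double>(L["p"]);
  q.T = as<double>(L["T"]);
  q.tau_n = as<double>(L["tau_n"]);
  q.theta = as<double>(L["theta"]);
  q.lambda = as<double>(L["lambda"]);
  q.reg_frac = as<double>(L["reg_frac"]);
  q.theta_ext = as<double>(L["theta_ext"]);
  q.eta_amp = as<double>(L["eta_amp"]);
  q.tau_corr = as<double>(L["tau_corr"]);
  q.U = as<double>(L["U"]);
  q.tau_r = as<double>(L["tau_r"]);
  q.xm = as<double>(L["x_max"]) / 1000.0;  // spikes/s -> spikes/ms
  return q;
}

// Pearson correlation of x with every row of the binary pattern matrix
static void pattern_cors(const mat& Xi, const vec& na, const vec& denom_xi,
                         const vec& x, vec& out) {
  const double N = (double)x.n_elem;
  const double sx = arma::accu(x);
  const double vx = arma::dot(x, x) - sx * sx / N;
  if (vx <= 0.0) {
    out.fill(arma::datum::nan);
    return;
  }
  out = (Xi * x - na * (sx / N)) / arma::sqrt(denom_xi * vx);
}

// converged pattern id (1-based), or 0: correlation >= hi with exactly one
// pattern and < lo with all others
static int conv_id(const vec& cor, double hi, double lo) {
  int id = 0;
  for (uword m = 0; m < cor.n_elem; ++m) {
    if (!(cor[m] < hi)) {            // cor >= hi (NaN fails both branches)
      if (id != 0) return 0;
      id = (int)m + 1;
    } else if (!(cor[m] < lo)) {
      return 0;
    }
  }
  return id;
}

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(const arma::mat& Xi_s, const arma::mat& Xi_l,
                   const List& par_s, const List& par_l, const List& par_c,
                   int baseline_s, int baseline_l,
                   int init_s, int init_l, int prime, int target,
                   double prime_dur, double soa, double timeout,
                   double burn_in, double dt,
                   double conv_hi, double conv_lo,
                   bool noise_on, bool depression_on,
                   int record_every, double max_time) {
  const NetPar S = unpack_par(par_s);
  const NetPar L = unpack_par(par_l);
  const double g_ls = as<double>(par_c["gain_ls"]);
  const double g_sl = as<double>(par_c["gain_sl"]);
  const double U_ls = as<double>(par_c["U_ls"]);
  const double tau_r_ls = as<double>(par_c["tau_r_ls"]);
  const double g_ext = as<double>(par_c["external_gain"]);

  const uword Ns = Xi_s.n_cols, Nl = Xi_l.n_cols;
  const uword nps = Xi_s.n_rows, npl = Xi_l.n_rows;
  if (npl != nps) stop("pattern index mismatch between networks");

  // low-rank recurrent factors
  mat Cs = Xi_s;  Cs -= S.p;
  mat Cl = Xi_l;  Cl -= L.p;
  const double ss = 1.0 / ((double)Ns * S.p * (1.0 - S.p));
  const double sl = 1.0 / ((double)Nl * L.p * (1.0 - L.p));
  const vec d_s = ss * arma::sum(arma::square(Cs), 0).t();
  const vec d_l = sl * arma::sum(arma::square(Cl), 0).t();

  // correlation bookkeeping
  const vec na_s = arma::sum(Xi_s, 1);
  const vec na_l = arma::sum(Xi_l, 1);
  const vec denom_s = na_s - arma::square(na_s) / (double)Ns;
  const vec denom_l = na_l - arma::square(na_l) / (double)Nl;

  // projection factors: all patterns except the baselines
  arma::uvec keep_s(nps - 1), keep_l(npl - 1);
  for (uword m = 0, k = 0; m < nps; ++m)
    if ((int)m + 1 != baseline_s) keep_s[k++] = m;
  for (uword m = 0, k = 0; m < npl; ++m)
    if ((int)m + 1 != baseline_l) keep_l[k++] = m;
  const mat Ps = Xi_s.rows(keep_s);
  const mat Pl = Xi_l.rows(keep_l);
  const vec na16_s = arma::sum(Ps, 1);
  const vec na16_l = arma::sum(Pl, 1);

  // state
  vec x_s = Xi_s.row(init_s - 1).t();
  vec x_l = Xi_l.row(init_l - 1).t();
  vec h_s = (2.0 * x_s - 1.0) * 0.5;
  vec h_l = (2.0 * x_l - 1.0) * 0.5;
  vec r_s(Ns, arma::fill::ones), r_ls(Nl, arma::fill::ones);
  vec eta_s(Ns, arma::fill::zeros), eta_l(Nl, arma::fill::zeros);
  const double a_s = std::exp(-dt / S.tau_corr);
  const double a_l = std::exp(-dt / L.tau_corr);
  const double b_s = S.eta_amp * std::sqrt(1.0 - a_s * a_s);
  const double b_l = L.eta_amp * std::sqrt(1.0 - a_l * a_l);
  if (noise_on) {
    for (uword i = 0; i < Ns; ++i) eta_s[i] = S.eta_amp * R::norm_rand();
    for (uword i = 0; i < Nl; ++i) eta_l[i] = L.eta_amp * R::norm_rand();
  }

  // burn-in: activities clamped to the initial patterns, resources frozen
  // at 1; the local inputs (and the noise process) settle to the baseline
  // fixed point
  const int n_burn = (int)std::lround(burn_in / dt);
  for (int k = 0; k < n_burn; ++k) {
    if (noise_on) {
      for (uword i = 0; i < Ns; ++i) eta_s[i] = a_s * eta_s[i] + b_s * R::norm_rand();
      for (uword i = 0; i < Nl; ++i) eta_l[i] = a_l * eta_l[i] + b_l * R::norm_rand();
    }
    vec fld_s = ss * (Cs.t() * (Cs * x_s)) - d_s % x_s;
    vec fld_l = sl * (Cl.t() * (Cl * x_l)) - d_l % x_l;
    vec ext_s = arma::clamp(g_ls * (Ps.t() * ((Pl * x_l) / na16_l)) - S.theta_ext,
                            0.0, arma::datum::inf);
    vec ext_l = arma::clamp(g_sl * (Pl.t() * ((Ps * x_s) / na16_s)) - L.theta_ext,
                            0.0, arma::datum::inf);
    const double reg_s = S.lambda * (arma::mean(x_s) - S.reg_frac * S.p);
    const double reg_l = L.lambda * (arma::mean(x_l) - L.reg_frac * L.p);
    h_s += (dt / S.tau_n) * (-h_s + fld_s - reg_s - S.theta + ext_s + eta_s);
    h_l += (dt / L.tau_n) * (-h_l + fld_l - reg_l - L.theta + ext_l + eta_l);
  }

  // main loop
  const int n_max =
      (int)std::ceil(((target > 0) ? (soa + timeout) : max_time) / dt);
  std::vector<double> ev_t_s, ev_t_l;
  std::vector<int> ev_id_s, ev_id_l;
  int cur_s = 0, cur_l = 0;
  double rt = NA_REAL;
  bool converged = false;
  double t_end = 0.0;

  const bool recording = record_every > 0;
  std::vector<double> rec_t;
  mat rec_s, rec_l;
  int rec_i = 0;
  if (recording) {
    int n_rec = n_max / record_every + 1;
    rec_s.set_size(n_rec, nps);
    rec_l.set_size(n_rec, npl);
  }
  vec cor_s(nps), cor_l(npl);

  for (int k = 0; k < n_max; ++k) {
    const double tk = k * dt;  // time of the state the drives are read from
    int word = 0;
    if (prime > 0 && tk < prime_dur - 1e-9) word = prime;
    else if (target > 0 && tk >= soa - 1e-9) word = target;

    vec rx_s = depression_on ? vec(r_s % x_s) : x_s;
    vec rx_l = depression_on ? vec(r_ls % x_l) : x_l;
    vec fld_s = ss * (Cs.t() * (Cs * rx_s)) - d_s % rx_s;
    vec fld_l = sl * (Cl.t() * (Cl * x_l)) - d_l % x_l;  // lexical recurrent U = 0
    vec ext_s = g_ls * (Ps.t() * ((Pl * rx_l) / na16_l));
    ext_s = arma::clamp(ext_s - S.theta_ext, 0.0, arma::datum::inf);
    vec ext_l = g_sl * (Pl.t() * ((Ps * x_s) / na16_s));
    if (word > 0) ext_l += g_ext * Xi_l.row(word - 1).t();
    ext_l = arma::clamp(ext_l - L.theta_ext, 0.0, arma::datum::inf);

    if (noise_on) {
      for (uword i = 0; i < Ns; ++i) eta_s[i] = a_s * eta_s[i] + b_s * R::norm_rand();
      for (uword i = 0; i < Nl; ++i) eta_l[i] = a_l * eta_l[i] + b_l * R::norm_rand();
    }
    const double reg_s = S.lambda * (arma::mean(x_s) - S.reg_frac * S.p);
    const double reg_l = L.lambda * (arma::mean(x_l) - L.reg_frac * L.p);

    if (depression_on) {  // resources advance from the pre-update activities
      r_s += dt * ((1.0 - r_s) / S.tau_r - S.U * S.xm * (x_s % r_s));
      r_ls += dt * ((1.0 - r_ls) / tau_r_ls - U_ls * L.xm * (x_l % r_ls));
    }

    h_s += (dt / S.tau_n) * (-h_s + fld_s - reg_s - S.theta + ext_s + eta_s);
    h_l += (dt / L.tau_n) * (-h_l + fld_l - reg_l - L.theta + ext_l + eta_l);
    x_s = 1.0 / (1.0 + arma::exp(-h_s / S.T));
    x_l = 1.0 / (1.0 + arma::exp(-h_l / L.T));
    const double tn = (k + 1) * dt;
    t_end = tn;

    if (!h_s.is_finite() || !h_l.is_finite())
      stop("non-finite network state at t = %f ms: parameter misconfiguration?", tn);

    pattern_cors(Xi_s, na_s, denom_s, x_s, cor_s);
    pattern_cors(Xi_l, na_l, denom_l, x_l, cor_l);
    const int id_s = conv_id(cor_s, conv_hi, conv_lo);
    if (id_s > 0 && id_s != cur_s) {
      ev_t_s.push_back(tn);
      ev_id_s.push_back(id_s);
      cur_s = id_s;
    }
    const int id_l = conv_id(cor_l, conv_hi, conv_lo);
    if (id_l > 0 && id_l != cur_l) {
      ev_t_l.push_back(tn);
      ev_id_l.push_back(id_l);
      cur_l = id_l;
    }

    if (recording && (k % record_every == 0)) {
      rec_t.push_back(tn);
      rec_s.row(rec_i) = cor_s.t();
      rec_l.row(rec_i) = cor_l.t();
      ++rec_i;
    }

    if (target > 0 && tn >= soa && id_l == target) {
      rt = tn - soa;
      converged = true;
      break;
    }
  }

  List out = List::create(
      _["rt"] = rt, _["converged"] = converged, _["t_end"] = t_end,
      _["sem_event_t"] = ev_t_s, _["sem_event_id"] = ev_id_s,
      _["lex_event_t"] = ev_t_l, _["lex_event_id"] = ev_id_l);
  if (recording) {
    out["traj_t"] = rec_t;
    out["traj_sem"] = rec_s.rows(0, rec_i - 1);
    out["traj_lex"] = rec_l.rows(0, rec_i - 1);
  }
  return out;
}
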