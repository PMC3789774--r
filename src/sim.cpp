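// Stochastic Hodgkin-Huxley single-compartment simulator.
//
// Channel gating follows the kinetic (Markov chain) formulation: an 8-state
// scheme for the transient Na+ channel (3 m-gates x 1 h-gate) and a 5-state
// scheme for the delayed-rectifier K+ channel (4 n-gates).  State occupancies
// are integer channel counts; per time step the number of channels leaving
// each state through each transition is drawn multinomially with
// probabilities rate*dt.  Voltage is advanced by forward Euler; synaptic
// conductances are supplied as precomputed Ornstein-Uhlenbeck traces so that
// stimulus and channel randomness can be seeded independently from R.
//
// All randomness goes through R's RNG (set.seed() in R controls everything).

#include <Rcpp.h>
using namespace Rcpp;

// x/(1 - exp(-x)), continuous at x = 0 (limit 1).
static inline double phi(double x) {
  if (std::fabs(x) < 1e-6) return 1.0 + 0.5 * x;
  return x / (1.0 - std::exp(-x));
}

struct Rates {
  double am, bm, ah, bh, an, bn;
};

// Canonical squid-axon rate constants, modern voltage convention
// (rest near -65 mV), units 1/ms.
static inline Rates hh_rates(double v) {
  Rates r;
  r.am = phi((v + 40.0) / 10.0);
  r.bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
  r.ah = 0.07 * std::exp(-(v + 65.0) / 20.0);
  r.bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.an = 0.1 * phi((v + 55.0) / 10.0);
  r.bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
  return r;
}

// [[Rcpp::export(name = ".hh_rates_cpp")]]
NumericVector hh_rates_cpp(double v) {
  Rates r = hh_rates(v);
  return NumericVector::create(
    _["alpha_m"] = r.am, _["beta_m"] = r.bm,
    _["alpha_h"] = r.ah, _["beta_h"] = r.bh,
    _["alpha_n"] = r.an, _["beta_n"] = r.bn);
}

// Multinomial draw of channels leaving one state, by sequential binomials.
// probs must sum to < 1 (the remainder stays put).
static inline void draw_exits(int n, const double *p, int k, int *out) {
  double remaining = 1.0;
  int left = n;
  for (int j = 0; j < k; ++j) {
    out[j] = 0;
    if (left <= 0 || p[j] <= 0.0) {
      remaining -= p[j];
      continue;
    }
    double pc = p[j] / remaining;
    if (pc > 1.0) pc = 1.0;
    out[j] = (int) R::rbinom((double) left, pc);
    left -= out[j];
    remaining -= p[j];
  }
}

// One Markov step for the 8-state Na scheme.  State index s = 4*h + m,
// m in 0..3 (activation gates open), h in {0 (inactivated), 1 (available)};
// the conducting state is m = 3, h = 1 (s = 7).
static void na_step(int *cnt, const Rates &r, double dt) {
  int delta[8] = {0};
  for (int s = 0; s < 8; ++s) {
    int n = cnt[s];
    if (n == 0) continue;
    int m = s % 4, h = s / 4;
    double p[3];
    int tgt[3];
    int k = 0;
    if (m < 3) { p[k] = (3 - m) * r.am * dt; tgt[k] = s + 1; ++k; }
    if (m > 0) { p[k] = m * r.bm * dt;       tgt[k] = s - 1; ++k; }
    if (h == 0) { p[k] = r.ah * dt; tgt[k] = s + 4; ++k; }
    else        { p[k] = r.bh * dt; tgt[k] = s - 4; ++k; }
    double ptot = 0.0;
    for (int j = 0; j < k; ++j) ptot += p[j];
    if (ptot >= 1.0)
      stop("per-step transition probability >= 1; reduce dt");
    int out[3];
    draw_exits(n, p, k, out);
    for (int j = 0; j < k; ++j) {
      delta[s] -= out[j];
      delta[tgt[j]] += out[j];
    }
  }
  for (int s = 0; s < 8; ++s) cnt[s] += delta[s];
}

// One Markov step for the 5-state K scheme.  State index = number of open
// n-gates (0..4); the conducting state is 4.
static void k_step(int *cnt, const Rates &r, double dt) {
  int delta[5] = {0};
  for (int s = 0; s < 5; ++s) {
    int n = cnt[s];
    if (n == 0) continue;
    double p[2];
    int tgt[2];
    int k = 0;
    if (s < 4) { p[k] = (4 - s) * r.an * dt; tgt[k] = s + 1; ++k; }
    if (s > 0) { p[k] = s * r.bn * dt;       tgt[k] = s - 1; ++k; }
    double ptot = 0.0;
    for (int j = 0; j < k; ++j) ptot += p[j];
    if (ptot >= 1.0)
      stop("per-step transition probability >= 1; reduce dt");
    int out[2];
    draw_exits(n, p, k, out);
    for (int j = 0; j < k; ++j) {
      delta[s] -= out[j];
      delta[tgt[j]] += out[j];
    }
  }
  for (int s = 0; s < 5; ++s) cnt[s] += delta[s];
}

// [[Rcpp::export(name = ".markov_step_cpp")]]
List markov_step_cpp(IntegerVector na_counts, IntegerVector k_counts,
                     double v, double dt) {
  if (na_counts.size() != 8) stop("na_counts must have 8 states");
  if (k_counts.size() != 5) stop("k_counts must have 5 states");
  Rates r = hh_rates(v);
  int na[8], kk[5];
  for (int s = 0; s < 8; ++s) na[s] = na_counts[s];
  for (int s = 0; s < 5; ++s) kk[s] = k_counts[s];
  na_step(na, r, dt);
  k_step(kk, r, dt);
  IntegerVector na_out(8), k_out(5);
  for (int s = 0; s < 8; ++s) na_out[s] = na[s];
  for (int s = 0; s < 5; ++s) k_out[s] = kk[s];
  return List::create(_["na"] = na_out, _["k"] = k_out);
}

// Long run at clamped voltage; returns time-averaged open fractions.
// [[Rcpp::export(name = ".markov_run_cpp")]]
NumericVector markov_run_cpp(IntegerVector na_counts, IntegerVector k_counts,
                             double v, double dt, int n_steps) {
  Rates r = hh_rates(v);
  int na[8], kk[5];
  for (int s = 0; s < 8; ++s) na[s] = na_counts[s];
  for (int s = 0; s < 5; ++s) kk[s] = k_counts[s];
  double n_na = 0, n_k = 0;
  for (int s = 0; s < 8; ++s) n_na += na[s];
  for (int s = 0; s < 5; ++s) n_k += kk[s];
  double acc_na = 0.0, acc_k = 0.0;
  for (int i = 0; i < n_steps; ++i) {
    na_step(na, r, dt);
    k_step(kk, r, dt);
    acc_na += na[7];
    acc_k += kk[4];
  }
  return NumericVector::create(
    _["na_open"] = acc_na / (n_steps * n_na),
    _["k_open"] = acc_k / (n_steps * n_k));
}

// Multinomial sample of initial channel-state occupancies from the
// steady-state gate distributions at voltage v.
static void init_counts(double v, int n_na, int n_k, int *na, int *kk) {
  Rates r = hh_rates(v);
  double minf = r.am / (r.am + r.bm);
  double hinf = r.ah / (r.ah + r.bh);
  double ninf = r.an / (r.an + r.bn);
  double pna[8], pk[5];
  for (int h = 0; h < 2; ++h)
    for (int m = 0; m < 4; ++m)
      pna[4 * h + m] = R::choose(3.0, m) * std::pow(minf, m) *
        std::pow(1.0 - minf, 3 - m) * (h == 1 ? hinf : 1.0 - hinf);
  for (int s = 0; s < 5; ++s)
    pk[s] = R::choose(4.0, s) * std::pow(ninf, s) * std::pow(1.0 - ninf, 4 - s);
  // sequential binomials = multinomial
  double rem = 1.0;
  int left = n_na;
  for (int s = 0; s < 8; ++s) {
    double pc = (rem > 0) ? pna[s] / rem : 1.0;
    if (pc > 1.0) pc = 1.0;
    na[s] = (s == 7) ? left : (int) R::rbinom((double) left, pc);
    left -= na[s];
    rem -= pna[s];
  }
  rem = 1.0;
  left = n_k;
  for (int s = 0; s < 5; ++s) {
    double pc = (rem > 0) ? pk[s] / rem : 1.0;
    if (pc > 1.0) pc = 1.0;
    kk[s] = (s == 4) ? left : (int) R::rbinom((double) left, pc);
    left -= kk[s];
    rem -= pk[s];
  }
}

// [[Rcpp::export(name = ".init_counts_cpp")]]
List init_counts_cpp(double v, int n_na, int n_k) {
  int na[8], kk[5];
  init_counts(v, n_na, n_k, na, kk);
  IntegerVector na_out(8), k_out(5);
  for (int s = 0; s < 8; ++s) na_out[s] = na[s];
  for (int s = 0; s < 5; ++s) k_out[s] = kk[s];
  return List::create(_["na"] = na_out, _["k"] = k_out);
}

// Core integrator.
//
// g_e, g_i: synaptic conductance densities in uS/cm^2 sampled on the dt grid
//           (g_i may be length 0 for excitation-only input).
// dt:       step, ms.
// Currents are densities in uA/cm^2 (mS/cm^2 * mV).  The returned integrals
// are rectangle sums sum(I)*dt in uA*ms/cm^2, consistent with the Euler
// update so that charge bookkeeping is exact.
//
// [[Rcpp::export(name = ".sim_compartment_cpp")]]
List sim_compartment_cpp(NumericVector g_e, NumericVector g_i, double dt,
                         List params, double v_init, bool deterministic,
                         bool record_trace, bool clip_negative,
                         double threshold, double refractory) {
  const int n = g_e.size();
  const bool has_inh = g_i.size() > 0;
  if (has_inh && g_i.size() != n) stop("g_e and g_i lengths differ");

  const double c_m = as<double>(params["c_m"]);
  const double gbar_na = as<double>(params["gbar_na"]);
  const double gbar_k = as<double>(params["gbar_k"]);
  const double g_leak = as<double>(params["g_leak"]);
  const double e_na = as<double>(params["e_na"]);
  const double e_k = as<double>(params["e_k"]);
  const double e_leak = as<double>(params["e_leak"]);
  const double e_e = as<double>(params["e_e"]);
  const double e_i = as<double>(params["e_i"]);
  const double gamma_ps = as<double>(params["gamma_ps"]);
  const double area_um2 = as<double>(params["area_um2"]);
  const int n_na = as<int>(params["n_na"]);
  const int n_k = as<int>(params["n_k"]);

  // single-channel conductance density, mS/cm^2 per open channel
  const double g_unit = (gamma_ps * 1e-9) / (area_um2 * 1e-8);

  // Na/K pool fractions of the synaptic and leak conductances
  const double fk_e = (e_na - e_e) / (e_na - e_k);
  const double fk_i = (e_na - e_i) / (e_na - e_k);
  const double fk_l = (e_na - e_leak) / (e_na - e_k);

  int na[8], kk[5];
  double m = 0, h = 0, nn = 0;
  {
    Rates r0 = hh_rates(v_init);
    if (deterministic) {
      m = r0.am / (r0.am + r0.bm);
      h = r0.ah / (r0.ah + r0.bh);
      nn = r0.an / (r0.an + r0.bn);
    } else {
      init_counts(v_init, n_na, n_k, na, kk);
    }
  }

  NumericVector v_tr, ina_tr, ik_tr, il_tr, ie_tr, ii_tr, pna_tr, pk_tr;
  if (record_trace) {
    v_tr = NumericVector(n);
    ina_tr = NumericVector(n);
    ik_tr = NumericVector(n);
    il_tr = NumericVector(n);
    ie_tr = NumericVector(n);
    ii_tr = NumericVector(n);
    pna_tr = NumericVector(n);
    pk_tr = NumericVector(n);
  }

  std::vector<double> spikes;
  double v = v_init;
  double v_prev = v_init;
  double last_spike = -1e9;

  double s_ina = 0, s_ik = 0, s_il = 0, s_ie = 0, s_ii = 0, s_itot = 0;
  double s_k_dr = 0, s_k_e = 0, s_k_i = 0, s_k_l = 0;

  for (int i = 0; i < n; ++i) {
    double ge = g_e[i] * 1e-3;           // uS/cm^2 -> mS/cm^2
    double gi = has_inh ? g_i[i] * 1e-3 : 0.0;
    if (clip_negative) {
      if (ge < 0) ge = 0;
      if (gi < 0) gi = 0;
    }

    double gna, gk, p_na, p_k;
    if (deterministic) {
      p_na = m * m * m * h;
      p_k = nn * nn * nn * nn;
      gna = gbar_na * p_na;
      gk = gbar_k * p_k;
    } else {
      p_na = (double) na[7] / n_na;
      p_k = (double) kk[4] / n_k;
      gna = g_unit * na[7];
      gk = g_unit * kk[4];
    }

    double i_na = gna * (v - e_na);
    double i_k = gk * (v - e_k);
    double i_l = g_leak * (v - e_leak);
    double i_e = ge * (v - e_e);
    double i_i = gi * (v - e_i);
    double i_tot = i_na + i_k + i_l + i_e + i_i;

    s_ina += i_na; s_ik += i_k; s_il += i_l; s_ie += i_e; s_ii += i_i;
    s_itot += i_tot;
    s_k_dr += i_k;
    s_k_e += fk_e * ge * (v - e_k);
    s_k_i += fk_i * gi * (v - e_k);
    s_k_l += fk_l * g_leak * (v - e_k);

    if (record_trace) {
      v_tr[i] = v;
      ina_tr[i] = i_na; ik_tr[i] = i_k; il_tr[i] = i_l;
      ie_tr[i] = i_e; ii_tr[i] = i_i;
      pna_tr[i] = p_na; pk_tr[i] = p_k;
    }

    // upward threshold crossing between sample i-1 and i, with lockout
    if (i > 0 && v >= threshold && v_prev < threshold &&
        (i * dt - last_spike) >= refractory) {
      last_spike = i * dt;
      spikes.push_back(last_spike);
    }
    v_prev = v;

    // advance channels at the current voltage, then the voltage itself
    Rates r = hh_rates(v);
    if (deterministic) {
      m += dt * (r.am * (1.0 - m) - r.bm * m);
      h += dt * (r.ah * (1.0 - h) - r.bh * h);
      nn += dt * (r.an * (1.0 - nn) - r.bn * nn);
    } else {
      na_step(na, r, dt);
      k_step(kk, r, dt);
    }
    v -= (dt / c_m) * i_tot;
    if (!R_finite(v) || std::fabs(v) > 200.0)
      stop("membrane potential diverged (|V| > 200 mV) at t = %f ms", i * dt);
  }

  List integrals = List::create(
    _["i_na"] = s_ina * dt, _["i_k"] = s_ik * dt, _["i_leak"] = s_il * dt,
    _["i_exc"] = s_ie * dt, _["i_inh"] = s_ii * dt, _["i_total"] = s_itot * dt,
    _["k_dr"] = s_k_dr * dt, _["k_exc"] = s_k_e * dt,
    _["k_inh"] = s_k_i * dt, _["k_leak"] = s_k_l * dt);

  List out = List::create(
    _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
    _["v_final"] = v,
    _["integrals"] = integrals,
    _["duration"] = n * dt);
  if (record_trace) {
    out["voltage"] = v_tr;
    out["i_na"] = ina_tr; out["i_k"] = ik_tr; out["i_leak"] = il_tr;
    out["i_exc"] = ie_tr; out["i_inh"] = ii_tr;
    out["p_open_na"] = pna_tr; out["p_open_k"] = pk_tr;
  }
  return out;
}
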