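#include <Rcpp.h>
#include "gating.h"

using namespace Rcpp;
using namespace kv3net;

// Gating evaluators exported for cross-checking the R reference
// implementations against the compiled core used by the integrators.

// [[Rcpp::export(name = ".kv3_gating_cpp")]]
List kv3_gating_cpp(NumericVector v, double delta_shift, double kin_scale,
                    int mtau_parse) {
  int n = v.size();
  NumericVector minf(n), hinf(n), mtau(n);
  for (int i = 0; i < n; ++i) {
    minf[i] = kv3_minf(v[i], delta_shift);
    hinf[i] = kv3_hinf(v[i], delta_shift);
    mtau[i] = kv3_mtau(v[i], delta_shift, kin_scale, mtau_parse);
  }
  return List::create(_["minf"] = minf, _["hinf"] = hinf, _["mtau"] = mtau);
}

// [[Rcpp::export(name = ".nav_hh_rates_cpp")]]
List nav_hh_rates_cpp(NumericVector v, double vshift, double kin_scale) {
  int n = v.size();
  NumericVector minf(n), hinf(n), mtau(n), htau(n);
  for (int i = 0; i < n; ++i) {
    HHRates r = nav_hh_rates(v[i], vshift, kin_scale);
    minf[i] = r.minf; hinf[i] = r.hinf; mtau[i] = r.mtau; htau[i] = r.htau;
  }
  return List::create(_["minf"] = minf, _["hinf"] = hinf,
                      _["mtau"] = mtau, _["htau"] = htau);
}

static double get_d(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

// Fixed-step integrator for the single-compartment PV model.
//
// Gates advance by exact exponential relaxation at the instantaneous
// voltage; the voltage itself advances by an exponential (linearly
// implicit) update with conductances frozen over the step, which is exact
// for a passive membrane and stable at dt = 0.025 ms even at spike-peak
// sodium conductances.
//
// Units: mV, ms, nA, uS, nF.  i_inj in nA; g_exc/g_inh in nS.
//
// [[Rcpp::export(name = ".simulate_pv_cpp")]]
List simulate_pv_cpp(List params, double dt, double v0,
                     NumericVector i_inj, NumericVector g_exc,
                     NumericVector g_inh, double e_exc, double e_inh,
                     bool record_im) {
  int n = i_inj.size();
  if (g_exc.size() != n || g_inh.size() != n)
    stop("input series must have equal length");

  double area = get_d(params, "area_cm2");
  double c_nF = get_d(params, "cm_uF_cm2") * area * 1e3;
  double gna = get_d(params, "gna_S_cm2") * area * 1e6;   // uS
  double gkv3 = get_d(params, "gkv3_S_cm2") * area * 1e6;
  double gkv7 = get_d(params, "gkv7_S_cm2") * area * 1e6;
  double gl = get_d(params, "gl_S_cm2") * area * 1e6;
  double ena = get_d(params, "ena"), ek = get_d(params, "ek");
  double el = get_d(params, "el");
  double na_vs = get_d(params, "na_vshift");
  double na_ks = get_d(params, "na_kin_scale");
  double k_ds = get_d(params, "kv3_delta_shift");
  double k_ks = get_d(params, "kv3_kin_scale");
  double k_ti = get_d(params, "kv3_tau_inact");
  int k_parse = as<int>(params["kv3_mtau_parse"]);
  double kv7_ds = get_d(params, "kv7_delta_shift");
  double kv7_ks = get_d(params, "kv7_kin_scale");
  // dynamic clamp: absolute conductance in nS, Kv3 gating at live voltage
  double dc_g = get_d(params, "dc_g_nS") * 1e-3;          // uS
  double dc_ds = get_d(params, "dc_delta_shift");
  double dc_ks = get_d(params, "dc_kin_scale");
  double dc_ti = get_d(params, "dc_tau_inact");
  double dc_e = get_d(params, "dc_e_rev");

  double v = v0;
  HHRates r0 = nav_hh_rates(v, na_vs, na_ks);
  double m_na = r0.minf, h_na = r0.hinf;
  double m_k = kv3_minf(v, k_ds), h_k = kv3_hinf(v, k_ds);
  double m_7 = kv7_minf(v, kv7_ds);
  double m_dc = kv3_minf(v, dc_ds), h_dc = kv3_hinf(v, dc_ds);

  NumericVector vout(n + 1), imem;
  if (record_im) imem = NumericVector(n + 1);
  vout[0] = v;
  bool blowup = false;
  double t_fail = NA_REAL;

  for (int i = 0; i < n; ++i) {
    HHRates r = nav_hh_rates(v, na_vs, na_ks);
    m_na = gate_relax(m_na, r.minf, r.mtau, dt);
    h_na = gate_relax(h_na, r.hinf, r.htau, dt);
    m_k = gate_relax(m_k, kv3_minf(v, k_ds),
                     kv3_mtau(v, k_ds, k_ks, k_parse), dt);
    h_k = gate_relax(h_k, kv3_hinf(v, k_ds), k_ti, dt);
    m_7 = gate_relax(m_7, kv7_minf(v, kv7_ds),
                     kv7_mtau(v, kv7_ds) * kv7_ks, dt);
    m_dc = gate_relax(m_dc, kv3_minf(v, dc_ds),
                      kv3_mtau(v, dc_ds, dc_ks, k_parse), dt);
    h_dc = gate_relax(h_dc, kv3_hinf(v, dc_ds), dc_ti, dt);

    double gNa = gna * m_na * m_na * m_na * h_na;
    double gK = gkv3 * m_k * h_k;
    double gM = gkv7 * m_7;
    double gDC = dc_g * m_dc * h_dc;
    double gE = g_exc[i] * 1e-3, gI = g_inh[i] * 1e-3;

    double gtot = gNa + gK + gM + gDC + gl + gE + gI;
    double isrc = gNa * ena + gK * ek + gM * ek + gDC * dc_e + gl * el +
                  gE * e_exc + gI * e_inh + i_inj[i];
    if (gtot > 0.0) {
      double vinf = isrc / gtot;
      v = vinf + (v - vinf) * std::exp(-dt * gtot / c_nF);
    } else {
      v += dt * i_inj[i] / c_nF;
    }
    vout[i + 1] = v;
    if (record_im) {
      imem[i + 1] = gNa * (v - ena) + gK * (v - ek) + gM * (v - ek) +
                    gDC * (v - dc_e) + gl * (v - el);
    }
    if (!std::isfinite(v) || std::fabs(v) > 200.0) {
      blowup = true;
      t_fail = (i + 1) * dt;
      break;
    }
  }
  List out = List::create(_["v"] = vout, _["blowup"] = blowup,
                          _["t_fail"] = t_fail);
  if (record_im) out["i_mem"] = imem;
  return out;
}

// Single-compartment bursting pyramidal cell: HH-type Na (instantaneous
// activation, inactivation slaved to the K gate) and delayed-rectifier K,
// plus a persistent Na current with slow inactivation that paces burst
// onset and termination.  Units: mV, ms, nA, uS, nF; conductances absolute
// in nS.
//
// [[Rcpp::export(name = ".simulate_pc_cpp")]]
List simulate_pc_cpp(List params, double dt, double v0,
                     NumericVector i_inj, NumericVector g_exc,
                     NumericVector g_inh, double e_exc, double e_inh,
                     bool record_im) {
  int n = i_inj.size();
  double c_nF = get_d(params, "c_pF") * 1e-3;
  double gna = get_d(params, "gna_nS") * 1e-3;   // uS
  double gk = get_d(params, "gk_nS") * 1e-3;
  double gnap = get_d(params, "gnap_nS") * 1e-3;
  double gl = get_d(params, "gl_nS") * 1e-3;
  double ena = get_d(params, "ena"), ek = get_d(params, "ek");
  double el = get_d(params, "el");
  double taun = get_d(params, "taun_bar_ms");
  double tauh = get_d(params, "tauh_bar_ms");

  double v = v0;
  double ngate = 1.0 / (1.0 + std::exp(-(v + 29.0) / 4.0));
  double hs = 1.0 / (1.0 + std::exp((v + 48.0) / 6.0));

  NumericVector vout(n + 1), imem;
  if (record_im) imem = NumericVector(n + 1);
  vout[0] = v;
  bool blowup = false;
  double t_fail = NA_REAL;

  for (int i = 0; i < n; ++i) {
    double ninf = 1.0 / (1.0 + std::exp(-(v + 29.0) / 4.0));
    double tn = taun / std::cosh((v + 29.0) / 8.0);
    ngate = gate_relax(ngate, ninf, tn, dt);
    double hinf = 1.0 / (1.0 + std::exp((v + 48.0) / 6.0));
    double th = tauh / std::cosh((v + 48.0) / 12.0);
    hs = gate_relax(hs, hinf, th, dt);

    double minf = 1.0 / (1.0 + std::exp(-(v + 34.0) / 5.0));
    double pinf = 1.0 / (1.0 + std::exp(-(v + 40.0) / 6.0));
    double gNa = gna * minf * minf * minf * (1.0 - ngate);
    double gK = gk * ngate * ngate * ngate * ngate;
    double gNaP = gnap * pinf * hs;
    double gE = g_exc[i] * 1e-3, gI = g_inh[i] * 1e-3;

    double gtot = gNa + gK + gNaP + gl + gE + gI;
    double isrc = (gNa + gNaP) * ena + gK * ek + gl * el +
                  gE * e_exc + gI * e_inh + i_inj[i];
    double vinf = isrc / gtot;
    v = vinf + (v - vinf) * std::exp(-dt * gtot / c_nF);
    vout[i + 1] = v;
    if (record_im) {
      imem[i + 1] = gNa * (v - ena) + gNaP * (v - ena) + gK * (v - ek) +
                    gl * (v - el);
    }
    if (!std::isfinite(v) || std::fabs(v) > 200.0) {
      blowup = true;
      t_fail = (i + 1) * dt;
      break;
    }
  }
  List out = List::create(_["v"] = vout, _["blowup"] = blowup,
                          _["t_fail"] = t_fail);
  if (record_im) out["i_mem"] = imem;
  return out;
}
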