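#include <Rcpp.h>
#include <vector>
#include "gating.h"

using namespace Rcpp;
using namespace kv3net;

// Reduced cortical circuit: n_pc bursting pyramidal cells followed by n_pv
// fast-spiking PV cells (global cell ids 0..n_pc+n_pv-1, PCs first).
// Chemical synapses are spike-triggered exponential-decay conductances with
// a fixed axonal+synaptic delay; gap junctions couple PV pairs ohmically.
// The LFP proxy accumulates the summed ionic transmembrane current of all
// cells, block-averaged down to 1 / (dt * lfp_decim) kHz.
//
// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(List pc_params, List pv_params,
                          int n_pc, int n_pv,
                          IntegerVector syn_pre, IntegerVector syn_post,
                          NumericVector syn_w_nS, LogicalVector syn_is_inh,
                          IntegerVector gap_a, IntegerVector gap_b,
                          double g_gap_nS,
                          NumericVector bias_nA, NumericVector v0,
                          double dt, int n_steps,
                          double tau_e, double tau_i,
                          double e_exc, double e_inh,
                          int delay_steps, double spike_thr,
                          double refrac_ms, int lfp_decim,
                          IntegerVector record_v_idx) {
  int n_cells = n_pc + n_pv;
  if (bias_nA.size() != n_cells || v0.size() != n_cells)
    stop("bias and v0 must have one entry per cell");

  // PC constants
  double pc_c = as<double>(pc_params["c_pF"]) * 1e-3;
  double pc_gna = as<double>(pc_params["gna_nS"]) * 1e-3;
  double pc_gk = as<double>(pc_params["gk_nS"]) * 1e-3;
  double pc_gnap = as<double>(pc_params["gnap_nS"]) * 1e-3;
  double pc_gl = as<double>(pc_params["gl_nS"]) * 1e-3;
  double pc_ena = as<double>(pc_params["ena"]);
  double pc_ek = as<double>(pc_params["ek"]);
  double pc_el = as<double>(pc_params["el"]);
  double pc_taun = as<double>(pc_params["taun_bar_ms"]);
  double pc_tauh = as<double>(pc_params["tauh_bar_ms"]);

  // PV constants
  double pv_area = as<double>(pv_params["area_cm2"]);
  double pv_c = as<double>(pv_params["cm_uF_cm2"]) * pv_area * 1e3;
  double pv_gna = as<double>(pv_params["gna_S_cm2"]) * pv_area * 1e6;
  double pv_gkv3 = as<double>(pv_params["gkv3_S_cm2"]) * pv_area * 1e6;
  double pv_gl = as<double>(pv_params["gl_S_cm2"]) * pv_area * 1e6;
  double pv_ena = as<double>(pv_params["ena"]);
  double pv_ek = as<double>(pv_params["ek"]);
  double pv_el = as<double>(pv_params["el"]);
  double na_vs = as<double>(pv_params["na_vshift"]);
  double na_ks = as<double>(pv_params["na_kin_scale"]);
  double k_ds = as<double>(pv_params["kv3_delta_shift"]);
  double k_ks = as<double>(pv_params["kv3_kin_scale"]);
  double k_ti = as<double>(pv_params["kv3_tau_inact"]);
  int k_parse = as<int>(pv_params["kv3_mtau_parse"]);

  // outgoing-edge CSR
  int n_syn = syn_pre.size();
  std::vector<int> deg(n_cells, 0);
  for (int s = 0; s < n_syn; ++s) deg[syn_pre[s]]++;
  std::vector<int> ptr(n_cells + 1, 0);
  for (int c = 0; c < n_cells; ++c) ptr[c + 1] = ptr[c] + deg[c];
  std::vector<int> edge_post(n_syn);
  std::vector<double> edge_w(n_syn);
  std::vector<char> edge_inh(n_syn);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int s = 0; s < n_syn; ++s) {
      int k = fill[syn_pre[s]]++;
      edge_post[k] = syn_post[s];
      edge_w[k] = syn_w_nS[s];
      edge_inh[k] = syn_is_inh[s] ? 1 : 0;
    }
  }

  // gap junctions: per-PV adjacency
  int n_gap = gap_a.size();
  std::vector<std::vector<int> > gap_adj(n_cells);
  for (int g = 0; g < n_gap; ++g) {
    gap_adj[gap_a[g]].push_back(gap_b[g]);
    gap_adj[gap_b[g]].push_back(gap_a[g]);
  }
  double ggap = g_gap_nS * 1e-3;  // uS

  // state
  std::vector<double> v(n_cells), vprev(n_cells);
  std::vector<double> m_na(n_pv), h_na(n_pv), m_k(n_pv), h_k(n_pv);
  std::vector<double> ngate(n_pc), hs(n_pc);
  std::vector<double> g_e(n_cells, 0.0), g_i(n_cells, 0.0);
  std::vector<double> refrac(n_cells, 0.0);
  for (int c = 0; c < n_cells; ++c) v[c] = v0[c];
  for (int c = 0; c < n_pc; ++c) {
    ngate[c] = 1.0 / (1.0 + std::exp(-(v[c] + 29.0) / 4.0));
    hs[c] = 1.0 / (1.0 + std::exp((v[c] + 48.0) / 6.0));
  }
  for (int j = 0; j < n_pv; ++j) {
    int c = n_pc + j;
    HHRates r = nav_hh_rates(v[c], na_vs, na_ks);
    m_na[j] = r.minf; h_na[j] = r.hinf;
    m_k[j] = kv3_minf(v[c], k_ds);
    h_k[j] = kv3_hinf(v[c], k_ds);
  }

  // delayed synaptic increments (ring buffer)
  int dlen = delay_steps > 0 ? delay_steps : 1;
  std::vector<double> ring_e((size_t)dlen * n_cells, 0.0);
  std::vector<double> ring_i((size_t)dlen * n_cells, 0.0);

  double dec_e = std::exp(-dt / tau_e), dec_i = std::exp(-dt / tau_i);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(n_cells * 64);
  spike_id.reserve(n_cells * 64);

  int n_lfp = n_steps / lfp_decim;
  NumericVector lfp(n_lfp);
  double lfp_acc = 0.0;
  int lfp_cnt = 0, lfp_idx = 0;

  int n_rec = record_v_idx.size();
  NumericMatrix vrec(n_rec > 0 ? n_steps : 0, n_rec);

  bool blowup = false;
  double t_fail = NA_REAL;

  for (int i = 0; i < n_steps && !blowup; ++i) {
    int slot = i % dlen;
    // deliver delayed increments, then decay
    for (int c = 0; c < n_cells; ++c) {
      g_e[c] = g_e[c] * dec_e + ring_e[(size_t)slot * n_cells + c];
      g_i[c] = g_i[c] * dec_i + ring_i[(size_t)slot * n_cells + c];
      ring_e[(size_t)slot * n_cells + c] = 0.0;
      ring_i[(size_t)slot * n_cells + c] = 0.0;
    }
    vprev = v;
    double im_sum = 0.0;

    // PCs
    for (int c = 0; c < n_pc; ++c) {
      double vc = vprev[c];
      double ninf = 1.0 / (1.0 + std::exp(-(vc + 29.0) / 4.0));
      double tn = pc_taun / std::cosh((vc + 29.0) / 8.0);
      ngate[c] = gate_relax(ngate[c], ninf, tn, dt);
      double hinf = 1.0 / (1.0 + std::exp((vc + 48.0) / 6.0));
      double th = pc_tauh / std::cosh((vc + 48.0) / 12.0);
      hs[c] = gate_relax(hs[c], hinf, th, dt);
      double minf = 1.0 / (1.0 + std::exp(-(vc + 34.0) / 5.0));
      double pinf = 1.0 / (1.0 + std::exp(-(vc + 40.0) / 6.0));
      double gNa = pc_gna * minf * minf * minf * (1.0 - ngate[c]);
      double gK = pc_gk * ngate[c] * ngate[c] * ngate[c] * ngate[c];
      double gNaP = pc_gnap * pinf * hs[c];
      double gE = g_e[c] * 1e-3, gI = g_i[c] * 1e-3;
      double gtot = gNa + gK + gNaP + pc_gl + gE + gI;
      double isrc = (gNa + gNaP) * pc_ena + gK * pc_ek + pc_gl * pc_el +
                    gE * e_exc + gI * e_inh + bias_nA[c];
      double vinf = isrc / gtot;
      v[c] = vinf + (vc - vinf) * std::exp(-dt * gtot / pc_c);
      im_sum += gNa * (v[c] - pc_ena) + gNaP * (v[c] - pc_ena) +
                gK * (v[c] - pc_ek) + pc_gl * (v[c] - pc_el);
    }

    // PVs
    for (int j = 0; j < n_pv; ++j) {
      int c = n_pc + j;
      double vc = vprev[c];
      HHRates r = nav_hh_rates(vc, na_vs, na_ks);
      m_na[j] = gate_relax(m_na[j], r.minf, r.mtau, dt);
      h_na[j] = gate_relax(h_na[j], r.hinf, r.htau, dt);
      m_k[j] = gate_relax(m_k[j], kv3_minf(vc, k_ds),
                          kv3_mtau(vc, k_ds, k_ks, k_parse), dt);
      h_k[j] = gate_relax(h_k[j], kv3_hinf(vc, k_ds), k_ti, dt);
      double gNa = pv_gna * m_na[j] * m_na[j] * m_na[j] * h_na[j];
      double gK = pv_gkv3 * m_k[j] * h_k[j];
      double gE = g_e[c] * 1e-3, gI = g_i[c] * 1e-3;
      double gtot = gNa + gK + pv_gl + gE + gI;
      double isrc = gNa * pv_ena + gK * pv_ek + pv_gl * pv_el +
                    gE * e_exc + gI * e_inh + bias_nA[c];
      // gap junctions as conductance toward neighbours' previous voltage
      for (size_t a = 0; a < gap_adj[c].size(); ++a) {
        gtot += ggap;
        isrc += ggap * vprev[gap_adj[c][a]];
      }
      double vinf = isrc / gtot;
      v[c] = vinf + (vc - vinf) * std::exp(-dt * gtot / pv_c);
      im_sum += gNa * (v[c] - pv_ena) + gK * (v[c] - pv_ek) +
                pv_gl * (v[c] - pv_el);
    }

    // spikes + synaptic propagation
    double tnow = (i + 1) * dt;
    for (int c = 0; c < n_cells; ++c) {
      if (refrac[c] > 0.0) refrac[c] -= dt;
      if (vprev[c] < spike_thr && v[c] >= spike_thr && refrac[c] <= 0.0) {
        refrac[c] = refrac_ms;
        spike_t.push_back(tnow);
        spike_id.push_back(c + 1);
        // delivered delay_steps later
        int dslot = (slot + (delay_steps > 0 ? delay_steps : 1)) % dlen;
        for (int k = ptr[c]; k < ptr[c + 1]; ++k) {
          if (edge_inh[k])
            ring_i[(size_t)dslot * n_cells + edge_post[k]] += edge_w[k];
          else
            ring_e[(size_t)dslot * n_cells + edge_post[k]] += edge_w[k];
        }
      }
      if (!std::isfinite(v[c]) || std::fabs(v[c]) > 200.0) {
        blowup = true;
        t_fail = tnow;
      }
    }

    for (int rix = 0; rix < n_rec; ++rix)
      if (n_rec > 0) vrec(i, rix) = v[record_v_idx[rix]];

    lfp_acc += im_sum;
    if (++lfp_cnt == lfp_decim) {
      if (lfp_idx < n_lfp) lfp[lfp_idx++] = lfp_acc / lfp_decim;
      lfp_acc = 0.0;
      lfp_cnt = 0;
    }
  }

  return List::create(
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["lfp"] = lfp, _["v_rec"] = vrec,
      _["blowup"] = blowup, _["t_fail"] = t_fail);
}
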