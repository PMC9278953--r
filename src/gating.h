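#ifndef KV3NET_GATING_H
#define KV3NET_GATING_H

#include <cmath>

// Gating primitives shared by the single-cell and network integrators.
// Voltage in mV, time constants in ms.  delta_shift follows the user-facing
// convention: the change of the half-activation voltage (negative =
// hyperpolarizing).  Internally the Kv3 equations use vshift = -delta_shift.

namespace kv3net {

inline double kv3_minf(double v, double ds) {
  return 1.0 - 1.0 / (1.0 + std::exp((v + 5.0 - ds) / 12.0));
}

inline double kv3_hinf(double v, double ds) {
  return 1.0 / (1.0 + std::exp((v + 30.0 - ds) / 10.0));
}

// parse = 0: the kinetic scale multiplies only the Gaussian term (default);
// parse = 1: it multiplies the whole expression including the 0.5 ms floor.
inline double kv3_mtau(double v, double ds, double scale, int parse) {
  double z = (v - ds + 25.0) / 25.0;
  double bell = 4.0 * std::exp(-0.5 * z * z);
  if (parse == 1) return (0.5 + bell) * scale;
  return 0.5 + bell * scale;
}

inline double kv7_minf(double v, double ds) {
  return 1.0 / (1.0 + std::exp(-(v + 27.0 - ds) / 4.0));
}

// Slow below spike threshold, two orders of magnitude faster at spike
// voltages: the gate integrates spike activity over hundreds of ms and is
// essentially frozen between spikes.
// The kinetic parameters are fixed: an activation-voltage shift moves
// only the steady-state curve, not tau(v).
inline double kv7_mtau(double v, double) {
  return 150.0 + 7850.0 / (1.0 + std::exp((v - 8.0) / 2.0));
}

// x/(exp(x/y)-1) with the removable singularity handled analytically.
inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct HHRates {
  double minf, hinf, mtau, htau;
};

// Squid-type Hodgkin-Huxley Nav rate functions with a rigid voltage shift
// (positive = depolarizing shift of both curves) and a multiplicative
// kinetic scale applied to both time constants.
inline HHRates nav_hh_rates(double v, double vshift, double kin_scale) {
  double vv = v - vshift;
  double am = 0.1 * vtrap(-(vv + 40.0), 10.0);
  double bm = 4.0 * std::exp(-(vv + 65.0) / 18.0);
  double ah = 0.07 * std::exp(-(vv + 65.0) / 20.0);
  double bh = 1.0 / (1.0 + std::exp(-(vv + 35.0) / 10.0));
  HHRates r;
  r.minf = am / (am + bm);
  r.hinf = ah / (ah + bh);
  r.mtau = kin_scale / (am + bm);
  r.htau = kin_scale / (ah + bh);
  return r;
}

// Exact exponential relaxation of a gate toward its steady state.
inline double gate_relax(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

}  // namespace kv3net

#endif
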