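#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rush-Larsen gating update + forward-Euler membrane potential update for
// the Hodgkin-Huxley reaction terms. Voltages in mV, time in ms, currents
// in uA/cm^2. Physiological-voltage convention (rest near -75 mV).
//
// amps holds the stimulus amplitude for each substep; it is applied at the
// (1-based) node indices in stim_idx.
// [[Rcpp::export]]
List hh_react_cpp(NumericVector V0, NumericVector m0, NumericVector h0,
                  NumericVector n0, IntegerVector stim_idx,
                  NumericVector amps, double dt, int n_sub,
                  double gNa, double gK, double gL,
                  double ENa, double EK, double EL, double Cm) {
  int n = V0.size();
  NumericVector V = clone(V0), m = clone(m0), h = clone(h0), nn = clone(n0);
  std::vector<double> stim(n, 0.0);
  for (int s = 0; s < n_sub; ++s) {
    double amp = amps[s];
    for (int k = 0; k < stim_idx.size(); ++k) stim[stim_idx[k] - 1] = amp;
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      double xm = v + 50.0;
      double am = (std::fabs(xm) < 1e-7) ? 1.0 : -0.1 * xm / expm1(-xm / 10.0);
      double bm = 4.0 * std::exp(-(v + 75.0) / 18.0);
      double ah = 0.07 * std::exp(-(v + 75.0) / 20.0);
      double bh = 1.0 / (std::exp(-(v + 45.0) / 10.0) + 1.0);
      double xn = v + 65.0;
      double an = (std::fabs(xn) < 1e-7) ? 0.1 : -0.01 * xn / expm1(-xn / 10.0);
      double bn = 0.125 * std::exp(-(v + 75.0) / 80.0);
      // exact exponential relaxation towards the steady state
      double sm = am + bm, sh = ah + bh, sn = an + bn;
      double mi = am / sm, hi = ah / sh, ni = an / sn;
      m[i] = mi + (m[i] - mi) * std::exp(-dt * sm);
      h[i] = hi + (h[i] - hi) * std::exp(-dt * sh);
      nn[i] = ni + (nn[i] - ni) * std::exp(-dt * sn);
      double m3 = m[i] * m[i] * m[i];
      double n4 = nn[i] * nn[i];
      n4 *= n4;
      double iion = gNa * m3 * h[i] * (v - ENa) + gK * n4 * (v - EK) +
                    gL * (v - EL) - stim[i];
      V[i] = v - dt * iion / Cm;
    }
  }
  return List::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = nn);
}
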