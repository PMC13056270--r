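#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step simulation of a leaky integrate-and-fire neuron with
// alpha-shaped post-synaptic currents, using exact exponential propagation
// of the linear subthreshold system (membrane potential + the two-variable
// alpha-current state). Input events are given as grid-step indices; spike
// times are reported at the grid point where the threshold is crossed.
//
// Subthreshold dynamics:
//   y1' = -y1 / tau_syn
//   y2' =  y1 - y2 / tau_syn          (I_syn = y2, in pA)
//   V'  = -(V - E_L) / tau_m + (I_e + y2) / C_m
// An input event adds w * e / tau_syn to y1, so the elicited current is
// w * e * (t/tau_syn) * exp(-t/tau_syn) with peak exactly w at t = tau_syn.

// [[Rcpp::export]]
NumericVector lif_simulate_cpp(double E_L, double V_th, double V_reset,
                               double tau_m, double C_m, double I_e,
                               double t_ref, double tau_syn, double w,
                               double dt, IntegerVector input_steps,
                               int n_spikes, double max_duration) {
  const double Pmm = std::exp(-dt / tau_m);
  const double P11 = std::exp(-dt / tau_syn);
  const double P21 = dt * P11;
  const double k = 1.0 / tau_syn - 1.0 / tau_m;
  double P31, P32;
  if (std::fabs(k) > 1e-10) {
    P32 = (Pmm - P11) / (C_m * k);
    P31 = (Pmm - (1.0 + k * dt) * P11) / (C_m * k * k);
  } else {  // tau_syn == tau_m limit
    P32 = dt * Pmm / C_m;
    P31 = 0.5 * dt * dt * Pmm / C_m;
  }
  const double P30 = (tau_m / C_m) * (1.0 - Pmm);  // drive of constant I_e
  const double kick = w * M_E / tau_syn;
  const int ref_steps = (t_ref > 0.0) ? (int)std::lround(t_ref / dt) : 0;
  const long max_steps = (long)std::ceil(max_duration / dt);

  std::vector<double> spikes;
  spikes.reserve(n_spikes);

  double V = E_L, y1 = 0.0, y2 = 0.0;
  long ref_until = -1;  // step index until which the membrane is clamped
  R_xlen_t n_in = input_steps.size(), j = 0;

  for (long s = 1; s <= max_steps; ++s) {
    double V_new;
    if (s <= ref_until) {
      V_new = V_reset;  // clamped; synaptic state keeps evolving
    } else {
      V_new = E_L + (V - E_L) * Pmm + I_e * P30 + P31 * y1 + P32 * y2;
    }
    y2 = P21 * y1 + P11 * y2;
    y1 = P11 * y1;
    // input events snapped to this grid point enter the synapse now
    while (j < n_in && input_steps[j] == s) { y1 += kick; ++j; }
    while (j < n_in && input_steps[j] < s) ++j;  // skip stale (defensive)
    V = V_new;
    if (s > ref_until && V >= V_th) {
      spikes.push_back(s * dt);
      V = V_reset;
      ref_until = s + ref_steps;
      if ((int)spikes.size() >= n_spikes) break;
    }
  }
  return wrap(spikes);
}
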