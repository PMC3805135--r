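#include <Rcpp.h>
using namespace Rcpp;

// First-order Boltzmann steady state. v_slope sign convention:
// positive slope -> gate opens with hyperpolarization (h-current activation,
// A-current inactivation); negative slope -> opens with depolarization.
static inline double boltz(double v, double v_half, double v_slope) {
  return 1.0 / (1.0 + std::exp((v - v_half) / v_slope));
}

// Bell-shaped voltage dependence of the activation time constant,
// tau(V) = tau_max / cosh((V - tau_v_half) / tau_v_slope).
static inline double tau_bell(double v, double tau_max, double tau_v_half,
                              double tau_v_slope) {
  return tau_max / std::cosh((v - tau_v_half) / tau_v_slope);
}

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// Forward-Euler integration of one gating variable along a sampled voltage
// trace. Causal: the state reported at sample i was computed from the
// voltage at sample i-1, mirroring a real-time dynamic clamp where the
// current injected at step n uses the state advanced from the previous
// measurement. tau is voltage dependent (bell) when tau_v_slope > 0 is
// finite; pass tau_v_slope = NA to use the constant tau_max.
// [[Rcpp::export]]
NumericVector euler_gate_cpp(NumericVector v, double dt, double v_half,
                             double v_slope, double tau_max,
                             double tau_v_half, double tau_v_slope,
                             double m0) {
  const int n = v.size();
  NumericVector m(n);
  const bool vtau = !NumericVector::is_na(tau_v_slope);
  double state = clamp01(m0);
  m[0] = state;
  for (int i = 1; i < n; ++i) {
    const double vp = v[i - 1];
    const double minf = boltz(vp, v_half, v_slope);
    const double tau = vtau ? tau_bell(vp, tau_max, tau_v_half, tau_v_slope)
                            : tau_max;
    state = clamp01(state + dt * (minf - state) / tau);
    m[i] = state;
  }
  return m;
}

// Single-compartment post-inhibitory-rebound neuron: leak + transient
// A-type potassium current (m^p h kinetics, constant taus) + slow
// hyperpolarization-activated inward current (first-order Boltzmann gate,
// bell tau) + a prescribed synaptic-inhibition conductance waveform.
// Units: nF, uS, mV, nA, ms. Forward Euler throughout.
// [[Rcpp::export]]
List rebound_sim_cpp(NumericVector g_syn_t, double dt,
                     double c_nF, double g_l, double e_l,
                     double e_syn,
                     double g_a, double e_a,
                     double a_act_v_half, double a_act_v_slope,
                     double a_act_tau, double a_act_exponent,
                     double a_inact_v_half, double a_inact_v_slope,
                     double a_inact_tau,
                     double g_h, double e_h,
                     double h_v_half, double h_v_slope,
                     double h_tau_max, double h_tau_v_half,
                     double h_tau_v_slope,
                     double v0, double m_a0, double h_a0, double m_h0) {
  const int n = g_syn_t.size();
  NumericVector v(n);
  double vm = v0, ma = clamp01(m_a0), ha = clamp01(h_a0), mh = clamp01(m_h0);
  v[0] = vm;
  for (int i = 1; i < n; ++i) {
    // currents at previous step's state
    const double i_l = g_l * (vm - e_l);
    const double i_a = g_a * std::pow(ma, a_act_exponent) * ha * (vm - e_a);
    const double i_h = g_h * mh * (vm - e_h);
    const double i_s = g_syn_t[i - 1] * (vm - e_syn);
    const double dv = -dt * (i_l + i_a + i_h + i_s) / c_nF;
    // gate updates use the previous voltage
    ma = clamp01(ma + dt * (boltz(vm, a_act_v_half, a_act_v_slope) - ma) / a_act_tau);
    ha = clamp01(ha + dt * (boltz(vm, a_inact_v_half, a_inact_v_slope) - ha) / a_inact_tau);
    mh = clamp01(mh + dt * (boltz(vm, h_v_half, h_v_slope) - mh) /
                 tau_bell(vm, h_tau_max, h_tau_v_half, h_tau_v_slope));
    vm += dv;
    v[i] = vm;
  }
  return List::create(_["v"] = v,
                      _["m_a"] = ma, _["h_a"] = ha, _["m_h"] = mh);
}
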