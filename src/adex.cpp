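#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Fixed-step explicit Euler for the extended AdEx neuron
//   C dV/dt = g_L((E_L+z)-V) + g_L*Delta_T*exp((V-(V_T-beta z))/Delta_T) - w - g_p z + I_s
//   tau_w dw/dt = a(V-(E_L+z)) - w
//   dz/dt = eps (Z0 - V - z)
// with reset V>=V_D -> V=V_R, w+=b, followed by a t_ref window during which V
// is clamped at V_R while w and z keep integrating (optionally w frozen).
// Spike times are the end times of the step on which detection fired.
//
// [[Rcpp::export]]
List adex_integrate_cpp(NumericVector par, double duration, double dt,
                        double V0, double w0, double z0, double t_since0,
                        int sample_stride, bool frozen_z, bool freeze_w_ref) {
  const double C = par["C"], gL = par["g_L"], EL = par["E_L"], VT = par["V_T"],
    DT = par["Delta_T"], tauw = par["tau_w"], a = par["a"], b = par["b"],
    Is = par["I_s"], VD = par["V_D"], VR = par["V_R"], tref = par["t_ref"],
    eps = par["epsilon"], Z0 = par["Z0"], gp = par["g_p"], beta = par["beta"];

  const long n_steps = (long)std::llround(duration / dt);
  double V = V0, w = w0, z = z0, t_since = t_since0;

  std::vector<double> sp;
  const long n_samp = n_steps / sample_stride + 1;
  NumericVector s_t(n_samp), s_V(n_samp), s_w(n_samp), s_z(n_samp);
  long k = 0;
  s_t[k] = 0.0; s_V[k] = V; s_w[k] = w; s_z[k] = z; ++k;

  for (long s = 1; s <= n_steps; ++s) {
    const double t_end = s * dt;
    const bool refractory = (t_since < tref);
    if (refractory) {
      V = VR;
      if (!freeze_w_ref) w += dt * ((a * (V - (EL + z)) - w) / tauw);
      if (!frozen_z) z += dt * (eps * (Z0 - V - z));
    } else {
      const double ex = std::exp((V - (VT - beta * z)) / DT);
      if (!std::isfinite(ex))
        stop("exponential term overflowed at step %ld (V = %g mV): spike detection was missed", s, V);
      const double dV = (gL * ((EL + z) - V) + gL * DT * ex - w - gp * z + Is) / C;
      const double dw = (a * (V - (EL + z)) - w) / tauw;
      const double dz = frozen_z ? 0.0 : eps * (Z0 - V - z);
      V += dt * dV;
      w += dt * dw;
      z += dt * dz;
    }
    t_since += dt;
    if (!refractory && V >= VD) {
      sp.push_back(t_end);
      V = VR;
      w += b;
      t_since = 0.0;
    }
    if (!(std::isfinite(V) && std::isfinite(w) && std::isfinite(z)))
      stop("non-finite state at step %ld (t = %g ms)", s, t_end);
    if (s % sample_stride == 0) {
      s_t[k] = t_end; s_V[k] = V; s_w[k] = w; s_z[k] = z; ++k;
    }
  }

  return List::create(_["time"] = s_t, _["V"] = s_V, _["w"] = s_w, _["z"] = s_z,
                      _["spikes"] = NumericVector(sp.begin(), sp.end()),
                      _["V_end"] = V, _["w_end"] = w, _["z_end"] = z,
                      _["t_since_end"] = t_since);
}
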