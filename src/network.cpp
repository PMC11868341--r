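#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Synchronous fixed-step update of the conductance-based network.
// Per step: (1) exact exponential decay of g_E, g_I; (2) Euler step of the
// extended-AdEx equations per cell with I_s + I_syn, I_syn = g_E(E_E - V) +
// g_I(E_I - V) evaluated at the pre-step V; (3) spike detection / reset /
// refractory clocks; (4) delivery of quantal increments Q_E / Q_I to
// postsynaptic conductances, effective from the next step.
//
// `par` is an n x 16 matrix, one row per cell, columns in the order
// C, g_L, E_L, V_T, Delta_T, tau_w, a, b, I_s, V_D, V_R, t_ref, epsilon, Z0,
// g_p, beta. Adjacency is CSR over presynaptic cells: targets[ptr[i]..ptr[i+1])
// are the 0-based postsynaptic cells of cell i.
//
// [[Rcpp::export]]
List network_integrate_cpp(NumericMatrix par, IntegerVector targets,
                           IntegerVector ptr, IntegerVector is_exc,
                           double EE, double EI, double QE, double QI,
                           double tau_syn, double duration, double dt,
                           NumericVector V0, NumericVector w0, NumericVector z0,
                           NumericVector gE0, NumericVector gI0,
                           IntegerVector record_idx, int sample_stride,
                           double ext_rate_hz) {
  const int n = par.nrow();
  const long n_steps = (long)std::llround(duration / dt);
  const double decay = std::exp(-dt / tau_syn);

  std::vector<double> V(V0.begin(), V0.end()), w(w0.begin(), w0.end()),
      z(z0.begin(), z0.end()), gE(gE0.begin(), gE0.end()),
      gI(gI0.begin(), gI0.end());
  std::vector<double> t_since(n, R_PosInf);
  std::vector<int> counts(n, 0);

  std::vector<int> sp_cell;
  std::vector<double> sp_time;
  std::vector<int> firing;
  firing.reserve(n);

  const int n_rec = record_idx.size();
  const long n_samp = n_steps / sample_stride + 1;
  NumericMatrix rV(n_samp, n_rec), rw(n_samp, n_rec), rz(n_samp, n_rec),
      rgE(n_samp, n_rec), rgI(n_samp, n_rec);
  NumericVector r_t(n_samp);
  long k = 0;
  for (int j = 0; j < n_rec; ++j) {
    const int i = record_idx[j];
    rV(k, j) = V[i]; rw(k, j) = w[i]; rz(k, j) = z[i];
    rgE(k, j) = gE[i]; rgI(k, j) = gI[i];
  }
  r_t[k] = 0.0; ++k;

  // local copies of per-cell parameters for cache-friendly access
  std::vector<double> C(n), gL(n), EL(n), VT(n), DT(n), tauw(n), a(n), b(n),
      Is(n), VD(n), VR(n), tref(n), eps(n), Z0(n), gp(n), beta(n);
  for (int i = 0; i < n; ++i) {
    C[i] = par(i, 0); gL[i] = par(i, 1); EL[i] = par(i, 2); VT[i] = par(i, 3);
    DT[i] = par(i, 4); tauw[i] = par(i, 5); a[i] = par(i, 6); b[i] = par(i, 7);
    Is[i] = par(i, 8); VD[i] = par(i, 9); VR[i] = par(i, 10);
    tref[i] = par(i, 11); eps[i] = par(i, 12); Z0[i] = par(i, 13);
    gp[i] = par(i, 14); beta[i] = par(i, 15);
  }

  for (long s = 1; s <= n_steps; ++s) {
    const double t_end = s * dt;
    firing.clear();
    for (int i = 0; i < n; ++i) {
      gE[i] *= decay;
      gI[i] *= decay;
      const bool refractory = (t_since[i] < tref[i]);
      if (refractory) {
        V[i] = VR[i];
        w[i] += dt * ((a[i] * (V[i] - (EL[i] + z[i])) - w[i]) / tauw[i]);
        z[i] += dt * (eps[i] * (Z0[i] - V[i] - z[i]));
      } else {
        const double ex = std::exp((V[i] - (VT[i] - beta[i] * z[i])) / DT[i]);
        const double Isyn = gE[i] * (EE - V[i]) + gI[i] * (EI - V[i]);
        const double dV = (gL[i] * ((EL[i] + z[i]) - V[i]) + gL[i] * DT[i] * ex -
                           w[i] - gp[i] * z[i] + Is[i] + Isyn) / C[i];
        const double dw = (a[i] * (V[i] - (EL[i] + z[i])) - w[i]) / tauw[i];
        const double dz = eps[i] * (Z0[i] - V[i] - z[i]);
        V[i] += dt * dV;
        w[i] += dt * dw;
        z[i] += dt * dz;
      }
      t_since[i] += dt;
      if (!refractory && V[i] >= VD[i]) {
        sp_cell.push_back(i + 1);
        sp_time.push_back(t_end);
        firing.push_back(i);
        V[i] = VR[i];
        w[i] += b[i];
        t_since[i] = 0.0;
        ++counts[i];
      }
      if (!(std::isfinite(V[i]) && std::isfinite(w[i]) && std::isfinite(z[i])))
        stop("non-finite state for cell %d at step %ld (t = %g ms)", i + 1, s, t_end);
    }
    // external background drive: homogeneous Poisson excitatory events at
    // ext_rate_hz per cell, delivered through the same quantal g_E synapse
    if (ext_rate_hz > 0) {
      const double lambda = n * ext_rate_hz * dt / 1000.0;
      const int K = (int)R::rpois(lambda);
      for (int k = 0; k < K; ++k) {
        int cell = (int)(unif_rand() * n);
        if (cell >= n) cell = n - 1;
        gE[cell] += QE;
      }
    }
    for (size_t f = 0; f < firing.size(); ++f) {
      const int i = firing[f];
      const double q = is_exc[i] ? QE : QI;
      if (is_exc[i]) {
        for (int e = ptr[i]; e < ptr[i + 1]; ++e) gE[targets[e]] += q;
      } else {
        for (int e = ptr[i]; e < ptr[i + 1]; ++e) gI[targets[e]] += q;
      }
    }
    if (s % sample_stride == 0) {
      for (int j = 0; j < n_rec; ++j) {
        const int i = record_idx[j];
        rV(k, j) = V[i]; rw(k, j) = w[i]; rz(k, j) = z[i];
        rgE(k, j) = gE[i]; rgI(k, j) = gI[i];
      }
      r_t[k] = t_end; ++k;
    }
  }

  return List::create(
      _["cell"] = IntegerVector(sp_cell.begin(), sp_cell.end()),
      _["time"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["counts"] = IntegerVector(counts.begin(), counts.end()),
      _["rec_time"] = r_t, _["rec_V"] = rV, _["rec_w"] = rw, _["rec_z"] = rz,
      _["rec_gE"] = rgE, _["rec_gI"] = rgI,
      _["gE_end"] = NumericVector(gE.begin(), gE.end()),
      _["gI_end"] = NumericVector(gI.begin(), gI.end()));
}
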