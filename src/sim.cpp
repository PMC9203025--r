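#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inverse-transform Poisson draw; efficient for small means (lambda << 1),
// which is the regime of per-bin cortical event counts at sub-ms time steps.
static inline int rpois_small(double lambda, double p0) {
  double u = unif_rand();
  if (u <= p0) return 0;
  int k = 0;
  double p = p0, cum = p0;
  while (u > cum && k < 1000) {
    ++k;
    p *= lambda / k;
    cum += p;
  }
  return k;
}

// Euler-Maruyama integration of the conductance-based LIF neuron
//   tau dv/dt = -(v - E_L) - g_GABA (v - E_GABA) - g_Glu (v - E_Glu) + I_const + sigma sqrt(tau) xi(t)
// Hard threshold at E_thr, instantaneous reset to E_reset, zero refractory period.
// [[Rcpp::export]]
List cpp_simulate_lif(double tau, double E_L, double E_thr, double E_reset,
                      double E_Glu, double g_Glu, double g_GABA, double E_GABA,
                      double sigma, double I_const, double dt, int n_steps,
                      double v_init, bool record_v, int v_stride) {
  std::vector<double> spikes;
  int n_rec = record_v ? n_steps / v_stride : 0;
  NumericVector vtrace(n_rec);
  double v = v_init;
  const double a = dt / tau;
  const double sq = sigma * std::sqrt(dt / tau);
  const bool noisy = sigma > 0.0;
  int ir = 0;
  for (int i = 0; i < n_steps; ++i) {
    double dv = a * (-(v - E_L) - g_GABA * (v - E_GABA) - g_Glu * (v - E_Glu) + I_const);
    if (noisy) dv += sq * norm_rand();
    v += dv;
    if (v >= E_thr) {
      spikes.push_back((i + 1) * dt);
      v = E_reset;
    }
    if (record_v && ((i + 1) % v_stride == 0) && ir < n_rec) vtrace[ir++] = v;
  }
  return List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["v"] = vtrace, _["v_final"] = v);
}

// EIF-Kir neuron: LIF currents plus an exponential spike-generating current
// Delta_T exp((v - V_T)/Delta_T) and an inward-rectifier potassium current
// -g_K/(1 + exp((v - V_P)/K)) (v - E_K). A spike is registered when v >= V_cut,
// after which v is reset to E_reset.
// [[Rcpp::export]]
List cpp_simulate_eif_kir(double tau, double E_L, double E_reset, double E_Glu,
                          double Delta_T, double V_T, double g_K, double K_slope,
                          double V_P, double E_K, double V_cut,
                          double g_Glu, double g_GABA, double E_GABA,
                          double sigma, double I_const, double dt, int n_steps,
                          double v_init, bool record_v, int v_stride) {
  std::vector<double> spikes;
  int n_rec = record_v ? n_steps / v_stride : 0;
  NumericVector vtrace(n_rec);
  double v = v_init;
  const double a = dt / tau;
  const double sq = sigma * std::sqrt(dt / tau);
  const bool noisy = sigma > 0.0;
  int ir = 0;
  for (int i = 0; i < n_steps; ++i) {
    double Iexp = Delta_T * std::exp((v - V_T) / Delta_T);
    double Ikir = -g_K / (1.0 + std::exp((v - V_P) / K_slope)) * (v - E_K);
    double dv = a * (-(v - E_L) - g_GABA * (v - E_GABA) - g_Glu * (v - E_Glu) +
                     Iexp + Ikir + I_const);
    if (noisy) dv += sq * norm_rand();
    v += dv;
    if (!R_finite(v))
      stop("voltage diverged beyond numeric range; decrease dt");
    if (v >= V_cut) {
      spikes.push_back((i + 1) * dt);
      v = E_reset;
    }
    if (record_v && ((i + 1) % v_stride == 0) && ir < n_rec) vtrace[ir++] = v;
  }
  return List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["v"] = vtrace, _["v_final"] = v);
}

// Recurrent network of conductance-based LIF neurons.
//
// Each neuron receives an independent Poisson glutamatergic drive filtered by a
// single-exponential kernel (decay tau_k, per-event jump amp[i]) and recurrent
// GABAergic input through a difference-of-exponentials conductance kernel
// (decay tau1, rise tau2). A presynaptic spike in j increments both kernel
// states of every postsynaptic target by the edge strength, so
// g_GABA_i(t) = sA_i(t) - sB_i(t) >= 0.
//
// Adjacency is CSR by presynaptic neuron: for pre j (0-based), its targets are
// tgt[ptr[j] .. ptr[j+1]-1] with strengths w[...]. E_GABA is per-neuron
// (postsynaptic reversal).
// [[Rcpp::export]]
List cpp_simulate_network(int n, double tau, double E_L, double E_thr,
                          double E_reset, double E_Glu,
                          NumericVector E_GABA, NumericVector amp,
                          NumericVector lambda, double tau_k,
                          double tau1, double tau2,
                          IntegerVector ptr, IntegerVector tgt, NumericVector w,
                          double dt, int n_steps, NumericVector v_init,
                          IntegerVector rec_idx, int vm_stride) {
  const double a = dt / tau;
  const double dk = std::exp(-dt / tau_k);
  const double d1 = std::exp(-dt / tau1);
  const double d2 = std::exp(-dt / tau2);

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> gE(n, 0.0), sA(n, 0.0), sB(n, 0.0);
  std::vector<double> eg(E_GABA.begin(), E_GABA.end());
  std::vector<double> am(amp.begin(), amp.end());
  std::vector<double> lam(lambda.begin(), lambda.end());
  std::vector<double> p0(n);
  for (int i = 0; i < n; ++i) p0[i] = std::exp(-lam[i]);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<int> fired;
  fired.reserve(64);

  std::vector<double> sum_gG(n, 0.0), sum_gE(n, 0.0);

  const int n_rec = rec_idx.size();
  int n_samp = (vm_stride > 0 && n_rec > 0) ? n_steps / vm_stride : 0;
  NumericMatrix vm(n_rec, n_samp);
  int is = 0;

  for (int step = 0; step < n_steps; ++step) {
    fired.clear();
    const double t_now = (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double ge = gE[i] * dk;
      if (lam[i] > 0.0) {
        int k = rpois_small(lam[i], p0[i]);
        if (k > 0) ge += am[i] * k;
      }
      gE[i] = ge;
      double A = sA[i] * d1, B = sB[i] * d2;
      sA[i] = A; sB[i] = B;
      double gg = A - B;
      double vi = v[i];
      vi += a * (-(vi - E_L) - gg * (vi - eg[i]) - ge * (vi - E_Glu));
      sum_gG[i] += gg;
      sum_gE[i] += ge;
      if (vi >= E_thr) {
        spike_id.push_back(i + 1);
        spike_t.push_back(t_now);
        fired.push_back(i);
        vi = E_reset;
      }
      v[i] = vi;
    }
    // deliver this step's spikes: increments are seen from the next step on
    for (size_t f = 0; f < fired.size(); ++f) {
      int j = fired[f];
      for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
        sA[tgt[e]] += w[e];
        sB[tgt[e]] += w[e];
      }
    }
    if (n_samp > 0 && ((step + 1) % vm_stride == 0) && is < n_samp) {
      for (int r = 0; r < n_rec; ++r) vm(r, is) = v[rec_idx[r]];
      ++is;
    }
  }

  NumericVector mean_gG(n), mean_gE(n);
  for (int i = 0; i < n; ++i) {
    mean_gG[i] = sum_gG[i] / n_steps;
    mean_gE[i] = sum_gE[i] / n_steps;
  }
  return List::create(_["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
                      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
                      _["vm"] = vm,
                      _["mean_gGABA"] = mean_gG,
                      _["mean_gGlu"] = mean_gE,
                      _["v_final"] = NumericVector(v.begin(), v.end()));
}
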