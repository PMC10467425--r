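#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step integration of a multi-region network of adaptive exponential
// integrate-and-fire neurons with conductance-based alpha synapses.
//
// Synaptic kernels use the exact two-state propagation of the alpha function
//   g' = -g/tau + h,  h' = -h/tau  (+ jump on spike arrival)
// so a presynaptic spike arriving at lag 0 yields a conductance
//   g(dt*) = J * dt* * exp(-dt*/tau),  J = gbar * e / tau
// which peaks at exactly gbar at lag tau.
//
// The membrane equation is Euler-integrated at dt; the exponential
// spike-initiation term is evaluated with v clamped at v_peak to prevent
// overflow. Spike: v >= v_peak -> reset, w += b, refractory clamp.
//
// Background drive: independent per-neuron Poisson trains (rate_hz) onto
// AMPA-kernel synapses with conductance g_noise; this current is kept
// separate from I_syn so the LFP is the signed sum of recurrent synaptic
// currents only.
//
// Delays are quantized to the step grid. Inter-regional projections are
// excitatory only; each region keeps a ring buffer of spike counts from
// which delayed deliveries are read.

// [[Rcpp::export]]
List simulate_aeif_cpp(NumericMatrix P,          // n x 12 neuron params
                       IntegerVector region,     // 0-based region per neuron
                       LogicalVector is_exc,
                       int n_regions,
                       List syn,                 // EA,EG,tauA,tauG,gA,gG,g_noise,noise_rate
                       NumericMatrix G_inter,    // K x K max conductance (nS)
                       IntegerMatrix delay_steps,// K x K inter delays (steps)
                       int intra_delay_steps,
                       NumericVector A,          // per-neuron stimulus amplitude
                       double V, double f,       // scaling (pA / unit), Hz
                       int n_steps, double dt,   // dt in ms
                       int transient_steps,
                       bool lfp_abs) {
  const int n = P.nrow();
  const double EA = syn["EA"], EG = syn["EG"];
  const double tauA = syn["tauA"], tauG = syn["tauG"];
  const double gA_intra = syn["gA"], gG_intra = syn["gG"];
  const double g_noise = syn["g_noise"], noise_rate = syn["noise_rate"];

  const double eA = std::exp(-dt / tauA), eG = std::exp(-dt / tauG);
  const double JA = gA_intra * M_E / tauA;   // intra AMPA jump per spike
  const double JG = gG_intra * M_E / tauG;   // intra GABA jump per spike
  const double JN = g_noise * M_E / tauA;    // noise jump per event
  const double lam = noise_rate * dt / 1000.0; // Poisson mean per step
  const double p0 = std::exp(-lam);            // P(no background event)

  // per-neuron state
  std::vector<double> v(n), w(n);
  std::vector<double> hA(n, 0.0), gA(n, 0.0), hG(n, 0.0), gG(n, 0.0);
  std::vector<double> hN(n, 0.0), gN(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<int> tref_steps(n);
  // hoisted per-neuron parameters (column-major copies of P)
  std::vector<double> pC(n), pgL(n), pEL(n), pa(n), pb(n), pDT(n), ptauw(n),
      pvth(n), pvpeak(n), pvreset(n), pI(n);
  for (int i = 0; i < n; ++i) {
    v[i] = P(i, 2);              // start at E_L
    w[i] = 0.0;
    tref_steps[i] = (int)std::lround(P(i, 10) / dt);
    pC[i] = P(i, 0); pgL[i] = P(i, 1); pEL[i] = P(i, 2); pa[i] = P(i, 3);
    pb[i] = P(i, 4); pDT[i] = P(i, 5); ptauw[i] = P(i, 6); pvth[i] = P(i, 7);
    pvpeak[i] = P(i, 8); pvreset[i] = P(i, 9); pI[i] = P(i, 11);
  }

  // delay ring buffers: per-region E and I spike counts
  int max_delay = intra_delay_steps;
  for (int k = 0; k < n_regions; ++k)
    for (int kp = 0; kp < n_regions; ++kp)
      if (delay_steps(k, kp) > max_delay) max_delay = delay_steps(k, kp);
  const int L = max_delay + 1;
  std::vector<int> Ebuf((size_t)n_regions * L, 0), Ibuf((size_t)n_regions * L, 0);
  // per-neuron self-spike flags at the intra delay (autapse exclusion)
  const int Ls = intra_delay_steps + 1;
  std::vector<unsigned char> selfbuf((size_t)n * Ls, 0);

  const int n_rec = n_steps - transient_steps;
  NumericMatrix lfp(n_regions, n_rec);
  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  sp_neuron.reserve(100000); sp_time.reserve(100000);

  std::vector<double> addA(n_regions), intraE(n_regions), intraI(n_regions);
  const double two_pi_f = 2.0 * M_PI * f;
  const bool do_stim = (V != 0.0) && (A.size() == n);

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % L, slot_s = t % Ls;
    const double t_ms = t * dt;
    const double stim_phase = do_stim ? std::sin(two_pi_f * t_ms / 1000.0) : 0.0;

    // delayed deliveries
    for (int k = 0; k < n_regions; ++k) {
      double acc = 0.0;
      if (t >= intra_delay_steps) {
        int s = (t - intra_delay_steps) % L;
        intraE[k] = Ebuf[(size_t)k * L + s];
        intraI[k] = Ibuf[(size_t)k * L + s];
      } else { intraE[k] = 0.0; intraI[k] = 0.0; }
      for (int kp = 0; kp < n_regions; ++kp) {
        if (kp == k) continue;
        double g = G_inter(k, kp);
        if (g <= 0.0) continue;
        int d = delay_steps(k, kp);
        if (t >= d) acc += g * (M_E / tauA) * Ebuf[(size_t)kp * L + (t - d) % L];
      }
      addA[k] = acc;
    }
    const int slot_read = (t >= intra_delay_steps) ? (t - intra_delay_steps) % Ls : -1;

    // clear current write slots
    for (int k = 0; k < n_regions; ++k) {
      Ebuf[(size_t)k * L + slot] = 0;
      Ibuf[(size_t)k * L + slot] = 0;
    }

    for (int i = 0; i < n; ++i) {
      const int k = region[i];
      // spike deliveries (minus own delayed spike: no autapses)
      double self_sp = (slot_read >= 0) ? (double)selfbuf[(size_t)i * Ls + slot_read] : 0.0;
      double nE = intraE[k], nI = intraI[k];
      if (is_exc[i]) nE -= self_sp; else nI -= self_sp;
      hA[i] += JA * nE + addA[k];
      hG[i] += JG * nI;
      // exact Poisson inversion from a single uniform (lam is small, so
      // the expected number of pmf terms is ~1 + lam)
      if (lam > 0.0) {
        double u = R::unif_rand();
        if (u >= p0) {
          int nn = 0; double c = p0, F = p0;
          while (u >= F) { ++nn; c *= lam / nn; F += c; }
          hN[i] += JN * nn;
        }
      }

      // exact alpha-kernel propagation
      gA[i] = (gA[i] + dt * hA[i]) * eA;  hA[i] *= eA;
      gG[i] = (gG[i] + dt * hG[i]) * eG;  hG[i] *= eG;
      gN[i] = (gN[i] + dt * hN[i]) * eA;  hN[i] *= eA;

      const double Isyn = gA[i] * (v[i] - EA) + gG[i] * (v[i] - EG); // pA (nS*mV)
      if (t >= transient_steps) {
        double contrib = lfp_abs ? (std::fabs(gA[i] * (v[i] - EA)) + std::fabs(gG[i] * (v[i] - EG)))
                                 : Isyn;
        lfp(k, t - transient_steps) += contrib;
      }

      const double C = pC[i], gL = pgL[i], EL = pEL[i], a = pa[i],
                   b = pb[i], DT = pDT[i], tauw = ptauw[i], vth = pvth[i],
                   vpeak = pvpeak[i], vreset = pvreset[i], Ibias = pI[i];

      unsigned char spiked = 0;
      if (refr[i] > 0) {
        --refr[i];
        v[i] = vreset;
        w[i] += dt * (a * (v[i] - EL) - w[i]) / tauw;
      } else {
        const double Inoise = -gN[i] * (v[i] - EA);  // depolarizing for v < E_AMPA
        const double Iext = do_stim ? A[i] * V * stim_phase : 0.0;
        const double ve = (v[i] < vpeak) ? v[i] : vpeak; // overflow guard
        const double dv = (-gL * (v[i] - EL) + gL * DT * std::exp((ve - vth) / DT)
                           - w[i] + Ibias + Inoise - Isyn + Iext) / C;
        const double dw = (a * (v[i] - EL) - w[i]) / tauw;
        v[i] += dt * dv;
        w[i] += dt * dw;
        if (!std::isfinite(v[i]) || !std::isfinite(w[i]))
          stop("integration failure (non-finite state) at t = %f ms, neuron %d",
               t_ms, i + 1);
        if (v[i] >= vpeak) {
          spiked = 1;
          v[i] = vreset;
          w[i] += b;
          refr[i] = tref_steps[i];
          sp_neuron.push_back(i + 1);
          sp_time.push_back(t_ms);
          if (is_exc[i]) ++Ebuf[(size_t)k * L + slot];
          else           ++Ibuf[(size_t)k * L + slot];
        }
      }
      selfbuf[(size_t)i * Ls + slot_s] = spiked;
    }
  }

  return List::create(_["spike_neuron"] = wrap(sp_neuron),
                      _["spike_time"] = wrap(sp_time),
                      _["lfp"] = lfp);
}
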