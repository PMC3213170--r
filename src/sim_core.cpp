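#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hybrid integrator for a conductance-based leaky integrate-and-fire network
// with Tsodyks-Markram short-term plasticity.
//
// Continuous dynamics (membrane potential) advance with fixed-step RK4 at dt,
// holding the synaptic conductances constant within a step; synaptic activity
// s, utilization u and resources x relax exactly (exponential factors) between
// spikes; spikes are detected after each step, timestamped at step end, and
// trigger the discrete plasticity update
//   u <- u + U*(1-u);  s_peak <- u*x;  x <- x - u*x
// (constant synapses: s_peak = 1).  Per-step Gaussian noise of standard
// deviation noise_sigma*sqrt(dt) is added to V (Euler-Maruyama convention).
//
// Synaptic activity is a presynaptic-neuron-level quantity (one value per
// neuron and synapse kind, shared by all efferent synapses of that kind);
// transmission delays are per synapse, quantized to integration steps, and
// served from a ring buffer of s history.

// [[Rcpp::export]]
List sim_network_cpp(IntegerVector pop_size,
                     LogicalVector pop_exc,
                     NumericMatrix npar,   // npop x 9: Cm,gL,VL,Vth,Vreset,tref,VE,VI,bias
                     List classes,         // each: post_pop, kind (0F,1D,2C,3I), w, pre, delay
                     NumericMatrix gextE,  // n_steps x npop
                     NumericMatrix gextI,  // n_steps x npop
                     NumericVector plast,  // U,tau_uF,tau_xF,tau_uD,tau_xD,tau_sE,tau_sI
                     double dt, int n_steps, int record_every,
                     double noise_sigma, bool freeze_plasticity) {
  const int npop = pop_size.size();
  int n_total = 0;
  std::vector<int> offset(npop);
  for (int p = 0; p < npop; ++p) { offset[p] = n_total; n_total += pop_size[p]; }

  std::vector<int> pop_of(n_total);
  for (int p = 0; p < npop; ++p)
    for (int i = 0; i < pop_size[p]; ++i) pop_of[offset[p] + i] = p;

  const double U      = plast["U"];
  const double tau_uF = plast["tau_uF"], tau_xF = plast["tau_xF"];
  const double tau_uD = plast["tau_uD"], tau_xD = plast["tau_xD"];
  const double tau_sE = plast["tau_sE"], tau_sI = plast["tau_sI"];
  const double dec_sE = std::exp(-dt / tau_sE), dec_sI = std::exp(-dt / tau_sI);
  const double dec_uF = std::exp(-dt / tau_uF), dec_xF = std::exp(-dt / tau_xF);
  const double dec_uD = std::exp(-dt / tau_uD), dec_xD = std::exp(-dt / tau_xD);

  // state
  std::vector<double> V(n_total), refrac(n_total, 0.0);
  std::vector<double> sF(n_total, 0.0), sD(n_total, 0.0), sC(n_total, 0.0);
  std::vector<double> uF(n_total, U), xF(n_total, 1.0), uD(n_total, U), xD(n_total, 1.0);
  for (int i = 0; i < n_total; ++i) V[i] = npar(pop_of[i], 2); // start at leak reversal

  // delay ring buffers, one per synapse kind actually addressed by classes
  int max_delay = 1;
  const int ncls = classes.size();
  std::vector<IntegerMatrix> cls_pre, cls_dly;
  std::vector<int> cls_post(ncls), cls_kind(ncls);
  std::vector<double> cls_w(ncls);
  for (int c = 0; c < ncls; ++c) {
    List cl = classes[c];
    cls_post[c] = as<int>(cl["post_pop"]);
    cls_kind[c] = as<int>(cl["kind"]);
    cls_w[c]    = as<double>(cl["w"]);
    cls_pre.push_back(as<IntegerMatrix>(cl["pre"]));
    cls_dly.push_back(as<IntegerMatrix>(cl["delay"]));
    IntegerMatrix d = cls_dly[c];
    for (int k = 0; k < d.size(); ++k) {
      if (d[k] < 1) stop("synaptic delay below one integration step");
      if (d[k] > max_delay) max_delay = d[k];
    }
  }
  const int H = max_delay + 1;
  // hist[kind][neuron*H + slot]
  std::vector<std::vector<double> > hist(4, std::vector<double>((size_t)n_total * H, 0.0));

  // recording
  const int nrec = n_steps / record_every;
  NumericVector rec_time(nrec);
  NumericMatrix r_sF(nrec, npop), r_sD(nrec, npop), r_sC(nrec, npop),
                r_uF(nrec, npop), r_xF(nrec, npop), r_uD(nrec, npop), r_xD(nrec, npop),
                r_uxF(nrec, npop), r_uxD(nrec, npop), r_V(nrec, npop);
  std::vector<int> spike_step, spike_neuron;
  spike_step.reserve(1 << 16); spike_neuron.reserve(1 << 16);

  std::vector<double> gE(n_total), gI(n_total);
  RNGScope rngscope;

  for (int t = 0; t < n_steps; ++t) {
    const int t_idx = t % H;
    // ---- collect conductances from delayed synaptic activity ----
    for (int i = 0; i < n_total; ++i) {
      const int p = pop_of[i];
      gE[i] = npar(p, 8) + gextE(t, p);
      gI[i] = gextI(t, p);
    }
    for (int c = 0; c < ncls; ++c) {
      const IntegerMatrix& pre = cls_pre[c];
      const IntegerMatrix& dly = cls_dly[c];
      const int indeg = pre.nrow(), nposti = pre.ncol();
      const int po = offset[cls_post[c]];
      const double w = cls_w[c];
      const std::vector<double>& hb = hist[cls_kind[c]];
      const bool inh = (cls_kind[c] == 3);
      const int* prep = INTEGER(pre); const int* dlyp = INTEGER(dly);
      for (int pn = 0; pn < nposti; ++pn) {
        double acc = 0.0;
        const int base = pn * indeg;
        for (int k = 0; k < indeg; ++k) {
          int slot = t_idx - dlyp[base + k];
          if (slot < 0) slot += H;
          acc += hb[(size_t)prep[base + k] * H + slot];
        }
        if (inh) gI[po + pn] += w * acc; else gE[po + pn] += w * acc;
      }
    }
    // ---- membrane update (RK4 with conductances frozen), noise, threshold ----
    for (int i = 0; i < n_total; ++i) {
      const int p = pop_of[i];
      const double Cm = npar(p, 0), gL = npar(p, 1), VL = npar(p, 2),
                   Vth = npar(p, 3), Vre = npar(p, 4), tref = npar(p, 5),
                   VE = npar(p, 6), VI = npar(p, 7);
      if (refrac[i] > 0.0) {
        refrac[i] -= dt;
        V[i] = Vre;
        continue;
      }
      // Cm in nF, conductances in nS: Cm/g is in seconds, times are in ms
      const double Cms = Cm * 1000.0;
      const double a = (gL * VL + gE[i] * VE + gI[i] * VI) / Cms;
      const double b = (gL + gE[i] + gI[i]) / Cms;      // dV/dt = a - b*V
      const double v0 = V[i];
      const double k1 = a - b * v0;
      const double k2 = a - b * (v0 + 0.5 * dt * k1);
      const double k3 = a - b * (v0 + 0.5 * dt * k2);
      const double k4 = a - b * (v0 + dt * k3);
      double v = v0 + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (noise_sigma > 0.0) v += noise_sigma * std::sqrt(dt) * norm_rand();
      if (!std::isfinite(v)) stop("non-finite membrane potential at t = %f ms", (t + 1) * dt);
      if (v >= Vth) {
        spike_step.push_back(t);
        spike_neuron.push_back(i);
        v = Vre;
        refrac[i] = tref;
      }
      V[i] = v;
    }
    // ---- relax synaptic variables over the step ----
    for (int i = 0; i < n_total; ++i) {
      if (pop_exc[pop_of[i]]) {
        sF[i] *= dec_sE; sD[i] *= dec_sE; sC[i] *= dec_sE;
        if (!freeze_plasticity) {
          uF[i] = U + (uF[i] - U) * dec_uF;
          xF[i] = 1.0 + (xF[i] - 1.0) * dec_xF;
          uD[i] = U + (uD[i] - U) * dec_uD;
          xD[i] = 1.0 + (xD[i] - 1.0) * dec_xD;
        }
      } else {
        sC[i] *= dec_sI;
      }
    }
    // ---- discrete plasticity update for neurons that just spiked ----
    for (size_t m = spike_step.size(); m-- > 0;) {
      if (spike_step[m] != t) break;
      const int i = spike_neuron[m];
      if (pop_exc[pop_of[i]]) {
        if (freeze_plasticity) {
          sF[i] = U; sD[i] = U;         // resting peak u*x = U*1
        } else {
          uF[i] += U * (1.0 - uF[i]);
          sF[i] = uF[i] * xF[i];
          xF[i] -= sF[i];
          uD[i] += U * (1.0 - uD[i]);
          sD[i] = uD[i] * xD[i];
          xD[i] -= sD[i];
        }
        sC[i] = 1.0;
      } else {
        sC[i] = 1.0;                    // interneuron constant synapse
      }
    }
    // ---- push new s values into the ring buffers ----
    const int w_idx = (t + 1) % H;
    for (int i = 0; i < n_total; ++i) {
      const size_t base = (size_t)i * H + w_idx;
      if (pop_exc[pop_of[i]]) {
        hist[0][base] = sF[i];
        hist[1][base] = sD[i];
        hist[2][base] = sC[i];
      } else {
        hist[3][base] = sC[i];
      }
    }
    // ---- record population means ----
    if ((t + 1) % record_every == 0) {
      const int r = (t + 1) / record_every - 1;
      rec_time[r] = (t + 1) * dt;
      for (int p = 0; p < npop; ++p) {
        double msF = 0, msD = 0, msC = 0, muF = 0, mxF = 0, muD = 0, mxD = 0,
               muxF = 0, muxD = 0, mV = 0;
        for (int i = offset[p]; i < offset[p] + pop_size[p]; ++i) {
          msF += sF[i]; msD += sD[i]; msC += sC[i];
          muF += uF[i]; mxF += xF[i]; muD += uD[i]; mxD += xD[i];
          muxF += uF[i] * xF[i]; muxD += uD[i] * xD[i];
          mV += V[i];
        }
        const double n = pop_size[p];
        r_sF(r, p) = msF / n; r_sD(r, p) = msD / n; r_sC(r, p) = msC / n;
        r_uF(r, p) = muF / n; r_xF(r, p) = mxF / n;
        r_uD(r, p) = muD / n; r_xD(r, p) = mxD / n;
        r_uxF(r, p) = muxF / n; r_uxD(r, p) = muxD / n;
        r_V(r, p) = mV / n;
      }
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_step"] = wrap(spike_step),
    _["spike_neuron"] = wrap(spike_neuron),
    _["time"] = rec_time,
    _["sF"] = r_sF, _["sD"] = r_sD, _["sC"] = r_sC,
    _["uF"] = r_uF, _["xF"] = r_xF, _["uD"] = r_uD, _["xD"] = r_xD,
    _["uxF"] = r_uxF, _["uxD"] = r_uxD, _["V"] = r_V);
}
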