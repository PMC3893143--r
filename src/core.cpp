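#include <Rcpp.h>
using namespace Rcpp;

// Event-driven triplet/pair/anti STDP on two prescribed spike trains.
// Traces decay analytically between events, so the result is exact for the
// given spike times (no integration-step error). Coincident events are
// processed pre-first, matching the network simulator's convention.
//
// rule: named vector with a2p, a2m, a3p, a3m, tau_p, tau_m, tau_x, tau_y
//       (ms), sign_pre, sign_post, lambda.
// [[Rcpp::export]]
double cpp_stdp_trains(NumericVector pre, NumericVector post,
                       NumericVector rule, double w0, double wmax) {
  const double a2p = rule["a2p"], a2m = rule["a2m"];
  const double a3p = rule["a3p"], a3m = rule["a3m"];
  const double tp = rule["tau_p"], tm = rule["tau_m"];
  const double tx = rule["tau_x"], ty = rule["tau_y"];
  const double sp = rule["sign_pre"], so = rule["sign_post"];
  const double lam = rule["lambda"];

  double r1 = 0, r2 = 0, o1 = 0, o2 = 0; // pre: r1,r2; post: o1,o2
  double t_r = 0, t_o = 0;               // last-update times
  double w = w0;
  R_xlen_t i = 0, j = 0;
  const R_xlen_t np = pre.size(), nq = post.size();
  while (i < np || j < nq) {
    // exact coincidence: depression-side and potentiation-side updates are
    // both computed from the pre-spike trace values, then all detectors
    // increment (same convention as the network engine)
    if (i < np && j < nq && pre[i] == post[j]) {
      const double t = pre[i++];
      ++j;
      r1 *= std::exp(-(t - t_r) / tp);
      r2 *= std::exp(-(t - t_r) / tx);
      t_r = t;
      o1 *= std::exp(-(t - t_o) / tm);
      o2 *= std::exp(-(t - t_o) / ty);
      t_o = t;
      w += sp * lam * o1 * (a2m + a3m * r2);
      w += so * lam * r1 * (a2p + a3p * o2);
      r1 += 1.0;
      r2 += 1.0;
      o1 += 1.0;
      o2 += 1.0;
      if (w < 0) w = 0;
      if (w > wmax) w = wmax;
      continue;
    }
    bool take_pre;
    if (i >= np) take_pre = false;
    else if (j >= nq) take_pre = true;
    else take_pre = pre[i] < post[j];
    if (take_pre) {
      const double t = pre[i++];
      r1 *= std::exp(-(t - t_r) / tp);
      r2 *= std::exp(-(t - t_r) / tx);
      t_r = t;
      o1 *= std::exp(-(t - t_o) / tm);
      o2 *= std::exp(-(t - t_o) / ty);
      t_o = t;
      w += sp * lam * o1 * (a2m + a3m * r2); // r2 just before the spike
      r1 += 1.0;
      r2 += 1.0;
    } else {
      const double t = post[j++];
      r1 *= std::exp(-(t - t_r) / tp);
      r2 *= std::exp(-(t - t_r) / tx);
      t_r = t;
      o1 *= std::exp(-(t - t_o) / tm);
      o2 *= std::exp(-(t - t_o) / ty);
      t_o = t;
      w += so * lam * r1 * (a2p + a3p * o2); // o2 just before the spike
      o1 += 1.0;
      o2 += 1.0;
    }
    if (w < 0) w = 0;
    if (w > wmax) w = wmax;
  }
  return w;
}

// Full network simulator: adaptive exponential IF neurons, current-based
// synapses with instantaneous rise / exponential decay, per-synapse
// Tsodyks-Markram short-term dynamics (lazy analytic relaxation between
// presynaptic spikes) and the triplet STDP rule on the scaling matrix w.
//
// Orientation: element [i, j] of C, A, w, kindF refers to the synapse from
// presynaptic neuron i (row) to postsynaptic neuron j (column).
//
// neuron: Cm, gL, EL, Vr, DT, VT, Vceil, tref, a, b, tauw  (pF, nS, mV, ms,
//         nS, pA, ms); rule as in cpp_stdp_trains; sd: U_D, taurec_D,
//         taufac_D, U_F, taurec_F, taufac_F, tausyn (ms).
// stim: baseline (pA, per neuron), extra (pA, per neuron), wave_on,
//       wave_amp (pA), wave_dwell (ms), wave_sigma (index units), wave_wrap,
//       noise_on, noise_mu (pA, per neuron), noise_sd (pA), noise_tau (ms).
// Noise draws use R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate_network(IntegerMatrix C, NumericMatrix A, NumericMatrix w,
                          LogicalMatrix kindF, NumericVector neuron,
                          NumericVector rule, NumericVector sd,
                          NumericVector baseline, NumericVector extra,
                          bool wave_on, double wave_amp, double wave_dwell,
                          double wave_sigma, bool wave_wrap,
                          bool noise_on, NumericVector noise_mu,
                          double noise_sd, double noise_tau,
                          double duration, double dt, double snapshot_every,
                          bool record_spikes) {
  const int N = C.nrow();
  const double Cm = neuron["Cm"], gL = neuron["gL"], EL = neuron["EL"],
               Vr = neuron["Vr"], DT = neuron["DT"], VT = neuron["VT"],
               Vceil = neuron["Vceil"], tref = neuron["tref"],
               aa = neuron["a"], bb = neuron["b"], tauw = neuron["tauw"];
  const double a2p = rule["a2p"], a2m = rule["a2m"], a3p = rule["a3p"],
               a3m = rule["a3m"], tp = rule["tau_p"], tm = rule["tau_m"],
               tx = rule["tau_x"], ty = rule["tau_y"],
               sgp = rule["sign_pre"], sgo = rule["sign_post"],
               lam = rule["lambda"], wmax = rule["wmax"];
  const double UD = sd["U_D"], trD = sd["taurec_D"], tfD = sd["taufac_D"],
               UF = sd["U_F"], trF = sd["taurec_F"], tfF = sd["taufac_F"],
               tausyn = sd["tausyn"];

  std::vector<double> V(N, EL), wad(N, 0.0), refr(N, 0.0), psc(N, 0.0);
  std::vector<double> r1(N, 0.0), r2(N, 0.0), o1(N, 0.0), o2(N, 0.0),
      t_tr(N, 0.0);
  NumericMatrix u(N, N), x(N, N);
  std::vector<double> tlastpre(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      u(i, j) = kindF(i, j) ? UF : UD;
      x(i, j) = 1.0;
    }
  std::vector<double> Inoise(N, 0.0);
  if (noise_on)
    for (int i = 0; i < N; ++i) Inoise[i] = noise_mu[i];

  const double psc_decay = std::exp(-dt / tausyn);
  const double n_rho = noise_on ? std::exp(-dt / noise_tau) : 0.0;
  const double n_sd1 = noise_on ? noise_sd * std::sqrt(1.0 - n_rho * n_rho)
                                : 0.0;
  const long nsteps = (long)std::floor(duration / dt + 0.5);
  const long snap_steps =
      snapshot_every > 0 ? (long)std::floor(snapshot_every / dt + 0.5) : 0;

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  List snaps;
  std::vector<double> snap_times;
  std::vector<int> spikers;
  spikers.reserve(N);

  RNGScope scope;
  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    // wave position: one unit per dwell interval, wrapping over indices
    double centre = 0.0;
    if (wave_on)
      centre = (double)((long)std::floor(t / wave_dwell) % (long)N);
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      double I = baseline[i] + extra[i] + psc[i];
      if (wave_on) {
        double d = std::fabs((double)i - centre);
        if (wave_wrap && d > N / 2.0) d = N - d;
        I += wave_amp * std::exp(-0.5 * d * d / (wave_sigma * wave_sigma));
      }
      if (noise_on) {
        Inoise[i] = noise_mu[i] + (Inoise[i] - noise_mu[i]) * n_rho +
                    n_sd1 * R::norm_rand();
        I += Inoise[i];
      }
      if (refr[i] > 0) {
        refr[i] -= dt;
        V[i] = Vr; // clamped during absolute refractoriness
        wad[i] += dt * (aa * (Vr - EL) - wad[i]) / tauw;
        continue;
      }
      double ex = (V[i] - VT) / DT;
      if (ex > 16.0) ex = 16.0; // numerical ceiling on the spike upstroke
      const double dV =
          dt * (-gL * (V[i] - EL) + gL * DT * std::exp(ex) - wad[i] + I) / Cm;
      wad[i] += dt * (aa * (V[i] - EL) - wad[i]) / tauw;
      V[i] += dV;
      if (V[i] >= Vceil) spikers.push_back(i);
    }
    for (int i = 0; i < N; ++i) psc[i] *= psc_decay;

    if (!spikers.empty()) {
      // decay the four rate detectors of every neuron touched this step
      for (int s : spikers) {
        for (int j = 0; j < N; ++j) {
          if (j != s && C(s, j) == 0 && C(j, s) == 0) continue;
          const double el = t - t_tr[j];
          if (el > 0) {
            r1[j] *= std::exp(-el / tp);
            r2[j] *= std::exp(-el / tx);
            o1[j] *= std::exp(-el / tm);
            o2[j] *= std::exp(-el / ty);
            t_tr[j] = t;
          }
        }
      }
      if (lam != 0) {
        // presynaptic-role (depression-side) updates first, ...
        for (int s : spikers)
          for (int j = 0; j < N; ++j)
            if (C(s, j)) {
              double ww = w(s, j) + sgp * lam * o1[j] * (a2m + a3m * r2[s]);
              w(s, j) = ww < 0 ? 0 : (ww > wmax ? wmax : ww);
            }
        // ... then postsynaptic-role (potentiation-side) updates
        for (int s : spikers)
          for (int j = 0; j < N; ++j)
            if (C(j, s)) {
              double ww = w(j, s) + sgo * lam * r1[j] * (a2p + a3p * o2[s]);
              w(j, s) = ww < 0 ? 0 : (ww > wmax ? wmax : ww);
            }
      }
      // ... then unit increments of the spiking neurons' detectors
      for (int s : spikers) {
        r1[s] += 1.0;
        r2[s] += 1.0;
        o1[s] += 1.0;
        o2[s] += 1.0;
      }
      // short-term dynamics and PSC kicks (targets feel them next step)
      for (int s : spikers) {
        const double el = t - tlastpre[s];
        const double efD = std::exp(-el / tfD), erD = std::exp(-el / trD);
        const double efF = std::exp(-el / tfF), erF = std::exp(-el / trF);
        for (int j = 0; j < N; ++j)
          if (C(s, j)) {
            const bool F = kindF(s, j);
            const double U = F ? UF : UD;
            double uu = U + (u(s, j) - U) * (F ? efF : efD);
            double xx = 1.0 + (x(s, j) - 1.0) * (F ? erF : erD);
            uu += U * (1.0 - uu); // facilitation applied first, ...
            const double rel = uu * xx;
            xx -= rel; // ... then depression uses the updated u
            u(s, j) = uu;
            x(s, j) = xx;
            psc[j] += w(s, j) * A(s, j) * rel;
          }
        tlastpre[s] = t;
        V[s] = Vr;
        wad[s] += bb;
        refr[s] = tref;
        if (record_spikes) {
          sp_t.push_back(t);
          sp_id.push_back(s + 1);
        }
      }
    }
    if (snap_steps > 0 && (step + 1) % snap_steps == 0) {
      snaps.push_back(clone(w));
      snap_times.push_back(t + dt);
    }
    if (!std::isfinite(V[0]))
      stop("non-finite membrane potential at t = %f ms", t);
  }
  return List::create(_["spike_time"] = wrap(sp_t),
                      _["spike_id"] = wrap(sp_id), _["w_final"] = w,
                      _["snapshots"] = snaps,
                      _["snapshot_times"] = wrap(snap_times));
}
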