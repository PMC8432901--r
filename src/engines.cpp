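#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// shared helpers -----------------------------------------------------------

static inline double act(double s, double beta) {
  return s > 0.0 ? beta * std::tanh(s) : 0.0;
}

struct StatAcc {
  // time-weighted stationary accumulators over [t_burn, t_max)
  double T = 0.0, iS = 0.0, iS2 = 0.0, iD = 0.0, iD2 = 0.0,
         iR = 0.0, iR2 = 0.0;
  double spikes = 0.0;
  void add(double w, double Sig, double Del, double R) {
    if (w <= 0.0) return;
    T += w;
    iS += w * Sig; iS2 += w * Sig * Sig;
    iD += w * Del; iD2 += w * Del * Del;
    iR += w * R;   iR2 += w * R * R;
  }
};

// Exact (Gillespie) simulation of the lumped (k, l) Markov chain.
// Exchangeability of the all-to-all identical neurons reduces the 2N-unit
// process to four channels: E-deactivation (rate alpha*k), E-activation
// ((N-k) f(s)), I-deactivation (alpha*l), I-activation ((N-l) f(s)).
// [[Rcpp::export]]
List gillespie_agg_cpp(double alpha, double beta, double wE, double wI,
                       double h, double N, double t_max, double t_burn,
                       double k0, double l0, double dt_sample,
                       bool record_series, double delta_bin, bool record_bins,
                       bool record_events, double max_events,
                       bool record_avalanches, double theta) {
  double k = k0, l = l0, t = 0.0;
  StatAcc acc;

  R_xlen_t n_s = 0;
  NumericVector ks(0), ls(0);
  if (record_series) {
    n_s = (R_xlen_t)std::floor((t_max - t_burn) / dt_sample) + 1;
    ks = NumericVector(n_s); ls = NumericVector(n_s);
  }
  R_xlen_t js = 0; // next sample index; sample times t_burn + js*dt_sample

  std::vector<double> bins;
  if (record_bins)
    bins.assign((size_t)std::ceil((t_max - t_burn) / delta_bin) + 1, 0.0);

  std::vector<double> ev_t; std::vector<int> ev_pop, ev_d;
  bool ev_overflow = false;

  // exact threshold-excursion avalanches: R(t) is piecewise constant
  // between events, so intervals with R > theta are tracked exactly
  std::vector<double> av_dur, av_int, av_exc, av_spk;
  bool in_av = false;
  double av_t0 = 0.0, av_i = 0.0, av_e = 0.0, av_s = 0.0;

  double n_events = 0.0;
  bool absorbed = false;
  bool pending_spike = false;

  for (;;) {
    double s = (wE * k - wI * l) / N + h;
    double fs = act(s, beta);
    double a1 = alpha * k, a2 = (N - k) * fs, a3 = alpha * l,
           a4 = (N - l) * fs;
    double r = a1 + a2 + a3 + a4;
    double Sig = (k + l) / (2.0 * N), Del = (k - l) / (2.0 * N);
    double R = (1.0 - Sig) * fs;

    if (record_avalanches) {
      double a = std::max(t, t_burn);
      if (a < t_max) {
        if (R > theta) {
          if (!in_av) { in_av = true; av_t0 = a; av_i = av_e = av_s = 0.0; }
          if (pending_spike) av_s += 1.0;
        } else if (in_av) {
          av_dur.push_back(a - av_t0); av_int.push_back(av_i);
          av_exc.push_back(av_e); av_spk.push_back(av_s);
          in_av = false;
        }
      }
      pending_spike = false;
    }

    if (r <= 0.0) { // absorbing quiescent state (possible only for h = 0)
      absorbed = true;
      acc.add(t_max - std::max(t, t_burn), Sig, Del, R);
      while (js < n_s) { ks[js] = k; ls[js] = l; ++js; }
      break;
    }

    double dt = exp_rand() / r;
    double t_next = t + dt;
    if (t_next >= t_max) {
      acc.add(t_max - std::max(t, t_burn), Sig, Del, R);
      while (js < n_s) { ks[js] = k; ls[js] = l; ++js; }
      break;  // an avalanche still open here is censored and dropped
    }
    acc.add(std::min(t_next, t_max) - std::max(t, t_burn), Sig, Del, R);
    if (record_avalanches && in_av && R > theta) {
      double w = std::min(t_next, t_max) - std::max(t, t_burn);
      if (w > 0) { av_i += R * w; av_e += (R - theta) * w; }
    }
    while (js < n_s && t_burn + js * dt_sample < t_next) {
      ks[js] = k; ls[js] = l; ++js;
    }

    double u = unif_rand() * r;
    int pop, d;
    if (u < a1)                { k -= 1; pop = 0; d = -1; }
    else if (u < a1 + a2)      { k += 1; pop = 0; d = +1; }
    else if (u < a1 + a2 + a3) { l -= 1; pop = 1; d = -1; }
    else                       { l += 1; pop = 1; d = +1; }
    n_events += 1.0;

    if (t_next >= t_burn) {
      if (d > 0) {
        acc.spikes += 1.0;
        pending_spike = true;
        if (record_bins)
          bins[(size_t)std::floor((t_next - t_burn) / delta_bin)] += 1.0;
      }
      if (record_events && !ev_overflow) {
        if ((double)ev_t.size() >= max_events) ev_overflow = true;
        else { ev_t.push_back(t_next); ev_pop.push_back(pop); ev_d.push_back(d); }
      }
    }
    t = t_next;
    if (((long long)n_events & 0xFFFFF) == 0) checkUserInterrupt();
  }

  List out = List::create(
    _["k"] = ks, _["l"] = ls,
    _["T_stat"] = acc.T, _["int_S"] = acc.iS, _["int_S2"] = acc.iS2,
    _["int_D"] = acc.iD, _["int_D2"] = acc.iD2,
    _["int_R"] = acc.iR, _["int_R2"] = acc.iR2,
    _["spikes"] = acc.spikes, _["n_events"] = n_events,
    _["k_final"] = k, _["l_final"] = l, _["absorbed"] = absorbed,
    _["event_overflow"] = ev_overflow);
  if (record_bins) out["bin_counts"] = NumericVector(bins.begin(), bins.end());
  if (record_avalanches) {
    out["av_duration"] = NumericVector(av_dur.begin(), av_dur.end());
    out["av_int_R"] = NumericVector(av_int.begin(), av_int.end());
    out["av_int_excess"] = NumericVector(av_exc.begin(), av_exc.end());
    out["av_spikes"] = NumericVector(av_spk.begin(), av_spk.end());
    out["av_theta"] = theta;
  }
  if (record_events) {
    out["ev_t"] = NumericVector(ev_t.begin(), ev_t.end());
    out["ev_pop"] = IntegerVector(ev_pop.begin(), ev_pop.end());
    out["ev_delta"] = IntegerVector(ev_d.begin(), ev_d.end());
  }
  return out;
}

// Literal per-neuron Gillespie: every one of the 2N two-state units carries
// its own rate (alpha if active, f(s of its population) if quiescent); the
// next unit to flip is chosen with probability r_i / sum(r). O(N) per event;
// retained for fidelity tests against the aggregated engine.
// [[Rcpp::export]]
List gillespie_per_neuron_cpp(double alpha, double beta, double wE, double wI,
                              double h, int N, double t_max, double t_burn,
                              int k0, int l0, bool record_events,
                              double max_events) {
  std::vector<int> a(2 * N, 0);          // 0..N-1 excitatory, N..2N-1 inhibitory
  for (int i = 0; i < k0; ++i) a[i] = 1;
  for (int i = 0; i < l0; ++i) a[N + i] = 1;
  int k = k0, l = l0;
  double t = 0.0, n_events = 0.0;
  StatAcc acc;
  std::vector<double> ev_t; std::vector<int> ev_pop, ev_d;
  bool ev_overflow = false, absorbed = false;

  std::vector<double> ri(2 * N);
  for (;;) {
    double s = (wE * (double)k - wI * (double)l) / N + h;
    double fs = act(s, beta);
    double r = 0.0;
    for (int i = 0; i < 2 * N; ++i) {
      ri[i] = a[i] ? alpha : fs;
      r += ri[i];
    }
    double Sig = (k + l) / (2.0 * N), Del = (k - l) / (2.0 * N);
    double R = (1.0 - Sig) * fs;
    if (r <= 0.0) {
      absorbed = true;
      acc.add(t_max - std::max(t, t_burn), Sig, Del, R);
      break;
    }
    double dt = exp_rand() / r;
    double t_next = t + dt;
    if (t_next >= t_max) {
      acc.add(t_max - std::max(t, t_burn), Sig, Del, R);
      break;
    }
    acc.add(t_next - std::max(t, t_burn), Sig, Del, R);
    double u = unif_rand() * r, csum = 0.0;
    int pick = 2 * N - 1;
    for (int i = 0; i < 2 * N; ++i) {
      csum += ri[i];
      if (u < csum) { pick = i; break; }
    }
    int pop = pick < N ? 0 : 1;
    int d = a[pick] ? -1 : +1;
    a[pick] = 1 - a[pick];
    if (pop == 0) k += d; else l += d;
    n_events += 1.0;
    if (t_next >= t_burn) {
      if (d > 0) acc.spikes += 1.0;
      if (record_events && !ev_overflow) {
        if ((double)ev_t.size() >= max_events) ev_overflow = true;
        else { ev_t.push_back(t_next); ev_pop.push_back(pop); ev_d.push_back(d); }
      }
    }
    t = t_next;
    if (((long long)n_events & 0xFFFF) == 0) checkUserInterrupt();
  }
  List out = List::create(
    _["T_stat"] = acc.T, _["int_S"] = acc.iS, _["int_S2"] = acc.iS2,
    _["int_D"] = acc.iD, _["int_D2"] = acc.iD2,
    _["int_R"] = acc.iR, _["int_R2"] = acc.iR2,
    _["spikes"] = acc.spikes, _["n_events"] = n_events,
    _["k_final"] = (double)k, _["l_final"] = (double)l,
    _["absorbed"] = absorbed, _["event_overflow"] = ev_overflow);
  if (record_events) {
    out["ev_t"] = NumericVector(ev_t.begin(), ev_t.end());
    out["ev_pop"] = IntegerVector(ev_pop.begin(), ev_pop.end());
    out["ev_delta"] = IntegerVector(ev_d.begin(), ev_d.end());
  }
  return out;
}

// Euler-Maruyama integration of the nonlinear chemical Langevin equations
// on continuous (k, l): drift -alpha*k + f(s)(N - k), noise amplitude
// sqrt(alpha*k + f(s)(N - k)) (clamped below at 0 before the square root);
// k, l clamped to [0, N] after each step.
// [[Rcpp::export]]
List langevin_cpp(double alpha, double beta, double wE, double wI, double h,
                  double N, double t_max, double dt, double t_burn,
                  double k0, double l0, double dt_sample, bool record_series,
                  bool noise) {
  double k = k0, l = l0;
  long long n_steps = (long long)std::llround(t_max / dt);
  long long m = (long long)std::max(1.0, std::round(dt_sample / dt));
  long long burn_steps = (long long)std::llround(t_burn / dt);
  StatAcc acc;
  R_xlen_t n_s = 0, js = 0;
  NumericVector ks(0), ls(0);
  if (record_series) {
    n_s = (n_steps - burn_steps) / m + 1;
    ks = NumericVector(n_s); ls = NumericVector(n_s);
  }
  double sdt = std::sqrt(dt);
  for (long long step = 0; step <= n_steps; ++step) {
    double s = (wE * k - wI * l) / N + h;
    double fs = act(s, beta);
    double Sig = (k + l) / (2.0 * N), Del = (k - l) / (2.0 * N);
    double R = (1.0 - Sig) * fs;
    if (step >= burn_steps) {
      if (record_series && js < n_s && (step - burn_steps) % m == 0) {
        ks[js] = k; ls[js] = l; ++js;
      }
      if (step < n_steps) acc.add(dt, Sig, Del, R);
    }
    if (step == n_steps) break;
    double dk = (-alpha * k + fs * (N - k)) * dt;
    double dl = (-alpha * l + fs * (N - l)) * dt;
    if (noise) {
      double vk = alpha * k + fs * (N - k);
      double vl = alpha * l + fs * (N - l);
      dk += std::sqrt(vk > 0.0 ? vk : 0.0) * sdt * norm_rand();
      dl += std::sqrt(vl > 0.0 ? vl : 0.0) * sdt * norm_rand();
    }
    k += dk; l += dl;
    if (k < 0.0) k = 0.0; else if (k > N) k = N;
    if (l < 0.0) l = 0.0; else if (l > N) l = N;
    if ((step & 0xFFFFF) == 0) checkUserInterrupt();
  }
  return List::create(
    _["k"] = ks, _["l"] = ls,
    _["T_stat"] = acc.T, _["int_S"] = acc.iS, _["int_S2"] = acc.iS2,
    _["int_D"] = acc.iD, _["int_D2"] = acc.iD2,
    _["int_R"] = acc.iR, _["int_R2"] = acc.iR2,
    _["k_final"] = k, _["l_final"] = l);
}
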